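# Per-score patient counts by need-of-intervention status (Y/N) for the three
# pre-endoscopy risk scores, 590-patient emergency-department UGIB cohort.
# Column totals per system: 590 patients = 280 intervention-positive + 310
# intervention-negative.
# corrected=1 flags the single cell that deviates from the published print:
# the GBS score-9 negative count is 66, not the printed 55 — forced jointly by
# the printed row total (70 patients at GBS 9) and the printed column total
# (310 intervention-negative); two independent marginal constraints beat one
# cell (marginal-consistency oracle).
system,score,n_pos,n_neg,corrected
gbs,5,1,1,0
gbs,6,27,40,0
gbs,7,26,15,0
gbs,8,9,2,0
gbs,9,4,66,1
gbs,10,21,65,0
gbs,11,34,10,0
gbs,12,19,38,0
gbs,13,55,41,0
gbs,14,13,30,0
gbs,15,31,1,0
gbs,16,6,1,0
gbs,17,31,0,0
gbs,18,3,0,0
mgbs,5,1,2,0
mgbs,6,28,40,0
mgbs,7,27,14,0
mgbs,8,12,13,0
mgbs,9,5,74,0
mgbs,10,33,54,0
mgbs,11,52,2,0
mgbs,12,4,68,0
mgbs,13,80,42,0
mgbs,14,19,1,0
mgbs,15,17,0,0
mgbs,16,2,0,0
pre_e_rs,0,24,46,0
pre_e_rs,1,80,16,0
pre_e_rs,2,77,234,0
pre_e_rs,3,29,9,0
pre_e_rs,4,35,4,0
pre_e_rs,5,22,0,0
pre_e_rs,6,1,0,0
pre_e_rs,7,12,1,0
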