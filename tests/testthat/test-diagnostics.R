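test_that("threshold metrics follow the strictly-greater rule", {
  g <- load_table4("pre_e_rs")
  # cutoff below every observed score: everything called positive
  m <- metrics_at_cutoff(g, -1)
  expect_equal(m$sens, 100)
  expect_equal(m$spec, 0)
  # direct count at cutoff 4: 35/280 positives and 309/310 negatives above/below
  m4 <- metrics_at_cutoff(g, 4)
  expect_equal(m4$sens, 100 * 35 / 280)
  expect_equal(m4$spec, 100 * 309 / 310)
  # cutoff at the maximum: nothing called positive, PPV undefined
  mmax <- metrics_at_cutoff(g, max(g$score))
  expect_equal(mmax$sens, 0)
  expect_true(is.na(mmax$ppv))
  expect_equal(mmax$spec, 100)
})

test_that("reconstructed mortality distribution reproduces the published rows", {
  mort <- reconstruct_mortality_by_score()
  m <- metrics_at_cutoff(mort, 4)
  expect_equal(round(m$sens, 2), 88.0)
  expect_equal(round(m$spec, 2), 97.52)
  expect_equal(round(m$ppv, 1), 61.1)
  expect_equal(round(m$npv, 1), 99.5)
})

test_that("threshold_table vectorizes and is monotone in the cutoff", {
  expect_identical(nrow(threshold_table(load_table4("gbs"), integer())), 0L)
  tab <- threshold_table(load_table4("mgbs"), 4:16)
  expect_identical(nrow(tab), 13L)
  expect_true(all(diff(tab$sens) <= 0))
  expect_true(all(diff(tab$spec) >= 0))
})

test_that("reconstructed 2x2 tables are Bayes-consistent with prevalence", {
  for (g in list(load_table4("gbs"), load_table4("mgbs"),
                 reconstruct_mortality_by_score())) {
    pi <- sum(g$n_pos) / sum(g$n_pos + g$n_neg)
    tab <- threshold_table(g, g$score[-nrow(g)])
    se <- tab$sens / 100
    sp <- tab$spec / 100
    expect_equal(tab$ppv / 100, se * pi / (se * pi + (1 - sp) * (1 - pi)),
                 tolerance = 1e-12)
  }
})

test_that("Youden selection matches the published optimal cutoffs", {
  expect_identical(youden_optimal(load_table5("gbs", "intervention")), 9L)
  expect_identical(youden_optimal(load_table5("mgbs", "intervention")), 9L)
  expect_identical(youden_optimal(load_table5("pre_e_rs", "death30")), 4L)
  one <- data.frame(cutoff = 3L, sens = 50, spec = 50)
  expect_identical(youden_optimal(one), 3L)
  # ties break toward the smaller cutoff
  tie <- data.frame(cutoff = c(2L, 5L), sens = c(80, 70), spec = c(60, 70))
  expect_identical(youden_optimal(tie), 2L)
  expect_error(youden_optimal(one[0, ]), "non-empty")
})

test_that("confusion reconstruction inverts printed sens/spec rows", {
  ct <- reconstruct_confusion(0.88, 0.9752, 25, 565)
  expect_identical(unclass(ct)[c("tp", "fp", "fn", "tn")],
                   list(tp = 22L, fp = 14L, fn = 3L, tn = 551L))
  ct2 <- reconstruct_confusion(0.7357, 0.8290, 280, 310)
  expect_identical(unclass(ct2)[c("tp", "fp", "fn", "tn")],
                   list(tp = 206L, fp = 53L, fn = 74L, tn = 257L))
  perfect <- reconstruct_confusion(1, 1, 10, 20)
  expect_identical(unclass(perfect)[c("tp", "fp", "fn", "tn")],
                   list(tp = 10L, fp = 0L, fn = 0L, tn = 20L))
  expect_error(reconstruct_confusion(1.2, 0.5, 10, 10), "fractions")
})

test_that("Woolf odds ratio reproduces the published timing analysis", {
  res <- odds_ratio_woolf(12, 62, 9, 314)
  expect_equal(round(res$odds_ratio, 3), 6.753)
  expect_equal(round(res$ci95, 3), c(2.729, 16.712))
  expect_equal(round(res$chi2, 3), 21.675)
  expect_lt(res$p, 0.001)

  unit <- odds_ratio_woolf(1, 1, 1, 1)
  expect_equal(unit$odds_ratio, 1)
  expect_equal(log(unit$ci95[1]), -log(unit$ci95[2]), tolerance = 1e-12)

  swapped <- odds_ratio_woolf(9, 314, 12, 62)
  expect_equal(swapped$odds_ratio, 1 / 6.752688, tolerance = 1e-6)
  # log-CI width is invariant under transposition
  transposed <- odds_ratio_woolf(12, 9, 62, 314)
  expect_equal(diff(log(transposed$ci95)), diff(log(res$ci95)),
               tolerance = 1e-12)

  expect_error(odds_ratio_woolf(0, 5, 3, 7), "cells > 0")
})

test_that("uncorrected Pearson chi-square matches the published statistics", {
  expect_equal(round(pearson_chi2(12, 62, 9, 314)$chi2, 3), 21.675)
  expect_equal(round(pearson_chi2(12, 62, 9, 289)$chi2, 3), 19.380)
  # proportional rows carry no association
  expect_equal(pearson_chi2(10, 20, 5, 10)$chi2, 0, tolerance = 1e-12)
  expect_error(pearson_chi2(0, 0, 3, 7), "margins")
})

test_that("survivor-split search recovers the unprinted timing cells uniquely", {
  gbs <- derive_survivor_split(397, 12, 9, target_or = 6.753)
  expect_identical(gbs$fp, 62L)
  expect_identical(gbs$tn, 314L)
  mgbs <- derive_survivor_split(372, 12, 9, target_chi2 = 19.380)
  expect_identical(mgbs$fp, 62L)
  expect_identical(mgbs$tn, 289L)

  expect_error(derive_survivor_split(10, 6, 5, target_or = 2), "exceed")
  expect_error(derive_survivor_split(397, 12, 9, target_or = 5000), "no survivor")
  expect_error(derive_survivor_split(397, 12, 9), "exactly one")
  # equal death counts make the chi-square symmetric in the split, so any
  # interior target is matched twice: the search must refuse to pick
  sym_target <- pearson_chi2(1, 2, 1, 8)$chi2
  expect_error(derive_survivor_split(12, 1, 1, target_chi2 = sym_target),
               "ambiguous")
})
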