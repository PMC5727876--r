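test_that("mGBS band sums match hand-computed examples", {
  # all bands below the scoring range
  expect_identical(compute_mgbs(base_patient()), 0L)
  # maximal band points: pulse 1 + SBP 3 + BUN 6 + Hb 6
  expect_identical(
    compute_mgbs(base_patient(pulse = 110, sbp = 85, bun_mg_dl = 75, hb_g_dl = 9)),
    16L
  )
  # hand-sum: pulse 102 -> 1, SBP 105 -> 1, BUN 25 -> 3, Hb 11.5 male -> 3
  expect_identical(
    compute_mgbs(base_patient(pulse = 102, sbp = 105, bun_mg_dl = 25, hb_g_dl = 11.5)),
    8L
  )
  # female Hb band differs: 11.5 scores 1, not 3
  expect_identical(
    compute_mgbs(base_patient(sex = "female", hb_g_dl = 11.5)),
    1L
  )
})

test_that("GBS adds the four categorical factors to the mGBS", {
  expect_identical(compute_gbs(base_patient()), 0L)
  expect_identical(
    compute_gbs(base_patient(pulse = 110, sbp = 85, bun_mg_dl = 75, hb_g_dl = 9,
                             melena = 1L, syncope = 1L, hepatic_disease = 1L,
                             cardiac_failure = 1L)),
    23L
  )
  expect_identical(
    compute_gbs(base_patient(pulse = 102, sbp = 105, bun_mg_dl = 25,
                             hb_g_dl = 11.5, melena = 1L)),
    9L
  )
  # flags absent from the data default to zero
  expect_identical(compute_gbs(base_patient()[1:6] |> cbind(rockall_comorbidity = "none")),
                   0L)
})

test_that("pre-endoscopy Rockall bands match hand-computed examples", {
  expect_identical(compute_pre_e_rs(base_patient(age = 55, pulse = 80, sbp = 130)), 0L)
  expect_identical(
    compute_pre_e_rs(base_patient(age = 85, sbp = 90,
                                  rockall_comorbidity = "severe")),
    7L
  )
  expect_identical(
    compute_pre_e_rs(base_patient(age = 65, pulse = 110, sbp = 120,
                                  rockall_comorbidity = "major")),
    4L
  )
})

test_that("pulse 100 scores in the mGBS but not in the Rockall shock item", {
  rec <- base_patient(pulse = 100, age = 50)
  expect_identical(compute_mgbs(rec), 1L)      # mGBS uses >= 100
  expect_identical(compute_pre_e_rs(rec), 0L)  # Rockall tachycardia is > 100
})

test_that("Rockall shock never sums hypotension and tachycardia", {
  rec <- base_patient(age = 50, pulse = 120, sbp = 85)
  expect_identical(compute_pre_e_rs(rec), 2L)
})

test_that("boundary grid maps every value into exactly one band", {
  grid <- expand.grid(
    pulse = c(99, 100), sbp = c(89, 90, 99, 100, 109, 110),
    bun_mg_dl = c(18.9, 19, 22.3, 22.4, 27.9, 28, 69.9, 70),
    hb_g_dl = c(9.9, 10, 11.9, 12, 12.9, 13),
    sex = c("male", "female"), stringsAsFactors = FALSE
  )
  grid$age <- 50
  grid$rockall_comorbidity <- "none"
  s <- compute_mgbs(grid)
  expect_true(all(!is.na(s)))
  expect_true(all(s >= 0 & s <= 16))
  # half-open convention: the 2-point band is [19, 22.4), so a value in the
  # printed one-decimal gap (22.35) still falls in exactly one band
  expect_identical(compute_mgbs(base_patient(bun_mg_dl = 22.3)), 2L)
  expect_identical(compute_mgbs(base_patient(bun_mg_dl = 22.35)), 2L)
  expect_identical(compute_mgbs(base_patient(bun_mg_dl = 22.4)), 3L)
})

test_that("raising any single variable into a higher band never lowers a score", {
  set.seed(41)
  for (i in 1:50) {
    rec <- base_patient(
      age = sample(18:95, 1), sex = sample(c("male", "female"), 1),
      pulse = runif(1, 45, 170), sbp = runif(1, 65, 200),
      bun_mg_dl = runif(1, 6, 120), hb_g_dl = runif(1, 5, 17),
      rockall_comorbidity = sample(c("none", "major", "severe"), 1)
    )
    for (var in c("pulse", "bun_mg_dl", "age")) {
      worse <- rec
      worse[[var]] <- rec[[var]] * 1.5
      expect_gte(compute_gbs(worse), compute_gbs(rec))
      expect_gte(compute_pre_e_rs(worse), compute_pre_e_rs(rec))
    }
    for (var in c("sbp", "hb_g_dl")) {
      worse <- rec
      worse[[var]] <- rec[[var]] * 0.6
      expect_gte(compute_gbs(worse), compute_gbs(rec))
      expect_gte(compute_pre_e_rs(worse), compute_pre_e_rs(rec))
    }
  }
})

test_that("GBS dominates mGBS by at most the four flag points", {
  coh <- generate_cohort(default_spec(400), seed = 11)
  d <- compute_gbs(coh) - compute_mgbs(coh)
  expect_true(all(d >= 0 & d <= 7))
  expect_true(all(compute_mgbs(coh) <= 16))
  expect_true(all(compute_gbs(coh) <= 23))
  expect_true(all(compute_pre_e_rs(coh) >= 0 & compute_pre_e_rs(coh) <= 7))
})

test_that("invalid records are rejected with the offending field named", {
  expect_error(compute_mgbs(base_patient(sbp = 0)), "sbp")
  expect_error(compute_mgbs(base_patient(pulse = -10)), "pulse")
  expect_error(compute_mgbs(base_patient(bun_mg_dl = NA_real_)), "bun_mg_dl")
  expect_error(compute_mgbs(base_patient()[-2]), "sex")
  expect_error(compute_gbs(base_patient(age = 16)), "age")
  expect_error(compute_pre_e_rs(base_patient(rockall_comorbidity = "mild")),
               "rockall_comorbidity")
  expect_error(compute_mgbs(base_patient(sex = "m")), "sex")
})

test_that("score_cohort groups correctly and conserves the cohort", {
  two <- rbind(base_patient(intervention = 1L), base_patient(intervention = 0L))
  g <- score_cohort(two, "gbs", "intervention")
  expect_identical(nrow(g), 1L)
  expect_identical(g$n_pos, 1L)
  expect_identical(g$n_neg, 1L)

  empty <- score_cohort(base_patient(intervention = 1L)[0, ], "gbs", "intervention")
  expect_identical(nrow(empty), 0L)

  coh <- generate_cohort(default_spec(590), seed = 5)
  g <- score_cohort(coh, "pre_e_rs", "intervention")
  expect_identical(sum(g$n_pos + g$n_neg), nrow(coh))
  expect_identical(sum(g$n_pos), sum(coh$intervention))

  expect_error(score_cohort(coh, "aims65", "intervention"))
  no_outcome <- coh
  no_outcome$death30 <- NULL
  expect_error(score_cohort(no_outcome, "gbs", "death30"), "death30")
})
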