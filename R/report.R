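# End-to-end analyses: reproduce the published evaluation from the packaged
# fixtures, or run the same workflow on any per-patient cohort.

round_half_up <- function(x, digits) {
  # the published tables round halves away from zero
  sign(x) * floor(abs(x) * 10^digits + 0.5) / 10^digits
}

#' Reproduce the published evaluation from the packaged fixtures
#'
#' Recomputes everything the grouped fixtures support and states explicitly
#' what they cannot support. The report contains: the intervention AUC of all
#' three scores from the grouped counts (only the Pre-E RS value matches the
#' published one — see below); the mean Pre-E RS; the reconstructed Pre-E RS
#' mortality distribution and its AUC; the full threshold-metric tables
#' recomputed from 2x2 reconstructions of every published row; Youden-optimal
#' cutoffs; both endoscopy-timing odds-ratio/chi-square analyses with their
#' survivor cells recovered by exhaustive search; and provenance notes for
#' every derived fixture used.
#'
#' Two published quantities are reported as NOT reproducible from the
#' available data, with reasons: the GBS and mGBS intervention AUCs (the
#' grouped counts yield about 0.653 and 0.632, not the published 0.727/0.733
#' — the grouped table and the published ROC analysis are mutually
#' inconsistent for these two scores), and all paired DeLong p-values
#' (pairing between scores is lost in marginal per-score counts; paired tests
#' are therefore only run on synthetic cohorts, flagged as such).
#'
#' @return A list of class `paper_report`; deterministic and fixture-only
#'   (no randomness on this path).
#' @export
reproduce_paper <- function() {
  t4 <- lapply(stats::setNames(.systems, .systems), load_table4)
  int_auc <- vapply(t4, auc_tied, numeric(1))

  pre <- t4$pre_e_rs
  mean_pre_e_rs <- sum(pre$score * (pre$n_pos + pre$n_neg)) /
    sum(pre$n_pos + pre$n_neg)

  mort <- reconstruct_mortality_by_score()
  mort_auc <- auc_tied(mort)

  # recompute every published threshold row from its integer reconstruction
  blocks <- list(
    list(system = "gbs", outcome = "intervention", n_pos = 280, n_neg = 310),
    list(system = "mgbs", outcome = "intervention", n_pos = 280, n_neg = 310),
    list(system = "pre_e_rs", outcome = "death30", n_pos = 25, n_neg = 565)
  )
  threshold_tables <- lapply(blocks, function(b) {
    t5 <- load_table5(b$system, b$outcome)
    rec <- lapply(seq_len(nrow(t5)), function(i) {
      ct <- reconstruct_confusion(t5$sens[i] / 100, t5$spec[i] / 100,
                                  b$n_pos, b$n_neg)
      data.frame(
        cutoff = t5$cutoff[i],
        sens = round_half_up(100 * ct$tp / (ct$tp + ct$fn), 2),
        spec = round_half_up(100 * ct$tn / (ct$tn + ct$fp), 2),
        ppv = round_half_up(100 * ct$tp / (ct$tp + ct$fp), 1),
        npv = round_half_up(100 * ct$tn / (ct$tn + ct$fn), 1)
      )
    })
    cbind(system = b$system, outcome = b$outcome, do.call(rbind, rec))
  })
  names(threshold_tables) <- vapply(blocks, `[[`, "", "system")

  optimal_cutoffs <- c(
    gbs = youden_optimal(load_table5("gbs", "intervention")),
    mgbs = youden_optimal(load_table5("mgbs", "intervention")),
    pre_e_rs = youden_optimal(load_table5("pre_e_rs", "death30"))
  )

  ti <- timing_inputs()
  timing <- lapply(seq_len(nrow(ti)), function(i) {
    row <- ti[i, ]
    split <- if (row$matcher == "or") {
      derive_survivor_split(row$total_n, row$deaths_late, row$deaths_early,
                            target_or = row$target)
    } else {
      derive_survivor_split(row$total_n, row$deaths_late, row$deaths_early,
                            target_chi2 = row$target)
    }
    c(list(system = row$system, table = split),
      odds_ratio_woolf(split$tp, split$fp, split$fn, split$tn))
  })
  names(timing) <- ti$system

  structure(list(
    intervention_auc = int_auc,
    mean_pre_e_rs = mean_pre_e_rs,
    mortality_auc_pre_e_rs = mort_auc,
    mortality_by_score = mort,
    threshold_tables = threshold_tables,
    optimal_cutoffs = optimal_cutoffs,
    timing = timing,
    not_reproducible = c(
      gbs_intervention_auc = paste(
        "published 0.727; the grouped per-score counts yield",
        sprintf("%.3f", int_auc[["gbs"]]),
        "- the grouped table and the published ROC analysis disagree for this score"),
      mgbs_intervention_auc = paste(
        "published 0.733; the grouped per-score counts yield",
        sprintf("%.3f", int_auc[["mgbs"]]),
        "- the grouped table and the published ROC analysis disagree for this score"),
      paired_delong_p = paste(
        "pairing between scores is lost in marginal per-score counts;",
        "paired DeLong tests run only on per-patient (synthetic) cohorts")
    ),
    provenance = c(
      "GBS score-9 negative count corrected 55 -> 66 (forced by printed row total 70 and column total 310)",
      "mortality-by-score distribution derived from the cumulative sensitivity ladder; 2 residual deaths placed at scores 0 and 2 (unique placement matching the published mortality AUC; all 6 enumerated placements ship in the fixture metadata)",
      "endoscopy-timing survivor cells recovered by exhaustive unique-match search against the printed OR/chi-square"
    )
  ), class = "paper_report")
}

#' @export
print.paper_report <- function(x, ...) {
  cat("Pre-endoscopy risk-score evaluation (fixture reproduction)\n")
  cat("----------------------------------------------------------\n")
  cat("Intervention AUC (grouped counts):",
      paste(sprintf("%s %.3f", names(x$intervention_auc), x$intervention_auc),
            collapse = ", "), "\n")
  cat(sprintf("Mean Pre-E RS: %.1f\n", x$mean_pre_e_rs))
  cat(sprintf("Pre-E RS 30-day mortality AUC (reconstructed): %.3f\n",
              x$mortality_auc_pre_e_rs))
  cat("Youden-optimal cutoffs:",
      paste(sprintf("%s > %d", names(x$optimal_cutoffs), x$optimal_cutoffs),
            collapse = ", "), "\n")
  for (tm in x$timing) {
    cat(sprintf(
      "Timing (%s subgroup): OR %.3f (95%% CI %.3f-%.3f), chi2 %.3f, p %.2g\n",
      tm$system, tm$odds_ratio, tm$ci95[1], tm$ci95[2], tm$chi2, tm$p))
  }
  cat("NOT reproducible from the packaged data:\n")
  for (nm in names(x$not_reproducible)) {
    cat(sprintf("  - %s: %s\n", nm, x$not_reproducible[[nm]]))
  }
  cat("Provenance notes:\n")
  for (p in x$provenance) cat(sprintf("  - %s\n", p))
  invisible(x)
}

#' Evaluate the risk scores on a per-patient cohort
#'
#' Runs the study's workflow on any cohort in the flat patient schema: per
#' system, the outcome AUC with DeLong standard error and 95% CI; paired
#' DeLong tests between every pair of requested systems; threshold-metric
#' tables; and the Youden-optimal cutoff.
#'
#' @param records Patient-record data frame (see [validate_patients()]); the
#'   chosen outcome column must be present with both classes represented.
#' @param outcome `"intervention"` or `"death30"`.
#' @param systems Character subset of `c("gbs", "mgbs", "pre_e_rs")`.
#' @param cutoffs Integer cutoffs for the threshold tables, or `"auto"` for
#'   every observed score value.
#' @return A list of class `cohort_evaluation` with elements `auc` (named
#'   list of [delong_se()] estimates), `paired` (data frame of pairwise
#'   DeLong tests; absent when a single system is requested),
#'   `threshold_tables`, `optimal_cutoffs`, `outcome` and `n`.
#' @export
evaluate_cohort <- function(records, outcome = c("intervention", "death30"),
                            systems = c("gbs", "mgbs", "pre_e_rs"),
                            cutoffs = "auto") {
  outcome <- match.arg(outcome)
  systems <- match.arg(systems, several.ok = TRUE)
  records <- validate_patients(records)
  if (!outcome %in% names(records) || anyNA(records[[outcome]])) {
    stop(sprintf("outcome column '%s' missing or incomplete", outcome),
         call. = FALSE)
  }
  y <- records[[outcome]]
  if (length(unique(y)) < 2L) {
    stop(sprintf("degenerate outcome: '%s' has a single class", outcome),
         call. = FALSE)
  }
  scores <- lapply(stats::setNames(systems, systems),
                   function(s) .score_funs[[s]](records))
  auc <- lapply(scores, delong_se, labels = y)

  paired <- NULL
  if (length(systems) > 1L) {
    pairs <- utils::combn(systems, 2, simplify = FALSE)
    paired <- do.call(rbind, lapply(pairs, function(pr) {
      cmp <- delong_paired_test(scores[[pr[1]]], scores[[pr[2]]], y)
      data.frame(system_a = pr[1], system_b = pr[2], auc_a = cmp$auc_a,
                 auc_b = cmp$auc_b, z = cmp$z, p = cmp$p)
    }))
  }

  tables <- lapply(stats::setNames(systems, systems), function(s) {
    counts <- score_cohort(records, s, outcome)
    cf <- if (identical(cutoffs, "auto")) counts$score else cutoffs
    threshold_table(counts, cf)
  })
  structure(list(
    outcome = outcome, n = nrow(records), auc = auc, paired = paired,
    threshold_tables = tables,
    optimal_cutoffs = vapply(tables, youden_optimal, numeric(1))
  ), class = "cohort_evaluation")
}

#' @export
print.cohort_evaluation <- function(x, ...) {
  cat(sprintf("Cohort evaluation: outcome %s, n = %d\n", x$outcome, x$n))
  for (s in names(x$auc)) {
    e <- x$auc[[s]]
    cat(sprintf("  %s: AUC %.3f (95%% CI %.3f-%.3f), Youden cutoff > %d\n",
                s, e$auc, e$ci95[1], e$ci95[2],
                as.integer(x$optimal_cutoffs[[s]])))
  }
  if (!is.null(x$paired)) {
    for (i in seq_len(nrow(x$paired))) {
      r <- x$paired[i, ]
      cat(sprintf("  %s vs %s: z = %.2f, p = %.3g\n",
                  r$system_a, r$system_b, r$z, r$p))
    }
  }
  invisible(x)
}
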