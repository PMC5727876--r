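# Threshold diagnostics under the strictly-greater rule: a patient is called
# positive when score > cutoff. Metrics are percentages; an empty denominator
# yields NA ("undefined"), never 0 or 100.

confusion_at_cutoff <- function(counts, cutoff) {
  counts <- as_grouped_counts(counts)
  above <- counts$score > cutoff
  tp <- sum(counts$n_pos[above])
  fp <- sum(counts$n_neg[above])
  list(tp = tp, fp = fp,
       fn = sum(counts$n_pos) - tp, tn = sum(counts$n_neg) - fp)
}

.pct <- function(num, den) if (den == 0) NA_real_ else 100 * num / den

#' Diagnostic metrics at one score cutoff
#'
#' Sensitivity, specificity, positive and negative predictive value (all
#' percentages) of the rule "positive when score > cutoff", computed from
#' grouped counts. Values are returned unrounded; published tables round
#' sensitivity/specificity to 2 decimals and PPV/NPV to 1.
#'
#' @inheritParams roc_points
#' @param cutoff Score threshold (strictly-greater rule).
#' @return A one-row data frame with columns `cutoff`, `sens`, `spec`, `ppv`,
#'   `npv`; undefined metrics (0/0) are `NA`.
#' @export
metrics_at_cutoff <- function(counts, cutoff) {
  ct <- confusion_at_cutoff(counts, cutoff)
  data.frame(
    cutoff = cutoff,
    sens = .pct(ct$tp, ct$tp + ct$fn),
    spec = .pct(ct$tn, ct$tn + ct$fp),
    ppv = .pct(ct$tp, ct$tp + ct$fp),
    npv = .pct(ct$tn, ct$tn + ct$fn)
  )
}

#' Threshold metric table over several cutoffs
#'
#' @inheritParams metrics_at_cutoff
#' @param cutoffs Integer vector of cutoffs; may be empty.
#' @return Data frame with one [metrics_at_cutoff()] row per cutoff.
#' @export
threshold_table <- function(counts, cutoffs) {
  if (length(cutoffs) == 0L) {
    return(data.frame(cutoff = integer(), sens = numeric(), spec = numeric(),
                      ppv = numeric(), npv = numeric()))
  }
  do.call(rbind, lapply(cutoffs, function(cf) metrics_at_cutoff(counts, cf)))
}

#' Optimal cutoff by the Youden index
#'
#' Selects the cutoff maximising Youden's J = sensitivity + specificity - 100
#' (percent scale). Ties are broken toward the smaller cutoff.
#'
#' @param metrics Data frame with columns `cutoff`, `sens`, `spec` (e.g. from
#'   [threshold_table()] or [load_table5()]).
#' @return The selected cutoff.
#' @export
youden_optimal <- function(metrics) {
  if (!is.data.frame(metrics) || nrow(metrics) == 0L) {
    stop("need a non-empty metrics table", call. = FALSE)
  }
  j <- metrics$sens + metrics$spec - 100
  candidates <- metrics$cutoff[which(j == max(j, na.rm = TRUE))]
  min(candidates)
}

#' Reconstruct an integer 2x2 table from sensitivity and specificity
#'
#' Inverts a printed threshold-metric row: TP is the nearest integer to
#' sens * n_pos, TN the nearest integer to spec * n_neg, and FN/FP follow by
#' complement. Recomputing sensitivity and specificity from the result
#' reproduces the inputs at their printed precision, and the reconstructed
#' PPV/NPV can be checked against the printed ones.
#'
#' @param sens,spec Sensitivity and specificity as fractions in \\[0, 1\\].
#' @param n_pos,n_neg Outcome-positive and outcome-negative class sizes.
#' @return A list of class `confusion_table` with integer cells `tp`, `fp`,
#'   `fn`, `tn`.
#' @export
reconstruct_confusion <- function(sens, spec, n_pos, n_neg) {
  if (sens < 0 || sens > 1 || spec < 0 || spec > 1) {
    stop("sens and spec must be fractions in [0, 1]", call. = FALSE)
  }
  tp <- round(sens * n_pos)
  tn <- round(spec * n_neg)
  ct <- list(tp = tp, fp = n_neg - tn, fn = n_pos - tp, tn = tn)
  if (any(unlist(ct) < 0)) {
    stop("reconstruction yields a negative cell", call. = FALSE)
  }
  structure(lapply(ct, as.integer), class = "confusion_table")
}

#' Odds ratio with Woolf (log-normal) confidence interval
#'
#' For a 2x2 table with cells a (exposed, event), b (exposed, no event),
#' c (unexposed, event), d (unexposed, no event): OR = ad / bc with 95% CI
#' exp(log OR +/- 1.96 sqrt(1/a + 1/b + 1/c + 1/d)). All four cells must be
#' positive; continuity-corrected variants for zero cells are deliberately
#' not offered.
#'
#' @param a,b,c,d The four cell counts (exposed-event, exposed-no-event,
#'   unexposed-event, unexposed-no-event).
#' @return A list of class `odds_ratio_result` with `odds_ratio`, `ci95`
#'   (length-2), `chi2` and `p` (uncorrected Pearson chi-square, 1 df).
#' @export
odds_ratio_woolf <- function(a, b, c, d) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(cells <= 0)) {
    stop(paste("Woolf odds-ratio CI requires all four cells > 0;",
               "continuity-corrected variants are out of scope"), call. = FALSE)
  }
  or <- (a * d) / (b * c)
  half <- 1.96 * sqrt(sum(1 / cells))
  chi <- pearson_chi2(a, b, c, d)
  structure(
    list(odds_ratio = or, ci95 = exp(log(or) + c(-half, half)),
         chi2 = chi$chi2, p = chi$p),
    class = "odds_ratio_result"
  )
}

#' @export
print.odds_ratio_result <- function(x, ...) {
  cat(sprintf("OR %.3f (95%% CI %.3f-%.3f); chi-square %.3f, p = %.4g\n",
              x$odds_ratio, x$ci95[1], x$ci95[2], x$chi2, x$p))
  invisible(x)
}

#' Pearson chi-square test on a 2x2 table, no continuity correction
#'
#' The uncorrected Pearson statistic (1 df). Yates' correction is never
#' applied anywhere in this package: the analyses it reproduces use the
#' uncorrected statistic throughout.
#'
#' @inheritParams odds_ratio_woolf
#' @return List with `chi2` and `p`.
#' @export
pearson_chi2 <- function(a, b, c, d) {
  tab <- matrix(c(a, b, c, d), nrow = 2, byrow = TRUE)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("chi-square requires positive margins", call. = FALSE)
  }
  res <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(chi2 = unname(res$statistic), p = unname(res$p.value))
}

#' Recover an unprinted survivor split by exhaustive search
#'
#' Reports sometimes print, for a subgroup of `total_n` patients split by an
#' exposure, only the event (death) counts in each arm together with the odds
#' ratio or chi-square of the full 2x2 table. This routine recovers the
#' missing survivor cells: it enumerates every integer split
#' (s_exposed, s_unexposed) of the `total_n - deaths` survivors, keeps the
#' splits whose odds ratio (or chi-square) rounds to the stated value at 3
#' decimals, and insists the match is unique — if zero or several splits
#' match it fails loudly rather than guessing.
#'
#' @param total_n Subgroup size.
#' @param deaths_exposed,deaths_unexposed Event counts in the two arms.
#' @param target_or,target_chi2 Exactly one of these: the printed statistic
#'   to match (3-decimal rounding).
#' @return A list of class `confusion_table` with cells `tp` (= deaths
#'   exposed), `fp` (survivors exposed), `fn` (deaths unexposed), `tn`
#'   (survivors unexposed).
#' @export
derive_survivor_split <- function(total_n, deaths_exposed, deaths_unexposed,
                                  target_or = NULL, target_chi2 = NULL) {
  if (is.null(target_or) == is.null(target_chi2)) {
    stop("supply exactly one of target_or / target_chi2", call. = FALSE)
  }
  target <- if (is.null(target_or)) target_chi2 else target_or
  if (target <= 0) stop("matcher value must be positive", call. = FALSE)
  survivors <- total_n - deaths_exposed - deaths_unexposed
  if (survivors <= 0) {
    stop("deaths meet or exceed the subgroup total", call. = FALSE)
  }
  stat <- if (is.null(target_or)) {
    function(se, su) pearson_chi2(deaths_exposed, se, deaths_unexposed, su)$chi2
  } else {
    function(se, su) (deaths_exposed * su) / (se * deaths_unexposed)
  }
  hits <- integer()
  for (se in seq_len(survivors - 1L)) {
    if (round(stat(se, survivors - se), 3) == round(target, 3)) {
      hits <- c(hits, se)
    }
  }
  if (length(hits) == 0L) {
    stop("no survivor split reproduces the target statistic", call. = FALSE)
  }
  if (length(hits) > 1L) {
    stop(sprintf("ambiguous: %d survivor splits match the target", length(hits)),
         call. = FALSE)
  }
  structure(
    list(tp = as.integer(deaths_exposed), fp = hits,
         fn = as.integer(deaths_unexposed), tn = as.integer(survivors - hits)),
    class = "confusion_table"
  )
}
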