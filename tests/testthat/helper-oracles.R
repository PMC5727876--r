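# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: AUCs by explicit pair enumeration, DeLong
# variance/covariance by direct placement-matrix computation.

# Tie-corrected AUC by brute-force enumeration of all pos-neg pairs
bf_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  mean(outer(pos, neg, function(p, q) (p > q) + 0.5 * (p == q)))
}

bf_auc_grouped <- function(counts) {
  x <- expand_counts(counts)
  bf_auc(x$scores, x$labels)
}

# Paired DeLong z by direct enumeration of placement values
bf_delong_paired <- function(sa, sb, labels) {
  pos <- which(labels == 1)
  neg <- which(labels == 0)
  m <- length(pos)
  n <- length(neg)
  psi <- function(s) outer(s[pos], s[neg], function(p, q) (p > q) + 0.5 * (p == q))
  A <- psi(sa)
  B <- psi(sb)
  va <- stats::var(rowMeans(A)) / m + stats::var(colMeans(A)) / n
  vb <- stats::var(rowMeans(B)) / m + stats::var(colMeans(B)) / n
  cab <- stats::cov(rowMeans(A), rowMeans(B)) / m +
    stats::cov(colMeans(A), colMeans(B)) / n
  z <- (mean(A) - mean(B)) / sqrt(va + vb - 2 * cab)
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}

# Random small grouped-counts instance with both classes present
rand_grouped <- function(k = 5, max_count = 8) {
  repeat {
    g <- grouped_counts(sort(sample(0:20, k)),
                        sample(0:max_count, k, replace = TRUE),
                        sample(0:max_count, k, replace = TRUE))
    if (sum(g$n_pos) > 0 && sum(g$n_neg) > 0) return(g)
  }
}

# A small valid patient record to perturb in scoring tests
base_patient <- function(...) {
  rec <- list(age = 45, sex = "male", pulse = 80, sbp = 120, bun_mg_dl = 15,
              hb_g_dl = 14, melena = 0L, syncope = 0L, hepatic_disease = 0L,
              cardiac_failure = 0L, rockall_comorbidity = "none")
  mods <- list(...)
  rec[names(mods)] <- mods
  as.data.frame(rec, stringsAsFactors = FALSE)
}
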