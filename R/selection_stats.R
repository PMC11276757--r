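# pN/pS summaries and the tests built on them.
#
# pN is the number of nonsynonymous SNPs per covered nonsynonymous site, pS
# the synonymous analogue; their ratio measures the efficacy of purifying
# selection (pN/pS << 1 under strong constraint). The likelihood-ratio test
# models, within each SNP class, the nonsynonymous count conditional on the
# class total as Binomial with success probability
#   pi(r) = r * SN / (r * SN + SS),
# where SN and SS are the covered nonsynonymous and synonymous site totals
# (exposure offsets) and r is the pN/pS ratio. This is the conditional form
# of a two-Poisson exposure model with the synonymous rate profiled out, so
# the shared-vs-separate-ratio comparison has exactly 1 df.

#' pN/pS summary from SNP counts and covered-site totals
#'
#' @param n_nonsyn,n_syn Nonsynonymous and synonymous SNP counts.
#' @param sites_nonsyn,sites_syn Covered nonsynonymous and synonymous site
#'   totals (fractional NG86 sites; must be positive).
#' @return A `pnps_summary`: the counts, the three SNP frequencies
#'   (overall, nonsynonymous, synonymous) and `pnps`. With `n_syn = 0` the
#'   ratio is reported as `NA` (missing), not 0 or infinity.
#' @examples
#' pnps_summary(12, 17, 1593394, 434906)
#' @export
pnps_summary <- function(n_nonsyn, n_syn, sites_nonsyn, sites_syn) {
  if (sites_nonsyn <= 0 || sites_syn <= 0) stop("site totals must be positive")
  if (n_nonsyn < 0 || n_syn < 0) stop("counts must be non-negative")
  freq_n <- n_nonsyn / sites_nonsyn
  freq_s <- n_syn / sites_syn
  structure(list(n_nonsyn = n_nonsyn, n_syn = n_syn,
                 sites_nonsyn = sites_nonsyn, sites_syn = sites_syn,
                 freq_overall = (n_nonsyn + n_syn) / (sites_nonsyn + sites_syn),
                 freq_nonsyn = freq_n, freq_syn = freq_s,
                 pnps = if (n_syn == 0) NA_real_ else freq_n / freq_s),
            class = "pnps_summary")
}

#' @export
print.pnps_summary <- function(x, ...) {
  cat("pN/pS summary\n")
  cat(sprintf("  nonsyn SNPs: %d over %.1f covered sites (pN = %.3g)\n",
              x$n_nonsyn, x$sites_nonsyn, x$freq_nonsyn))
  cat(sprintf("  syn SNPs:    %d over %.1f covered sites (pS = %.3g)\n",
              x$n_syn, x$sites_syn, x$freq_syn))
  cat(sprintf("  overall SNP frequency: %.3g\n", x$freq_overall))
  if (is.na(x$pnps)) {
    cat("  pN/pS: undefined (no synonymous SNPs)\n")
  } else {
    cat(sprintf("  pN/pS: %.4f\n", x$pnps))
  }
  invisible(x)
}

# conditional-binomial log-likelihood of one class at ratio r
.lrt_ll <- function(r, nN, nS, SN, SS) {
  p <- r * SN / (r * SN + SS)
  dbinom(nN, nN + nS, p, log = TRUE)
}

.check_counts4 <- function(counts, label) {
  if (length(counts) != 4L || any(is.na(counts))) {
    stop(label, " must be (n_nonsyn, n_syn, sites_nonsyn, sites_syn)")
  }
  if (counts[3] <= 0 || counts[4] <= 0) stop(label, ": site totals must be positive")
  if (counts[1] < 0 || counts[2] < 0) stop(label, ": counts must be non-negative")
  if (counts[1] + counts[2] < 1) stop(label, ": at least one SNP is required")
  if (counts[2] == 0) {
    stop(label, ": no synonymous SNPs; the pN/pS ratio is unidentifiable")
  }
  as.numeric(counts)
}

#' Likelihood-ratio test for unequal pN/pS between two SNP classes
#'
#' Null: both classes share one pN/pS ratio; alternative: each class has its
#' own. Within each class the nonsynonymous count, conditional on the class
#' total, is Binomial with success probability `r*SN/(r*SN + SS)` where SN
#' and SS are covered-site offsets. The per-class maximum-likelihood ratio
#' has the closed form `(nN/SN)/(nS/SS)`; the shared ratio is maximised
#' numerically on the log scale.
#'
#' @param counts_a,counts_b Numeric length-4 vectors
#'   `(n_nonsyn, n_syn, sites_nonsyn, sites_syn)` for the two classes.
#' @return A `pnps_lrt`: per-class and shared ratio MLEs, both
#'   log-likelihoods, `chi2 = 2 * (loglik_alt - loglik_null)`, `df = 1`, and
#'   the upper-tail chi-square p-value.
#' @examples
#' pnps_lrt(c(12, 17, 1593394, 434906), c(388, 1209, 881978, 237763))
#' @export
pnps_lrt <- function(counts_a, counts_b) {
  a <- .check_counts4(counts_a, "counts_a")
  b <- .check_counts4(counts_b, "counts_b")
  r_hat <- function(v) (v[1] / v[3]) / (v[2] / v[4])
  ra <- r_hat(a); rb <- r_hat(b)
  # alternative log-likelihood at the per-class MLEs (pi_hat = nN / n)
  ll_alt <- dbinom(a[1], a[1] + a[2], a[1] / (a[1] + a[2]), log = TRUE) +
    dbinom(b[1], b[1] + b[2], b[1] / (b[1] + b[2]), log = TRUE)
  shared_ll <- function(logr) {
    .lrt_ll(exp(logr), a[1], a[2], a[3], a[4]) +
      .lrt_ll(exp(logr), b[1], b[2], b[3], b[4])
  }
  centre <- log(pmax(c(ra, rb), 1e-12))
  lo <- min(centre) - 15; hi <- max(centre) + 15
  opt <- optimize(shared_ll, c(lo, hi), maximum = TRUE, tol = 1e-10)
  chi2 <- max(0, 2 * (ll_alt - opt$objective))
  structure(list(ratio_shared_mle = exp(opt$maximum),
                 ratio_a_mle = ra, ratio_b_mle = rb,
                 loglik_null = opt$objective, loglik_alt = ll_alt,
                 chi2 = chi2, df = 1L,
                 p_value = pchisq(chi2, df = 1, lower.tail = FALSE)),
            class = "pnps_lrt")
}

#' @export
print.pnps_lrt <- function(x, ...) {
  cat("Likelihood-ratio test: shared vs separate pN/pS\n")
  cat(sprintf("  ratio MLEs: A = %.4f, B = %.4f, shared = %.4f\n",
              x$ratio_a_mle, x$ratio_b_mle, x$ratio_shared_mle))
  cat(sprintf("  chi-square = %.1f on %d df, p = %.3g\n",
              x$chi2, x$df, x$p_value))
  invisible(x)
}

.exact_test_result <- function(statistic, p_value, method) {
  structure(list(statistic = statistic, p_value = p_value, method = method),
            class = "exact_test")
}

#' @export
print.exact_test <- function(x, ...) {
  cat(x$method, "\n")
  cat(sprintf("  statistic = %g, p = %.3g\n", x$statistic, x$p_value))
  invisible(x)
}

#' Two-sided exact binomial test on a sex ratio
#'
#' Tests observed female/male counts against a null female proportion `p0`
#' using the exact binomial distribution with the standard two-sided
#' minimum-likelihood rule (all outcomes no more probable than the observed
#' one are summed), as implemented by [stats::binom.test()].
#'
#' @param k_female,k_male Observed counts.
#' @param p0 Null female proportion, strictly inside (0, 1).
#' @return An `exact_test` with the female count as statistic.
#' @examples
#' exact_binomial_test(7, 4)
#' @export
exact_binomial_test <- function(k_female, k_male, p0 = 0.5) {
  if (p0 <= 0 || p0 >= 1) stop("p0 must lie strictly inside (0, 1)")
  n <- k_female + k_male
  if (n < 1) stop("at least one observation is required")
  p <- stats::binom.test(k_female, n, p = p0)$p.value
  .exact_test_result(k_female, p, "Exact binomial test (two-sided)")
}

#' Exact two-sample rank-sum (Mann-Whitney) test by full enumeration
#'
#' Computes the Mann-Whitney U statistic for group A over group B and its
#' exact two-sided p-value by enumerating all `choose(nA + nB, nA)` group
#' assignments of the pooled ranks:
#' `p = min(1, 2 * min(P(U <= u), P(U >= u)))`. Ties across the pooled
#' values are an error (the tie-corrected large-sample test is out of
#' scope), as are group sizes whose enumeration would be impractical.
#'
#' @param values_a,values_b Numeric vectors, each non-empty, no ties in the
#'   pooled values.
#' @return An `exact_test` with U as statistic.
#' @examples
#' exact_rank_sum_test(c(1, 2), c(3, 4))
#' @export
exact_rank_sum_test <- function(values_a, values_b) {
  na <- length(values_a); nb <- length(values_b)
  if (na < 1 || nb < 1) stop("both groups must be non-empty")
  pooled <- c(values_a, values_b)
  if (anyDuplicated(pooled)) {
    stop("tied values present; the exact enumeration test requires untied data ",
         "(a tie-corrected large-sample alternative is out of scope)")
  }
  if (choose(na + nb, na) > 5e6) {
    stop("group sizes too large for full enumeration")
  }
  ranks <- rank(pooled)
  u_obs <- sum(ranks[seq_len(na)]) - na * (na + 1) / 2
  assignments <- utils::combn(na + nb, na)
  r_all <- seq_len(na + nb)   # pooled ranks are 1..N (no ties)
  u_null <- colSums(matrix(r_all[assignments], nrow = na)) - na * (na + 1) / 2
  p <- min(1, 2 * min(mean(u_null <= u_obs), mean(u_null >= u_obs)))
  .exact_test_result(u_obs, p, "Exact Mann-Whitney rank-sum test (full enumeration, two-sided)")
}
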