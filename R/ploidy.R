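# Allele-balance ploidy inference. At a heterozygous site the fraction of
# reads carrying the reference allele has expectation 1/2 in a diploid and
# 1/3 or 2/3 in a triploid (one or two reference copies), so the read-count
# data discriminate the two ploidies via a binomial likelihood.

# rows of x that are biallelic (single alt, no allele index > 1 anywhere)
.is_biallelic <- function(x) {
  one_alt <- !grepl(",", x$sites$alt, fixed = TRUE)
  no_high <- !apply(x$gt, 1, function(g) any(grepl("[2-9]", g[!is.na(g)])))
  one_alt & no_high
}

# heterozygous for sample j: genotype contains both allele 0 and allele 1
.is_het <- function(gt_col) {
  !is.na(gt_col) & grepl("0", gt_col, fixed = TRUE) &
    grepl("1", gt_col, fixed = TRUE)
}

# ref/alt read counts for one sample at biallelic records
.ref_alt_depths <- function(x, sample_id, rows) {
  ad <- x$ad[rows, sample_id]
  parts <- strsplit(ad, ",", fixed = TRUE)
  r <- as.numeric(vapply(parts, `[`, character(1), 1L))
  a <- as.numeric(vapply(parts, function(p) if (length(p) >= 2L) p[2L] else NA_character_,
                         character(1)))
  cbind(ref = r, alt = a)
}

#' Reference-allele read fractions at heterozygous sites
#'
#' For each biallelic record where the sample is heterozygous (carries both
#' allele 0 and allele 1), returns `AD_ref / (AD_ref + AD_alt)`. Homozygous,
#' missing, and multiallelic-involved calls are skipped; sites with zero
#' informative reads are skipped with a warning.
#'
#' @param x A quality-filtered [snp_set].
#' @param sample_id A single sample id.
#' @return Numeric vector of balances in `[0, 1]`.
#' @export
het_allele_balances <- function(x, sample_id) {
  stopifnot(inherits(x, "snp_set"), sample_id %in% x$samples$sample_id)
  rows <- which(.is_biallelic(x) & .is_het(x$gt[, sample_id]))
  if (!length(rows)) return(numeric(0))
  rd <- .ref_alt_depths(x, sample_id, rows)
  n <- rd[, "ref"] + rd[, "alt"]
  zero <- is.na(n) | n == 0
  if (any(zero)) {
    warning(sum(zero), " heterozygous site(s) with no informative reads skipped")
  }
  unname((rd[, "ref"] / n)[!zero])
}

#' Histogram of allele balances on fixed bins
#'
#' Bins are `[0, w), [w, 2w), ..., [1 - w, 1]` — right-open except the last.
#'
#' @param balances Numeric vector in `[0, 1]`.
#' @param bin_width Bin width (default 0.02).
#' @return data.frame with `bin_start`, `bin_end`, `count`.
#' @export
balance_histogram <- function(balances, bin_width = 0.02) {
  stopifnot(all(balances >= 0 & balances <= 1))
  edges <- seq(0, 1, by = bin_width)
  if (edges[length(edges)] < 1) edges <- c(edges, 1)
  idx <- findInterval(balances, edges, rightmost.closed = TRUE)
  counts <- tabulate(idx, nbins = length(edges) - 1L)
  data.frame(bin_start = edges[-length(edges)], bin_end = edges[-1],
             count = counts)
}

#' Infer sample ploidy from allele balance at heterozygous sites
#'
#' Compares two models of the reference-read count `r` at each heterozygous
#' site with `n` informative reads: diploid, `r ~ Binom(n, 1/2)`; triploid,
#' an equal-weight mixture `r ~ 1/2 Binom(n, 1/3) + 1/2 Binom(n, 2/3)`
#' (the two orientations of a single heterozygous copy in an AAB-style
#' genome). The call is the model with the higher total log-likelihood,
#' or `"undetermined"` with fewer than `min_sites` usable sites.
#'
#' @param x A quality-filtered [snp_set].
#' @param sample_id A single sample id.
#' @param min_sites Minimum heterozygous site count for a call (default 100).
#' @param bin_width Histogram bin width carried in the profile.
#' @return An `allele_balance_profile`: sample id, balances, histogram, both
#'   log-likelihoods, site count and the inferred ploidy.
#' @export
infer_ploidy <- function(x, sample_id, min_sites = 100, bin_width = 0.02) {
  stopifnot(inherits(x, "snp_set"), sample_id %in% x$samples$sample_id)
  rows <- which(.is_biallelic(x) & .is_het(x$gt[, sample_id]))
  if (length(rows)) {
    rd <- .ref_alt_depths(x, sample_id, rows)
    n <- rd[, "ref"] + rd[, "alt"]
    keep <- !is.na(n) & n > 0
    r <- unname(rd[keep, "ref"]); n <- unname(n[keep])
  } else {
    r <- n <- numeric(0)
  }
  ll2 <- sum(dbinom(r, n, 0.5, log = TRUE))
  l13 <- dbinom(r, n, 1 / 3, log = TRUE)
  l23 <- dbinom(r, n, 2 / 3, log = TRUE)
  m <- pmax(l13, l23)
  ll3 <- sum(m + log(0.5 * exp(l13 - m) + 0.5 * exp(l23 - m)))
  balances <- r / n
  call <- if (length(n) < min_sites) {
    "undetermined"
  } else if (ll3 > ll2) "triploid" else "diploid"
  structure(list(sample_id = sample_id, balances = balances,
                 histogram = balance_histogram(balances, bin_width),
                 n_sites = length(n),
                 loglik_diploid = ll2, loglik_triploid = ll3,
                 inferred_ploidy = call),
            class = "allele_balance_profile")
}

#' @export
print.allele_balance_profile <- function(x, ...) {
  cat("Allele-balance profile for", x$sample_id, "\n")
  cat("  heterozygous sites used:", x$n_sites, "\n")
  cat(sprintf("  log-likelihood diploid:  %.2f\n", x$loglik_diploid))
  cat(sprintf("  log-likelihood triploid: %.2f\n", x$loglik_triploid))
  cat("  inferred ploidy:", x$inferred_ploidy, "\n")
  invisible(x)
}
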