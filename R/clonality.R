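# Genotype-identity clonality metrics: the fraction of biallelic SNPs at
# which a set of samples share identical genotypes. In a clonal (apomictic)
# lineage this fraction approaches 1; in an outcrossing population it is low.

#' Restrict an SNP set to biallelic records
#'
#' Keeps records with exactly one alternate allele and no genotype
#' referencing an allele index above 1.
#'
#' @param x A [snp_set].
#' @return A filtered [snp_set].
#' @export
biallelic_subset <- function(x) {
  stopifnot(inherits(x, "snp_set"))
  x[which(.is_biallelic(x))]
}

#' Restrict an SNP set to a list of marker transcripts
#'
#' @param x A [snp_set].
#' @param transcript_ids Character vector of transcript ids to keep (e.g.
#'   single-copy ortholog markers).
#' @return A filtered [snp_set].
#' @export
subset_by_markers <- function(x, transcript_ids) {
  stopifnot(inherits(x, "snp_set"))
  x[which(x$sites$transcript_id %in% transcript_ids)]
}

.clonality_summary <- function(n_identical, n_biallelic, sample_set,
                               subset_label) {
  structure(list(n_biallelic = n_biallelic, n_identical = n_identical,
                 fraction = if (n_biallelic > 0) n_identical / n_biallelic else NA_real_,
                 sample_set = sample_set, subset_label = subset_label),
            class = "clonality_summary")
}

#' Fraction of biallelic SNPs with identical genotypes across samples
#'
#' A record counts as identical when every listed sample carries the same
#' sorted allele multiset (canonical genotype string). Records with any
#' missing call among the listed samples are excluded from both numerator
#' and denominator. Samples of different ploidy are never identical at
#' sites where their multisets differ in length.
#'
#' @param x A biallelic, quality-filtered [snp_set] (use
#'   [biallelic_subset()] first; non-biallelic records are ignored here too).
#' @param sample_ids Two or more sample ids.
#' @param subset_label Free-text label carried into the summary.
#' @return A `clonality_summary`: counts, fraction, sample set, label.
#' @export
identity_fraction <- function(x, sample_ids, subset_label = "all SNPs") {
  stopifnot(inherits(x, "snp_set"))
  if (length(sample_ids) < 2L) stop("at least two samples are required")
  missing_s <- setdiff(sample_ids, x$samples$sample_id)
  if (length(missing_s)) stop("unknown sample(s): ", paste(missing_s, collapse = ", "))
  g <- x$gt[.is_biallelic(x), sample_ids, drop = FALSE]
  complete <- rowSums(is.na(g)) == 0L
  g <- g[complete, , drop = FALSE]
  ident <- if (nrow(g)) {
    rowSums(g == g[, 1L]) == ncol(g)
  } else {
    logical(0)
  }
  .clonality_summary(sum(ident), nrow(g), sample_ids, subset_label)
}

#' Pairwise genotype identity between two samples
#'
#' @param x A [snp_set].
#' @param sample_a,sample_b Sample ids.
#' @param subset_label Free-text label.
#' @return A `clonality_summary`.
#' @export
pairwise_identity <- function(x, sample_a, sample_b,
                              subset_label = "all SNPs") {
  identity_fraction(x, c(sample_a, sample_b), subset_label)
}

#' @export
print.clonality_summary <- function(x, ...) {
  cat("Genotype identity (", x$subset_label, ")\n", sep = "")
  cat("  samples:", paste(x$sample_set, collapse = ", "), "\n")
  cat("  identical / biallelic with complete calls:",
      x$n_identical, "/", x$n_biallelic, "\n")
  if (is.na(x$fraction)) {
    cat("  fraction: undefined (no usable records)\n")
  } else {
    cat(sprintf("  fraction: %.3f (%.1f%%)\n", x$fraction, 100 * x$fraction))
  }
  invisible(x)
}
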