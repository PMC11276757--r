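# Genotype-pattern partitioning of SNPs into analysis classes:
#  - per-individual heterozygous sets (the per-sample pN/pS numerators);
#  - candidate novel mutations in the clonal triploids (some adults 0/0/0,
#    others 0/0/1, nothing else) — variants postdating the origin of the
#    clone;
#  - ancestral identical-heterozygous sites (every adult exactly 0/0/1) —
#    variants inherited from the hybrid founding event;
#  - low-frequency SNPs in the sexual diploids (a single 0/1 carrier, all
#    other samples 0/0).

.check_samples <- function(x, sample_ids, ploidy = NULL, role = NULL) {
  sheet <- x$samples
  missing_s <- setdiff(sample_ids, sheet$sample_id)
  if (length(missing_s)) stop("unknown sample(s): ", paste(missing_s, collapse = ", "))
  rows <- sheet[match(sample_ids, sheet$sample_id), ]
  if (!is.null(ploidy) && !all(rows$ploidy == ploidy)) {
    stop("sample(s) not of ploidy ", ploidy, ": ",
         paste(rows$sample_id[rows$ploidy != ploidy], collapse = ", "))
  }
  if (!is.null(role) && !all(rows$role == role)) {
    stop("sample(s) not of role '", role, "': ",
         paste(rows$sample_id[rows$role != role], collapse = ", "))
  }
  invisible(rows)
}

#' Heterozygous SNPs of one individual
#'
#' Biallelic records where the sample carries both allele 0 and allele 1
#' (e.g. diploid `0/1`, triploid `0/0/1` or `0/1/1`).
#'
#' @param x A quality-filtered [snp_set].
#' @param sample_id A single sample id.
#' @return A filtered [snp_set].
#' @export
per_individual_het <- function(x, sample_id) {
  stopifnot(inherits(x, "snp_set"))
  .check_samples(x, sample_id)
  x[which(.is_biallelic(x) & .is_het(x$gt[, sample_id]))]
}

#' Candidate novel mutations in a clonal triploid adult set
#'
#' Biallelic records where, among the listed triploid adults, at least one
#' is `0/0/0`, at least one is `0/0/1`, no adult shows any other genotype,
#' and every adult has a call. The single-copy derived allele in a subset of
#' clones is the signature of a mutation arising after the clone's origin.
#' Matching is strict: any third genotype pattern disqualifies the site.
#'
#' @param x A quality-filtered [snp_set].
#' @param adults Ids of the triploid adult samples (offspring pools excluded
#'   by the caller; non-triploid or non-adult ids are an error).
#' @return A filtered [snp_set].
#' @export
candidate_novel <- function(x, adults) {
  stopifnot(inherits(x, "snp_set"))
  .check_samples(x, adults, ploidy = 3L, role = "adult")
  g <- x$gt[, adults, drop = FALSE]
  complete <- rowSums(is.na(g)) == 0L
  hom <- g == "0/0/0"
  het <- g == "0/0/1"
  keep <- complete & rowSums(hom, na.rm = TRUE) >= 1L &
    rowSums(het, na.rm = TRUE) >= 1L &
    rowSums(hom | het, na.rm = TRUE) == length(adults)
  x[which(.is_biallelic(x) & keep)]
}

#' Ancestral identical-heterozygous SNPs in a clonal triploid adult set
#'
#' Biallelic records where every listed triploid adult is exactly `0/0/1`:
#' heterozygosity shared by all clones, inherited from the hybrid origin of
#' the lineage.
#'
#' @inheritParams candidate_novel
#' @return A filtered [snp_set].
#' @export
ancestral_identical <- function(x, adults) {
  stopifnot(inherits(x, "snp_set"))
  .check_samples(x, adults, ploidy = 3L, role = "adult")
  g <- x$gt[, adults, drop = FALSE]
  keep <- rowSums(!is.na(g) & g == "0/0/1") == length(adults)
  x[which(.is_biallelic(x) & keep)]
}

#' Low-frequency SNPs in a diploid sample set
#'
#' Biallelic records where exactly one listed diploid sample is `0/1` and
#' all others are `0/0` — an alternate-allele count of 1 out of 2N, the
#' frequency class enriched for mildly deleterious variants.
#'
#' @param x A quality-filtered [snp_set].
#' @param sample_ids Ids of the diploid samples (non-diploid ids are an
#'   error).
#' @return A filtered [snp_set].
#' @export
low_frequency <- function(x, sample_ids) {
  stopifnot(inherits(x, "snp_set"))
  .check_samples(x, sample_ids, ploidy = 2L)
  g <- x$gt[, sample_ids, drop = FALSE]
  complete <- rowSums(is.na(g)) == 0L
  keep <- complete & rowSums(g == "0/1", na.rm = TRUE) == 1L &
    rowSums(g == "0/0", na.rm = TRUE) == length(sample_ids) - 1L
  x[which(.is_biallelic(x) & keep)]
}
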