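# In-code fixture builders shared across test files.

# quick sample sheet
make_sheet <- function(ids, ploidy, species = "spX", role = "adult",
                       sex = "female") {
  data.frame(sample_id = ids, species_id = rep_len(species, length(ids)),
             ploidy = rep_len(ploidy, length(ids)),
             role = rep_len(role, length(ids)),
             sex = rep_len(sex, length(ids)), stringsAsFactors = FALSE)
}

# deterministic AD string consistent with a canonical genotype at depth dp
ad_for_gt <- function(gt, dp) {
  if (is.na(gt)) return(NA_character_)
  al <- as.integer(strsplit(gt, "/", fixed = TRUE)[[1]])
  r <- round(dp * sum(al == 0) / length(al))
  paste0(r, ",", dp - r)
}

# snp_set from a genotype matrix; site/quality fields default to passing
make_set <- function(gt, sheet, dp = 60, gq = 99, qual = 60,
                     alt = "G", transcript = "tx1", positions = NULL,
                     ref = "A", ad = NULL) {
  gt <- as.matrix(gt)
  n <- nrow(gt); k <- ncol(gt)
  if (is.null(positions)) positions <- seq_len(n)
  dpm <- matrix(rep_len(dp, n * k), nrow = n, ncol = k)
  gqm <- matrix(rep_len(gq, n * k), nrow = n, ncol = k)
  if (is.null(ad)) {
    ad <- if (n == 0) {
      matrix(character(0), 0, k)
    } else {
      matrix(mapply(ad_for_gt, canonical_gt(gt), dpm), nrow = n, ncol = k)
    }
  }
  sites <- data.frame(transcript_id = rep_len(transcript, n),
                      position = positions,
                      ref = rep_len(ref, n), alt = rep_len(alt, n),
                      qual = rep_len(qual, n), stringsAsFactors = FALSE)
  snp_set(sites, gt, dpm, ad, gqm, sheet)
}

# minimal coding region: bare CDS, no UTRs
make_region <- function(sequence, transcript_id = "tx1", cds_start = 1L,
                        cds_end = nchar(sequence)) {
  r <- data.frame(transcript_id = transcript_id, sequence = sequence,
                  cds_start = cds_start, cds_end = cds_end,
                  stringsAsFactors = FALSE)
  class(r) <- c("cds_set", "data.frame")
  r
}

# depth table from a matrix (rows = positions of one transcript)
make_depths <- function(depth_matrix, sample_ids, transcript_id = "tx1",
                        positions = seq_len(nrow(depth_matrix))) {
  d <- data.frame(transcript_id = transcript_id, position = positions,
                  stringsAsFactors = FALSE)
  for (j in seq_along(sample_ids)) d[[sample_ids[j]]] <- depth_matrix[, j]
  class(d) <- c("depth_table", "data.frame")
  d
}

# independent genetic-code oracle (seqinr), used to cross-check the
# package's Biostrings-based tables
seqinr_aa <- function(codon) {
  seqinr::translate(strsplit(codon, "")[[1]], ambiguous = FALSE)
}

# write a small VCF text fixture
write_vcf_text <- function(body_lines, sample_ids, path) {
  header <- c("##fileformat=VCFv4.2",
              '##FORMAT=<ID=GT,Number=1,Type=String,Description="GT">',
              '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="DP">',
              '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="AD">',
              '##FORMAT=<ID=GQ,Number=1,Type=Float,Description="GQ">',
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", sample_ids), collapse = "\t"))
  writeLines(c(header, body_lines), path)
  path
}
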