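# SNP-set container: per-site metadata plus per-sample genotype matrices.
# Genotype strings are stored in canonical unphased form (allele indices
# sorted ascending, "/" separated); missing calls are NA.

#' Construct an SNP-set object
#'
#' The in-memory form of a (subset-dialect) VCF: a site table plus genotype,
#' depth, allele-depth and genotype-quality matrices, one column per sample.
#' Genotypes are canonicalised (allele indices sorted ascending), so
#' `"0/1/0"` and `"0/0/1"` compare equal.
#'
#' @param sites data.frame with columns `transcript_id`, `position`, `ref`,
#'   `alt` (comma-separated for multiallelic records), `qual`.
#' @param gt Character matrix of canonical genotype strings (`NA` = missing).
#' @param dp Integer matrix of read depths.
#' @param ad Character matrix of comma-separated per-allele depths (ref first).
#' @param gq Numeric matrix of genotype qualities.
#' @param samples Sample sheet (see [read_sample_sheet()]); its `sample_id`
#'   order defines the column order of the matrices.
#' @return An object of class `snp_set`.
#' @export
snp_set <- function(sites, gt, dp, ad, gq, samples) {
  stopifnot(is.data.frame(sites),
            all(c("transcript_id", "position", "ref", "alt", "qual") %in% names(sites)),
            nrow(gt) == nrow(sites), ncol(gt) == nrow(samples))
  ids <- samples$sample_id
  for (m in list(gt, dp, ad, gq)) stopifnot(identical(dim(m), dim(gt)))
  dimnames(gt) <- dimnames(dp) <- dimnames(ad) <- dimnames(gq) <- list(NULL, ids)
  gt[] <- canonical_gt(gt)
  sites <- as.data.frame(sites, stringsAsFactors = FALSE)
  rownames(sites) <- NULL
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  rownames(samples) <- NULL
  structure(list(sites = sites, gt = gt, dp = dp, ad = ad, gq = gq,
                 samples = samples),
            class = "snp_set")
}

#' @export
print.snp_set <- function(x, ...) {
  cat("snp_set:", nrow(x$sites), "variant record(s),",
      nrow(x$samples), "sample(s)\n")
  cat("  samples:", paste(x$samples$sample_id, collapse = ", "), "\n")
  invisible(x)
}

#' Number of variant records in an SNP set
#' @param x A [snp_set] object.
#' @return Integer count.
#' @export
n_variants <- function(x) nrow(x$sites)

#' Subset an SNP set by record index
#' @param x A [snp_set] object.
#' @param i Row (record) index.
#' @param ... Ignored.
#' @return A [snp_set] with the selected records, all samples retained.
#' @export
`[.snp_set` <- function(x, i, ...) {
  structure(list(sites = x$sites[i, , drop = FALSE],
                 gt = x$gt[i, , drop = FALSE], dp = x$dp[i, , drop = FALSE],
                 ad = x$ad[i, , drop = FALSE], gq = x$gq[i, , drop = FALSE],
                 samples = x$samples),
            class = "snp_set")
}

#' Canonicalise genotype strings
#'
#' Sorts allele indices ascending and joins with `"/"` (unphased canonical
#' form); any genotype containing `"."` becomes `NA`.
#'
#' @param gt Character vector (or matrix) of GT strings.
#' @return Same shape, canonicalised.
#' @export
canonical_gt <- function(gt) {
  u <- unique(as.vector(gt))
  u <- u[!is.na(u)]
  mapped <- vapply(u, function(g) {
    parts <- strsplit(g, "[/|]")[[1]]
    if (any(parts == ".")) return(NA_character_)
    paste(sort(as.integer(parts)), collapse = "/")
  }, character(1))
  out <- unname(mapped)[match(as.vector(gt), u)]
  if (is.matrix(gt)) dim(out) <- dim(gt)
  out
}

# allele indices of one canonical genotype string, or NULL if missing
.gt_alleles <- function(g) {
  if (is.na(g)) return(NULL)
  as.integer(strsplit(g, "/", fixed = TRUE)[[1]])
}

#' Read a sample sheet
#'
#' Tab-separated columns: `sample_id`, `species_id`, `ploidy` (2 or 3),
#' `role` (`adult` or `offspring_pool`), `sex` (`female`, `male`, `unknown`).
#'
#' @param path Path to the TSV.
#' @return data.frame with the five columns, validated.
#' @export
read_sample_sheet <- function(path) {
  sheet <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("sample_id", "species_id", "ploidy", "role", "sex")
  if (!all(req %in% names(sheet))) {
    stop("sample sheet must have columns: ", paste(req, collapse = ", "))
  }
  if (anyDuplicated(sheet$sample_id)) stop("duplicate sample_id in sample sheet")
  if (!all(sheet$ploidy %in% c(2L, 3L))) stop("ploidy must be 2 or 3")
  if (!all(sheet$role %in% c("adult", "offspring_pool"))) {
    stop("role must be 'adult' or 'offspring_pool'")
  }
  if (!all(sheet$sex %in% c("female", "male", "unknown"))) {
    stop("sex must be 'female', 'male' or 'unknown'")
  }
  sheet[req]
}

#' Write a sample sheet
#' @param samples Sample-sheet data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sample_sheet <- function(samples, path) {
  utils::write.table(samples, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a VCF into an SNP set
#'
#' Accepts a VCF 4.x subset with GT, DP, AD and GQ FORMAT fields and
#' single-base SNP records only; indel/MNP records are skipped with a
#' warning. Triploid genotypes like `"0/0/1"` are parsed into length-3
#' allele multisets and canonicalised; `"./."`-style genotypes (any ploidy)
#' become missing calls. A non-missing genotype whose arity differs from the
#' sample's declared ploidy is a hard error.
#'
#' @param path Path to the VCF (plain text).
#' @param samples Sample sheet covering every VCF sample column.
#' @return A [snp_set].
#' @export
read_vcf <- function(path, samples) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fixm <- vcfR::getFIX(v)
  if (is.null(dim(fixm))) fixm <- t(fixm)   # single-record VCF
  fix <- as.data.frame(fixm, stringsAsFactors = FALSE)
  if (nrow(fix) == 0L) {
    empty <- matrix(character(0), 0, nrow(samples))
    return(snp_set(data.frame(transcript_id = character(0), position = integer(0),
                              ref = character(0), alt = character(0),
                              qual = numeric(0)),
                   empty, empty, empty, empty, samples))
  }
  vcf_samples <- colnames(v@gt)[-1]
  unknown <- setdiff(vcf_samples, samples$sample_id)
  if (length(unknown)) {
    stop("VCF sample(s) not in the sample sheet: ", paste(unknown, collapse = ", "))
  }
  alt_list <- strsplit(fix$ALT, ",", fixed = TRUE)
  is_snp <- nchar(fix$REF) == 1L &
    vapply(alt_list, function(a) all(nchar(a) == 1L), logical(1))
  if (any(!is_snp)) {
    warning(sum(!is_snp), " non-SNP record(s) (indel/MNP) skipped")
  }
  gt <- vcfR::extract.gt(v, "GT")
  dp <- vcfR::extract.gt(v, "DP", as.numeric = TRUE)
  ad <- vcfR::extract.gt(v, "AD")
  gq <- vcfR::extract.gt(v, "GQ", as.numeric = TRUE)
  keep <- which(is_snp)
  ord <- match(samples$sample_id, vcf_samples)
  if (anyNA(ord)) {
    stop("sample sheet sample(s) absent from VCF: ",
         paste(samples$sample_id[is.na(ord)], collapse = ", "))
  }
  sub <- function(m) m[keep, ord, drop = FALSE]
  gt <- sub(gt); dp <- sub(dp); ad <- sub(ad); gq <- sub(gq)
  # arity check before canonicalisation
  arity <- matrix(lengths(strsplit(as.vector(gt), "[/|]")), nrow = nrow(gt))
  miss <- matrix(grepl(".", as.vector(gt), fixed = TRUE) | is.na(as.vector(gt)),
                 nrow = nrow(gt))
  exp_ploidy <- matrix(samples$ploidy, nrow = nrow(gt), ncol = nrow(samples),
                       byrow = TRUE)
  bad <- !miss & arity != exp_ploidy
  if (any(bad)) {
    w <- which(bad, arr.ind = TRUE)[1, ]
    stop("genotype arity mismatch for sample '", samples$sample_id[w[2]],
         "' at ", fix$CHROM[keep[w[1]]], ":", fix$POS[keep[w[1]]],
         " (declared ploidy ", samples$ploidy[w[2]], ")")
  }
  sites <- data.frame(transcript_id = fix$CHROM[keep],
                      position = as.integer(fix$POS[keep]),
                      ref = fix$REF[keep], alt = fix$ALT[keep],
                      qual = as.numeric(fix$QUAL[keep]),
                      stringsAsFactors = FALSE)
  storage.mode(dp) <- "integer"
  snp_set(sites, gt, dp, ad, gq, samples)
}

#' Write an SNP set as a VCF 4.2 file
#'
#' Emits GT:DP:AD:GQ with genotypes in canonical sorted form (`"0/0/1"`,
#' never `"0/1/0"`), records ordered by (transcript_id, position), and
#' `##FORMAT` headers for all four fields. Output is byte-deterministic for
#' a given input.
#'
#' @param x A [snp_set].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(x, path) {
  stopifnot(inherits(x, "snp_set"))
  ord <- order(x$sites$transcript_id, x$sites$position)
  s <- x$sites[ord, , drop = FALSE]
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=pnpstools",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
    '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allele read depths (ref first)">',
    '##FORMAT=<ID=GQ,Number=1,Type=Float,Description="Genotype quality">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", x$samples$sample_id), collapse = "\t"))
  if (nrow(s) == 0L) {
    writeLines(header, path)
    return(invisible(path))
  }
  ploidy <- x$samples$ploidy
  miss_gt <- vapply(ploidy, function(p) paste(rep(".", p), collapse = "/"),
                    character(1))
  cols <- lapply(seq_len(nrow(x$samples)), function(j) {
    g <- x$gt[ord, j]
    g[is.na(g)] <- miss_gt[j]
    d <- x$dp[ord, j]; a <- x$ad[ord, j]; q <- x$gq[ord, j]
    paste(g, ifelse(is.na(d), ".", d), ifelse(is.na(a), ".", a),
          ifelse(is.na(q), ".", format(q, trim = TRUE, scientific = FALSE)),
          sep = ":")
  })
  lines <- do.call(paste, c(list(s$transcript_id, s$position, ".", s$ref, s$alt,
                                 format(s$qual, trim = TRUE, scientific = FALSE),
                                 ".", ".", "GT:DP:AD:GQ"),
                            cols, sep = "\t"))
  writeLines(c(header, lines), path)
  invisible(path)
}

#' Read coding regions from a FASTA plus a CDS coordinate table
#'
#' The coordinate table is a TSV with columns `transcript_id`, `cds_start`,
#' `cds_end` (1-based inclusive, header optional). Transcripts present in
#' the FASTA but absent from the table are skipped with a warning. The CDS
#' length must be divisible by 3, lie within the sequence, and contain no
#' ambiguity codes.
#'
#' @param fasta Path to the transcript FASTA.
#' @param cds_table Path to the coordinate TSV.
#' @return data.frame of class `cds_set` with columns `transcript_id`,
#'   `sequence`, `cds_start`, `cds_end`.
#' @export
read_cds <- function(fasta, cds_table) {
  seqs <- Biostrings::readDNAStringSet(fasta)
  tab <- utils::read.delim(cds_table, header = FALSE, stringsAsFactors = FALSE,
                           col.names = c("transcript_id", "cds_start", "cds_end"))
  if (tab$transcript_id[1] == "transcript_id") tab <- tab[-1, , drop = FALSE]
  tab$cds_start <- as.integer(tab$cds_start)
  tab$cds_end <- as.integer(tab$cds_end)
  ids <- sub("\\s.*$", "", names(seqs))
  absent <- setdiff(ids, tab$transcript_id)
  if (length(absent)) {
    warning(length(absent), " transcript(s) in FASTA but not in CDS table; skipped")
  }
  missing_seq <- setdiff(tab$transcript_id, ids)
  if (length(missing_seq)) {
    stop("CDS table transcript(s) absent from FASTA: ",
         paste(head(missing_seq, 5), collapse = ", "))
  }
  seq_chr <- as.character(seqs)
  names(seq_chr) <- ids
  regions <- data.frame(transcript_id = tab$transcript_id,
                        sequence = unname(seq_chr[tab$transcript_id]),
                        cds_start = tab$cds_start, cds_end = tab$cds_end,
                        stringsAsFactors = FALSE)
  len <- regions$cds_end - regions$cds_start + 1L
  if (any(len %% 3L != 0L)) {
    stop("CDS length not divisible by 3 for: ",
         paste(head(regions$transcript_id[len %% 3L != 0L], 5), collapse = ", "))
  }
  if (any(regions$cds_end > nchar(regions$sequence))) {
    bad <- regions$cds_end > nchar(regions$sequence)
    stop("cds_end beyond sequence for: ",
         paste(head(regions$transcript_id[bad], 5), collapse = ", "))
  }
  cds <- substr(regions$sequence, regions$cds_start, regions$cds_end)
  if (any(grepl("[^ACGT]", cds))) {
    bad <- grepl("[^ACGT]", cds)
    stop("ambiguity code inside CDS for: ",
         paste(head(regions$transcript_id[bad], 5), collapse = ", "))
  }
  class(regions) <- c("cds_set", "data.frame")
  regions
}

#' Write coding regions as FASTA plus CDS coordinate TSV
#' @param regions A `cds_set` data.frame.
#' @param fasta Output FASTA path.
#' @param cds_table Output TSV path.
#' @return Invisibly, `c(fasta, cds_table)`.
#' @export
write_cds <- function(regions, fasta, cds_table) {
  ss <- Biostrings::DNAStringSet(setNames(regions$sequence, regions$transcript_id))
  Biostrings::writeXStringSet(ss, fasta, width = 80L)
  utils::write.table(regions[c("transcript_id", "cds_start", "cds_end")],
                     cds_table, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(fasta, cds_table))
}

#' Read a per-base depth table
#'
#' TSV with columns `transcript_id`, `position`, then one integer depth
#' column per sample (header row carries the sample ids).
#'
#' @param path Path to the TSV.
#' @return data.frame of class `depth_table`.
#' @export
read_depth_table <- function(path) {
  d <- as.data.frame(data.table::fread(path, sep = "\t", header = TRUE,
                                       showProgress = FALSE))
  if (!all(c("transcript_id", "position") %in% names(d))) {
    stop("depth table must start with transcript_id and position columns")
  }
  if (any(vapply(d[-(1:2)], function(col) any(col < 0), logical(1)))) {
    stop("negative depths in depth table")
  }
  class(d) <- c("depth_table", "data.frame")
  d
}

#' Write a per-base depth table
#' @param depths A `depth_table` data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_depth_table <- function(depths, path) {
  data.table::fwrite(as.data.frame(depths), path, sep = "\t")
  invisible(path)
}

#' Apply per-genotype and per-site quality filters
#'
#' Retains only records where every sample's call has depth and genotype
#' quality at or above the thresholds (inclusive) and the site quality is at
#' or above its threshold. Missing calls fail the filter. The input is not
#' modified.
#'
#' @param x A [snp_set].
#' @param min_depth Minimum per-sample depth (default 20).
#' @param min_gq Minimum per-sample genotype quality (default 30).
#' @param min_site_qual Minimum site QUAL (default 30).
#' @return A filtered [snp_set].
#' @export
apply_quality_filters <- function(x, min_depth = 20, min_gq = 30,
                                  min_site_qual = 30) {
  stopifnot(inherits(x, "snp_set"))
  if (n_variants(x) == 0L) return(x)
  ok_call <- !is.na(x$gt) & !is.na(x$dp) & x$dp >= min_depth &
    !is.na(x$gq) & x$gq >= min_gq
  keep <- rowSums(ok_call) == ncol(x$gt) &
    !is.na(x$sites$qual) & x$sites$qual >= min_site_qual
  x[which(keep)]
}
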