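NUCLEOTIDES <- c("A", "C", "G", "T")

# 64 codons in fixed lexicographic order; amino acids from the standard code.
ALL_CODONS <- as.vector(outer(outer(NUCLEOTIDES, NUCLEOTIDES, paste0),
                              NUCLEOTIDES, paste0))
ALL_CODONS <- sort(ALL_CODONS)
CODON_AA <- Biostrings::GENETIC_CODE[ALL_CODONS]
STOP_CODONS <- names(CODON_AA)[CODON_AA == "*"]
SENSE_CODONS <- setdiff(ALL_CODONS, STOP_CODONS)

# Per-codon, per-position fraction of the three single-base changes that are
# synonymous (NG86 site weights). Stop codons get NA rows.
.syn_frac <- local({
  m <- matrix(NA_real_, nrow = 64, ncol = 3, dimnames = list(ALL_CODONS, NULL))
  for (cod in SENSE_CODONS) {
    bases <- strsplit(cod, "")[[1]]
    for (pos in 1:3) {
      alts <- setdiff(NUCLEOTIDES, bases[pos])
      syn <- 0L
      for (alt in alts) {
        mut <- bases
        mut[pos] <- alt
        if (CODON_AA[[paste(mut, collapse = "")]] == CODON_AA[[cod]]) {
          syn <- syn + 1L
        }
      }
      m[cod, pos] <- syn / 3
    }
  }
  m
})

#' Translate a codon under the standard genetic code
#'
#' @param codon A single 3-letter string over A/C/G/T.
#' @return A one-letter amino-acid code, or `"*"` for a stop codon.
#' @examples
#' translate_codon("ATG")
#' translate_codon("TAA")
#' @export
translate_codon <- function(codon) {
  if (!is.character(codon) || length(codon) != 1L || nchar(codon) != 3L) {
    stop("`codon` must be a single 3-letter string")
  }
  codon <- toupper(codon)
  if (grepl("[^ACGT]", codon)) {
    stop("codon '", codon, "' contains a non-ACGT character (ambiguity codes are not supported)")
  }
  unname(CODON_AA[[codon]])
}

#' Nei-Gojobori (1986) synonymous/nonsynonymous site counts for one codon
#'
#' Each codon position contributes `s/3` synonymous sites, where `s` is the
#' number of the three possible single-base changes at that position that
#' preserve the encoded amino acid; the remainder is nonsynonymous. Changes
#' creating a stop codon count as nonsynonymous. The two counts always sum
#' to 3.
#'
#' @param codon A sense codon (3-letter string over A/C/G/T).
#' @return Named numeric vector with elements `syn_sites` and `nonsyn_sites`.
#' @examples
#' ng86_codon_sites("TTT")  # 1/3 synonymous site
#' ng86_codon_sites("GGG")  # 1 synonymous site (4-fold third position)
#' @export
ng86_codon_sites <- function(codon) {
  if (!is.character(codon) || length(codon) != 1L || nchar(codon) != 3L) {
    stop("`codon` must be a single 3-letter string")
  }
  codon <- toupper(codon)
  if (grepl("[^ACGT]", codon)) stop("codon contains a non-ACGT character")
  if (codon %in% STOP_CODONS) {
    stop("'", codon, "' is a stop codon; NG86 site counts are defined for sense codons only")
  }
  syn <- sum(.syn_frac[codon, ])
  c(syn_sites = syn, nonsyn_sites = 3 - syn)
}

# Effect of substituting `alt` at codon position `codon_pos` of `codon`,
# vectorised. Returns "synonymous"/"nonsynonymous".
.substitution_effect <- function(codon, codon_pos, alt) {
  mut <- codon
  substr(mut, codon_pos, codon_pos) <- alt
  unname(ifelse(CODON_AA[codon] == CODON_AA[mut],
                "synonymous", "nonsynonymous"))
}

#' Classify a single-base substitution as synonymous or nonsynonymous
#'
#' The substitution is judged against the reference codon containing the
#' position: the alternate base is swapped in, both codons are translated and
#' compared. Identical amino acids give `"synonymous"`; anything else,
#' including stop gain or loss, gives `"nonsynonymous"`. Positions outside
#' the CDS give `"non_coding"`.
#'
#' @param region A single coding region (one row of a [read_cds()] table, or
#'   a list with `sequence`, `cds_start`, `cds_end`).
#' @param position 1-based position on the transcript.
#' @param ref Reference base; must match the region's sequence at `position`.
#' @param alt Alternate base.
#' @return One of `"synonymous"`, `"nonsynonymous"`, `"non_coding"`.
#' @export
classify_substitution <- function(region, position, ref, alt) {
  if (is.data.frame(region)) {
    stopifnot(nrow(region) == 1L)
    region <- as.list(region)
  }
  seq <- region$sequence
  have <- substr(seq, position, position)
  if (have != ref) {
    stop("reference mismatch at ", region$transcript_id, ":", position,
         ": sequence has '", have, "', record claims '", ref, "'")
  }
  if (position < region$cds_start || position > region$cds_end) {
    return("non_coding")
  }
  off <- position - region$cds_start          # 0-based within CDS
  codon_start <- region$cds_start + 3L * (off %/% 3L)
  codon <- substr(seq, codon_start, codon_start + 2L)
  .substitution_effect(codon, off %% 3L + 1L, alt)
}

# Long-format table of every CDS nucleotide position across a set of coding
# regions: transcript_id, position, base, codon, codon_pos, syn_w (NG86
# synonymous weight of that position under the reference codon).
.cds_position_table <- function(regions) {
  cds_seq <- substr(regions$sequence, regions$cds_start, regions$cds_end)
  lens <- nchar(cds_seq)
  bases <- unlist(strsplit(cds_seq, ""), use.names = FALSE)
  tid <- rep(regions$transcript_id, lens)
  pos <- unlist(lapply(seq_len(nrow(regions)), function(i) {
    seq.int(regions$cds_start[i], regions$cds_end[i])
  }), use.names = FALSE)
  codon_pos <- unlist(lapply(lens, function(n) rep_len(1:3, n)), use.names = FALSE)
  # codon string at each position
  n <- length(bases)
  first <- seq_len(n) - (codon_pos - 1L)
  codon <- paste0(bases[first], bases[first + 1L], bases[first + 2L])
  syn_w <- .syn_frac[cbind(match(codon, ALL_CODONS), codon_pos)]
  if (anyNA(syn_w)) {
    bad <- unique(tid[is.na(syn_w)])
    stop("internal stop codon(s) in CDS of: ", paste(utils::head(bad, 5), collapse = ", "))
  }
  data.table::data.table(transcript_id = tid, position = pos, base = bases,
                         codon = codon, codon_pos = codon_pos, syn_w = syn_w)
}

#' Depth-conditioned NG86 covered-site totals (the pN/pS denominators)
#'
#' A CDS nucleotide position contributes its NG86 fractional synonymous and
#' nonsynonymous weights (taken from its reference codon) if and only if its
#' sequencing depth reaches `min_depth` in the focal sample
#' (`mode = "per_individual"`) or in every listed sample
#' (`mode = "all_individuals"`). Positions absent from the depth table count
#' as depth 0; positions outside any CDS contribute nothing. Exclusion is
#' per-nucleotide, not per-codon.
#'
#' @param regions A coding-region table from [read_cds()].
#' @param depths A depth table from [read_depth_table()].
#' @param samples Sample ids (character), or a sample-sheet subset.
#' @param mode `"per_individual"` (exactly one sample) or `"all_individuals"`.
#' @param min_depth Minimum depth, inclusive (default 20).
#' @return List with `covered_nonsyn_sites` and `covered_syn_sites`
#'   (fractional site counts).
#' @export
covered_site_totals <- function(regions, depths, samples,
                                mode = c("per_individual", "all_individuals"),
                                min_depth = 20) {
  mode <- match.arg(mode)
  if (is.data.frame(samples)) samples <- samples$sample_id
  if (mode == "per_individual" && length(samples) != 1L) {
    stop("per_individual mode requires exactly one sample")
  }
  missing_cols <- setdiff(samples, names(depths))
  if (length(missing_cols)) {
    stop("sample(s) absent from depth table: ", paste(missing_cols, collapse = ", "))
  }
  ptab <- attr(regions, "position_table")
  if (is.null(ptab)) ptab <- .cds_position_table(regions)
  key <- paste(ptab$transcript_id, ptab$position)
  dkey <- paste(depths$transcript_id, depths$position)
  idx <- match(key, dkey)
  pass <- rep(TRUE, nrow(ptab))
  for (s in samples) {
    d <- depths[[s]][idx]
    d[is.na(d)] <- 0
    pass <- pass & d >= min_depth
  }
  syn <- sum(ptab$syn_w[pass])
  list(covered_nonsyn_sites = sum(pass) - syn, covered_syn_sites = syn)
}

#' Precompute and cache the per-position NG86 weight table on a region set
#'
#' Attaches the long-format CDS position table as an attribute so repeated
#' calls to [covered_site_totals()] and [snp_effects()] on the same regions
#' avoid rebuilding it.
#'
#' @param regions A coding-region table from [read_cds()].
#' @return `regions`, with a `position_table` attribute.
#' @export
index_regions <- function(regions) {
  attr(regions, "position_table") <- .cds_position_table(regions)
  regions
}

#' Effect class of every biallelic SNP record against a region set
#'
#' @param x A [snp_set] object.
#' @param regions A coding-region table from [read_cds()] (ideally passed
#'   through [index_regions()]).
#' @return Character vector, one element per record: `"synonymous"`,
#'   `"nonsynonymous"`, `"non_coding"` (outside the CDS), or `NA` for
#'   multiallelic records.
#' @export
snp_effects <- function(x, regions) {
  stopifnot(inherits(x, "snp_set"))
  ptab <- attr(regions, "position_table")
  if (is.null(ptab)) ptab <- .cds_position_table(regions)
  sites <- x$sites
  unknown <- setdiff(unique(sites$transcript_id), regions$transcript_id)
  if (length(unknown)) {
    stop("variant transcript(s) not in the region set: ",
         paste(utils::head(unknown, 5), collapse = ", "))
  }
  out <- rep(NA_character_, nrow(sites))
  bi <- !grepl(",", sites$alt, fixed = TRUE)
  idx <- match(paste(sites$transcript_id, sites$position),
               paste(ptab$transcript_id, ptab$position))
  coding <- bi & !is.na(idx)
  out[bi & is.na(idx)] <- "non_coding"
  if (any(coding)) {
    i <- idx[coding]
    mismatch <- ptab$base[i] != sites$ref[coding]
    if (any(mismatch)) {
      w <- which(coding)[mismatch][1]
      stop("reference mismatch at ", sites$transcript_id[w], ":", sites$position[w])
    }
    out[coding] <- .substitution_effect(ptab$codon[i], ptab$codon_pos[i],
                                        sites$alt[coding])
  }
  out
}
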