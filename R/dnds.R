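# Pairwise dN/dS by Nei-Gojobori (1986) counting with Jukes-Cantor
# correction. This is a deliberate desk-scale stand-in for maximum-
# likelihood codon-model estimation: sites are averaged over both
# sequences' NG86 counts, multi-difference codons average the synonymous/
# nonsynonymous step counts over all substitution orderings (paths through
# stop codons allowed, stop steps counted nonsynonymous), and proportions
# are corrected with d = -(3/4) ln(1 - 4p/3).

# average (syn, nonsyn) step counts between two differing codons over all
# orderings of the differing positions
.codon_path_diffs <- function(ca, cb) {
  pos <- which(strsplit(ca, "")[[1]] != strsplit(cb, "")[[1]])
  k <- length(pos)
  if (k == 0L) return(c(syn = 0, nonsyn = 0))
  perms <- if (k == 1L) {
    list(pos)
  } else if (k == 2L) {
    list(pos, rev(pos))
  } else {
    list(pos[c(1, 2, 3)], pos[c(1, 3, 2)], pos[c(2, 1, 3)],
         pos[c(2, 3, 1)], pos[c(3, 1, 2)], pos[c(3, 2, 1)])
  }
  tb <- strsplit(cb, "")[[1]]
  tot <- c(syn = 0, nonsyn = 0)
  for (ord in perms) {
    cur <- ca
    for (p in ord) {
      nxt <- cur
      substr(nxt, p, p) <- tb[p]
      aa1 <- CODON_AA[[cur]]; aa2 <- CODON_AA[[nxt]]
      if (aa1 == aa2 && aa1 != "*") {
        tot["syn"] <- tot["syn"] + 1
      } else {
        tot["nonsyn"] <- tot["nonsyn"] + 1   # includes any stop-passing step
      }
      cur <- nxt
    }
  }
  tot / length(perms)
}

.jc_correct <- function(p) {
  if (is.na(p) || p >= 3 / 4) return(NA_real_)
  -0.75 * log(1 - 4 * p / 3)
}

#' Pairwise dN/dS by NG86 counting with Jukes-Cantor correction
#'
#' @param seq_a,seq_b Aligned coding sequences of equal length divisible by
#'   3, over A/C/G/T, with no gaps and no internal stop codons (pre-filter
#'   codons containing gaps or ambiguity before calling).
#' @return A `dnds_result`: mean NG86 site counts, average synonymous and
#'   nonsynonymous differences, proportions `pS_prop`/`pN_prop`,
#'   Jukes-Cantor distances `dS`/`dN` (missing when the proportion reaches
#'   the correction's 3/4 saturation bound) and their ratio `dnds` (missing
#'   when `dS` is 0 or undefined).
#' @examples
#' pairwise_dnds("TTTGGGAAA", "TTCGGGAAA")
#' @export
pairwise_dnds <- function(seq_a, seq_b) {
  seq_a <- toupper(seq_a); seq_b <- toupper(seq_b)
  if (nchar(seq_a) != nchar(seq_b)) stop("sequences must have equal length")
  if (nchar(seq_a) %% 3L != 0L) stop("sequence length must be divisible by 3")
  if (grepl("[^ACGT]", seq_a) || grepl("[^ACGT]", seq_b)) {
    stop("sequences must contain only A/C/G/T (pre-filter gaps and ambiguity)")
  }
  n_codon <- nchar(seq_a) %/% 3L
  starts <- 3L * seq_len(n_codon) - 2L
  cod_a <- substring(seq_a, starts, starts + 2L)
  cod_b <- substring(seq_b, starts, starts + 2L)
  if (any(cod_a %in% STOP_CODONS) || any(cod_b %in% STOP_CODONS)) {
    stop("internal stop codon in input; trim terminal stops and pre-filter")
  }
  sites_a <- rowSums(vapply(cod_a, ng86_codon_sites, numeric(2)))
  sites_b <- rowSums(vapply(cod_b, ng86_codon_sites, numeric(2)))
  syn_sites <- (sites_a["syn_sites"] + sites_b["syn_sites"]) / 2
  nonsyn_sites <- (sites_a["nonsyn_sites"] + sites_b["nonsyn_sites"]) / 2
  diffs <- c(syn = 0, nonsyn = 0)
  for (i in which(cod_a != cod_b)) {
    diffs <- diffs + .codon_path_diffs(cod_a[i], cod_b[i])
  }
  pS <- unname(diffs["syn"] / syn_sites)
  pN <- unname(diffs["nonsyn"] / nonsyn_sites)
  dS <- .jc_correct(pS)
  dN <- .jc_correct(pN)
  dnds <- if (is.na(dS) || dS == 0 || is.na(dN)) NA_real_ else dN / dS
  structure(list(syn_sites_mean = unname(syn_sites),
                 nonsyn_sites_mean = unname(nonsyn_sites),
                 syn_diffs = unname(diffs["syn"]),
                 nonsyn_diffs = unname(diffs["nonsyn"]),
                 pS_prop = pS, pN_prop = pN, dS = dS, dN = dN, dnds = dnds),
            class = "dnds_result")
}

#' @export
print.dnds_result <- function(x, ...) {
  cat("Pairwise NG86 dN/dS (Jukes-Cantor corrected)\n")
  cat(sprintf("  sites (mean of pair): %.2f syn, %.2f nonsyn\n",
              x$syn_sites_mean, x$nonsyn_sites_mean))
  cat(sprintf("  differences: %.2f syn, %.2f nonsyn\n", x$syn_diffs, x$nonsyn_diffs))
  cat(sprintf("  dS = %s, dN = %s, dN/dS = %s\n",
              format(x$dS, digits = 4), format(x$dN, digits = 4),
              if (is.na(x$dnds)) "undefined" else format(x$dnds, digits = 4)))
  invisible(x)
}
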