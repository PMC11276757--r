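# Independent brute-force oracle: NG86 site counts via enumeration of all
# nine single-base mutants, translated with seqinr (not Biostrings).
oracle_ng86 <- function(codon) {
  bases <- strsplit(codon, "")[[1]]
  syn <- 0
  for (pos in 1:3) {
    for (alt in setdiff(c("A", "C", "G", "T"), bases[pos])) {
      mut <- bases
      mut[pos] <- alt
      if (seqinr_aa(paste(mut, collapse = "")) == seqinr_aa(codon)) {
        syn <- syn + 1
      }
    }
  }
  c(syn_sites = syn / 3, nonsyn_sites = 3 - syn / 3)
}

sense <- setdiff(
  apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                    c("A", "C", "G", "T")), 1, paste, collapse = ""),
  c("TAA", "TAG", "TGA"))

test_that("codon translation follows the standard code and rejects ambiguity", {
  expect_equal(translate_codon("ATG"), "M")
  expect_equal(translate_codon("TAA"), "*")
  expect_equal(translate_codon("GGA"), "G")
  expect_error(translate_codon("ANG"), "ambiguity|non-ACGT")
  expect_error(translate_codon("AT"))
})

test_that("NG86 site counts match brute-force enumeration for all 61 sense codons", {
  for (cod in sense) {
    expect_equal(ng86_codon_sites(cod), oracle_ng86(cod), info = cod)
  }
  # frozen examples from the oracle
  expect_equal(ng86_codon_sites("TTT"), c(syn_sites = 1 / 3, nonsyn_sites = 8 / 3))
  expect_equal(ng86_codon_sites("GGG"), c(syn_sites = 1, nonsyn_sites = 2))
  expect_equal(ng86_codon_sites("ATG"), c(syn_sites = 0, nonsyn_sites = 3))
  expect_error(ng86_codon_sites("TAA"), "stop codon")
})

test_that("sense-codon site totals always sum to 3 (183 over the code)", {
  tot <- vapply(sense, function(cod) sum(ng86_codon_sites(cod)), numeric(1))
  expect_true(all(abs(tot - 3) < 1e-12))
  expect_equal(sum(tot), 183)
})

test_that("substitutions classify by amino-acid change against the reference codon", {
  reg <- make_region("GGAAAACAA")  # Gly Lys Gln
  expect_equal(classify_substitution(reg, 3, "A", "G"), "synonymous")     # GGA->GGG
  expect_equal(classify_substitution(reg, 5, "A", "G"), "nonsynonymous")  # AAA->AGA
  expect_equal(classify_substitution(reg, 7, "C", "T"), "nonsynonymous")  # CAA->TAA (stop gain)
  expect_error(classify_substitution(reg, 3, "C", "G"), "mismatch")
  reg2 <- make_region("TTGGAAAATT", cds_start = 3L, cds_end = 8L)
  expect_equal(classify_substitution(reg2, 1, "T", "C"), "non_coding")
  expect_equal(classify_substitution(reg2, 10, "T", "C"), "non_coding")
})

test_that("synonymy is symmetric under ref/alt swap within a fixed codon", {
  set.seed(7)
  for (i in 1:200) {
    cod <- sample(sense, 1)
    pos <- sample(1:3, 1)
    ref <- substr(cod, pos, pos)
    alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
    mut <- cod
    substr(mut, pos, pos) <- alt
    if (mut %in% c("TAA", "TAG", "TGA")) next   # reverse would start from a stop
    fwd <- classify_substitution(make_region(cod), pos, ref, alt)
    rev <- classify_substitution(make_region(mut), pos, alt, ref)
    expect_equal(fwd, rev, info = paste(cod, pos, alt))
  }
})

test_that("covered-site totals apply the depth condition per nucleotide", {
  reg <- make_region("TTT")
  d1 <- make_depths(matrix(25L, 3, 1), "s1")
  r1 <- covered_site_totals(reg, d1, "s1", mode = "per_individual")
  expect_equal(r1$covered_syn_sites, 1 / 3)
  expect_equal(r1$covered_nonsyn_sites, 8 / 3)

  d2 <- make_depths(matrix(c(25L, 19L, 25L), 3, 1), "s1")
  r2 <- covered_site_totals(reg, d2, "s1", mode = "per_individual")
  expect_equal(r2$covered_syn_sites, 1 / 3)      # only positions 1 and 3 count
  expect_equal(r2$covered_nonsyn_sites, 5 / 3)

  d3 <- make_depths(cbind(rep(25L, 3), rep(5L, 3)), c("s1", "s2"))
  r3 <- covered_site_totals(reg, d3, c("s1", "s2"), mode = "all_individuals")
  expect_equal(r3$covered_syn_sites, 0)
  expect_equal(r3$covered_nonsyn_sites, 0)

  # positions absent from the depth table count as depth 0
  d4 <- make_depths(matrix(25L, 2, 1), "s1", positions = c(1L, 3L))
  r4 <- covered_site_totals(reg, d4, "s1", mode = "per_individual")
  expect_equal(r4$covered_syn_sites + r4$covered_nonsyn_sites, 2)
  expect_error(covered_site_totals(reg, d1, c("s1", "sZ"),
                                   mode = "all_individuals"), "sZ")
  expect_error(covered_site_totals(reg, d3, c("s1", "s2"),
                                   mode = "per_individual"), "exactly one")
})

test_that("covered-site totals are monotone in depth threshold and sample count", {
  set.seed(11)
  seq <- paste(c("ATG", sample(sense, 40, replace = TRUE)), collapse = "")
  reg <- make_region(seq)
  dm <- matrix(sample(0:60, nchar(seq) * 3, replace = TRUE), ncol = 3)
  d <- make_depths(dm, c("s1", "s2", "s3"))
  prev <- Inf
  for (thr in c(5, 20, 40, 55)) {
    r <- covered_site_totals(reg, d, "s1", mode = "per_individual",
                             min_depth = thr)
    tot <- r$covered_syn_sites + r$covered_nonsyn_sites
    expect_lte(tot, prev)
    prev <- tot
  }
  tot_k <- vapply(1:3, function(k) {
    r <- covered_site_totals(reg, d, c("s1", "s2", "s3")[1:k],
                             mode = "all_individuals")
    r$covered_syn_sites + r$covered_nonsyn_sites
  }, numeric(1))
  expect_true(all(diff(tot_k) <= 0))
})

test_that("snp_effects classifies records in bulk and guards the reference", {
  reg <- index_regions(make_region("GGAAAACAA"))
  sheet <- make_sheet("s1", ploidy = 2L)
  x <- make_set(rbind("0/1", "0/1", "0/1"), sheet, positions = c(3L, 5L, 7L),
                ref = c("A", "A", "C"), alt = c("G", "G", "T"))
  expect_equal(snp_effects(x, reg),
               c("synonymous", "nonsynonymous", "nonsynonymous"))
  bad <- make_set(rbind("0/1"), sheet, positions = 3L, ref = "C", alt = "G")
  expect_error(snp_effects(bad, reg), "mismatch")
  multi <- make_set(rbind("0/1"), sheet, positions = 3L, ref = "A", alt = "G,T")
  expect_true(is.na(snp_effects(multi, reg)))
})
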