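small_cfg <- function(seed = 1, ...) {
  sim_config(seed = seed, n_transcripts = 60, cds_length_codons = 50, ...)
}

test_that("reference CDS generation is deterministic and stop-free", {
  cfg <- small_cfg(seed = 5)
  r1 <- generate_reference_cds(cfg, prefix = "x")
  r2 <- generate_reference_cds(cfg, prefix = "x")
  expect_identical(r1, r2)
  r3 <- generate_reference_cds(cfg, prefix = "x", seed = 6)
  expect_false(identical(r1$sequence, r3$sequence))
  expect_true(all(startsWith(r1$sequence, "ATG")))
  expect_equal(unique(nchar(r1$sequence)), 3 * 50 + 3)   # CDS + terminal stop
  expect_equal(unique(r1$cds_end), 150L)
  cds_codons <- substring(r1$sequence[1], seq(1, 148, 3), seq(3, 150, 3))
  expect_false(any(cds_codons %in% c("TAA", "TAG", "TGA")))
})

test_that("progenitor divergence controls the ancestral het-site density", {
  cfg0 <- small_cfg(divergence = 0)
  reg <- generate_reference_cds(cfg0, prefix = "x", seed = 2)
  expect_equal(nrow(make_triploid_clone(cfg0, reg)$het_sites), 0L)

  cfg <- sim_config(seed = 3, n_transcripts = 400, cds_length_codons = 80,
                    divergence = 0.01)
  reg2 <- generate_reference_cds(cfg, prefix = "x", seed = 2)
  clone <- make_triploid_clone(cfg, reg2)
  L <- 400 * 240
  # closed-form expectation: d * L * (P_syn + P_nonsyn * f_ancestral), where
  # P_syn is the NG86 synonymous fraction of sites in the generated regions
  p_syn <- sum(vapply(seq_len(nrow(reg2)), function(i) {
    s <- substr(reg2$sequence[i], reg2$cds_start[i], reg2$cds_end[i])
    cods <- substring(s, seq(1, nchar(s) - 2, 3), seq(3, nchar(s), 3))
    sum(vapply(cods, function(cd) ng86_codon_sites(cd)[["syn_sites"]],
               numeric(1)))
  }, numeric(1))) / L
  expected <- cfg$divergence * L * (p_syn + (1 - p_syn) * cfg$f_ancestral)
  sd3 <- 3 * sqrt(cfg$divergence * L)
  expect_gt(nrow(clone$het_sites), expected - sd3)
  expect_lt(nrow(clone$het_sites), expected + sd3)
  # with f_ancestral = 1 every proposal is retained
  cfg_f1 <- sim_config(seed = 3, n_transcripts = 60, cds_length_codons = 50,
                       divergence = 0.01, f_ancestral = 1)
  reg3 <- generate_reference_cds(cfg_f1, prefix = "x", seed = 2)
  c3 <- make_triploid_clone(cfg_f1, reg3)
  expect_equal(nrow(c3$het_sites), c3$n_proposed)
  expect_equal(c3$n_retained_nonsyn, c3$n_proposed_nonsyn)
})

test_that("novel mutations are per-adult singleton events with selection on nonsyn", {
  cfg <- small_cfg(novel_mut_rate = 0)
  reg <- generate_reference_cds(cfg, prefix = "x", seed = 9)
  clone <- make_triploid_clone(cfg, reg)
  nov0 <- add_novel_mutations(cfg, reg, clone$het_sites, c("a1", "a2"))
  expect_equal(nrow(nov0), 0L)

  cfg2 <- sim_config(seed = 12, n_transcripts = 200, cds_length_codons = 60,
                     novel_mut_rate = 2e-3, nonsyn_retention = 1)
  reg2 <- generate_reference_cds(cfg2, prefix = "x", seed = 9)
  cl2 <- make_triploid_clone(cfg2, reg2)
  nov_f1 <- add_novel_mutations(cfg2, reg2, cl2$het_sites,
                                c("a1", "a2", "a3", "a4"))
  cfg3 <- sim_config(seed = 12, n_transcripts = 200, cds_length_codons = 60,
                     novel_mut_rate = 2e-3, nonsyn_retention = 0.1)
  nov_f01 <- add_novel_mutations(cfg3, reg2, cl2$het_sites,
                                 c("a1", "a2", "a3", "a4"))
  ratio_f1 <- sum(nov_f1$effect == "nonsynonymous") /
    sum(nov_f1$effect == "synonymous")
  ratio_f01 <- sum(nov_f01$effect == "nonsynonymous") /
    sum(nov_f01$effect == "synonymous")
  expect_gt(ratio_f1 / ratio_f01, 5)   # ~10x by construction
  # no site is hit twice and none collides with an ancestral site
  keys <- paste(nov_f1$transcript_id, nov_f1$position)
  expect_false(anyDuplicated(keys) > 0)
  expect_length(intersect(keys, paste(cl2$het_sites$transcript_id,
                                      cl2$het_sites$position)), 0)
})

test_that("the sexual population honours density and frequency settings", {
  cfg0 <- small_cfg(sexual_snp_density = 0)
  reg <- generate_reference_cds(cfg0, prefix = "x", seed = 4)
  expect_equal(nrow(make_sexual_population(cfg0, reg)$sites), 0L)

  n <- 4L
  spec1 <- c(1, rep(0, 2 * n - 2))   # every alternate allele is a singleton
  cfg1 <- small_cfg(sexual_snp_density = 0.02, sexual_alt_freq_spec = spec1)
  pop1 <- make_sexual_population(cfg1, reg)
  expect_true(all(pop1$sites$alt_count == 1L))
  expect_true(all(rowSums(pop1$alt_copies) == 1L))

  spec4 <- c(0, 0, 0, 1, rep(0, 3))  # alt count fixed at 4 of 8
  cfg4 <- small_cfg(sexual_snp_density = 0.02, sexual_alt_freq_spec = spec4)
  pop4 <- make_sexual_population(cfg4, reg)
  expect_true(all(rowSums(pop4$alt_copies) == 4L))
})

test_that("simulated datasets are byte-identical under a fixed seed", {
  cfg <- small_cfg(seed = 31)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  simulate_dataset(cfg, d1)
  simulate_dataset(cfg, d2)
  f1 <- sort(list.files(d1, recursive = TRUE))
  expect_identical(f1, sort(list.files(d2, recursive = TRUE)))
  for (f in f1) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     info = f)
  }
})

test_that("the offspring pool copies its mother's genotypes exactly", {
  cfg <- small_cfg(seed = 8, novel_mut_rate = 1e-3)
  d <- withr::local_tempdir()
  sim <- simulate_dataset(cfg, d)
  gt <- sim$asexual$gt
  expect_identical(gt[, "tp_offspring"], gt[, "tp_adult_1"])
  # and with mutations disabled all adults are genotype-identical
  cfg0 <- small_cfg(seed = 8, novel_mut_rate = 0)
  sim0 <- simulate_dataset(cfg0, withr::local_tempdir())
  adults <- sprintf("tp_adult_%d", 1:4)
  s <- identity_fraction(biallelic_subset(sim0$asexual), adults)
  expect_equal(s$fraction, 1)
})

test_that("emitted files form a coherent bundle with one truth row per record", {
  cfg <- small_cfg(seed = 15, novel_mut_rate = 2e-4)
  d <- withr::local_tempdir()
  sim <- simulate_dataset(cfg, d)
  expect_true(all(file.exists(unlist(sim$paths))))
  # truth covers every VCF record exactly once
  truth_keys <- paste(sim$truth$transcript_id, sim$truth$position)
  vcf_keys <- c(paste(sim$asexual$sites$transcript_id, sim$asexual$sites$position),
                paste(sim$sexual$sites$transcript_id, sim$sexual$sites$position))
  expect_setequal(truth_keys, vcf_keys)
  expect_false(anyDuplicated(truth_keys) > 0)
  # depth tables cover every CDS position of their species
  expect_equal(nrow(sim$depth_asexual), 60 * 150)
  expect_equal(nrow(sim$depth_sexual), 60 * 150)
  # reading the bundle back reproduces the in-memory objects
  sheet <- read_sample_sheet(sim$paths$sample_sheet)
  expect_equal(sheet, sim$samples)
  back <- read_vcf(sim$paths$vcf[["T_pusillus"]],
                   sheet[sheet$species_id == "T_pusillus", ])
  expect_equal(back$gt, sim$asexual$gt)
  regions <- read_cds(sim$paths$fasta, sim$paths$cds_table)
  expect_equal(nrow(regions), 120L)
})

test_that("allele depths track the true reference copy number in expectation", {
  cfg <- sim_config(seed = 44, n_transcripts = 300, cds_length_codons = 50,
                    divergence = 0.01, mean_depth = 60)
  sim <- simulate_dataset(cfg, withr::local_tempdir())
  x <- sim$asexual
  het <- x$gt[, "tp_adult_1"] == "0/0/1"
  rd <- do.call(rbind, strsplit(x$ad[het, "tp_adult_1"], ","))
  frac <- as.numeric(rd[, 1]) / (as.numeric(rd[, 1]) + as.numeric(rd[, 2]))
  expect_equal(mean(frac), 2 / 3, tolerance = 0.02)
})

test_that("with no selection differential the class LRT rejects at ~nominal rate", {
  # f = 1 everywhere: the novel and low-frequency classes share pN/pS = 1,
  # so rejections at alpha = 0.05 should be ~5% across replicate seeds
  sense <- setdiff(names(Biostrings::GENETIC_CODE), c("TAA", "TAG", "TGA"))
  syn_per_codon <- vapply(sense, function(cd) ng86_codon_sites(cd)[["syn_sites"]],
                          numeric(1))
  site_totals <- function(reg) {
    cds <- substr(reg$sequence, reg$cds_start, reg$cds_end)
    starts <- lapply(nchar(cds), function(n) seq(1, n - 2, 3))
    cods <- unlist(Map(function(s, st) substring(s, st, st + 2), cds, starts))
    syn <- sum(syn_per_codon[cods])
    c(nonsyn = length(cods) * 3 - syn, syn = syn)
  }
  reps <- 50L
  rej <- 0L; used <- 0L
  for (r in seq_len(reps)) {
    cfg <- sim_config(seed = 7000 + r, n_transcripts = 100,
                      cds_length_codons = 50, novel_mut_rate = 1e-3,
                      nonsyn_retention = 1, f_ancestral = 1, f_sexual = 1,
                      sexual_snp_density = 0.02)
    reg_a <- generate_reference_cds(cfg, prefix = "a", seed = cfg$seed + 1L)
    reg_s <- generate_reference_cds(cfg, prefix = "s", seed = cfg$seed + 2L)
    clone <- make_triploid_clone(cfg, reg_a, seed = cfg$seed + 3L)
    nov <- add_novel_mutations(cfg, reg_a, clone$het_sites,
                               sprintf("a%d", 1:4), seed = cfg$seed + 4L)
    pop <- make_sexual_population(cfg, reg_s, seed = cfg$seed + 5L)
    lowf <- pop$sites[pop$sites$alt_count == 1L, ]
    a <- c(sum(nov$effect == "nonsynonymous"), sum(nov$effect == "synonymous"))
    b <- c(sum(lowf$effect == "nonsynonymous"), sum(lowf$effect == "synonymous"))
    if (a[2] == 0 || b[2] == 0 || sum(a) == 0 || sum(b) == 0) next
    ta <- site_totals(reg_a); ts <- site_totals(reg_s)
    fit <- pnps_lrt(c(a, ta[["nonsyn"]], ta[["syn"]]),
                    c(b, ts[["nonsyn"]], ts[["syn"]]))
    used <- used + 1L
    rej <- rej + (fit$p_value < 0.05)
  }
  expect_gte(used, 45L)
  expect_lte(rej, 7L)   # P(X >= 8 | n = 50, p = 0.05) < 0.005
})
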