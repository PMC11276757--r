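# Synthetic-data generator. Emulates the statistical structure the analysis
# assumes: a triploid apomictic clone set of hybrid (AAB) origin — high
# shared heterozygosity from two divergent progenitor haplotypes plus rare
# per-individual novel mutations — and a diploid outcrossing population with
# segregating SNPs, down to read-count-backed genotype calls. Selection is
# modelled as a simple retention filter: a proposed nonsynonymous change
# survives with a class-specific probability (f), so the expected pN/pS of a
# class equals its f under NG86 counting, which makes recovery directly
# testable.

#' Simulation configuration
#'
#' @param seed Integer seed; fully determines every output byte.
#' @param n_transcripts Transcripts per species.
#' @param cds_length_codons Sense codons per CDS (the terminal stop codon is
#'   appended after the CDS and excluded from it).
#' @param divergence Per-site substitution probability between the two
#'   progenitor haplotypes A and B of the triploid (ancestral
#'   heterozygosity source).
#' @param novel_mut_rate Expected novel mutations per haploid CDS site per
#'   asexual adult.
#' @param nonsyn_retention Probability a proposed nonsynonymous novel
#'   mutation is retained (the purifying-selection proxy for the novel
#'   class).
#' @param f_ancestral,f_sexual Retention probabilities for nonsynonymous
#'   proposals among ancestral haplotype differences and sexual segregating
#'   sites (prior selection in the sexual progenitors/population).
#' @param sexual_snp_density Per-CDS-site probability of a segregating site
#'   in the sexual population (before the nonsynonymous retention filter).
#' @param sexual_alt_freq_spec Probabilities over alternate-allele counts
#'   `1 .. 2N-1`; default proportional to `1/i` (the neutral site-frequency
#'   spectrum shape).
#' @param n_adults_asexual Number of triploid wild-caught adults.
#' @param include_offspring_pool Add a pooled-offspring sample that copies
#'   the first adult's genotypes exactly (apomixis).
#' @param n_samples_sexual Number of diploid samples.
#' @param mean_depth Mean per-site sequencing depth.
#' @param depth_dispersion Negative-binomial size parameter for depth
#'   (`Inf` gives Poisson).
#' @param gq_constant Genotype quality assigned to every call (a model
#'   stand-in; a caller's error model is not simulated).
#' @param site_qual Site QUAL assigned to every record.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_transcripts = 2000L,
                       cds_length_codons = 150L,
                       divergence = 0.005,
                       novel_mut_rate = 2e-5,
                       nonsyn_retention = 0.2,
                       f_ancestral = 0.1,
                       f_sexual = 0.1,
                       sexual_snp_density = 0.003,
                       sexual_alt_freq_spec = NULL,
                       n_adults_asexual = 4L,
                       include_offspring_pool = TRUE,
                       n_samples_sexual = 4L,
                       mean_depth = 60,
                       depth_dispersion = 40,
                       gq_constant = 99,
                       site_qual = 60) {
  rates <- c(divergence, novel_mut_rate, nonsyn_retention, f_ancestral,
             f_sexual, sexual_snp_density)
  stopifnot(all(rates >= 0 & rates <= 1), divergence <= 0.1,
            n_transcripts >= 1, cds_length_codons >= 2,
            n_adults_asexual >= 2, n_samples_sexual >= 2, mean_depth > 0)
  if (is.null(sexual_alt_freq_spec)) {
    i <- seq_len(2L * n_samples_sexual - 1L)
    sexual_alt_freq_spec <- (1 / i) / sum(1 / i)
  }
  stopifnot(length(sexual_alt_freq_spec) == 2L * n_samples_sexual - 1L,
            abs(sum(sexual_alt_freq_spec) - 1) < 1e-8)
  structure(list(seed = as.integer(seed), n_transcripts = as.integer(n_transcripts),
                 cds_length_codons = as.integer(cds_length_codons),
                 divergence = divergence, novel_mut_rate = novel_mut_rate,
                 nonsyn_retention = nonsyn_retention,
                 f_ancestral = f_ancestral, f_sexual = f_sexual,
                 sexual_snp_density = sexual_snp_density,
                 sexual_alt_freq_spec = sexual_alt_freq_spec,
                 n_adults_asexual = as.integer(n_adults_asexual),
                 include_offspring_pool = isTRUE(include_offspring_pool),
                 n_samples_sexual = as.integer(n_samples_sexual),
                 mean_depth = mean_depth, depth_dispersion = depth_dispersion,
                 gq_constant = gq_constant, site_qual = site_qual),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Simulation configuration (seed", x$seed, ")\n")
  cat(sprintf("  %d transcripts x %d codons per species\n",
              x$n_transcripts, x$cds_length_codons))
  cat(sprintf("  progenitor divergence d = %g, novel mutation rate mu = %g\n",
              x$divergence, x$novel_mut_rate))
  cat(sprintf("  nonsyn retention: novel %g, ancestral %g, sexual %g\n",
              x$nonsyn_retention, x$f_ancestral, x$f_sexual))
  cat(sprintf("  depth: NB(mean %g, size %g); GQ = %g\n",
              x$mean_depth, x$depth_dispersion, x$gq_constant))
  invisible(x)
}

#' Generate random reference coding regions
#'
#' Each transcript is `ATG` followed by random sense codons, with a stop
#' codon appended after the CDS (so every counted codon is a sense codon).
#'
#' @param config A [sim_config].
#' @param prefix Transcript-id prefix.
#' @param seed Seed for this step (default `config$seed`).
#' @return A `cds_set` data.frame.
#' @export
generate_reference_cds <- function(config, prefix = "t", seed = config$seed) {
  set.seed(seed)
  n <- config$n_transcripts
  k <- config$cds_length_codons
  body <- matrix(sample(SENSE_CODONS, n * (k - 1L), replace = TRUE), nrow = n)
  cds <- paste0("ATG", apply(body, 1, paste, collapse = ""))
  seqs <- paste0(cds, sample(STOP_CODONS, n, replace = TRUE))
  regions <- data.frame(
    transcript_id = sprintf("%s%05d", prefix, seq_len(n)),
    sequence = seqs, cds_start = 1L, cds_end = 3L * k,
    stringsAsFactors = FALSE)
  class(regions) <- c("cds_set", "data.frame")
  regions
}

# propose a uniform alternative base for each reference base (vectorised)
.propose_alt <- function(bases) {
  others <- lapply(NUCLEOTIDES, function(b) setdiff(NUCLEOTIDES, b))
  names(others) <- NUCLEOTIDES
  pick <- sample.int(3L, length(bases), replace = TRUE)
  vapply(seq_along(bases), function(i) others[[bases[i]]][pick[i]], character(1))
}

#' Create the triploid clone's ancestral heterozygous sites
#'
#' Haplotype B differs from haplotype A (the reference) at `Bernoulli(d)`
#' CDS sites with a uniformly chosen alternative base; proposed
#' nonsynonymous differences are retained with probability `f_ancestral`
#' (prior purifying selection in the sexual progenitors). Every retained
#' difference is an ancestral `0/0/1`-pattern heterozygous site shared by
#' all asexual individuals (AAB karyotype).
#'
#' @param config A [sim_config].
#' @param regions A `cds_set` for the asexual species.
#' @param seed Seed for this step.
#' @return List with `het_sites` (data.frame: transcript_id, position, ref,
#'   alt, effect) and proposal bookkeeping counts.
#' @export
make_triploid_clone <- function(config, regions, seed = config$seed) {
  set.seed(seed)
  ptab <- .cds_position_table(regions)
  hit <- which(runif(nrow(ptab)) < config$divergence)
  if (!length(hit)) {
    return(list(het_sites = data.frame(transcript_id = character(0),
                                       position = integer(0), ref = character(0),
                                       alt = character(0), effect = character(0)),
                n_proposed = 0L, n_proposed_nonsyn = 0L, n_retained_nonsyn = 0L))
  }
  alt <- .propose_alt(ptab$base[hit])
  effect <- .substitution_effect(ptab$codon[hit], ptab$codon_pos[hit], alt)
  keep <- effect == "synonymous" | runif(length(hit)) < config$f_ancestral
  het <- data.frame(transcript_id = ptab$transcript_id[hit][keep],
                    position = ptab$position[hit][keep],
                    ref = ptab$base[hit][keep], alt = alt[keep],
                    effect = effect[keep], stringsAsFactors = FALSE)
  list(het_sites = het, n_proposed = length(hit),
       n_proposed_nonsyn = sum(effect == "nonsynonymous"),
       n_retained_nonsyn = sum(het$effect == "nonsynonymous"))
}

#' Add per-individual novel mutations to the clone set
#'
#' Each CDS site of each adult acquires a proposed novel mutation (on one
#' haploid copy, hence a single derived allele) with probability
#' `novel_mut_rate`; nonsynonymous proposals are retained with probability
#' `nonsyn_retention` (the key purifying-selection knob for pN/pS
#' recovery). Each retained mutation is a single-adult `0/0/1` event.
#' Proposals colliding with an ancestral heterozygous site or an earlier
#' novel mutation are skipped (a message reports the count).
#'
#' @param config A [sim_config].
#' @param regions The asexual `cds_set`.
#' @param ancestral_sites `het_sites` from [make_triploid_clone()].
#' @param adults Character vector of asexual adult sample ids.
#' @param seed Seed for this step.
#' @return data.frame: transcript_id, position, ref, alt, effect, carrier.
#' @export
add_novel_mutations <- function(config, regions, ancestral_sites, adults,
                                seed = config$seed) {
  set.seed(seed)
  ptab <- .cds_position_table(regions)
  L <- nrow(ptab)
  taken <- paste(ancestral_sites$transcript_id, ancestral_sites$position)
  out <- vector("list", length(adults))
  n_skipped <- 0L
  for (j in seq_along(adults)) {
    n_prop <- rbinom(1L, L, config$novel_mut_rate)
    if (n_prop == 0L) next
    idx <- unique(sample.int(L, n_prop, replace = TRUE))
    alt <- .propose_alt(ptab$base[idx])
    effect <- .substitution_effect(ptab$codon[idx], ptab$codon_pos[idx], alt)
    keep <- effect == "synonymous" | runif(length(idx)) < config$nonsyn_retention
    idx <- idx[keep]; alt <- alt[keep]; effect <- effect[keep]
    if (!length(idx)) next
    key <- paste(ptab$transcript_id[idx], ptab$position[idx])
    free <- !(key %in% taken)
    n_skipped <- n_skipped + sum(!free)
    taken <- c(taken, key[free])
    out[[j]] <- data.frame(transcript_id = ptab$transcript_id[idx][free],
                           position = ptab$position[idx][free],
                           ref = ptab$base[idx][free], alt = alt[free],
                           effect = effect[free], carrier = adults[j],
                           stringsAsFactors = FALSE)
  }
  if (n_skipped > 0L) {
    message(n_skipped, " novel mutation proposal(s) collided with an existing site; skipped")
  }
  res <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(res)) {
    res <- data.frame(transcript_id = character(0), position = integer(0),
                      ref = character(0), alt = character(0),
                      effect = character(0), carrier = character(0))
  }
  res
}

#' Create segregating SNPs for the diploid outcrossing population
#'
#' Sites appear with probability `sexual_snp_density` per CDS position;
#' nonsynonymous proposals are retained with probability `f_sexual`. The
#' alternate-allele count is drawn from `sexual_alt_freq_spec` and alleles
#' are assigned by sampling slots without replacement among the 2N
#' chromosomes.
#'
#' @param config A [sim_config].
#' @param regions The sexual `cds_set`.
#' @param seed Seed for this step.
#' @return List with `sites` (transcript_id, position, ref, alt, effect,
#'   alt_count) and `alt_copies` (sites x samples matrix of 0/1/2).
#' @export
make_sexual_population <- function(config, regions, seed = config$seed) {
  set.seed(seed)
  N <- config$n_samples_sexual
  ptab <- .cds_position_table(regions)
  hit <- which(runif(nrow(ptab)) < config$sexual_snp_density)
  alt <- .propose_alt(ptab$base[hit])
  effect <- .substitution_effect(ptab$codon[hit], ptab$codon_pos[hit], alt)
  keep <- effect == "synonymous" | runif(length(hit)) < config$f_sexual
  hit <- hit[keep]; alt <- alt[keep]; effect <- effect[keep]
  n <- length(hit)
  counts <- sample.int(2L * N - 1L, n, replace = TRUE,
                       prob = config$sexual_alt_freq_spec)
  copies <- matrix(0L, nrow = n, ncol = N)
  for (i in seq_len(n)) {
    slots <- sample.int(2L * N, counts[i])
    smp <- (slots + 1L) %/% 2L          # slots 1,2 -> sample 1; 3,4 -> 2; ...
    tab <- tabulate(smp, nbins = N)
    copies[i, ] <- tab
  }
  list(sites = data.frame(transcript_id = ptab$transcript_id[hit],
                          position = ptab$position[hit],
                          ref = ptab$base[hit], alt = alt, effect = effect,
                          alt_count = counts, stringsAsFactors = FALSE),
       alt_copies = copies)
}

.sim_depth_matrix <- function(config, n_pos, n_samples) {
  draw <- function(n) {
    if (is.finite(config$depth_dispersion)) {
      rnbinom(n, size = config$depth_dispersion, mu = config$mean_depth)
    } else {
      stats::rpois(n, config$mean_depth)
    }
  }
  matrix(draw(n_pos * n_samples), nrow = n_pos, ncol = n_samples)
}

# build snp_set matrices for one species from genotype strings + ref copy
# numbers, drawing DP from the species depth matrix
.emit_species_set <- function(config, sites, gt, ref_copies, ploidy,
                              depth_df, samples) {
  n <- nrow(sites)
  ids <- samples$sample_id
  dkey <- paste(depth_df$transcript_id, depth_df$position)
  idx <- match(paste(sites$transcript_id, sites$position), dkey)
  dp <- as.matrix(depth_df[idx, ids, drop = FALSE])
  dimnames(dp) <- NULL
  ad_ref <- matrix(rbinom(n * length(ids), as.vector(dp),
                          as.vector(ref_copies) / ploidy), nrow = n)
  ad <- matrix(paste0(ad_ref, ",", dp - ad_ref), nrow = n)
  gq <- matrix(config$gq_constant, nrow = n, ncol = length(ids))
  sites_df <- data.frame(transcript_id = sites$transcript_id,
                         position = sites$position, ref = sites$ref,
                         alt = sites$alt, qual = config$site_qual,
                         stringsAsFactors = FALSE)
  storage.mode(dp) <- "integer"
  snp_set(sites_df, gt, dp, ad, gq, samples)
}

#' Simulate a complete two-species dataset and write all files
#'
#' Chains [generate_reference_cds()], [make_triploid_clone()],
#' [add_novel_mutations()] and [make_sexual_population()], then simulates
#' per-site read depths (negative binomial) and allele depths (binomial in
#' the true allele copy number over ploidy), and writes a full file bundle:
#' reference FASTA + CDS table, sample sheet, one VCF and one depth TSV per
#' species, a truth table, and the resolved configuration as YAML. All
#' outputs are byte-deterministic under the configuration seed.
#'
#' @param config A [sim_config].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a list with the in-memory objects (`asexual` and
#'   `sexual` [snp_set]s, depth tables, region sets, `truth`, `samples`)
#'   and the written `paths`.
#' @export
simulate_dataset <- function(config, dir) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  s <- config$seed
  regions_a <- generate_reference_cds(config, prefix = "tp_t", seed = s + 1L)
  regions_s <- generate_reference_cds(config, prefix = "hr_t", seed = s + 2L)

  adults <- sprintf("tp_adult_%d", seq_len(config$n_adults_asexual))
  asex_ids <- c(adults, if (config$include_offspring_pool) "tp_offspring")
  sex_ids <- sprintf("hr_adult_%d", seq_len(config$n_samples_sexual))
  sexes <- rep_len(c("female", "male"), config$n_samples_sexual)
  samples <- data.frame(
    sample_id = c(asex_ids, sex_ids),
    species_id = c(rep("T_pusillus", length(asex_ids)),
                   rep("H_riparius", length(sex_ids))),
    ploidy = c(rep(3L, length(asex_ids)), rep(2L, length(sex_ids))),
    role = c(rep("adult", length(adults)),
             if (config$include_offspring_pool) "offspring_pool",
             rep("adult", length(sex_ids))),
    sex = c(rep("female", length(adults)),
            if (config$include_offspring_pool) "unknown",
            sexes),
    stringsAsFactors = FALSE)

  clone <- make_triploid_clone(config, regions_a, seed = s + 3L)
  novel <- add_novel_mutations(config, regions_a, clone$het_sites, adults,
                               seed = s + 4L)
  sex <- make_sexual_population(config, regions_s, seed = s + 5L)

  set.seed(s + 6L)
  samp_a <- samples[samples$species_id == "T_pusillus", ]
  samp_s <- samples[samples$species_id == "H_riparius", ]

  # ---- asexual species: genotypes + truth
  anc <- clone$het_sites
  nov <- novel
  sites_a <- rbind(
    if (nrow(anc)) cbind(anc[c("transcript_id", "position", "ref", "alt", "effect")],
                         class = "ancestral_hybrid", carrier = NA_character_),
    if (nrow(nov)) cbind(nov[c("transcript_id", "position", "ref", "alt", "effect")],
                         class = "novel", carrier = nov$carrier))
  if (is.null(sites_a)) {
    sites_a <- data.frame(transcript_id = character(0), position = integer(0),
                          ref = character(0), alt = character(0),
                          effect = character(0), class = character(0),
                          carrier = character(0), stringsAsFactors = FALSE)
  }
  ord <- order(sites_a$transcript_id, sites_a$position)
  sites_a <- sites_a[ord, , drop = FALSE]
  n_a <- nrow(sites_a)
  gt_a <- matrix("0/0/0", nrow = n_a, ncol = length(asex_ids),
                 dimnames = list(NULL, asex_ids))
  is_anc <- sites_a$class == "ancestral_hybrid"
  gt_a[is_anc, adults] <- "0/0/1"
  for (j in adults) {
    gt_a[!is_anc & sites_a$carrier == j, j] <- "0/0/1"
  }
  if (config$include_offspring_pool) {
    gt_a[, "tp_offspring"] <- gt_a[, adults[1L]]   # apomixis: exact copy
  }
  ref_copies_a <- matrix(3L, nrow = n_a, ncol = length(asex_ids))
  ref_copies_a[gt_a == "0/0/1"] <- 2L

  # ---- sexual species: genotypes
  sites_s <- sex$sites
  n_s <- nrow(sites_s)
  gt_s <- matrix(c("0/0", "0/1", "1/1")[sex$alt_copies + 1L], nrow = n_s,
                 dimnames = list(NULL, sex_ids))
  ref_copies_s <- 2L - sex$alt_copies

  # ---- depths over every CDS position (covered-site denominators)
  ptab_a <- .cds_position_table(regions_a)
  ptab_s <- .cds_position_table(regions_s)
  depth_a <- cbind(as.data.frame(ptab_a)[c("transcript_id", "position")],
                   as.data.frame(.sim_depth_matrix(config, nrow(ptab_a),
                                                   length(asex_ids))))
  names(depth_a) <- c("transcript_id", "position", asex_ids)
  depth_s <- cbind(as.data.frame(ptab_s)[c("transcript_id", "position")],
                   as.data.frame(.sim_depth_matrix(config, nrow(ptab_s),
                                                   length(sex_ids))))
  names(depth_s) <- c("transcript_id", "position", sex_ids)
  depth_a <- as.data.frame(depth_a); depth_s <- as.data.frame(depth_s)
  class(depth_a) <- class(depth_s) <- c("depth_table", "data.frame")

  set_a <- .emit_species_set(config, sites_a, gt_a, ref_copies_a, 3L,
                             depth_a, samp_a)
  set_s <- .emit_species_set(config, sites_s, gt_s, ref_copies_s, 2L,
                             depth_s, samp_s)

  carriers_a <- ifelse(is_anc, paste(asex_ids, collapse = ","),
                       ifelse(config$include_offspring_pool &
                                sites_a$carrier == adults[1L],
                              paste(sites_a$carrier, "tp_offspring", sep = ","),
                              sites_a$carrier))
  carriers_s <- apply(sex$alt_copies > 0L, 1, function(v)
    paste(sex_ids[v], collapse = ","))
  truth <- rbind(
    data.frame(transcript_id = sites_a$transcript_id, position = sites_a$position,
               true_class = ifelse(is_anc, "ancestral_hybrid", "novel"),
               true_effect = sites_a$effect, carriers = carriers_a,
               stringsAsFactors = FALSE),
    data.frame(transcript_id = sites_s$transcript_id, position = sites_s$position,
               true_class = "sexual_segregating", true_effect = sites_s$effect,
               carriers = carriers_s, stringsAsFactors = FALSE))

  paths <- list(fasta = file.path(dir, "reference.fasta"),
                cds_table = file.path(dir, "cds.tsv"),
                sample_sheet = file.path(dir, "samples.tsv"),
                vcf = c(T_pusillus = file.path(dir, "asexual.vcf"),
                        H_riparius = file.path(dir, "sexual.vcf")),
                depth = c(T_pusillus = file.path(dir, "depth_asexual.tsv"),
                          H_riparius = file.path(dir, "depth_sexual.tsv")),
                truth = file.path(dir, "truth.tsv"),
                config = file.path(dir, "config.yaml"))
  all_regions <- rbind(regions_a, regions_s)
  class(all_regions) <- c("cds_set", "data.frame")
  write_cds(all_regions, paths$fasta, paths$cds_table)
  write_sample_sheet(samples, paths$sample_sheet)
  write_vcf(set_a, paths$vcf[["T_pusillus"]])
  write_vcf(set_s, paths$vcf[["H_riparius"]])
  write_depth_table(depth_a, paths$depth[["T_pusillus"]])
  write_depth_table(depth_s, paths$depth[["H_riparius"]])
  utils::write.table(truth, paths$truth, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  yaml::write_yaml(unclass(config), paths$config)

  invisible(list(asexual = set_a, sexual = set_s,
                 depth_asexual = depth_a, depth_sexual = depth_s,
                 regions_asexual = regions_a, regions_sexual = regions_s,
                 truth = truth, samples = samples, paths = paths,
                 config = config))
}
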