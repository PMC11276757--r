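# Full-analysis orchestration: reads the file bundle, applies the quality
# filters, and emits the report tables — sex ratios with an exact binomial
# test, clonality summaries, per-individual heterozygous pN/pS,
# SNP-class pN/pS with the likelihood-ratio tests, allele-balance
# histograms and ploidy calls — plus a run log of record counts at every
# filtering step. Outputs are byte-deterministic for a given config.

#' Pipeline configuration
#'
#' @param sample_sheet,fasta,cds_table Paths to the shared inputs.
#' @param vcf,depth Named character vectors of per-species VCF and depth
#'   TSV paths; names are species ids from the sample sheet.
#' @param outdir Output directory for the report bundle.
#' @param markers Optional character vector of marker transcript ids (e.g.
#'   single-copy orthologs) for the marker-subset clonality rows, or a path
#'   to a one-column text file of ids.
#' @param min_depth,min_gq,min_site_qual Quality thresholds (defaults 20,
#'   30, 30).
#' @param ploidy_min_sites Minimum heterozygous site count for a ploidy
#'   call (default 100; see [infer_ploidy()]).
#' @param sex_counts Optional data.frame (`species_id`, `n_female`,
#'   `n_male`) of field counts for the sex-ratio table; when absent the
#'   sheet's sexed adults are counted.
#' @param seed Seed for the one randomised choice (the random adult pair in
#'   the clonality table).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(sample_sheet, fasta, cds_table, vcf, depth,
                            outdir, markers = NULL,
                            min_depth = 20, min_gq = 30, min_site_qual = 30,
                            ploidy_min_sites = 100, sex_counts = NULL,
                            seed = 1L) {
  stopifnot(length(vcf) >= 1L, !is.null(names(vcf)),
            identical(sort(names(vcf)), sort(names(depth))))
  if (is.character(markers) && length(markers) == 1L && file.exists(markers)) {
    markers <- readLines(markers)
  }
  structure(list(sample_sheet = sample_sheet, fasta = fasta,
                 cds_table = cds_table, vcf = vcf, depth = depth,
                 outdir = outdir, markers = markers,
                 min_depth = min_depth, min_gq = min_gq,
                 min_site_qual = min_site_qual,
                 ploidy_min_sites = ploidy_min_sites,
                 sex_counts = sex_counts, seed = as.integer(seed)),
            class = "pipeline_config")
}

.fmt3 <- function(x) ifelse(is.na(x), NA, signif(x, 3))

#' Run the full analysis and write the report bundle
#'
#' Emits, under `config$outdir`: `table1_sex_ratio.tsv` (counts + exact
#' binomial p), `table3_clonality.tsv`, `table4_per_individual.tsv`,
#' `table5_classes.tsv`, `test_results.json` (the likelihood-ratio tests,
#' the between-species rank-sum test on per-individual pN/pS, and the
#' sex-ratio tests), `fig1_histograms/<sample>.tsv`, `ploidy_calls.tsv` and
#' `run_log.txt`. Any stage error aborts with a stage-named message and
#' removes the partial outputs.
#'
#' @param config A [pipeline_config].
#' @return Invisibly, a list with every table and test object computed.
#' @export
run_report <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  outdir <- config$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(outdir, "fig1_histograms"), showWarnings = FALSE)
  written <- character(0)
  log_lines <- c("pnpstools run log",
                 paste0("package version: ", as.character(utils::packageVersion("pnpstools"))),
                 paste0("thresholds: min_depth=", config$min_depth,
                        " min_gq=", config$min_gq,
                        " min_site_qual=", config$min_site_qual))
  note <- function(...) log_lines <<- c(log_lines, paste0(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      unlink(written)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }
  emit <- function(df, file) {
    path <- file.path(outdir, file)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    written <<- c(written, path)
  }

  samples <- stage("inputs", read_sample_sheet(config$sample_sheet))
  regions <- stage("inputs", read_cds(config$fasta, config$cds_table))
  species <- names(config$vcf)
  stopifnot(all(species %in% samples$species_id))

  # ---- per-species data loading and filtering
  data_by_sp <- list()
  for (sp in species) {
    data_by_sp[[sp]] <- stage(paste0("load:", sp), {
      sheet <- samples[samples$species_id == sp, , drop = FALSE]
      depth <- read_depth_table(config$depth[[sp]])
      reg <- regions[regions$transcript_id %in% unique(depth$transcript_id), ,
                     drop = FALSE]
      class(reg) <- c("cds_set", "data.frame")
      reg <- index_regions(reg)
      raw <- read_vcf(config$vcf[[sp]], sheet)
      filt <- apply_quality_filters(raw, config$min_depth, config$min_gq,
                                    config$min_site_qual)
      note(sp, ": ", n_variants(raw), " records read, ",
           n_variants(filt), " pass quality filters")
      list(sheet = sheet, depth = depth, regions = reg, raw = raw,
           filtered = filt, effects = snp_effects(filt, reg))
    })
  }

  # ---- table 1: sex ratios + exact binomial test
  table1 <- stage("sex_ratio", {
    counts <- config$sex_counts
    if (is.null(counts)) {
      counts <- do.call(rbind, lapply(species, function(sp) {
        sheet <- samples[samples$species_id == sp & samples$role == "adult", ]
        data.frame(species_id = sp,
                   n_female = sum(sheet$sex == "female"),
                   n_male = sum(sheet$sex == "male"))
      }))
    }
    counts$p_value <- vapply(seq_len(nrow(counts)), function(i) {
      if (counts$n_female[i] + counts$n_male[i] < 1) return(NA_real_)
      exact_binomial_test(counts$n_female[i], counts$n_male[i])$p_value
    }, numeric(1))
    counts
  })
  emit(transform(table1, p_value = .fmt3(p_value)), "table1_sex_ratio.tsv")

  # ---- ploidy calls + allele-balance histograms
  ploidy_tab <- stage("ploidy", {
    rows <- list()
    for (sp in species) {
      d <- data_by_sp[[sp]]
      for (id in d$sheet$sample_id) {
        prof <- infer_ploidy(d$filtered, id,
                             min_sites = config$ploidy_min_sites)
        emit(prof$histogram, file.path("fig1_histograms", paste0(id, ".tsv")))
        rows[[id]] <- data.frame(sample_id = id, species_id = sp,
                                 n_sites = prof$n_sites,
                                 loglik_diploid = round(prof$loglik_diploid, 2),
                                 loglik_triploid = round(prof$loglik_triploid, 2),
                                 call = prof$inferred_ploidy)
      }
    }
    do.call(rbind, rows)
  })
  emit(ploidy_tab, "ploidy_calls.tsv")

  # ---- table 3: clonality
  table3 <- stage("clonality", {
    rows <- list()
    add_rows <- function(x, sheet, sp, label) {
      adults <- sheet$sample_id[sheet$role == "adult"]
      offspring <- sheet$sample_id[sheet$role == "offspring_pool"]
      out <- list()
      if (length(adults) >= 2L) {
        s <- identity_fraction(x, adults, label)
        out$all <- data.frame(species_id = sp, subset = label,
                              comparison = "all adults",
                              n_biallelic = s$n_biallelic,
                              n_identical = s$n_identical,
                              pct_identical = round(100 * s$fraction, 1))
        set.seed(config$seed)
        pair <- sort(sample(adults, 2L))
        s2 <- pairwise_identity(x, pair[1], pair[2], label)
        out$pair <- data.frame(species_id = sp, subset = label,
                               comparison = paste("random adult pair:",
                                                  paste(pair, collapse = "+")),
                               n_biallelic = s2$n_biallelic,
                               n_identical = s2$n_identical,
                               pct_identical = round(100 * s2$fraction, 1))
      }
      if (length(offspring) == 1L && length(adults) >= 1L) {
        s3 <- pairwise_identity(x, adults[1], offspring, label)
        out$mo <- data.frame(species_id = sp, subset = label,
                             comparison = "mother + offspring pool",
                             n_biallelic = s3$n_biallelic,
                             n_identical = s3$n_identical,
                             pct_identical = round(100 * s3$fraction, 1))
      }
      out
    }
    for (sp in species) {
      d <- data_by_sp[[sp]]
      bi <- biallelic_subset(d$filtered)
      note(sp, ": ", n_variants(bi), " biallelic records for clonality")
      rows <- c(rows, add_rows(bi, d$sheet, sp, "all SNPs"))
      if (!is.null(config$markers)) {
        rows <- c(rows, add_rows(subset_by_markers(bi, config$markers),
                                 d$sheet, sp, "marker subset"))
      }
    }
    do.call(rbind, rows)
  })
  emit(table3, "table3_clonality.tsv")

  # ---- table 4: per-individual heterozygous pN/pS
  table4_objs <- list()
  table4 <- stage("per_individual_pnps", {
    rows <- list()
    for (sp in species) {
      d <- data_by_sp[[sp]]
      for (id in d$sheet$sample_id) {
        het <- per_individual_het(d$filtered, id)
        eff <- snp_effects(het, d$regions)
        cov <- covered_site_totals(d$regions, d$depth, id,
                                   mode = "per_individual",
                                   min_depth = config$min_depth)
        ps <- pnps_summary(sum(eff == "nonsynonymous", na.rm = TRUE),
                           sum(eff == "synonymous", na.rm = TRUE),
                           cov$covered_nonsyn_sites, cov$covered_syn_sites)
        table4_objs[[id]] <- ps
        rows[[id]] <- data.frame(
          sample_id = id, species_id = sp,
          covered_nonsyn_sites = round(ps$sites_nonsyn, 1),
          covered_syn_sites = round(ps$sites_syn, 1),
          nonsyn_snps = ps$n_nonsyn, syn_snps = ps$n_syn,
          freq_overall = .fmt3(ps$freq_overall),
          freq_nonsyn = .fmt3(ps$freq_nonsyn),
          freq_syn = .fmt3(ps$freq_syn),
          pnps = round(ps$pnps, 4))
      }
    }
    do.call(rbind, rows)
  })
  emit(table4, "table4_per_individual.tsv")

  # ---- table 5: SNP-class pN/pS + LRTs
  class_sets <- list()
  table5_objs <- list()
  table5 <- stage("class_pnps", {
    rows <- list()
    add_class <- function(sp, label, set) {
      d <- data_by_sp[[sp]]
      class_sets[[paste(sp, label, sep = ":")]] <<- set
      eff <- snp_effects(set, d$regions)
      cov <- covered_site_totals(d$regions, d$depth, d$sheet$sample_id,
                                 mode = "all_individuals",
                                 min_depth = config$min_depth)
      ps <- pnps_summary(sum(eff == "nonsynonymous", na.rm = TRUE),
                         sum(eff == "synonymous", na.rm = TRUE),
                         cov$covered_nonsyn_sites, cov$covered_syn_sites)
      table5_objs[[paste(sp, label, sep = ":")]] <<- ps
      note(sp, " class '", label, "': ", n_variants(set), " records, ",
           ps$n_nonsyn, " nonsyn + ", ps$n_syn, " syn in coding regions")
      rows[[paste(sp, label)]] <<- data.frame(
        species_id = sp, snp_class = label,
        covered_nonsyn_sites = round(ps$sites_nonsyn, 1),
        covered_syn_sites = round(ps$sites_syn, 1),
        nonsyn_snps = ps$n_nonsyn, syn_snps = ps$n_syn,
        freq_overall = .fmt3(ps$freq_overall),
        freq_nonsyn = .fmt3(ps$freq_nonsyn),
        freq_syn = .fmt3(ps$freq_syn),
        pnps = round(ps$pnps, 4))
    }
    for (sp in species) {
      d <- data_by_sp[[sp]]
      bi <- biallelic_subset(d$filtered)
      sheet <- d$sheet
      if (all(sheet$ploidy == 3L)) {
        adults <- sheet$sample_id[sheet$role == "adult"]
        add_class(sp, "candidate_novel", candidate_novel(bi, adults))
        add_class(sp, "ancestral_identical", ancestral_identical(bi, adults))
      } else if (all(sheet$ploidy == 2L)) {
        add_class(sp, "all_snps", bi)
        add_class(sp, "low_frequency", low_frequency(bi, sheet$sample_id))
      }
    }
    do.call(rbind, rows)
  })
  emit(table5, "table5_classes.tsv")

  # ---- LRTs and rank-sum test
  tests <- stage("tests", {
    out <- list()
    counts_of <- function(key) {
      ps <- table5_objs[[key]]
      if (is.null(ps)) return(NULL)
      c(ps$n_nonsyn, ps$n_syn, ps$sites_nonsyn, ps$sites_syn)
    }
    tri_sp <- species[vapply(species, function(sp)
      all(data_by_sp[[sp]]$sheet$ploidy == 3L), logical(1))]
    di_sp <- species[vapply(species, function(sp)
      all(data_by_sp[[sp]]$sheet$ploidy == 2L), logical(1))]
    if (length(tri_sp) == 1L && length(di_sp) == 1L) {
      a <- counts_of(paste(tri_sp, "candidate_novel", sep = ":"))
      b <- counts_of(paste(di_sp, "low_frequency", sep = ":"))
      if (!is.null(a) && !is.null(b) && a[2] > 0 && b[2] > 0) {
        out$lrt_novel_vs_low_frequency <- pnps_lrt(a, b)
      }
      b2 <- counts_of(paste(tri_sp, "ancestral_identical", sep = ":"))
      if (!is.null(a) && !is.null(b2) && a[2] > 0 && b2[2] > 0) {
        out$lrt_novel_vs_ancestral_identical <- pnps_lrt(a, b2)
      }
      pn_of <- function(sp) {
        ad <- data_by_sp[[sp]]$sheet
        ad <- ad$sample_id[ad$role == "adult"]
        vapply(ad, function(id) table4_objs[[id]]$pnps, numeric(1))
      }
      va <- pn_of(tri_sp); vb <- pn_of(di_sp)
      out$rank_sum_per_individual_pnps <- tryCatch(
        exact_rank_sum_test(va, vb), error = function(e) NULL)
    }
    out
  })
  json <- list()
  for (nm in names(tests)) {
    t <- tests[[nm]]
    json[[nm]] <- if (inherits(t, "pnps_lrt")) {
      list(method = "conditional-binomial likelihood-ratio test",
           chi2 = t$chi2, chi2_rounded = round(t$chi2, 1), df = t$df,
           p_value = t$p_value,
           ratio_a = t$ratio_a_mle, ratio_b = t$ratio_b_mle,
           ratio_shared = t$ratio_shared_mle)
    } else {
      list(method = t$method, statistic = t$statistic, p_value = t$p_value)
    }
  }
  for (i in seq_len(nrow(table1))) {
    json[[paste0("sex_ratio_", table1$species_id[i])]] <-
      list(method = "exact binomial test (two-sided)",
           n_female = table1$n_female[i], n_male = table1$n_male[i],
           p_value = table1$p_value[i])
  }
  json_path <- file.path(outdir, "test_results.json")
  jsonlite::write_json(json, json_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  written <- c(written, json_path)

  log_path <- file.path(outdir, "run_log.txt")
  writeLines(log_lines, log_path)

  invisible(list(table1 = table1, table3 = table3, table4 = table4,
                 table5 = table5, ploidy = ploidy_tab,
                 table4_summaries = table4_objs,
                 table5_summaries = table5_objs,
                 class_sets = class_sets, tests = tests,
                 samples = samples, log = log_lines))
}
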