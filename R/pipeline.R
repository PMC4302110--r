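#' End-to-end candidate-gene pipeline
#'
#' Orchestrates regions -> genotype QC -> consequences -> diversity -> FST
#' -> structure from a single declarative config, either on input files
#' (VCF + GFF3 + FASTA + panel) or on a simulated study, producing the
#' gene-accounting, diversity, per-population and FST tables plus structure
#' outputs, all seeded and reproducible.
#'
#' @name pipeline
NULL

#' Default simulated study regime
#'
#' Emulates a 77-pig, 21-gene candidate-gene resequencing design: ten
#' single-exon bitter-receptor-like loci with elevated diversity
#' (2.8e-3/site), six multi-exon amino-acid-sensor-like loci (1.5e-3) and
#' five fatty-acid-sensor-like loci (1.2e-3), 10 kb flanks, ~20% genotype
#' missingness (two amino-acid loci at ~55%, the exclusion regime), seven
#' populations of sizes 31/4/14/3/8/6/9 plus two single-sample breeds and a
#' two-sample outgroup, island-model structure and a transition-biased
#' mutation draw (ti/tv ~ 2.35).
#'
#' @param n_genes_per_group named integer vector (`bitter`, `aminoacid`,
#'   `fattyacid`).
#' @param missing_rate baseline genotype missingness.
#' @param high_missing_genes how many amino-acid loci get `high_missing_rate`.
#' @param high_missing_rate the exclusion-regime missing rate.
#' @return list with `genes` and `populations` data.frames plus simulation
#'   parameters, suitable for `config$simulate` in [run_pipeline()].
#' @export
study_config <- function(n_genes_per_group = c(bitter = 10L, aminoacid = 6L,
                                               fattyacid = 5L),
                         missing_rate = 0.2, high_missing_genes = 2L,
                         high_missing_rate = 0.55) {
  mk <- function(group, n, pi_kb, n_exons, cds_len, utr5, utr3) {
    if (n == 0L) return(NULL)
    data.frame(gene_id = sprintf("%s%02d", group, seq_len(n)), group = group,
               n_exons = n_exons, cds_len = cds_len, utr5_len = utr5,
               utr3_len = utr3, intron_len = 800L, pi_kb = pi_kb,
               missing_rate = missing_rate, stringsAsFactors = FALSE)
  }
  genes <- rbind(
    mk("bitter", n_genes_per_group[["bitter"]], 2.8, 1L, 903L, 0L, 0L),
    mk("aminoacid", n_genes_per_group[["aminoacid"]], 1.5, 7L, 2520L,
       120L, 300L),
    mk("fattyacid", n_genes_per_group[["fattyacid"]], 1.2, 2L, 960L, 0L, 0L))
  if (high_missing_genes > 0L) {
    idx <- which(genes$group == "aminoacid")[seq_len(min(
      high_missing_genes, sum(genes$group == "aminoacid")))]
    genes$missing_rate[idx] <- high_missing_rate
  }
  populations <- data.frame(
    population = c("INT", "IB", "CR", "BR", "ASD", "ASWB", "EUWB", "TW",
                   "MJ", "SWB"),
    n = c(31L, 4L, 14L, 3L, 8L, 6L, 9L, 1L, 1L, 2L),
    is_outgroup = c(rep(FALSE, 9), TRUE))
  list(genes = genes, populations = populations, flank_bp = 10000L,
       fragments = 11L, kappa = 4.7, mig = 1, outgroup_tau = 2)
}

#' Simulate a full candidate-gene study
#'
#' One gene per synthetic chromosome; per-gene theta is the target per-kb
#' diversity times the window length.  Population structure follows a
#' symmetric island model with an optional deep-split outgroup deme.
#'
#' @param sim a list shaped like [study_config()].
#' @param seed RNG seed (drives every gene deterministically).
#' @return list `matrix`, `genes`, `partitions`, `ref`, `chrom_lengths`,
#'   `panel`, `gene_groups`, `truth` (per gene).
#' @export
simulate_study <- function(sim, seed = 1L) {
  genes_df <- sim$genes
  pops <- sim$populations
  flank <- sim$flank_bp %||% 10000L
  templates <- list(); chrom_lengths <- integer()
  for (i in seq_len(nrow(genes_df))) {
    chrom <- paste0("chr_", genes_df$gene_id[i])
    g <- make_gene_template(
      genes_df$gene_id[i], chrom, gene_start = flank + 5001L,
      strand = if (i %% 2L == 0L) "-" else "+",
      n_exons = genes_df$n_exons[i], cds_len = genes_df$cds_len[i],
      utr5_len = genes_df$utr5_len[i], utr3_len = genes_df$utr3_len[i],
      intron_len = genes_df$intron_len[i])
    templates[[genes_df$gene_id[i]]] <- g
    chrom_lengths[chrom] <- g$span[["end"]] + flank + 5000L
  }
  ref <- make_reference(templates, chrom_lengths,
                        seed = derive_seed(seed, 13L))
  partitions <- build_windows(templates, flank, chrom_lengths)

  panel <- data.frame(
    sample = unlist(lapply(seq_len(nrow(pops)), function(p)
      sprintf("%s%02d", pops$population[p], seq_len(pops$n[p])))),
    population = rep(pops$population, pops$n),
    is_outgroup = rep(pops$is_outgroup, pops$n), stringsAsFactors = FALSE)

  og_deme <- if (any(pops$is_outgroup)) which(pops$is_outgroup)[1] else 0L
  demography <- list(type = "island", mig = sim$mig %||% 1,
                     outgroup_deme = og_deme,
                     outgroup_tau = sim$outgroup_tau %||% 2)
  # Calibrate theta so the pooled ingroup sample hits the target diversity:
  # under the island model the expected pairwise coalescence time is d (2N
  # units) within a deme and d + (d-1)/(2 mig) between demes, so the
  # pooled mean time exceeds 1 and theta must be divided by it.
  t_scale <- island_mean_pairwise_time(2L * pops$n[!pops$is_outgroup],
                                       demography$mig)
  mats <- list(); truth <- list()
  for (i in seq_len(nrow(genes_df))) {
    gid <- genes_df$gene_id[i]
    part <- partitions[[gid]]
    L <- sum(part$class_lengths)
    cfg <- sim_config(
      n_per_deme = pops$n, theta = genes_df$pi_kb[i] / 1000 * L / t_scale,
      L = L,
      demography = demography, fragments = sim$fragments %||% 11L,
      missing_rate = genes_df$missing_rate[i], kappa = sim$kappa %||% 4.7,
      seed = derive_seed(seed, i * 3L))
    out <- simulate_gene_dataset(templates[[gid]], part, ref, cfg,
                                 panel$sample)
    mats[[gid]] <- out$matrix
    truth[[gid]] <- out$truth
  }
  gm <- combine_matrices(mats)
  list(matrix = gm, genes = templates, partitions = partitions, ref = ref,
       chrom_lengths = chrom_lengths, panel = panel,
       gene_groups = stats::setNames(genes_df$group, genes_df$gene_id),
       truth = truth)
}

#' Expected pooled pairwise coalescence time under the island model
#'
#' For d demes of equal size with per-lineage migration rate `mig`,
#' `E[T] = d` for two lineages in one deme and `d + (d - 1)/(2 mig)` for
#' two lineages in different demes (2N-generation units).  The pooled mean
#' weights pair classes by their counts; it converts a target pooled
#' diversity into the simulator's locus theta.
#'
#' @param n_hap_per_deme haploid sample sizes per (migrating) deme.
#' @param mig per-lineage migration rate.
#' @return expected mean pairwise coalescence time of the pooled sample.
#' @export
island_mean_pairwise_time <- function(n_hap_per_deme, mig) {
  d <- length(n_hap_per_deme)
  if (d < 2L) return(1)
  n <- sum(n_hap_per_deme)
  w_pairs <- sum(choose(n_hap_per_deme, 2))
  t_pairs <- choose(n, 2)
  b_pairs <- t_pairs - w_pairs
  (w_pairs * d + b_pairs * (d + (d - 1) / (2 * mig))) / t_pairs
}

#' Concatenate genotype matrices over the same samples
#'
#' @param mats list of `genotype_matrix` with identical sample sets.
#' @return a single `genotype_matrix`.
#' @export
combine_matrices <- function(mats) {
  stopifnot(length(mats) >= 1L)
  samples <- mats[[1]]$samples
  for (m in mats) stopifnot(identical(m$samples, samples))
  new_genotype_matrix(do.call(rbind, lapply(mats, `[[`, "sites")),
                      do.call(rbind, lapply(mats, `[[`, "a1")),
                      do.call(rbind, lapply(mats, `[[`, "a2")), samples)
}

#' Validate a pipeline config
#'
#' Reports every problem at once rather than failing fast.
#'
#' @param config list (or path to a YAML file encoding one).
#' @return list `config` (normalized) and `errors` (character; empty when
#'   valid).
#' @export
validate_config <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  errs <- character()
  has_sim <- !is.null(config$simulate)
  if (!has_sim) {
    for (f in c("vcf", "gff", "fasta", "panel")) {
      if (is.null(config[[f]]))
        errs <- c(errs, paste0("missing input path '", f,
                               "' (and no simulation block)"))
      else if (!file.exists(config[[f]]))
        errs <- c(errs, paste0("file not found: ", config[[f]]))
    }
  }
  if (!is.null(config$flank_bp) && config$flank_bp < 0)
    errs <- c(errs, "flank_bp must be >= 0")
  if (!is.null(config$missing_threshold) &&
      (config$missing_threshold <= 0 || config$missing_threshold > 1))
    errs <- c(errs, "missing_threshold must be in (0, 1]")
  for (f in c("n_perm", "ci_reps"))
    if (!is.null(config[[f]]) && config[[f]] < 1)
      errs <- c(errs, paste0(f, " must be >= 1"))
  config$flank_bp <- config$flank_bp %||% 10000L
  config$missing_threshold <- config$missing_threshold %||% 0.5
  config$n_perm <- config$n_perm %||% 1000L
  config$ci_reps <- config$ci_reps %||% 200L
  config$fragments <- config$fragments %||% 11L
  config$seed <- config$seed %||% 1L
  list(config = config, errors = errs)
}

#' Run the full pipeline
#'
#' Stages: regions -> matrix/QC -> consequences -> diversity -> FST ->
#' structure.  Genes whose missing rate reaches `missing_threshold` are
#' excluded from every downstream statistic and listed with reasons.
#'
#' @param config list with either `simulate` (see [study_config()]) or input
#'   paths `vcf`, `gff`, `fasta`, `panel` (+ optional `gene_groups` named
#'   vector); tuning fields `flank_bp`, `missing_threshold`, `n_perm`,
#'   `ci_reps`, `fragments`, `seed`, optional `out_dir`.
#' @return list of class `report_bundle`: `snp_table`, `diversity_table`,
#'   `population_table`, `fst_table`, `structure`, `qc`, `exclusions`,
#'   `log`.
#' @export
run_pipeline <- function(config) {
  val <- validate_config(config)
  if (length(val$errors))
    stop("invalid config:\n  - ", paste(val$errors, collapse = "\n  - "))
  config <- val$config
  log <- c(paste0("tasrdiv ", as.character(utils::packageVersion("tasrdiv"))),
           paste0("seed ", config$seed))

  if (!is.null(config$simulate)) {
    study <- simulate_study(config$simulate, seed = config$seed)
    gm <- study$matrix; genes <- study$genes
    partitions <- study$partitions; ref <- study$ref
    panel <- study$panel; gene_groups <- study$gene_groups
    log <- c(log, paste0("simulated study: ", length(genes), " genes, ",
                         length(gm$samples), " samples"))
  } else {
    ann <- load_annotation(config$gff, config$fasta)
    genes <- ann$genes; ref <- ann$ref
    partitions <- build_windows(genes, config$flank_bp, ann$chrom_lengths)
    panel <- read_panel(config$panel)
    gm <- read_vcf(config$vcf, panel)
    gene_groups <- config$gene_groups %||%
      stats::setNames(rep("all", length(genes)), names(genes))
    log <- c(log, paste0("loaded ", length(genes), " genes, ",
                         n_sites(gm), " sites"))
  }

  ingroup <- panel$sample[!panel$is_outgroup]
  gm_in <- subset_matrix(gm, samples = ingroup)

  # --- QC ---------------------------------------------------------------
  qc <- missing_rates(gm_in, partitions, mask = config$mask)
  excluded <- filter_genes_by_missing(qc, config$missing_threshold)
  retained <- setdiff(names(partitions), excluded)
  titv <- tryCatch(titv_ratio(gm_in), warning = function(w) NA_real_)
  log <- c(log, paste0("ti/tv = ", signif(titv, 4)),
           paste0("excluded genes: ",
                  if (length(excluded)) paste(excluded, collapse = ", ")
                  else "none"))

  # --- consequences -----------------------------------------------------
  cons <- annotate_matrix(gm_in, genes, partitions, ref)
  gene_of <- assign_sites_to_genes(gm_in, partitions)

  # --- SNP accounting (per gene, all genes incl. excluded) --------------
  snp_table <- do.call(rbind, lapply(names(partitions), function(gid) {
    p <- partitions[[gid]]
    rows <- cons[cons$gene_id == gid, , drop = FALSE]
    cnt <- function(x) sum(rows$site_class == x)
    ccnt <- function(x) sum(rows$consequence == x)
    data.frame(
      gene_id = gid, group = unname(gene_groups[gid]), chrom = p$chrom,
      window_start = p$window[["start"]], window_end = p$window[["end"]],
      snps = nrow(rows), intergenic = cnt("intergenic"), exon = cnt("exon"),
      intron = cnt("intron"), utr5 = cnt("utr5"), utr3 = cnt("utr3"),
      stop_lost = ccnt("stop_lost"), stop_gained = ccnt("stop_gained"),
      synonymous = ccnt("synonymous"), nonsynonymous = ccnt("nonsynonymous"),
      pct_missing = 100 *
        qc$per_gene$missing[qc$per_gene$gene_id == gid],
      excluded = gid %in% excluded, stringsAsFactors = FALSE)
  }))

  # --- diversity + FST per retained gene --------------------------------
  seed_i <- function(i, k) derive_seed(config$seed, i * 97L + k)
  div_rows <- list(); fst_rows <- list()
  for (i in seq_along(retained)) {
    gid <- retained[i]
    p <- partitions[[gid]]
    byc <- pi_by_class(gm_in, p, ci_reps = config$ci_reps,
                       fragments = config$fragments, seed = seed_i(i, 1L))
    counts <- count_syn_nonsyn_sites(genes[[gid]], ref)
    om <- pi_syn_nonsyn(gm_in, genes[[gid]], counts, cons)
    win_sites <- which(gene_of == gid)
    ft <- fst_permutation_test(gm_in, panel, n_perm = config$n_perm,
                               seed = seed_i(i, 2L), sites = win_sites)
    wide <- function(cl, col) byc[byc$region_class == cl, col]
    div_rows[[gid]] <- data.frame(
      gene_id = gid, group = unname(gene_groups[gid]),
      pi_t_kb = wide("total", "pi_per_kb"),
      pi_t_se = wide("total", "se_per_kb"),
      pi_int_kb = wide("intergenic", "pi_per_kb"),
      pi_int_se = wide("intergenic", "se_per_kb"),
      pi_g_kb = wide("genic", "pi_per_kb"),
      pi_g_se = wide("genic", "se_per_kb"),
      pi_e_kb = wide("exon", "pi_per_kb"),
      pi_i_kb = wide("intron", "pi_per_kb"),
      pi_utr_kb = wide("utr", "pi_per_kb"),
      pi_s_kb = 1000 * om$pi_s, pi_a_kb = 1000 * om$pi_a,
      omega = om$omega, fst = ft$fst_obs, fst_p = ft$p_perm,
      stringsAsFactors = FALSE)
    fst_rows[[gid]] <- data.frame(gene_id = gid, scope = "global",
                                  fst = ft$fst_obs, p_perm = ft$p_perm,
                                  n_perm = ft$n_perm,
                                  seed = seed_i(i, 2L))
  }
  diversity_table <- do.call(rbind, div_rows); rownames(diversity_table) <- NULL
  fst_table <- do.call(rbind, fst_rows); rownames(fst_table) <- NULL

  # --- per-population diversity by gene group ---------------------------
  pop_panel <- panel[!panel$is_outgroup, , drop = FALSE]
  pops <- names(which(table(pop_panel$population) >= 2L))
  groups <- unique(unname(gene_groups[retained]))
  pop_rows <- list()
  for (pop in pops) for (grp in c(groups, "all")) {
    gids <- retained[grp == "all" | gene_groups[retained] == grp]
    pt <- pg <- numeric()
    for (gid in gids) {
      byc <- pi_by_class(gm_in, partitions[[gid]], panel = pop_panel,
                         population = pop)
      pt <- c(pt, byc$pi_per_kb[byc$region_class == "total"])
      pg <- c(pg, byc$pi_per_kb[byc$region_class == "genic"])
    }
    pop_rows[[paste(pop, grp)]] <- data.frame(
      population = pop, group = grp, n_genes = length(gids),
      pi_t_kb = mean(pt, na.rm = TRUE), pi_g_kb = mean(pg, na.rm = TRUE),
      stringsAsFactors = FALSE)
  }
  population_table <- do.call(rbind, pop_rows); rownames(population_table) <- NULL

  # --- structure --------------------------------------------------------
  retained_sites <- which(gene_of %in% retained)
  str_out <- list()
  str_out$pca_all <- genotype_pca(gm_in, sites = retained_sites)
  grp_main <- groups[1]
  grp_sites <- which(gene_of %in%
                       retained[gene_groups[retained] == grp_main])
  if (length(grp_sites) >= 2L)
    str_out[[paste0("pca_", grp_main)]] <- genotype_pca(gm_in, grp_sites)
  ns_sites <- cons$site_index[cons$consequence %in%
                                c("nonsynonymous", "stop_gained",
                                  "stop_lost") &
                                cons$gene_id %in% retained &
                                gene_groups[cons$gene_id] == grp_main]
  if (length(ns_sites) >= 2L)
    str_out[[paste0("pca_nonsyn_", grp_main)]] <-
      genotype_pca(gm_in, ns_sites)
  d <- allele_sharing_distance(subset_matrix(gm_in, retained_sites))
  str_out$nj <- neighbor_joining(d)
  str_out$distances <- d

  bundle <- structure(list(
    snp_table = snp_table, diversity_table = diversity_table,
    population_table = population_table, fst_table = fst_table,
    structure = str_out, qc = qc, titv = titv,
    exclusions = data.frame(
      gene_id = excluded,
      reason = if (length(excluded))
        paste0("missing rate >= ", config$missing_threshold) else character()),
    consequences = cons, log = log), class = "report_bundle")

  if (!is.null(config$out_dir)) write_bundle(bundle, config$out_dir)
  bundle
}

#' Write a report bundle as TSV/newick files
#'
#' @param bundle a `report_bundle` from [run_pipeline()].
#' @param dir output directory.
#' @export
write_bundle <- function(bundle, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  wt <- function(x, f) utils::write.table(
    x, file.path(dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  wt(bundle$snp_table, "snp_accounting.tsv")
  wt(bundle$diversity_table, "diversity.tsv")
  wt(bundle$population_table, "diversity_by_population.tsv")
  wt(bundle$fst_table, "fst.tsv")
  wt(bundle$exclusions, "excluded_genes.tsv")
  wt(bundle$consequences, "consequences.tsv")
  coords <- as.data.frame(bundle$structure$pca_all$coordinates)
  coords <- cbind(sample = rownames(coords), coords)
  wt(coords, "pca_coordinates.tsv")
  wt(data.frame(component = seq_along(
        bundle$structure$pca_all$variance_fraction),
      variance_fraction = bundle$structure$pca_all$variance_fraction),
     "pca_variance.tsv")
  ape::write.tree(bundle$structure$nj, file.path(dir, "nj_tree.nwk"))
  utils::write.table(bundle$structure$distances,
                     file.path(dir, "distances.tsv"), sep = "\t",
                     quote = FALSE, col.names = NA)
  writeLines(bundle$log, file.path(dir, "run_log.txt"))
  invisible(dir)
}

#' @export
print.report_bundle <- function(x, ...) {
  cat("<report_bundle>\n")
  cat("  genes:", nrow(x$snp_table), "(", nrow(x$exclusions), "excluded )\n")
  cat("  SNPs:", sum(x$snp_table$snps), " ti/tv:", signif(x$titv, 4), "\n")
  invisible(x)
}
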