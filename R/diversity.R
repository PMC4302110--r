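#' Missing-data-aware nucleotide diversity
#'
#' Per site, with `n_i` called alleles and sample allele frequencies
#' `p_a`, diversity is the unbiased heterozygosity
#' `pi_i = n_i/(n_i - 1) * (1 - sum(p_a^2))`, equivalently the fraction of
#' mismatching pairs among all `choose(n_i, 2)` called pairs.  Region
#' aggregates are ratios of sums: `sum(pi_i)` over the class's variant sites
#' divided by the class's effective length, which keeps the estimator stable
#' under heavy missingness.  Sites with fewer than two called alleles are
#' skipped and tallied.
#'
#' @name diversity
NULL

#' Per-site diversity values
#'
#' @param gm a `genotype_matrix`.
#' @param sites optional site index (default all).
#' @param samples optional character vector of sample ids.
#' @return data.frame `site, n_called, pi` (`pi` is `NA` where fewer than
#'   two alleles were called); attribute `n_skipped` counts such sites.
#' @export
pi_per_site_vector <- function(gm, sites = NULL, samples = NULL) {
  si <- sites %||% seq_len(n_sites(gm))
  ci <- if (is.null(samples)) NULL else match(samples, gm$samples)
  sub <- subset_matrix(gm, si)
  cnt <- allele_count_matrix(sub, ci)
  n <- rowSums(cnt)
  sumsq <- rowSums(cnt^2)
  pi <- ifelse(n >= 2, (n^2 - sumsq) / (n * (n - 1)), NA_real_)
  out <- data.frame(site = si, n_called = n, pi = pi)
  attr(out, "n_skipped") <- sum(n < 2)
  out
}

# class-specific effective length: class bp minus variant sites that had to
# be skipped (fewer than two called alleles); mask-aware when one is given
effective_length <- function(partition, class_positions_bp, skipped_var_pos) {
  class_positions_bp - skipped_var_pos
}

#' Diversity by region class
#'
#' Computes pi for the total window, the genic region (exon + intron +
#' UTRs), and each of intergenic / exon / intron / utr (5' and 3' pooled),
#' per site and per kb.
#'
#' @param gm a `genotype_matrix` (variant sites; invariant window positions
#'   are assumed callable unless skipped sites say otherwise).
#' @param partition the gene's `region_partition`.
#' @param panel optional panel data.frame.
#' @param population `"global"` (default) or one population label from the
#'   panel.  Outgroup samples are excluded from `"global"`.
#' @param ci_reps if > 0, standard errors and 95% CIs from this many neutral
#'   coalescent replicates (see [coalescent_ci()]).
#' @param fragments independent-fragment count for the CI replicates.
#' @param seed RNG seed for the CI replicates.
#' @return data.frame with one row per region class: `gene_id, population,
#'   region_class, n_snps, L_eff, pi_per_site, pi_per_kb, se_per_kb,
#'   ci_lo_per_kb, ci_hi_per_kb`.
#' @export
pi_by_class <- function(gm, partition, panel = NULL, population = "global",
                        ci_reps = 0L, fragments = 11L, seed = NULL) {
  samples <- gm$samples
  if (!is.null(panel)) {
    samples <- if (identical(population, "global"))
      panel$sample[!panel$is_outgroup]
    else panel$sample[panel$population == population & !panel$is_outgroup]
    if (length(samples) == 0L) stop("no samples in population ", population)
  }
  in_win <- which(gm$sites$chrom == partition$chrom &
                    gm$sites$pos >= partition$window[["start"]] &
                    gm$sites$pos <= partition$window[["end"]])
  cls <- if (length(in_win)) classify_site(partition, gm$sites$pos[in_win])
         else character()
  pvals <- pi_per_site_vector(gm, in_win, samples)

  groups <- list(
    total = SITE_CLASSES,
    genic = c("exon", "intron", "utr5", "utr3"),
    intergenic = "intergenic", exon = "exon", intron = "intron",
    utr = c("utr5", "utr3"))
  res <- lapply(names(groups), function(g) {
    member <- cls %in% groups[[g]]
    len <- sum(partition$class_lengths[groups[[g]]])
    skipped <- sum(member & is.na(pvals$pi))
    l_eff <- effective_length(partition, len, skipped)
    if (l_eff <= 0)
      return(data.frame(gene_id = partition$gene_id, population = population,
                        region_class = g, n_snps = sum(member), L_eff = 0,
                        pi_per_site = NA_real_, pi_per_kb = NA_real_,
                        se_per_kb = NA_real_, ci_lo_per_kb = NA_real_,
                        ci_hi_per_kb = NA_real_))
    pi_site <- sum(pvals$pi[member], na.rm = TRUE) / l_eff
    se <- lo <- hi <- NA_real_
    if (ci_reps > 0L && pi_site == 0) {
      se <- 0; lo <- 0; hi <- 0   # no diversity: degenerate interval
    } else if (ci_reps > 0L) {
      n_alleles <- if (length(which(member & !is.na(pvals$pi))))
        round(stats::median(pvals$n_called[member & !is.na(pvals$pi)]))
      else 2L * length(samples)
      ci <- coalescent_ci(pi_site, n = max(2L, n_alleles), L_eff = l_eff,
                          reps = ci_reps, fragments = fragments, seed = seed)
      se <- 1000 * ci$se; lo <- 1000 * ci$ci95[1]; hi <- 1000 * ci$ci95[2]
    }
    data.frame(gene_id = partition$gene_id, population = population,
               region_class = g, n_snps = sum(member), L_eff = l_eff,
               pi_per_site = pi_site, pi_per_kb = 1000 * pi_site,
               se_per_kb = se, ci_lo_per_kb = lo, ci_hi_per_kb = hi)
  })
  do.call(rbind, res)
}

#' Synonymous / non-synonymous diversity and omega
#'
#' `pi_s` sums per-site diversity over synonymous SNPs divided by the
#' synonymous site count S; `pi_a` likewise over non-synonymous SNPs and N.
#' `omega = pi_a / pi_s`, undefined (NA) when `pi_s` is 0.
#'
#' @param gm a `genotype_matrix`.
#' @param gene a [gene_model()].
#' @param counts named `c(S=,N=)` from [count_syn_nonsyn_sites()].
#' @param consequences data.frame from [annotate_matrix()] (rows for this
#'   gene are used).
#' @param panel,population as in [pi_by_class()].
#' @param pool_stops count stop_gained/stop_lost SNPs with the
#'   non-synonymous class (default TRUE).
#' @return one-row data.frame `gene_id, pi_s, pi_a, omega` (per-site
#'   diversities).
#' @export
pi_syn_nonsyn <- function(gm, gene, counts, consequences, panel = NULL,
                          population = "global", pool_stops = TRUE) {
  cons <- consequences[consequences$gene_id == gene$gene_id, , drop = FALSE]
  samples <- NULL
  if (!is.null(panel)) {
    samples <- if (identical(population, "global"))
      panel$sample[!panel$is_outgroup]
    else panel$sample[panel$population == population & !panel$is_outgroup]
  }
  nonsyn_cls <- if (pool_stops) c("nonsynonymous", "stop_gained", "stop_lost")
                else "nonsynonymous"
  sum_pi <- function(idx) {
    if (length(idx) == 0L) return(0)
    sum(pi_per_site_vector(gm, idx, samples)$pi, na.rm = TRUE)
  }
  pi_s <- sum_pi(cons$site_index[cons$consequence == "synonymous"]) /
    counts[["S"]]
  pi_a <- sum_pi(cons$site_index[cons$consequence %in% nonsyn_cls]) /
    counts[["N"]]
  data.frame(gene_id = gene$gene_id, pi_s = pi_s, pi_a = pi_a,
             omega = if (pi_s > 0) pi_a / pi_s else NA_real_)
}

#' Coalescent standard error and confidence interval for pi
#'
#' Simulates `reps` neutral coalescent samples of `n` alleles at
#' `theta = pi_hat * L_eff` (recombination approximated by `fragments`
#' independent fragments), and summarizes the replicate per-site diversity
#' distribution.
#'
#' @param pi_hat per-site diversity estimate (>= 0).
#' @param n number of sampled alleles (>= 2).
#' @param L_eff effective length in bp.
#' @param reps number of replicates (default 1000).
#' @param fragments independent fragments (default 11, an intermediate
#'   recombination stand-in).
#' @param seed RNG seed.
#' @return list `se`, `ci95` (length-2), `replicates` (per-site values).
#' @export
coalescent_ci <- function(pi_hat, n, L_eff, reps = 1000L, fragments = 11L,
                          seed = NULL) {
  stopifnot(pi_hat >= 0, n >= 2)
  if (pi_hat == 0) {
    warning("pi_hat is 0: degenerate CI")
    return(list(se = 0, ci95 = c(0, 0), replicates = rep(0, reps)))
  }
  theta <- pi_hat * L_eff
  vals <- with_seed(seed, vapply(seq_len(reps), function(i) {
    sim <- simulate_locus(sim_config(
      n_haplotypes = n, theta = theta, L = max(L_eff, 1), diploid = FALSE,
      fragments = fragments))
    mean_pairwise_diff(sim$haplotypes) / L_eff
  }, 0))
  list(se = stats::sd(vals),
       ci95 = unname(stats::quantile(vals, c(0.025, 0.975))),
       replicates = vals)
}

#' McDonald-Kreitman test
#'
#' Contrasts synonymous and non-synonymous counts of within-ingroup
#' polymorphisms (Pn, Ps) against fixed differences from the outgroup
#' consensus (Dn, Ds) with a two-sided Fisher exact test; the neutrality
#' index is `NI = (Pn/Ps)/(Dn/Ds)`.
#'
#' @param gm a `genotype_matrix` containing ingroup and outgroup samples.
#' @param panel panel data.frame with at least one `is_outgroup` sample.
#' @param gene a [gene_model()].
#' @param consequences data.frame from [annotate_matrix()].
#' @return one-row data.frame `gene_id, Pn, Ps, Dn, Ds, fisher_p, NI`.
#' @export
mk_test <- function(gm, panel, gene, consequences) {
  og <- panel$sample[panel$is_outgroup]
  if (length(og) == 0L) stop("no outgroup samples flagged in panel")
  ig <- panel$sample[!panel$is_outgroup]
  cons <- consequences[consequences$gene_id == gene$gene_id &
                         consequences$consequence %in%
                           c("synonymous", "nonsynonymous", "stop_gained",
                             "stop_lost"), , drop = FALSE]
  Pn <- Ps <- Dn <- Ds <- 0L
  for (i in seq_len(nrow(cons))) {
    idx <- cons$site_index[i]
    syn <- cons$consequence[i] == "synonymous"
    in_cnt <- allele_count_matrix(subset_matrix(gm, idx),
                                  match(ig, gm$samples))
    og_cnt <- allele_count_matrix(subset_matrix(gm, idx),
                                  match(og, gm$samples))
    in_called <- which(in_cnt[1, ] > 0) - 1L
    if (length(in_called) == 0L) next
    if (length(in_called) > 1L) {          # ingroup polymorphism
      if (syn) Ps <- Ps + 1L else Pn <- Pn + 1L
    } else if (sum(og_cnt) > 0) {          # ingroup fixed: divergence?
      og_consensus <- which.max(og_cnt[1, ]) - 1L
      if (og_consensus != in_called) {
        if (syn) Ds <- Ds + 1L else Dn <- Dn + 1L
      }
    }
  }
  p <- stats::fisher.test(matrix(c(Pn, Ps, Dn, Ds), nrow = 2))$p.value
  ni <- if (Dn > 0 && Ds > 0 && Ps > 0) (Pn / Ps) / (Dn / Ds) else NA_real_
  data.frame(gene_id = gene$gene_id, Pn = Pn, Ps = Ps, Dn = Dn, Ds = Ds,
             fisher_p = p, NI = ni)
}
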