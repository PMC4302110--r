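# Missing-data-aware diversity, region aggregation, omega, coalescent CIs
# and the McDonald-Kreitman test.

test_that("per-site diversity matches worked examples and the all-pairs
           oracle under missingness", {
  # two het samples A/G + A/G: alleles {A,A,G,G} -> 4 of 6 pairs differ
  gm <- random_matrix(1, 2)
  gm$a1[1, ] <- c(0L, 0L); gm$a2[1, ] <- c(1L, 1L)
  expect_equal(pi_per_site_vector(gm)$pi, 2 / 3)
  # monomorphic called site
  gm$a1[1, ] <- 0L; gm$a2[1, ] <- 0L
  expect_equal(pi_per_site_vector(gm)$pi, 0)
  # 200 random sites with random missingness vs brute force
  gm <- random_matrix(200, 9, miss = 0.35, seed = 42)
  got <- pi_per_site_vector(gm)
  want <- vapply(seq_len(200), function(i) oracle_pi_site(site_alleles(gm, i)),
                 0)
  expect_equal(got$pi, want, tolerance = 1e-12)
  expect_equal(attr(got, "n_skipped"), sum(is.na(want)))
})

test_that("diversity by region class follows the ratio-of-sums definition", {
  # a gene spanning its whole window: 1 difference between 2 haplotype-like
  # samples over 1,000 genic bp -> pi_g = 1.0 per kb
  g <- make_gene_template("g1", "chr1", gene_start = 1L, n_exons = 1L,
                          cds_len = 999L, utr3_len = 1L)
  cl <- c(chr1 = 1000L)
  ref <- make_reference(list(g1 = g), cl, seed = 2)
  parts <- build_windows(list(g1 = g), 0L, cl)
  sites <- data.frame(chrom = "chr1", pos = 500L, id = ".", ref = "A",
                      alt = "G", stringsAsFactors = FALSE)
  gm <- tasrdiv:::new_genotype_matrix(
    sites, matrix(0L, 1, 2), matrix(c(0L, 1L), 1, 2), c("h1", "h2"))
  # alleles {0,0,0,1}: pi = (4/3)(1 - (3/4)^2 - (1/4)^2) = 0.5
  byc <- pi_by_class(gm, parts$g1)
  expect_equal(byc$pi_per_kb[byc$region_class == "genic"], 0.5)
  expect_equal(byc$pi_per_kb[byc$region_class == "total"], 0.5)
  # restricted to identical samples -> 0
  byc0 <- pi_by_class(subset_matrix(gm, samples = "h1"), parts$g1)
  expect_equal(byc0$pi_per_kb[byc0$region_class == "total"], 0)
})

test_that("pi_t equals the all-pairs oracle on a simulated gene without
           missingness", {
  s <- toy_gene_setup(flank = 2000L, seed = 3)
  cfg <- sim_config(n_per_deme = 8L, theta = 20,
                    demography = list(type = "panmictic"), fragments = 1L,
                    seed = 31)
  out <- simulate_gene_dataset(s$gene, s$partition, s$ref, cfg,
                               sprintf("d%02d", 1:8))
  gm <- out$matrix
  byc <- pi_by_class(gm, s$partition)
  want <- mean(vapply(seq_len(n_sites(gm)), function(i)
    oracle_pi_site(site_alleles(gm, i)), 0)) * n_sites(gm) /
    sum(s$partition$class_lengths)
  expect_equal(byc$pi_per_site[byc$region_class == "total"], want,
               tolerance = 1e-12)
  # and matches the generator's truth exactly (complete data)
  expect_equal(byc$pi_per_site[byc$region_class == "total"],
               unname(out$truth$pi_per_site["total"]), tolerance = 1e-9)
})

test_that("estimates are invariant to sample and site order", {
  s <- toy_gene_setup(flank = 1000L, seed = 8)
  gm <- random_matrix(40, 10, miss = 0.25, seed = 13)
  gm$sites$pos <- sort(withr::with_seed(5, sample(
    seq(s$partition$window[["start"]], s$partition$window[["end"]]), 40)))
  byc <- pi_by_class(gm, s$partition)
  perm_s <- withr::with_seed(6, sample(10))
  gm2 <- subset_matrix(gm, samples = gm$samples[perm_s])
  byc2 <- pi_by_class(gm2, s$partition)
  expect_equal(byc$pi_per_site, byc2$pi_per_site)
  perm_sites <- withr::with_seed(7, sample(40))
  gm3 <- subset_matrix(gm, sites = perm_sites)
  expect_equal(sum(pi_per_site_vector(gm3)$pi, na.rm = TRUE),
               sum(pi_per_site_vector(gm)$pi, na.rm = TRUE))
})

test_that("omega handles zero synonymous diversity and the balanced case", {
  s <- toy_gene_setup(n_exons = 1L, cds_len = 300L, utr5_len = 0L,
                      utr3_len = 0L, flank = 1000L, seed = 23)
  g <- s$gene
  counts <- count_syn_nonsyn_sites(g, s$ref)
  # find one synonymous and one nonsynonymous mutable site
  find_site <- function(target) {
    for (pos in seq(g$cds$start[1], g$cds$end[1])) {
      rb <- as.character(Biostrings::subseq(s$ref[[g$chrom]], pos, pos))
      for (alt in setdiff(c("A", "C", "G", "T"), rb)) {
        if (annotate_variant(g, s$partition, s$ref, pos, rb, alt) == target)
          return(list(pos = pos, ref = rb, alt = alt))
      }
    }
    stop("not found")
  }
  syn <- find_site("synonymous"); ns <- find_site("nonsynonymous")
  mk_gm <- function(spec) {
    sites <- do.call(rbind, lapply(spec, function(x)
      data.frame(chrom = "chr1", pos = x$pos, id = ".", ref = x$ref,
                 alt = x$alt, stringsAsFactors = FALSE)))
    n <- length(spec)
    tasrdiv:::new_genotype_matrix(
      sites, matrix(0L, n, 4), matrix(rep(c(0L, 1L, 0L, 1L), each = n),
                                      n, 4), sprintf("s%d", 1:4))
  }
  parts <- s$partition
  gm_both <- mk_gm(list(syn, ns))
  cons <- annotate_matrix(gm_both, list(g1 = g), list(g1 = parts), s$ref)
  om <- pi_syn_nonsyn(gm_both, g, counts, cons)
  expect_gt(om$pi_s, 0); expect_gt(om$pi_a, 0)
  # equal summed pi over the S and N classes -> omega = S/N
  expect_equal(om$omega, counts[["S"]] / counts[["N"]])
  gm_ns <- mk_gm(list(ns))
  cons_ns <- annotate_matrix(gm_ns, list(g1 = g), list(g1 = parts), s$ref)
  om_ns <- pi_syn_nonsyn(gm_ns, g, counts, cons_ns)
  expect_true(is.na(om_ns$omega))   # no synonymous diversity -> undefined
  expect_gt(om_ns$pi_a, 0)
})

test_that("coalescent CIs are degenerate at zero diversity, calibrated in
           the mean, and tighter with more fragments", {
  expect_warning(ci0 <- coalescent_ci(0, n = 10, L_eff = 100), "degenerate")
  expect_equal(ci0$se, 0); expect_equal(ci0$ci95, c(0, 0))
  # E[pi] = theta under the neutral coalescent
  ci <- coalescent_ci(2 / 500, n = 10, L_eff = 500, reps = 2000,
                      fragments = 1, seed = 99)
  expect_lt(abs(mean(ci$replicates) * 500 - 2) / 2, 0.03)
  ci_frag <- coalescent_ci(2 / 500, n = 10, L_eff = 500, reps = 2000,
                           fragments = 11, seed = 100)
  expect_lt(ci_frag$se, ci$se)
  expect_true(ci$ci95[1] <= ci$ci95[2])
})

test_that("the McDonald-Kreitman table and Fisher p behave as expected", {
  # symmetric table -> p = 1
  expect_equal(stats::fisher.test(matrix(c(5, 5, 5, 5), 2))$p.value, 1.0)
  # random small tables vs exhaustive hypergeometric enumeration
  withr::with_seed(17, {
    for (k in 1:25) {
      t4 <- rpois(4, 6)
      p1 <- stats::fisher.test(matrix(t4, 2))$p.value
      p2 <- oracle_fisher(t4[1], t4[2], t4[3], t4[4])
      expect_equal(p1, p2, tolerance = 1e-9)
    }
  })
})

test_that("mk_test counts polymorphism and divergence off a constructed
           gene", {
  s <- toy_gene_setup(n_exons = 1L, cds_len = 300L, utr5_len = 0L,
                      utr3_len = 0L, flank = 500L, seed = 29)
  g <- s$gene
  classify <- function(pos, alt) {
    rb <- as.character(Biostrings::subseq(s$ref[[g$chrom]], pos, pos))
    annotate_variant(g, s$partition, s$ref, pos, rb, alt)
  }
  # collect coding sites by label
  syn_sites <- list(); ns_sites <- list()
  for (pos in seq(g$cds$start[1], g$cds$end[1])) {
    rb <- as.character(Biostrings::subseq(s$ref[[g$chrom]], pos, pos))
    for (alt in setdiff(c("A", "C", "G", "T"), rb)) {
      lab <- classify(pos, alt)
      item <- list(pos = pos, ref = rb, alt = alt)
      if (lab == "synonymous" && length(syn_sites) < 4)
        syn_sites[[length(syn_sites) + 1]] <- item
      if (lab == "nonsynonymous" && length(ns_sites) < 4)
        ns_sites[[length(ns_sites) + 1]] <- item
    }
    if (length(syn_sites) >= 4 && length(ns_sites) >= 4) break
  }
  # 4 ingroup + 1 outgroup; build: 1 syn polymorphism, 2 ns polymorphisms,
  # 1 syn divergence, 1 ns divergence, plus 1 shared-fixed site (no count)
  spec <- list(
    list(site = syn_sites[[1]], in_geno = c(0L, 1L, 0L, 0L), og = 0L), # Ps
    list(site = ns_sites[[1]], in_geno = c(0L, 1L, 0L, 0L), og = 0L),  # Pn
    list(site = ns_sites[[2]], in_geno = c(1L, 1L, 0L, 0L), og = 0L),  # Pn
    list(site = syn_sites[[2]], in_geno = c(0L, 0L, 0L, 0L), og = 1L), # Ds
    list(site = ns_sites[[3]], in_geno = c(1L, 1L, 1L, 1L), og = 0L),  # Dn
    list(site = ns_sites[[4]], in_geno = c(1L, 1L, 1L, 1L), og = 1L))  # none
  sites <- do.call(rbind, lapply(spec, function(x)
    data.frame(chrom = "chr1", pos = x$site$pos, id = ".", ref = x$site$ref,
               alt = x$site$alt, stringsAsFactors = FALSE)))
  a1 <- cbind(do.call(rbind, lapply(spec, function(x) x$in_geno)),
              vapply(spec, function(x) x$og, 0L))
  gm <- tasrdiv:::new_genotype_matrix(sites, a1, a1,
                                      c(sprintf("in%d", 1:4), "og1"))
  panel <- data.frame(sample = gm$samples,
                      population = c(rep("P", 4), "OG"),
                      is_outgroup = c(rep(FALSE, 4), TRUE))
  cons <- annotate_matrix(gm, list(g1 = g),
                          stats::setNames(list(s$partition), "g1"), s$ref)
  mk <- mk_test(gm, panel, g, cons)
  expect_equal(c(mk$Pn, mk$Ps, mk$Dn, mk$Ds), c(2, 1, 1, 1))
  expect_equal(mk$fisher_p,
               stats::fisher.test(matrix(c(2, 1, 1, 1), 2))$p.value)
  expect_equal(mk$NI, (2 / 1) / (1 / 1))
  # Ds = 0 -> NI undefined
  gm2 <- subset_matrix(gm, sites = c(1:3, 5))
  cons2 <- annotate_matrix(gm2, list(g1 = g),
                           stats::setNames(list(s$partition), "g1"), s$ref)
  mk2 <- mk_test(gm2, panel, g, cons2)
  expect_true(is.na(mk2$NI))
  expect_error(mk_test(gm, panel[!panel$is_outgroup, ], g, cons),
               "outgroup")
})
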