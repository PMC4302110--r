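# Shared fixtures and independent oracles, built in code at test time.

iv <- tasrdiv:::iv   # interval constructor, used when building models by hand

# all-pairs brute-force per-site diversity: mean mismatch fraction over
# every pair of called alleles (independent of the estimator under test)
oracle_pi_site <- function(alleles) {
  alleles <- alleles[!is.na(alleles)]
  n <- length(alleles)
  if (n < 2) return(NA_real_)
  mism <- sum(outer(alleles, alleles, `!=`)) / 2   # every unordered pair
  mism / choose(n, 2)
}

# per-site alleles of a genotype_matrix row as one vector
site_alleles <- function(gm, i, samples = NULL) {
  ci <- if (is.null(samples)) seq_along(gm$samples)
        else match(samples, gm$samples)
  c(gm$a1[i, ci], gm$a2[i, ci])
}

# random genotype matrix: biallelic sites, optional missingness
random_matrix <- function(n_sites, n_samples, miss = 0, seed = 1) {
  withr::with_seed(seed, {
    p <- runif(n_sites, 0.05, 0.95)
    a1 <- matrix(rbinom(n_sites * n_samples, 1, p), nrow = n_sites)
    a2 <- matrix(rbinom(n_sites * n_samples, 1, p), nrow = n_sites)
    if (miss > 0) {
      drop <- matrix(runif(n_sites * n_samples) < miss, nrow = n_sites)
      a1[drop] <- NA; a2[drop] <- NA
    }
    sites <- data.frame(chrom = "chr1", pos = seq_len(n_sites) * 10L,
                        id = ".", ref = "A", alt = "G",
                        stringsAsFactors = FALSE)
    tasrdiv:::new_genotype_matrix(sites, a1, a2,
                                  sprintf("s%03d", seq_len(n_samples)))
  })
}

# one annotated test gene + reference + partition in a single call
toy_gene_setup <- function(gene_id = "g1", n_exons = 3L, cds_len = 300L,
                           utr5_len = 30L, utr3_len = 60L,
                           intron_len = 100L, strand = "+",
                           gene_start = 12001L, flank = 10000L, seed = 7) {
  g <- make_gene_template(gene_id, "chr1", gene_start = gene_start,
                          strand = strand, n_exons = n_exons,
                          cds_len = cds_len, utr5_len = utr5_len,
                          utr3_len = utr3_len, intron_len = intron_len)
  cl <- c(chr1 = g$span[["end"]] + flank + 5000L)
  ref <- make_reference(stats::setNames(list(g), gene_id), cl, seed = seed)
  parts <- build_windows(stats::setNames(list(g), gene_id), flank, cl)
  list(gene = g, ref = ref, partition = parts[[gene_id]], chrom_lengths = cl)
}

# hand enumeration of Hudson pi_w / pi_t over explicit allele pair loops
oracle_fst <- function(gm, pop_of) {
  w_mism <- w_pairs <- t_mism <- t_pairs <- 0
  for (s in seq_len(nrow(gm$sites))) {
    al <- list()
    for (k in seq_along(gm$samples))
      al[[k]] <- c(gm$a1[s, k], gm$a2[s, k])
    alleles <- unname(unlist(al))
    pops <- rep(pop_of, each = 2)
    keep <- !is.na(alleles)
    alleles <- alleles[keep]; pops <- pops[keep]
    usable <- any(table(pops) >= 2)
    if (!usable) next
    n <- length(alleles)
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      d <- alleles[i] != alleles[j]
      t_mism <- t_mism + d; t_pairs <- t_pairs + 1
      if (pops[i] == pops[j]) { w_mism <- w_mism + d; w_pairs <- w_pairs + 1 }
    }
  }
  pi_w <- w_mism / w_pairs; pi_t <- t_mism / t_pairs
  list(pi_w = pi_w, pi_t = pi_t, fst = 1 - pi_w / pi_t)
}

# two-sided Fisher p by exhaustive hypergeometric enumeration
oracle_fisher <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  support <- max(0, k - n):min(k, m)
  probs <- dhyper(support, m, n, k)
  p_obs <- dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

write_lines_tmp <- function(lines, ext) {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}
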