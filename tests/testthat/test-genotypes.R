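# VCF parsing, missingness accounting, allele frequencies and ti/tv.

vcf_fixture <- function(rows, samples = c("sA", "sB", "sC")) {
  write_lines_tmp(c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"),
    rows), ".vcf")
}

test_that("VCF genotypes parse with explicit missingness and indels are
           dropped with a count", {
  f <- vcf_fixture(c(
    "chr1\t100\t.\tA\tG\t.\tPASS\t.\tGT\t0/1\t1/1\t./.",
    "chr1\t200\t.\tA\tAT\t.\tPASS\t.\tGT\t0/0\t0/1\t0/0",   # indel
    "chr1\t300\t.\tC\tT,G\t.\tPASS\t.\tGT\t1/2\t0|0\t./1")) # half-call
  expect_message(gm <- read_vcf(f), "dropped 1 non-SNP")
  expect_equal(n_sites(gm), 2L)
  expect_equal(gm$sites$pos, c(100L, 300L))
  expect_equal(unname(gm$a1[1, ]), c(0L, 1L, NA))
  expect_equal(unname(gm$a2[1, ]), c(1L, 1L, NA))
  # multiallelic kept, pipe separators fine, half-call fully missing
  expect_equal(unname(gm$a1[2, ]), c(1L, 0L, NA))
  expect_equal(unname(gm$a2[2, ]), c(2L, 0L, NA))
  expect_error(read_vcf(f, data.frame(sample = c("sA", "ghost"),
                                      population = "P",
                                      is_outgroup = FALSE)),
               "ghost")
})

test_that("missing rates average per site and per gene", {
  s <- toy_gene_setup(flank = 1000L)
  p <- s$partition
  pos <- p$window[["start"]] + c(10L, 20L)
  sites <- data.frame(chrom = "chr1", pos = pos, id = ".", ref = "A",
                      alt = "G", stringsAsFactors = FALSE)
  # site 1: 2 of 10 missing; site 2: 3 of 10 missing
  a1 <- matrix(0L, 2, 10); a2 <- matrix(1L, 2, 10)
  a1[1, 1:2] <- NA; a2[1, 1:2] <- NA
  a1[2, 1:3] <- NA; a2[2, 1:3] <- NA
  gm <- tasrdiv:::new_genotype_matrix(sites, a1, a2, sprintf("s%02d", 1:10))
  qc <- missing_rates(gm, stats::setNames(list(p), p$gene_id))
  expect_equal(qc$per_site$missing, c(0.2, 0.3))
  expect_equal(qc$per_gene$missing, 0.25)
  expect_equal(filter_genes_by_missing(qc, threshold = 0.25), p$gene_id)
  expect_equal(filter_genes_by_missing(qc, threshold = 1.0), character())
})

test_that("Bernoulli-injected missingness is recovered within binomial
           error", {
  gm <- random_matrix(500, 10, seed = 11)
  gm <- inject_missingness(gm, 0.25, seed = 12)
  realized <- mean(tasrdiv:::geno_missing(gm))
  expect_lt(abs(realized - 0.25), 0.02)   # 5,000 genotypes
})

test_that("allele frequencies match a brute-force tally and strata with no
           calls are undefined", {
  gm <- random_matrix(40, 12, miss = 0.3, seed = 3)
  panel <- data.frame(sample = gm$samples,
                      population = rep(c("P1", "P2"), each = 6),
                      is_outgroup = FALSE)
  af <- allele_frequencies(gm, panel)
  for (i in c(1L, 7L, 40L)) {
    for (pop in c("global", "P1", "P2")) {
      al <- site_alleles(gm, i, if (pop == "global") NULL else
        panel$sample[panel$population == pop])
      al <- al[!is.na(al)]
      for (v in 0:1) {
        got <- af$freq$freq[af$freq$pos == gm$sites$pos[i] &
                              af$freq$stratum == pop & af$freq$allele == v]
        want <- if (length(al)) mean(al == v) else NA_real_
        expect_equal(got, want, tolerance = 1e-12)
      }
    }
  }
  # frequencies over called alleles sum to 1 at every site/stratum
  sums <- tapply(af$freq$freq, list(af$freq$pos, af$freq$stratum), sum)
  expect_true(all(is.na(sums) | abs(sums - 1) < 1e-12))
  expect_true(all(af$maf$maf <= 0.5 + 1e-12, na.rm = TRUE))
  # a population entirely missing at a site yields NA, not zero
  gm2 <- random_matrix(1, 4, seed = 5)
  gm2$a1[1, 1:2] <- NA; gm2$a2[1, 1:2] <- NA
  panel2 <- data.frame(sample = gm2$samples,
                       population = rep(c("P1", "P2"), each = 2),
                       is_outgroup = FALSE)
  af2 <- allele_frequencies(gm2, panel2)
  expect_true(all(is.na(af2$freq$freq[af2$freq$stratum == "P1"])))
})

test_that("QC and frequencies are invariant to sample order", {
  s <- toy_gene_setup(flank = 1000L)
  gm <- random_matrix(30, 8, miss = 0.2, seed = 21)
  gm$sites$pos <- s$partition$window[["start"]] + seq_len(30) * 10L
  gm$sites$alt <- rep(c("G", "T", "C"), each = 10L)
  perm <- withr::with_seed(1, sample(8))
  gm_perm <- subset_matrix(gm, samples = gm$samples[perm])
  parts <- stats::setNames(list(s$partition), s$partition$gene_id)
  expect_equal(missing_rates(gm, parts)$per_gene,
               missing_rates(gm_perm, parts)$per_gene)
  af1 <- allele_frequencies(gm)$freq
  af2 <- allele_frequencies(gm_perm)$freq
  expect_equal(af1$freq, af2$freq)
  expect_equal(titv_ratio(gm), titv_ratio(gm_perm))
})

test_that("ti/tv counts transitions A<->G and C<->T once per alt allele", {
  gm <- random_matrix(3, 2, seed = 1)
  gm$sites$ref <- c("A", "C", "A")
  gm$sites$alt <- c("G", "T", "C")
  expect_equal(titv_ratio(gm), 2.0)
  gm$sites$alt <- c("G", "A", "G")  # transversion C->A among them
  expect_equal(titv_ratio(gm), 2.0)
  gm$sites$alt <- c("G", "T", "G")  # no transversions
  expect_warning(r <- titv_ratio(gm), "undefined")
  expect_true(is.na(r))
  expect_error(titv_ratio(subset_matrix(gm, integer(0))), "empty")
})

test_that("the transition-biased mutation draw hits its target ti/tv", {
  # kappa / 2 is the expected ti/tv of the derived-allele draw
  refs <- withr::with_seed(31, sample(c("A", "C", "G", "T"), 2000,
                                      replace = TRUE))
  alts <- withr::with_seed(32, tasrdiv:::draw_alt_alleles(refs, kappa = 4.7))
  purine <- function(b) b %in% c("A", "G")
  ti <- sum(purine(refs) == purine(alts))
  tv <- length(refs) - ti
  p_hat <- ti / length(refs)
  p_expect <- 4.7 / 6.7
  expect_lt(abs(p_hat - p_expect), 3 * sqrt(p_expect * (1 - p_expect) / 2000))
})
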