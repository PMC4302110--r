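# Codon-level classification and Nei-Gojobori site counting, checked against
# a full-CDS translate-and-compare oracle.

GC <- Biostrings::GENETIC_CODE
SENSE <- names(GC)[GC != "*"]

# oracle: label of replacing base at position p of `codon` with b,
# via whole-codon translation
oracle_label <- function(codon, p, b) {
  mutant <- codon
  substring(mutant, p, p) <- b
  aa0 <- unname(GC[codon]); aa1 <- unname(GC[mutant])
  if (aa0 == aa1) "synonymous"
  else if (aa1 == "*") "stop_gained"
  else if (aa0 == "*") "stop_lost"
  else "nonsynonymous"
}

test_that("worked codon examples classify correctly", {
  expect_equal(oracle_label("TTT", 3, "C"), "synonymous")     # Phe/Phe
  expect_equal(oracle_label("TAC", 3, "A"), "stop_gained")
  expect_equal(oracle_label("TAA", 3, "C"), "stop_lost")
  s <- tasrdiv:::codon_site_counts("TTT")
  expect_equal(unname(s), c(1 / 3, 8 / 3))
  expect_equal(unname(tasrdiv:::codon_site_counts("ATG")), c(0, 3))
})

test_that("for all 61 sense codons the (S, N) counts and all 9 single-base
           labels match the enumeration oracle", {
  for (codon in SENSE) {
    syn <- 0
    for (p in 1:3) for (b in setdiff(c("A", "C", "G", "T"),
                                     substring(codon, p, p))) {
      lab <- oracle_label(codon, p, b)
      if (lab == "synonymous") syn <- syn + 1
    }
    counts <- tasrdiv:::codon_site_counts(codon)
    expect_equal(unname(counts["S"]), syn / 3, info = codon)
    expect_equal(sum(counts), 3, info = codon)
  }
})

test_that("gene-level site counts respect terminal-stop exclusion and
           internal stops are errors", {
  s <- toy_gene_setup(n_exons = 2L, cds_len = 300L)
  counts <- count_syn_nonsyn_sites(s$gene, s$ref)
  # terminal stop excluded: 99 codons counted
  expect_equal(unname(counts["S"] + counts["N"]), 297)
  # corrupt the reference with an internal stop
  chrom <- s$gene$chrom
  seqs <- as.character(s$ref)
  cds4 <- s$gene$cds$start[1] + 3L   # codon 2, plus strand
  substring(seqs[chrom], cds4, cds4 + 2L) <- "TAA"
  badref <- Biostrings::DNAStringSet(seqs)
  expect_error(count_syn_nonsyn_sites(s$gene, badref), "internal stop")
})

test_that("random coding SNPs on both strands agree with the full-CDS
           translation oracle", {
  for (strand in c("+", "-")) {
    s <- toy_gene_setup(n_exons = 3L, cds_len = 602L + 1L, strand = strand,
                        utr5_len = 20L, utr3_len = 30L, seed = 17)
    g <- s$gene
    cds_pos_all <- unlist(Map(seq, g$cds$start, g$cds$end))
    cds_seq <- tasrdiv:::cds_sequence(g, s$ref)
    prot0 <- as.character(Biostrings::translate(
      Biostrings::DNAString(cds_seq), no.init.codon = TRUE))
    set.seed(1 + (strand == "-"))
    pos_sample <- sample(cds_pos_all, 400, replace = TRUE)
    for (pos in pos_sample) {
      ref_base <- as.character(Biostrings::subseq(s$ref[[g$chrom]], pos, pos))
      alt <- sample(setdiff(c("A", "C", "G", "T"), ref_base), 1)
      got <- annotate_variant(g, s$partition, s$ref, pos, ref_base, alt)
      # oracle: substitute in the spliced CDS, translate whole protein
      cpos <- tasrdiv:::cds_position(g, pos)
      mutant <- cds_seq
      sub_base <- if (strand == "-") tasrdiv:::revcomp(alt) else alt
      substring(mutant, cpos, cpos) <- sub_base
      prot1 <- as.character(Biostrings::translate(
        Biostrings::DNAString(mutant), no.init.codon = TRUE))
      aa0 <- substring(prot0, (cpos - 1) %/% 3 + 1, (cpos - 1) %/% 3 + 1)
      aa1 <- substring(prot1, (cpos - 1) %/% 3 + 1, (cpos - 1) %/% 3 + 1)
      want <- if (aa0 == aa1) "synonymous"
              else if (aa1 == "*") "stop_gained"
              else if (aa0 == "*") "stop_lost"
              else "nonsynonymous"
      expect_equal(got, want,
                   info = sprintf("%s pos %d %s>%s", strand, pos, ref_base,
                                  alt))
    }
  }
})

test_that("a minus-strand gene classifies like the plus-strand classification
           of the reverse-complemented construct", {
  sp <- toy_gene_setup(n_exons = 1L, cds_len = 300L, strand = "+", seed = 5)
  # build the minus-strand gene whose CDS is the revcomp at the same coords
  g <- sp$gene
  gm <- gene_model(g$gene_id, g$chrom, "-", g$exons, g$cds, g$utr3, g$utr5)
  seqs <- as.character(sp$ref)
  cds_s <- g$cds$start[1]; cds_e <- g$cds$end[1]
  substring(seqs[g$chrom], cds_s, cds_e) <-
    tasrdiv:::revcomp(substring(seqs[g$chrom], cds_s, cds_e))
  ref_m <- Biostrings::DNAStringSet(seqs)
  set.seed(9)
  for (k in 1:50) {
    pos <- sample(cds_s:cds_e, 1)
    mirror <- cds_e - (pos - cds_s)
    ref_p <- as.character(Biostrings::subseq(sp$ref[[g$chrom]], pos, pos))
    alt_p <- sample(setdiff(c("A", "C", "G", "T"), ref_p), 1)
    lab_p <- annotate_variant(g, sp$partition, sp$ref, pos, ref_p, alt_p)
    ref_m_base <- as.character(Biostrings::subseq(ref_m[[g$chrom]], mirror,
                                                  mirror))
    lab_m <- annotate_variant(gm, sp$partition, ref_m, mirror, ref_m_base,
                              tasrdiv:::revcomp(alt_p))
    expect_equal(lab_m, lab_p)
  }
})

test_that("non-coding classes pass through and reference mismatches are
           errors", {
  s <- toy_gene_setup(n_exons = 2L, cds_len = 300L, utr5_len = 30L,
                      intron_len = 100L)
  g <- s$gene
  flank_pos <- s$partition$window[["start"]] + 5L
  rb <- function(p) as.character(Biostrings::subseq(s$ref[[g$chrom]], p, p))
  expect_equal(annotate_variant(g, s$partition, s$ref, flank_pos,
                                rb(flank_pos), "A"), "intergenic")
  intron_pos <- g$exons$end[1] + 10L
  expect_equal(annotate_variant(g, s$partition, s$ref, intron_pos,
                                rb(intron_pos), "A"), "intron")
  utr_pos <- g$utr5$start[1] + 2L
  expect_equal(annotate_variant(g, s$partition, s$ref, utr_pos,
                                rb(utr_pos), "A"), "utr5")
  cds_pos <- g$cds$start[1] + 10L
  wrong <- setdiff(c("A", "C", "G", "T"), rb(cds_pos))[1]
  expect_error(annotate_variant(g, s$partition, s$ref, cds_pos, wrong, "A"),
               "mismatch")
})
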