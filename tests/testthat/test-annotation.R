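# Gene models, flanked windows, the midpoint split rule and site classes.

test_that("windows get full flanks when genes are far apart and split gaps
           at the midpoint when close", {
  g1 <- make_gene_template("g1", "chr1", gene_start = 50001L, n_exons = 1L,
                           cds_len = 300L)
  end1 <- g1$span[["end"]]
  # gap of exactly 15,000 bp between spans -> 7,500 bp each
  g2 <- make_gene_template("g2", "chr1", gene_start = end1 + 15001L,
                           n_exons = 1L, cds_len = 300L)
  cl <- c(chr1 = g2$span[["end"]] + 50000L)
  parts <- build_windows(list(g1 = g1, g2 = g2), 10000L, cl)
  expect_equal(parts$g1$window[["end"]], end1 + 7500)
  expect_equal(parts$g2$window[["start"]], end1 + 7501)
  expect_equal(parts$g1$window[["start"]], 50001 - 10000)
  # gap of 25,000 bp -> untouched 10 kb flanks
  g3 <- make_gene_template("g3", "chr1", gene_start = end1 + 25001L,
                           n_exons = 1L, cds_len = 300L)
  parts2 <- build_windows(list(g1 = g1, g3 = g3), 10000L,
                          c(chr1 = g3$span[["end"]] + 50000L))
  expect_equal(parts2$g1$window[["end"]], end1 + 10000)
  expect_equal(parts2$g3$window[["start"]], end1 + 25001 - 10000)
  # windows never overlap
  expect_lt(parts$g1$window[["end"]], parts$g2$window[["start"]])
})

test_that("odd gaps give the extra base to the upstream gene", {
  g1 <- make_gene_template("g1", "chr1", gene_start = 50001L, cds_len = 300L)
  end1 <- g1$span[["end"]]
  g2 <- make_gene_template("g2", "chr1", gene_start = end1 + 15002L,
                           cds_len = 300L)  # gap 15001 (odd)
  parts <- build_windows(list(g1 = g1, g2 = g2), 10000L,
                         c(chr1 = g2$span[["end"]] + 50000L))
  left_take <- parts$g1$window[["end"]] - end1
  right_take <- (end1 + 15002L) - parts$g2$window[["start"]]
  expect_equal(left_take, 7501)
  expect_equal(right_take, 7500)
  expect_equal(left_take + right_take, 15001)
})

test_that("windows clamp at chromosome ends", {
  g <- make_gene_template("g1", "chr1", gene_start = 4000L, cds_len = 300L)
  parts <- build_windows(list(g1 = g), 10000L,
                         c(chr1 = g$span[["end"]] + 2000L))
  expect_equal(parts$g1$window[["start"]], 1)
  expect_equal(parts$g1$window[["end"]], g$span[["end"]] + 2000L)
})

test_that("every window position gets exactly one class and the class
           lengths tile the window", {
  for (strand in c("+", "-")) {
    s <- toy_gene_setup(n_exons = 3L, cds_len = 300L, utr5_len = 30L,
                        utr3_len = 60L, intron_len = 100L, strand = strand,
                        flank = 2000L)
    p <- s$partition
    pos <- seq(p$window[["start"]], p$window[["end"]])
    cls <- classify_site(p, pos)
    counts <- table(factor(cls, levels = names(p$class_lengths)))
    expect_equal(as.integer(counts), unname(p$class_lengths))
    expect_equal(sum(p$class_lengths), length(pos))
    # CDS positions are always exon, never intergenic
    cds_pos <- unlist(Map(seq, s$gene$cds$start, s$gene$cds$end))
    expect_true(all(classify_site(p, cds_pos) == "exon"))
    # UTR and intron bookkeeping
    expect_equal(unname(p$class_lengths[["utr5"]]), 30L)
    expect_equal(unname(p$class_lengths[["utr3"]]), 60L)
    expect_equal(unname(p$class_lengths[["intron"]]), 200L)
  }
})

test_that("a 7-exon gene model implies 6 introns", {
  s <- toy_gene_setup(n_exons = 7L, cds_len = 2520L, utr5_len = 0L,
                      utr3_len = 0L, intron_len = 150L)
  expect_equal(nrow(s$gene$exons), 7L)
  expect_equal(unname(s$partition$class_lengths[["intron"]]), 6L * 150L)
})

test_that("positions outside the window and bad CDS lengths are errors", {
  s <- toy_gene_setup()
  expect_error(classify_site(s$partition, s$partition$window[["end"]] + 1L),
               "outside window")
  expect_error(make_gene_template("bad", "chr1", cds_len = 10L))
  expect_error(gene_model("bad", "chr1", "+", iv(1, 10), iv(1, 10)),
               "multiple of 3")
})

test_that("GFF3 round-trip reproduces gene models on both strands", {
  for (strand in c("+", "-")) {
    s <- toy_gene_setup(strand = strand, n_exons = 2L, cds_len = 303L,
                        utr5_len = 25L, utr3_len = 40L)
    gff <- write_lines_tmp(character(), ".gff3")
    write_gff3(list(s$gene), gff)
    fa <- tempfile(fileext = ".fa")
    Biostrings::writeXStringSet(s$ref, fa)
    ann <- load_annotation(gff, fa)
    g2 <- ann$genes[[s$gene$gene_id]]
    for (f in c("gene_id", "chrom", "strand", "exons", "cds", "utr5",
                "utr3", "phase"))
      expect_equal(g2[[f]], s$gene[[f]], info = paste(strand, f))
  }
})

test_that("genes on sequences absent from the assembly are skipped with a
           message", {
  s <- toy_gene_setup()
  orphan <- make_gene_template("orphan", "scaffold_17", cds_len = 300L)
  gff <- write_lines_tmp(character(), ".gff3")
  write_gff3(list(s$gene, orphan), gff)
  fa <- tempfile(fileext = ".fa")
  Biostrings::writeXStringSet(s$ref, fa)
  expect_message(ann <- load_annotation(gff, fa), "scaffold_17")
  expect_named(ann$genes, s$gene$gene_id)
  expect_equal(ann$skipped, "orphan")
})
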