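#' Gene models, analysis windows and site classes
#'
#' A gene model holds the exon/CDS/UTR structure of one canonical transcript
#' in genomic coordinates (1-based inclusive) together with its strand.
#' Analysis windows are the gene span extended by a flank on both sides,
#' truncated where two genes sit closer than twice the flank (the intergenic
#' gap is split at its midpoint) and clamped at chromosome ends.  Every
#' window position carries exactly one site class out of
#' intergenic / exon (coding) / intron / utr5 / utr3.
#'
#' @name annotation
NULL

SITE_CLASSES <- c("intergenic", "exon", "intron", "utr5", "utr3")

#' Construct a gene model
#'
#' @param gene_id gene name.
#' @param chrom chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param exons,cds,utr5,utr3 data.frames with 1-based inclusive `start`,`end`
#'   columns, in genomic coordinates (any order; sorted internally).
#' @param phase leading CDS phase (bases to skip before the first complete
#'   codon); almost always 0 for curated annotations.
#' @return an object of class `gene_model`.
#' @export
gene_model <- function(gene_id, chrom, strand, exons, cds,
                       utr5 = iv(), utr3 = iv(), phase = 0L) {
  stopifnot(strand %in% c("+", "-"))
  exons <- iv_sort(iv(exons$start, exons$end))
  cds   <- iv_sort(iv(cds$start, cds$end))
  utr5  <- iv_sort(iv(utr5$start, utr5$end))
  utr3  <- iv_sort(iv(utr3$start, utr3$end))
  g <- structure(list(
    gene_id = gene_id, chrom = chrom, strand = strand,
    span = c(start = min(exons$start, cds$start),
             end   = max(exons$end, cds$end)),
    exons = exons, cds = cds, utr5 = utr5, utr3 = utr3,
    phase = as.integer(phase)
  ), class = "gene_model")
  validate_gene_model(g)
  g
}

validate_gene_model <- function(g) {
  if (nrow(g$exons) > 1L &&
      any(g$exons$start[-1L] <= g$exons$end[-nrow(g$exons)]))
    stop("gene ", g$gene_id, ": overlapping exons")
  outside <- function(x) iv_length(iv_subtract(x, g$exons)) > 0L
  if (outside(g$cds))  stop("gene ", g$gene_id, ": CDS outside exons")
  if (outside(g$utr5) || outside(g$utr3))
    stop("gene ", g$gene_id, ": UTR outside exons")
  if (iv_length(iv_intersect(g$utr5, g$cds)) > 0L ||
      iv_length(iv_intersect(g$utr3, g$cds)) > 0L)
    stop("gene ", g$gene_id, ": UTR overlaps CDS")
  cds_len <- iv_length(g$cds) - g$phase
  if (cds_len %% 3L != 0L)
    stop("gene ", g$gene_id, ": CDS length not a multiple of 3")
  invisible(g)
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model> %s %s:%d-%d (%s), %d exon(s), CDS %d bp\n",
              x$gene_id, x$chrom, x$span["start"], x$span["end"], x$strand,
              nrow(x$exons), iv_length(x$cds)))
  invisible(x)
}

#' Load gene annotation and reference sequence
#'
#' Reads a GFF3 file and a reference FASTA.  One canonical transcript is kept
#' per gene; when several transcripts are annotated the one with the longest
#' CDS is used and a warning is issued.  Genes on sequences absent from the
#' FASTA (unplaced contigs / isolated scaffolds) are skipped with a logged
#' reason rather than analysed.
#'
#' @param gff_path GFF3 file with gene / mRNA / exon / CDS / UTR features.
#' @param fasta_path reference FASTA; one record per chromosome.
#' @return list with `genes` (named list of [gene_model()]), `ref`
#'   (a `Biostrings::DNAStringSet`), `chrom_lengths` (named integer) and
#'   `skipped` (character, gene ids not on an assembled chromosome).
#' @export
load_annotation <- function(gff_path, fasta_path) {
  ref <- Biostrings::readDNAStringSet(fasta_path)
  names(ref) <- sub("\\s.*$", "", names(ref))
  chrom_lengths <- stats::setNames(Biostrings::width(ref), names(ref))

  gr <- rtracklayer::import(gff_path)
  feat <- data.frame(
    chrom  = as.character(GenomicRanges::seqnames(gr)),
    start  = GenomicRanges::start(gr),
    end    = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    type   = as.character(gr$type),
    id     = if (!is.null(gr$ID)) as.character(gr$ID) else NA_character_,
    parent = if (is.null(gr$Parent)) rep(NA_character_, length(gr)) else
               vapply(as.list(gr$Parent),
                      function(p) if (length(p)) as.character(p)[1]
                                  else NA_character_,
                      character(1)),
    phase  = if (!is.null(gr$phase)) as.integer(as.character(gr$phase))
             else NA_integer_,
    stringsAsFactors = FALSE
  )

  gene_rows <- feat[feat$type == "gene", , drop = FALSE]
  genes <- list(); skipped <- character()
  for (i in seq_len(nrow(gene_rows))) {
    gid <- gene_rows$id[i]
    chrom <- gene_rows$chrom[i]
    if (!chrom %in% names(ref)) {
      skipped <- c(skipped, gid)
      tasrdiv_msg("skipping gene ", gid, ": sequence '", chrom,
                  "' not in the assembly FASTA")
      next
    }
    if (gene_rows$end[i] > chrom_lengths[[chrom]])
      stop("gene ", gid, " extends beyond the end of ", chrom)
    has_parent <- !is.na(feat$parent)
    tx <- feat[feat$type %in% c("mRNA", "transcript") & has_parent &
                 feat$parent == gid, , drop = FALSE]
    parents <- if (nrow(tx) > 0L) tx$id else gid
    # pick the transcript with the longest CDS
    cds_by_tx <- lapply(parents, function(p)
      feat[feat$type == "CDS" & has_parent & feat$parent == p, , drop = FALSE])
    cds_len <- vapply(cds_by_tx, function(x) iv_length(iv(x$start, x$end)), 0L)
    if (length(parents) > 1L) {
      warning("gene ", gid, ": ", length(parents),
              " transcripts annotated; keeping the longest CDS")
    }
    sel <- which.max(cds_len)
    p <- parents[sel]
    sub <- function(ty) {
      x <- feat[feat$type == ty & has_parent & feat$parent == p, , drop = FALSE]
      iv(x$start, x$end)
    }
    exons <- sub("exon"); cds <- iv(cds_by_tx[[sel]]$start, cds_by_tx[[sel]]$end)
    if (nrow(exons) == 0L) exons <- cds
    # GFF3 phase of the transcription-first CDS segment
    cds_feat <- cds_by_tx[[sel]]
    phase <- 0L
    if (nrow(cds_feat) > 0L && !all(is.na(cds_feat$phase))) {
      first <- if (gene_rows$strand[i] == "-") which.max(cds_feat$end)
               else which.min(cds_feat$start)
      ph <- cds_feat$phase[first]
      if (!is.na(ph)) phase <- ph
    }
    genes[[gid]] <- gene_model(
      gene_id = gid, chrom = chrom, strand = gene_rows$strand[i],
      exons = exons, cds = cds,
      utr5 = sub("five_prime_UTR"), utr3 = sub("three_prime_UTR"),
      phase = phase
    )
  }
  list(genes = genes, ref = ref, chrom_lengths = chrom_lengths,
       skipped = skipped)
}

#' Write gene models as GFF3
#'
#' Inverse of [load_annotation()]: writing then re-reading reproduces the
#' same gene models.
#'
#' @param genes named list of [gene_model()].
#' @param path output file.
#' @export
write_gff3 <- function(genes, path) {
  lines <- "##gff-version 3"
  for (g in genes) {
    a <- function(type, ivs, parent, id = NULL) {
      if (nrow(ivs) == 0L) return(character())
      attr <- if (is.null(id)) paste0("Parent=", parent)
              else paste0("ID=", id, ";Parent=", parent)
      phase <- rep(".", nrow(ivs))
      if (type == "CDS") {
        phase <- rep("0", nrow(ivs))
        ord <- if (g$strand == "-") order(-ivs$end) else order(ivs$start)
        lens <- ivs$end[ord] - ivs$start[ord] + 1L
        ph <- c(g$phase, (3L - (cumsum(lens) - g$phase) %% 3L) %% 3L)
        phase[ord] <- as.character(ph[seq_len(nrow(ivs))])
      }
      sprintf("%s\ttasrdiv\t%s\t%d\t%d\t.\t%s\t%s\t%s",
              g$chrom, type, ivs$start, ivs$end, g$strand, phase, attr)
    }
    tid <- paste0(g$gene_id, ".t1")
    lines <- c(lines,
      sprintf("%s\ttasrdiv\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
              g$chrom, g$span["start"], g$span["end"], g$strand, g$gene_id),
      sprintf("%s\ttasrdiv\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
              g$chrom, g$span["start"], g$span["end"], g$strand, tid,
              g$gene_id),
      a("exon", g$exons, tid), a("CDS", g$cds, tid),
      a("five_prime_UTR", g$utr5, tid), a("three_prime_UTR", g$utr3, tid))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Build flanked analysis windows with the midpoint split rule
#'
#' Each window is the gene span extended `flank_bp` both sides and clamped
#' at chromosome ends.  When two gene spans on the same chromosome are
#' separated by a gap smaller than `2 * flank_bp`, the gap is split at its
#' midpoint between the two windows; for an odd gap the extra base goes to
#' the upstream (smaller-coordinate) gene.  Windows never overlap.
#'
#' @param genes named list of [gene_model()].
#' @param flank_bp flank length in bp (default 10000).
#' @param chrom_lengths named integer vector of chromosome lengths.
#' @return named list of `region_partition` objects (see
#'   [classify_site()]), one per gene.
#' @export
build_windows <- function(genes, flank_bp = 10000L, chrom_lengths) {
  stopifnot(flank_bp >= 0L)
  spans <- data.frame(
    gene_id = vapply(genes, `[[`, "", "gene_id"),
    chrom = vapply(genes, `[[`, "", "chrom"),
    start = vapply(genes, function(g) g$span[["start"]], 0),
    end = vapply(genes, function(g) g$span[["end"]], 0),
    stringsAsFactors = FALSE
  )
  out <- list()
  for (chrom in unique(spans$chrom)) {
    s <- spans[spans$chrom == chrom, , drop = FALSE]
    s <- s[order(s$start), , drop = FALSE]
    if (nrow(s) > 1L && any(s$start[-1L] <= s$end[-nrow(s)]))
      stop("overlapping gene spans on ", chrom)
    if (!chrom %in% names(chrom_lengths))
      stop("no chromosome length for ", chrom)
    clen <- chrom_lengths[[chrom]]
    for (i in seq_len(nrow(s))) {
      left <- s$start[i] - flank_bp
      right <- s$end[i] + flank_bp
      if (i > 1L) {
        gap <- s$start[i] - s$end[i - 1L] - 1L
        if (gap < 2L * flank_bp)
          left <- s$end[i - 1L] + ceiling(gap / 2) + 1L
      }
      if (i < nrow(s)) {
        gap <- s$start[i + 1L] - s$end[i] - 1L
        if (gap < 2L * flank_bp)
          right <- s$end[i] + ceiling(gap / 2)
      }
      window <- c(start = max(1L, as.integer(left)),
                  end = min(clen, as.integer(right)))
      out[[s$gene_id[i]]] <- region_partition(genes[[s$gene_id[i]]], window)
    }
  }
  out[spans$gene_id[spans$gene_id %in% names(out)]]
}

# Partition one window into disjoint site-class segments.
# Precedence inside the gene span: CDS/exon > UTR > intron.
region_partition <- function(gene, window) {
  win <- iv(window[["start"]], window[["end"]])
  span <- iv(gene$span[["start"]], gene$span[["end"]])
  clip <- function(x) iv_intersect(x, win)
  cds_cls  <- clip(gene$cds)
  utr5_cls <- clip(iv_subtract(gene$utr5, gene$cds))
  utr3_cls <- clip(iv_subtract(gene$utr3, gene$cds))
  # exonic bases not CDS and not UTR stay in the exon (coding-region) class
  exon_rest <- clip(iv_subtract(gene$exons,
                                rbind(gene$cds, gene$utr5, gene$utr3)))
  exon_cls <- iv_merge(rbind(cds_cls, exon_rest))
  intron_cls <- clip(iv_subtract(span, gene$exons))
  intergenic_cls <- iv_subtract(win, span)

  seg <- rbind(
    cbind(intergenic_cls, class = rep("intergenic", nrow(intergenic_cls))),
    cbind(exon_cls, class = rep("exon", nrow(exon_cls))),
    cbind(intron_cls, class = rep("intron", nrow(intron_cls))),
    cbind(utr5_cls, class = rep("utr5", nrow(utr5_cls))),
    cbind(utr3_cls, class = rep("utr3", nrow(utr3_cls)))
  )
  seg <- seg[order(seg$start), , drop = FALSE]
  rownames(seg) <- NULL
  lens <- vapply(split(seg, seg$class), iv_length, 0L)
  class_lengths <- stats::setNames(integer(length(SITE_CLASSES)), SITE_CLASSES)
  class_lengths[names(lens)] <- lens
  win_len <- iv_length(win)
  if (sum(class_lengths) != win_len)
    stop("gene ", gene$gene_id, ": partition does not tile the window (",
         sum(class_lengths), " vs ", win_len, " bp)")
  structure(list(
    gene_id = gene$gene_id, chrom = gene$chrom,
    window = c(start = win$start, end = win$end),
    gene_span = gene$span,
    segments = seg, class_lengths = class_lengths
  ), class = "region_partition")
}

#' @export
print.region_partition <- function(x, ...) {
  cat(sprintf("<region_partition> %s %s:%d-%d (%d bp)\n", x$gene_id, x$chrom,
              x$window[["start"]], x$window[["end"]],
              sum(x$class_lengths)))
  print(x$class_lengths)
  invisible(x)
}

#' Site class of positions inside a window
#'
#' @param partition a `region_partition` from [build_windows()].
#' @param pos vector of 1-based positions; all must lie inside the window.
#' @return character vector over
#'   `c("intergenic", "exon", "intron", "utr5", "utr3")`.
#' @export
classify_site <- function(partition, pos) {
  if (any(pos < partition$window[["start"]] | pos > partition$window[["end"]]))
    stop("position outside window of ", partition$gene_id)
  seg <- partition$segments
  idx <- findInterval(pos, seg$start)
  cls <- seg$class[idx]
  bad <- pos > seg$end[idx]
  if (any(bad)) stop("internal error: position not covered by any segment")
  cls
}

#' Per-gene window and class-length report
#'
#' @param partitions named list of `region_partition` objects.
#' @return data.frame, one row per gene, with 1-based window coordinates and
#'   per-class bp.
#' @export
region_report <- function(partitions) {
  do.call(rbind, lapply(partitions, function(p) {
    data.frame(gene_id = p$gene_id, chrom = p$chrom,
               window_start = p$window[["start"]],
               window_end = p$window[["end"]],
               window_bp = sum(p$class_lengths),
               t(p$class_lengths), row.names = NULL)
  }))
}
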