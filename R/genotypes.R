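#' Genotype matrices with explicit missingness
#'
#' A `genotype_matrix` stores diploid genotypes as two parallel integer
#' matrices of allele indices (0 = REF, 1.. = ALT order in the VCF), sites in
#' rows and samples in columns, with `NA` marking missing calls.  Half-called
#' genotypes are treated as fully missing.  Nothing is ever imputed.
#'
#' @name genotypes
NULL

new_genotype_matrix <- function(sites, a1, a2, samples) {
  stopifnot(nrow(sites) == nrow(a1), identical(dim(a1), dim(a2)),
            ncol(a1) == length(samples))
  rownames(a1) <- rownames(a2) <- NULL
  colnames(a1) <- colnames(a2) <- samples
  structure(list(sites = sites, a1 = a1, a2 = a2, samples = samples),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d sites x %d samples, %.1f%% missing\n",
              nrow(x$sites), length(x$samples),
              100 * mean(is.na(x$a1) | is.na(x$a2))))
  invisible(x)
}

n_sites <- function(gm) nrow(gm$sites)

geno_missing <- function(gm) is.na(gm$a1) | is.na(gm$a2)

#' Read a population panel table
#'
#' @param path TSV with columns `sample`, `population` and optionally
#'   `is_outgroup` (logical).
#' @return data.frame with those columns (`is_outgroup` filled with `FALSE`).
#' @export
read_panel <- function(path) {
  p <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("sample", "population") %in% names(p)))
  if (is.null(p$is_outgroup)) p$is_outgroup <- FALSE
  p$is_outgroup <- as.logical(p$is_outgroup)
  if (anyDuplicated(p$sample)) stop("duplicated sample ids in panel")
  p
}

#' Read a joint VCF into a genotype matrix
#'
#' SNP records (single-nucleotide REF and ALT alleles) are retained,
#' including multiallelic ones; indels and other non-SNP records are dropped
#' with a logged count.  `./.` and half-calls become missing genotypes.
#'
#' @param vcf_path VCF v4.x file (may be bgzipped).
#' @param panel optional panel data.frame ([read_panel()]); every panel
#'   sample must be present in the VCF (error listing absentees otherwise).
#' @return a `genotype_matrix`; `sites` has columns
#'   `chrom, pos, id, ref, alt` (alt comma-separated).
#' @export
read_vcf <- function(vcf_path, panel = NULL) {
  v <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = nrow(fix))

  alt_split <- strsplit(ifelse(is.na(fix$ALT), "", fix$ALT), ",", fixed = TRUE)
  is_snp <- nchar(fix$REF) == 1L & fix$REF %in% c("A", "C", "G", "T") &
    vapply(alt_split, function(a)
      length(a) >= 1L && all(nchar(a) == 1L & a %in% c("A", "C", "G", "T")),
      TRUE)
  n_drop <- sum(!is_snp)
  if (n_drop > 0L)
    tasrdiv_msg("dropped ", n_drop, " non-SNP record(s) from ",
                basename(vcf_path))
  fix <- fix[is_snp, , drop = FALSE]
  gt <- gt[is_snp, , drop = FALSE]

  sites <- data.frame(chrom = fix$CHROM, pos = as.integer(fix$POS),
                      id = fix$ID, ref = fix$REF, alt = fix$ALT,
                      stringsAsFactors = FALSE)
  a1c <- sub("[/|].*$", "", gt)
  a2c <- sub("^[^/|]*[/|]", "", gt)
  a2c[!grepl("[/|]", gt)] <- NA   # haploid/malformed entries -> missing
  a1 <- suppressWarnings(matrix(as.integer(a1c), nrow = nrow(gt)))
  a2 <- suppressWarnings(matrix(as.integer(a2c), nrow = nrow(gt)))
  half <- is.na(a1) | is.na(a2)
  a1[half] <- NA; a2[half] <- NA
  colnames(a1) <- colnames(a2) <- colnames(gt)

  if (!is.null(panel)) {
    absent <- setdiff(panel$sample, colnames(gt))
    if (length(absent))
      stop("panel sample(s) absent from VCF: ", paste(absent, collapse = ", "))
  }
  new_genotype_matrix(sites, a1, a2, colnames(gt))
}

#' Subset a genotype matrix
#'
#' @param gm a `genotype_matrix`.
#' @param sites integer or logical index over sites (default all).
#' @param samples character vector of sample ids (default all).
#' @return the subsetted `genotype_matrix`.
#' @export
subset_matrix <- function(gm, sites = NULL, samples = NULL) {
  si <- sites %||% seq_len(n_sites(gm))
  sa <- samples %||% gm$samples
  ci <- match(sa, gm$samples)
  if (anyNA(ci)) stop("unknown sample(s): ",
                      paste(sa[is.na(ci)], collapse = ", "))
  new_genotype_matrix(gm$sites[si, , drop = FALSE],
                      gm$a1[si, ci, drop = FALSE],
                      gm$a2[si, ci, drop = FALSE], sa)
}

#' Assign variant sites to gene windows
#'
#' @param gm a `genotype_matrix`.
#' @param partitions named list of `region_partition`.
#' @return character vector (one per site) of gene ids, `NA` outside all
#'   windows.
#' @export
assign_sites_to_genes <- function(gm, partitions) {
  gene <- rep(NA_character_, n_sites(gm))
  for (p in partitions) {
    hit <- gm$sites$chrom == p$chrom &
      gm$sites$pos >= p$window[["start"]] & gm$sites$pos <= p$window[["end"]]
    gene[hit] <- p$gene_id
  }
  gene
}

#' Per-site and per-gene missing rates
#'
#' Per-position missing rate is the fraction of non-callable genotypes over
#' all samples.  The per-gene rate averages over the gene's variant
#' positions; when a per-sample callability mask is supplied it averages
#' over *all* window positions, with invariant positions taken from the
#' mask.
#'
#' @param gm a `genotype_matrix`.
#' @param partitions named list of `region_partition` (defines the genes).
#' @param mask optional callability mask: named list (by sample) of
#'   data.frames `chrom,start,end` of *callable* 1-based intervals.
#' @return list with `per_site` (data.frame chrom,pos,missing) and
#'   `per_gene` (data.frame gene_id,missing).
#' @export
missing_rates <- function(gm, partitions, mask = NULL) {
  miss <- geno_missing(gm)
  per_site <- data.frame(chrom = gm$sites$chrom, pos = gm$sites$pos,
                         missing = rowMeans(miss))
  gene_of <- assign_sites_to_genes(gm, partitions)
  n_samp <- length(gm$samples)
  per_gene <- vapply(partitions, function(p) {
    in_gene <- which(gene_of == p$gene_id)
    if (is.null(mask)) {
      if (length(in_gene) == 0L) return(NA_real_)
      return(mean(per_site$missing[in_gene]))
    }
    win_len <- sum(p$class_lengths)
    var_pos <- gm$sites$pos[in_gene]
    # mask-based missing genotype-positions over the whole window,
    # replacing the mask's answer at variant positions by observed calls
    total_missing <- 0
    for (s in gm$samples) {
      m <- mask[[s]]
      if (is.null(m)) { callable <- iv() } else {
        m <- m[m$chrom == p$chrom, , drop = FALSE]
        callable <- iv_intersect(iv(m$start, m$end),
                                 iv(p$window[["start"]], p$window[["end"]]))
      }
      miss_bp <- win_len - iv_length(callable)
      # variant positions are scored from observed genotypes, not the mask
      if (length(var_pos))
        miss_bp <- miss_bp - sum(!iv_contains(callable, var_pos))
      total_missing <- total_missing + miss_bp
    }
    # observed missingness at variant positions
    if (length(in_gene))
      total_missing <- total_missing + sum(miss[in_gene, , drop = FALSE])
    total_missing / (n_samp * win_len)
  }, 0)
  list(per_site = per_site,
       per_gene = data.frame(gene_id = names(partitions),
                             missing = unname(per_gene),
                             row.names = NULL))
}

#' Exclude genes whose missing rate reaches a threshold
#'
#' @param qc result of [missing_rates()].
#' @param threshold exclusion threshold on the per-gene missing fraction
#'   (genes with rate `>= threshold` are excluded; default 0.5).
#' @return character vector of excluded gene ids.
#' @export
filter_genes_by_missing <- function(qc, threshold = 0.5) {
  excl <- qc$per_gene$gene_id[!is.na(qc$per_gene$missing) &
                                qc$per_gene$missing >= threshold]
  if (length(excl))
    tasrdiv_msg("excluding ", length(excl), " gene(s) with missing rate >= ",
                threshold, ": ", paste(excl, collapse = ", "))
  excl
}

# per-site allele counts over a set of samples: matrix sites x alleles
# (columns = allele index 0..max); counts over called alleles only
allele_count_matrix <- function(gm, sample_idx = NULL) {
  ci <- sample_idx %||% seq_along(gm$samples)
  a1 <- gm$a1[, ci, drop = FALSE]; a2 <- gm$a2[, ci, drop = FALSE]
  max_allele <- max(0L, a1, a2, na.rm = TRUE)
  cnt <- matrix(0L, nrow = n_sites(gm), ncol = max_allele + 1L)
  for (v in 0:max_allele)
    cnt[, v + 1L] <- rowSums(a1 == v, na.rm = TRUE) +
      rowSums(a2 == v, na.rm = TRUE)
  colnames(cnt) <- as.character(0:max_allele)
  cnt
}

#' Global and per-population allele frequencies
#'
#' Frequencies are computed over called alleles only.  A stratum with zero
#' called alleles at a site yields `NA`, never zero.
#'
#' @param gm a `genotype_matrix`.
#' @param panel optional panel data.frame; when given, per-population
#'   frequencies are added (outgroup samples keep their population label).
#' @return list with `freq` (long data.frame: chrom, pos, allele index,
#'   allele base, stratum, count, freq) and `maf` (data.frame chrom, pos,
#'   maf over the global stratum).
#' @export
allele_frequencies <- function(gm, panel = NULL) {
  strata <- list(global = seq_along(gm$samples))
  if (!is.null(panel)) {
    for (pop in unique(panel$population))
      strata[[pop]] <- match(panel$sample[panel$population == pop],
                             gm$samples)
  }
  alt_split <- strsplit(gm$sites$alt, ",", fixed = TRUE)
  base_of <- function(site, allele)
    if (allele == 0L) gm$sites$ref[site] else alt_split[[site]][allele]
  out <- list(); maf <- NULL
  for (nm in names(strata)) {
    cnt <- allele_count_matrix(gm, strata[[nm]])
    n <- rowSums(cnt)
    for (v in seq_len(ncol(cnt)) - 1L) {
      keep <- if (v == 0L) rep(TRUE, n_sites(gm))
              else vapply(alt_split, length, 0L) >= v
      f <- ifelse(n > 0, cnt[, v + 1L] / n, NA_real_)
      out[[length(out) + 1L]] <- data.frame(
        chrom = gm$sites$chrom[keep], pos = gm$sites$pos[keep],
        allele = v,
        base = vapply(which(keep), base_of, "", allele = v),
        stratum = nm, count = cnt[keep, v + 1L], freq = f[keep],
        stringsAsFactors = FALSE)
    }
    if (nm == "global") {
      fmat <- cnt / ifelse(n > 0, n, NA_real_)
      maf <- data.frame(chrom = gm$sites$chrom, pos = gm$sites$pos,
                        maf = 1 - apply(fmat, 1, max))
    }
  }
  list(freq = do.call(rbind, out), maf = maf)
}

#' Transition/transversion ratio
#'
#' Each REF/ALT allele pair counts once; transitions are A<->G and C<->T.
#'
#' @param gm a `genotype_matrix` with at least one SNP.
#' @return ti/tv ratio; `NA` (undefined) when there are no transversions.
#' @export
titv_ratio <- function(gm) {
  if (n_sites(gm) == 0L) stop("empty genotype matrix")
  purines <- c("A", "G")
  ti <- 0L; tv <- 0L
  alt_split <- strsplit(gm$sites$alt, ",", fixed = TRUE)
  for (i in seq_len(n_sites(gm))) {
    for (alt in alt_split[[i]]) {
      if ((gm$sites$ref[i] %in% purines) == (alt %in% purines))
        ti <- ti + 1L else tv <- tv + 1L
    }
  }
  if (tv == 0L) {
    warning("no transversions; ti/tv undefined")
    return(NA_real_)
  }
  ti / tv
}
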