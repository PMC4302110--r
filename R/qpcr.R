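#' Efficiency-corrected relative qPCR quantification
#'
#' Pfaffl-style normalization with one or more reference genes and a
#' calibrator gene.  Per sample and gene the relative quantity is
#' `Q(s,g) = E_g^(Ct0 - Ct[s,g])` (the anchoring constant `Ct0` cancels),
#' normalized by the geometric mean of the reference-gene quantities of the
#' same sample, and finally expressed as a fold change relative to the mean
#' normalized quantity of the calibrator gene across its replicates, so the
#' calibrator's mean fold change is exactly 1.
#'
#' @name qpcr
NULL

#' Construct a qPCR plate
#'
#' @param ct data.frame with columns `sample, gene, ct` (threshold cycles);
#'   one row per assay (technical means).
#' @param efficiency named numeric: amplification factor per cycle per gene,
#'   in (1, 2.2].
#' @param reference_genes character vector of reference gene names.
#' @param calibrator calibrator gene name.
#' @return object of class `qpcr_plate`.
#' @export
qpcr_plate <- function(ct, efficiency, reference_genes, calibrator) {
  stopifnot(all(c("sample", "gene", "ct") %in% names(ct)))
  genes <- unique(ct$gene)
  missing_e <- setdiff(genes, names(efficiency))
  if (length(missing_e))
    stop("no efficiency for gene(s): ", paste(missing_e, collapse = ", "))
  if (any(efficiency <= 1)) stop("efficiency must be > 1")
  if (any(efficiency > 2.2)) stop("efficiency above sanity bound 2.2")
  if (!calibrator %in% genes) stop("calibrator gene not on the plate")
  if (!all(reference_genes %in% genes))
    stop("reference gene(s) not on the plate")
  structure(list(ct = ct, efficiency = efficiency,
                 reference_genes = reference_genes, calibrator = calibrator),
            class = "qpcr_plate")
}

#' Pfaffl normalization
#'
#' Samples missing a reference-gene Ct are excluded with a warning.
#'
#' @param plate a [qpcr_plate()].
#' @return list of class `rel_expression`: `fold` (data.frame sample, gene,
#'   fold_change) and `summary` (per-gene mean and SEM over biological
#'   replicates of the normalized fold changes).
#' @export
pfaffl_normalize <- function(plate) {
  ct <- plate$ct
  eff <- plate$efficiency
  refs <- plate$reference_genes
  # log-space relative quantity: log Q = -Ct * log E  (anchor cancels)
  ct$logq <- -ct$ct * log(eff[ct$gene])

  samples <- unique(ct$sample)
  ref_ok <- vapply(samples, function(s)
    all(refs %in% ct$gene[ct$sample == s & !is.na(ct$ct)]), TRUE)
  if (any(!ref_ok)) {
    warning("excluding sample(s) without all reference Cts: ",
            paste(samples[!ref_ok], collapse = ", "))
    ct <- ct[ct$sample %in% samples[ref_ok], , drop = FALSE]
  }
  # per-sample geometric-mean reference factor (log scale)
  ref_log <- vapply(unique(ct$sample), function(s)
    mean(ct$logq[ct$sample == s & ct$gene %in% refs]), 0)
  names(ref_log) <- unique(ct$sample)
  ct$log_norm <- ct$logq - ref_log[ct$sample]

  cal <- ct$log_norm[ct$gene == plate$calibrator & !is.na(ct$ct)]
  if (length(cal) == 0L) stop("calibrator gene has no measured Ct")
  cal_mean <- mean(exp(cal))
  fold <- data.frame(sample = ct$sample, gene = ct$gene,
                     fold_change = exp(ct$log_norm) / cal_mean,
                     stringsAsFactors = FALSE)
  fold <- fold[!is.na(fold$fold_change), , drop = FALSE]
  summ <- do.call(rbind, lapply(split(fold, fold$gene), function(x)
    data.frame(gene = x$gene[1], n = nrow(x), mean = mean(x$fold_change),
               sem = stats::sd(x$fold_change) / sqrt(nrow(x)))))
  rownames(summ) <- NULL
  structure(list(fold = fold, summary = summ), class = "rel_expression")
}

#' @export
print.rel_expression <- function(x, ...) {
  cat("<rel_expression> fold changes relative to the calibrator mean\n")
  print(x$summary)
  invisible(x)
}
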