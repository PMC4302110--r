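#' Codon-level consequences and synonymous/non-synonymous site counts
#'
#' Coding SNPs are classified by rebuilding the reference codon from the
#' reference sequence (honoring strand and CDS phase), substituting each ALT
#' allele singly, and comparing the encoded amino acids under the standard
#' genetic code.  Site counts follow the Nei-Gojobori convention: each codon
#' position contributes (number of synonymous single-base changes)/3 to S
#' and the remainder to N; changes creating a stop count as non-synonymous;
#' the terminal stop codon is excluded.
#'
#' @name consequence
NULL

CONSEQUENCE_LEVELS <- c("synonymous", "nonsynonymous", "stop_gained",
                        "stop_lost", "intron", "intergenic", "utr5", "utr3")

BASES <- c("A", "C", "G", "T")

codon_aa <- function(codon) unname(Biostrings::GENETIC_CODE[codon])

revcomp <- function(x) as.character(Biostrings::reverseComplement(
  Biostrings::DNAStringSet(x)))

# CDS segments in transcription order
cds_segments_tx <- function(gene) {
  cds <- gene$cds
  if (gene$strand == "-") cds <- cds[order(-cds$end), , drop = FALSE]
  cds
}

# Extract spliced CDS sequence (coding strand), phase-trimmed
cds_sequence <- function(gene, ref) {
  chrom_seq <- ref[[gene$chrom]]
  segs <- cds_segments_tx(gene)
  pieces <- vapply(seq_len(nrow(segs)), function(i) {
    s <- as.character(Biostrings::subseq(chrom_seq, segs$start[i],
                                         segs$end[i]))
    if (gene$strand == "-") revcomp(s) else s
  }, "")
  seq <- paste(pieces, collapse = "")
  if (gene$phase > 0L) seq <- substring(seq, gene$phase + 1L)
  seq
}

# genomic position -> 1-based position within the (phase-trimmed) CDS,
# NA when outside the CDS (or inside the phase-trimmed leader)
cds_position <- function(gene, pos) {
  segs <- cds_segments_tx(gene)
  offset <- 0L
  for (i in seq_len(nrow(segs))) {
    s <- segs$start[i]; e <- segs$end[i]
    if (pos >= s && pos <= e) {
      within <- if (gene$strand == "-") e - pos + 1L else pos - s + 1L
      p <- offset + within - gene$phase
      return(if (p >= 1L) p else NA_integer_)
    }
    offset <- offset + (e - s + 1L)
  }
  NA_integer_
}

#' Classify one SNP by codon-level consequence
#'
#' Non-CDS sites take their class from the region partition.  For CDS sites
#' the codon is rebuilt from the reference, each ALT substituted singly
#' (other segregating positions held at reference), and the amino acids
#' compared.  With several ALT alleles the most severe label is returned
#' (stop_gained > stop_lost > nonsynonymous > synonymous).
#'
#' @param gene a [gene_model()].
#' @param partition the gene's `region_partition`.
#' @param ref `DNAStringSet` reference.
#' @param pos 1-based genomic position of the SNP.
#' @param ref_allele,alt_alleles REF base and character vector of ALT bases
#'   (as in the VCF, forward strand).
#' @return one of `synonymous, nonsynonymous, stop_gained, stop_lost,
#'   intron, intergenic, utr5, utr3`.
#' @export
annotate_variant <- function(gene, partition, ref, pos, ref_allele,
                             alt_alleles) {
  cls <- classify_site(partition, pos)
  cpos <- if (cls == "exon") cds_position(gene, pos) else NA_integer_
  if (is.na(cpos)) return(cls)

  genome_base <- as.character(Biostrings::subseq(ref[[gene$chrom]], pos, pos))
  if (genome_base != ref_allele)
    stop("reference mismatch at ", gene$chrom, ":", pos, " (FASTA ",
         genome_base, ", VCF ", ref_allele, ")")

  cds <- cds_sequence(gene, ref)
  codon_idx <- (cpos - 1L) %/% 3L + 1L
  within <- (cpos - 1L) %% 3L + 1L
  codon <- substring(cds, 3L * codon_idx - 2L, 3L * codon_idx)
  if (nchar(codon) < 3L) return(cls)   # trailing partial codon: no call
  aa_ref <- codon_aa(codon)

  labels <- vapply(alt_alleles, function(alt) {
    alt_cs <- if (gene$strand == "-") revcomp(alt) else alt
    mutant <- codon
    substring(mutant, within, within) <- alt_cs
    aa_alt <- codon_aa(mutant)
    if (aa_ref == aa_alt) "synonymous"
    else if (aa_alt == "*") "stop_gained"
    else if (aa_ref == "*") "stop_lost"
    else "nonsynonymous"
  }, "")
  severity <- c(stop_gained = 4, stop_lost = 3, nonsynonymous = 2,
                synonymous = 1)
  unname(labels[which.max(severity[labels])])
}

#' Classify every CDS-overlapping SNP of a matrix
#'
#' @param gm a `genotype_matrix`.
#' @param genes named list of [gene_model()].
#' @param partitions matching named list of `region_partition`.
#' @param ref `DNAStringSet` reference.
#' @return data.frame `chrom, pos, gene_id, ref, alt, site_class,
#'   consequence` with one row per site inside a window (`consequence` equals
#'   the site class for non-coding sites).
#' @export
annotate_matrix <- function(gm, genes, partitions, ref) {
  gene_of <- assign_sites_to_genes(gm, partitions)
  rows <- which(!is.na(gene_of))
  res <- lapply(rows, function(i) {
    gid <- gene_of[i]
    alt <- strsplit(gm$sites$alt[i], ",", fixed = TRUE)[[1]]
    cls <- classify_site(partitions[[gid]], gm$sites$pos[i])
    cons <- annotate_variant(genes[[gid]], partitions[[gid]], ref,
                             gm$sites$pos[i], gm$sites$ref[i], alt)
    data.frame(chrom = gm$sites$chrom[i], pos = gm$sites$pos[i],
               gene_id = gid, ref = gm$sites$ref[i],
               alt = gm$sites$alt[i], site_class = cls,
               consequence = cons, site_index = i,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

# (S, N) contribution of a single codon, Nei-Gojobori style
codon_site_counts <- function(codon) {
  aa <- codon_aa(codon)
  syn <- 0
  for (p in 1:3) for (b in BASES) {
    if (b == substring(codon, p, p)) next
    mutant <- codon
    substring(mutant, p, p) <- b
    if (codon_aa(mutant) == aa && aa != "*") syn <- syn + 1
  }
  s <- syn / 3
  c(S = s, N = 3 - s)
}

#' Synonymous and non-synonymous site counts for a gene
#'
#' @param gene a [gene_model()].
#' @param ref `DNAStringSet` reference.
#' @return named numeric `c(S=, N=)`; `S + N` equals the CDS length used
#'   (terminal stop codon excluded).  An internal stop codon in the
#'   reference is an error naming the codon index.
#' @export
count_syn_nonsyn_sites <- function(gene, ref) {
  cds <- cds_sequence(gene, ref)
  n_codon <- nchar(cds) %/% 3L
  codons <- substring(cds, 3L * seq_len(n_codon) - 2L, 3L * seq_len(n_codon))
  aas <- vapply(codons, codon_aa, "")
  if (n_codon > 1L && any(aas[-n_codon] == "*"))
    stop("gene ", gene$gene_id, ": internal stop at codon ",
         which(aas[-n_codon] == "*")[1])
  if (aas[n_codon] == "*") codons <- codons[-n_codon]
  counts <- vapply(codons, codon_site_counts, c(S = 0, N = 0))
  c(S = sum(counts["S", ]), N = sum(counts["N", ]))
}
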