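#!/usr/bin/env Rscript

# Exploratory structure on the simulated study: genotype PCA on all SNPs,
# on the bitter-gene subset and on non-synonymous bitter SNPs, plus a
# neighbor-joining tree from allele-sharing distances.  Island-model demes
# should separate along the leading components.

suppressPackageStartupMessages(library(tasrdiv))

ann <- load_annotation("results/study/annotation.gff3",
                       "results/study/reference.fa")
panel <- read_panel("results/study/panel.tsv")
gm <- read_vcf("results/study/variants.vcf", panel)
parts <- build_windows(ann$genes, 10000L, ann$chrom_lengths)
ingroup <- subset_matrix(gm, samples = panel$sample[!panel$is_outgroup])
gene_of <- assign_sites_to_genes(ingroup, parts)
cons <- annotate_matrix(ingroup, ann$genes, parts, ann$ref)

subsets <- list(
  all = which(!is.na(gene_of)),
  bitter = which(grepl("^bitter", gene_of)),
  nonsyn_bitter = cons$site_index[grepl("^bitter", cons$gene_id) &
                                    cons$consequence %in%
                                      c("nonsynonymous", "stop_gained",
                                        "stop_lost")])

for (nm in names(subsets)) {
  idx <- subsets[[nm]]
  if (length(idx) < 2) { cat("subset", nm, "too small, skipped\n"); next }
  pc <- genotype_pca(ingroup, sites = idx)
  coords <- data.frame(sample = rownames(pc$coordinates),
                       population = panel$population[
                         match(rownames(pc$coordinates), panel$sample)],
                       pc$coordinates[, 1:4])
  write.table(coords, sprintf("results/pca_%s.tsv", nm), sep = "\t",
              quote = FALSE, row.names = FALSE)
  cat(sprintf("PCA[%s]: %d SNPs, PC1 %.2f%%, PC2 %.2f%% of variance\n", nm,
              length(idx), 100 * pc$variance_fraction[1],
              100 * pc$variance_fraction[2]))
}

d <- allele_sharing_distance(ingroup)
tr <- neighbor_joining(d)
ape::write.tree(tr, "results/nj_tree.nwk")
cat("wrote results/pca_*.tsv and results/nj_tree.nwk\n")
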