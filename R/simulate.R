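#' Neutral coalescent simulation with infinite-sites mutations
#'
#' Time is measured in units of 2N generations; `theta = 4*N*mu*L` is the
#' population-scaled mutation rate of the whole locus.  Genealogies follow
#' the standard coalescent with optional structure: a clean split (all demes
#' merge at time `tau`), a symmetric island model (per-lineage migration
#' rate `mig`), and an optional deeply diverged outgroup deme.
#' Recombination is approximated by simulating `fragments` independent
#' coalescent fragments of equal length.  Mutations are Poisson on total
#' branch length at rate `theta/2` per fragment share, placed uniformly at
#' distinct positions (collisions redrawn), with the derived allele drawn
#' from the three alternatives to the reference base (optionally
#' transition-biased).  Haplotypes are paired into diploids in order.
#'
#' @name synthetic_data
NULL

#' Simulation configuration
#'
#' @param n_per_deme integer vector of diploid counts per deme (ignored if
#'   `n_haplotypes` given).
#' @param n_haplotypes total haploid sample size for a single panmictic deme
#'   (used with `diploid = FALSE`, e.g. CI replicates).
#' @param theta population-scaled mutation rate for the whole locus.
#' @param L locus length in bp.
#' @param demography list: `type` in `c("panmictic", "split", "island")`,
#'   with `tau` (split time, 2N units) for `"split"`, `mig` (per-lineage
#'   migration rate) for `"island"`, and optional `outgroup_deme` +
#'   `outgroup_tau` for a non-migrating deme that joins deme 1 at
#'   `outgroup_tau`.
#' @param fragments independent-fragment count (recombination stand-in,
#'   default 11).
#' @param missing_rate genotype missingness to inject in `[0, 1)`.
#' @param kappa transition/transversion bias of the derived-allele draw
#'   (`NULL` = uniform over the 3 alternatives; `kappa/2` is the expected
#'   ti/tv ratio, so 4.7 emulates ti/tv = 2.35).
#' @param diploid pair haplotypes into diploid genotypes (default TRUE).
#' @param seed RNG seed.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_per_deme = NULL, n_haplotypes = NULL, theta = 10,
                       L = 1000L,
                       demography = list(type = "panmictic"),
                       fragments = 11L, missing_rate = 0,
                       kappa = NULL, diploid = TRUE, seed = NULL) {
  if (is.null(n_per_deme) && is.null(n_haplotypes))
    stop("give n_per_deme or n_haplotypes")
  n_hap_per_deme <- if (!is.null(n_haplotypes)) as.integer(n_haplotypes)
                    else 2L * as.integer(n_per_deme)
  stopifnot(theta > 0, missing_rate >= 0, missing_rate < 1, fragments >= 1)
  structure(list(n_hap_per_deme = n_hap_per_deme,
                 n_per_deme = n_per_deme, theta = theta, L = as.integer(L),
                 demography = demography, fragments = as.integer(fragments),
                 missing_rate = missing_rate, kappa = kappa,
                 diploid = diploid, seed = seed),
            class = "sim_config")
}

# one genealogy for structured samples; returns per-branch lengths and leaf
# sets, TMRCA and total branch length
simulate_genealogy <- function(n_hap_per_deme, demography) {
  type <- demography$type %||% "panmictic"
  n_demes <- length(n_hap_per_deme)
  if (type == "panmictic" || n_demes == 1L)
    return(simulate_genealogy_panmictic(sum(n_hap_per_deme)))
  deme <- rep(seq_len(n_demes), n_hap_per_deme)
  n <- length(deme)
  leaves <- as.list(seq_len(n))
  birth <- numeric(n)
  mig <- demography$mig %||% 0
  tau <- demography$tau %||% Inf
  og <- demography$outgroup_deme %||% 0L
  og_tau <- demography$outgroup_tau %||% Inf
  merged <- og_merged <- FALSE
  br_len <- numeric(0); br_leaves <- list()
  t <- 0
  while (length(leaves) > 1L) {
    kd <- tabulate(deme, nbins = n_demes)
    coal <- kd * (kd - 1) / 2
    can_migrate <- deme != og & type == "island" & n_demes > 1L
    m_rate <- mig * sum(can_migrate)
    R <- sum(coal) + m_rate
    t_ev <- if (R > 0) t + stats::rexp(1, R) else Inf
    if (type == "split" && !merged && t_ev >= tau) {
      t <- tau; deme[] <- 1L; merged <- TRUE; next
    }
    if (og > 0L && !og_merged && t_ev >= og_tau) {
      t <- og_tau; deme[deme == og] <- 1L; og_merged <- TRUE; next
    }
    if (!is.finite(t_ev)) stop("genealogy cannot coalesce: isolated demes")
    t <- t_ev
    if (stats::runif(1) < sum(coal) / R) {
      d <- sample.int(n_demes, 1L, prob = coal)
      members <- which(deme == d)
      pair <- members[sample.int(length(members), 2L)]
      for (x in pair) {
        br_len <- c(br_len, t - birth[x])
        br_leaves <- c(br_leaves, leaves[x])
      }
      leaves[[pair[1]]] <- c(leaves[[pair[1]]], leaves[[pair[2]]])
      birth[pair[1]] <- t
      leaves <- leaves[-pair[2]]; birth <- birth[-pair[2]]
      deme <- deme[-pair[2]]
    } else {
      mig_idx <- which(can_migrate)
      x <- mig_idx[sample.int(length(mig_idx), 1L)]
      others <- setdiff(seq_len(n_demes), c(og, deme[x]))
      if (length(others)) deme[x] <- others[sample.int(length(others), 1L)]
    }
  }
  list(branch_length = br_len, branch_leaves = br_leaves, tmrca = t,
       total_branch_length = sum(br_len))
}

# single-deme Kingman coalescent, vectorized waiting times
simulate_genealogy_panmictic <- function(n) {
  if (n < 2L) stop("need at least two lineages")
  waits <- stats::rexp(n - 1L, rate = choose(seq.int(n, 2L), 2))
  times <- cumsum(waits)
  cluster <- seq_len(n)          # cluster id per leaf
  active <- seq_len(n)           # active cluster ids
  birth <- numeric(2L * n - 1L)  # birth time per cluster id
  br_len <- numeric(2L * (n - 1L))
  br_leaves <- vector("list", 2L * (n - 1L))
  nb <- 0L
  for (j in seq_len(n - 1L)) {
    pair <- sample.int(length(active), 2L)
    a <- active[pair[1L]]; b <- active[pair[2L]]
    new_id <- n + j
    for (x in c(a, b)) {
      nb <- nb + 1L
      br_len[nb] <- times[j] - birth[x]
      br_leaves[[nb]] <- which(cluster == x)
    }
    cluster[cluster == a | cluster == b] <- new_id
    birth[new_id] <- times[j]
    active <- c(active[-pair], new_id)
  }
  list(branch_length = br_len, branch_leaves = br_leaves,
       tmrca = times[n - 1L], total_branch_length = sum(br_len))
}

#' Simulate one locus
#'
#' @param config a [sim_config()].
#' @return list: `haplotypes` (0/1 derived-allele matrix, haplotypes x
#'   sites, columns ordered by position), `positions` (1-based within the
#'   locus), and `truth` (per-fragment TMRCA and total branch length,
#'   segregating-site count).  Deterministic given (config, seed).
#' @export
simulate_locus <- function(config) {
  with_seed(config$seed, {
    n_hap <- sum(config$n_hap_per_deme)
    frag <- config$fragments
    bounds <- floor(seq(0, config$L, length.out = frag + 1L))
    theta_f <- config$theta * diff(bounds) / config$L
    used <- integer(0)
    pos_all <- integer(0)
    cols <- list()
    tmrca <- tbl <- numeric(frag)
    for (f in seq_len(frag)) {
      g <- simulate_genealogy(config$n_hap_per_deme, config$demography)
      tmrca[f] <- g$tmrca; tbl[f] <- g$total_branch_length
      n_mut <- stats::rpois(1, g$total_branch_length * theta_f[f] / 2)
      if (n_mut == 0L || bounds[f + 1L] <= bounds[f]) next
      flen <- bounds[f + 1L] - bounds[f]
      if (n_mut > flen - sum(used > bounds[f] & used <= bounds[f + 1L]))
        stop("theta too large for L: fragment saturated")
      # distinct positions; collisions redrawn (infinite-sites convention)
      pos <- integer(0)
      while (length(pos) < n_mut) {
        cand <- bounds[f] + sample.int(flen, n_mut - length(pos))
        cand <- setdiff(unique(cand), c(used, pos))
        pos <- c(pos, cand)
      }
      pos <- sort(pos)
      used <- c(used, pos)
      br <- sample.int(length(g$branch_length), n_mut, replace = TRUE,
                       prob = g$branch_length)
      for (k in seq_len(n_mut)) {
        col <- integer(n_hap)
        col[g$branch_leaves[[br[k]]]] <- 1L
        cols[[length(cols) + 1L]] <- col
        pos_all <- c(pos_all, pos[k])
      }
    }
    ord <- order(pos_all)
    hap <- if (length(cols)) do.call(cbind, cols)[, ord, drop = FALSE]
           else matrix(0L, nrow = n_hap, ncol = 0L)
    list(haplotypes = hap, positions = pos_all[ord],
         truth = list(tmrca = tmrca, total_branch_length = tbl,
                      S = length(pos_all)))
  })
}

# derived-allele bases given reference bases; transition-biased if kappa
draw_alt_alleles <- function(ref_bases, kappa = NULL) {
  transition <- c(A = "G", G = "A", C = "T", T = "C")
  vapply(ref_bases, function(b) {
    alts <- setdiff(BASES, b)
    if (is.null(kappa)) return(sample(alts, 1L))
    w <- ifelse(alts == transition[[b]], kappa, 1)
    sample(alts, 1L, prob = w)
  }, "")
}

#' Pair haplotypes into a diploid genotype matrix
#'
#' Adjacent haplotypes (1,2), (3,4), ... form diploids, the standard
#' convention.
#'
#' @param hap 0/1 haplotype matrix from [simulate_locus()].
#' @param positions 1-based positions within the locus.
#' @param chrom,offset chromosome name and window start (genomic position =
#'   `offset + position - 1`).
#' @param ref_bases reference base per site.
#' @param alt_bases derived base per site.
#' @param samples sample names (length = rows/2).
#' @return a `genotype_matrix`.
#' @export
haplotypes_to_matrix <- function(hap, positions, chrom, offset, ref_bases,
                                 alt_bases, samples) {
  stopifnot(nrow(hap) %% 2L == 0L, length(samples) == nrow(hap) / 2L)
  odd <- seq(1L, nrow(hap), by = 2L)
  a1 <- t(hap[odd, , drop = FALSE])
  a2 <- t(hap[odd + 1L, , drop = FALSE])
  sites <- data.frame(chrom = chrom, pos = as.integer(offset + positions - 1L),
                      id = ".", ref = ref_bases, alt = alt_bases,
                      stringsAsFactors = FALSE)
  new_genotype_matrix(sites, a1, a2, samples)
}

#' Inject genotype missingness
#'
#' Each diploid genotype goes missing independently with probability `m`.
#'
#' @param gm a `genotype_matrix`.
#' @param m missing rate in `[0, 1)`.
#' @param seed RNG seed (same seed, same pattern).
#' @return the `genotype_matrix` with missing entries.
#' @export
inject_missingness <- function(gm, m, seed = NULL) {
  stopifnot(m >= 0, m < 1)
  if (m == 0) return(gm)
  with_seed(seed, {
    drop <- matrix(stats::runif(length(gm$a1)) < m, nrow = nrow(gm$a1))
    gm$a1[drop] <- NA; gm$a2[drop] <- NA
    gm
  })
}

#' Gene template for simulated loci
#'
#' Builds a [gene_model()] with `n_exons` exons whose CDS totals `cds_len`
#' bp (a multiple of 3, terminal stop included), optional UTRs on the first
#' and last exon, and fixed intron lengths.
#'
#' @param gene_id,chrom,strand identifiers.
#' @param gene_start genomic start of the gene span.
#' @param n_exons exon count.
#' @param cds_len total CDS length in bp (multiple of 3).
#' @param utr5_len,utr3_len UTR lengths (0 for none).
#' @param intron_len length of each intron.
#' @return a [gene_model()].
#' @export
make_gene_template <- function(gene_id, chrom, gene_start = 15001L,
                               strand = "+", n_exons = 1L, cds_len = 903L,
                               utr5_len = 0L, utr3_len = 0L,
                               intron_len = 800L) {
  stopifnot(cds_len %% 3L == 0L, n_exons >= 1L)
  per <- cds_len %/% n_exons
  cds_parts <- rep(per, n_exons)
  cds_parts[n_exons] <- cds_len - per * (n_exons - 1L)
  # exon i carries cds_parts[i] coding bases; UTRs sit on terminal exons
  exon_lens <- cds_parts
  exon_lens[1L] <- exon_lens[1L] + utr5_len
  exon_lens[n_exons] <- exon_lens[n_exons] + utr3_len
  starts <- integer(n_exons); ends <- integer(n_exons)
  pos <- gene_start
  for (i in seq_len(n_exons)) {
    starts[i] <- pos; ends[i] <- pos + exon_lens[i] - 1L
    pos <- ends[i] + intron_len + 1L
  }
  exons <- iv(starts, ends)
  left_utr <- if (strand == "+") utr5_len else utr3_len
  right_utr <- if (strand == "+") utr3_len else utr5_len
  # left UTR occupies the head of exon 1, right UTR the tail of the last
  cds_starts <- starts; cds_ends <- ends
  cds_starts[1L] <- starts[1L] + (if (strand == "+") utr5_len else utr3_len)
  cds_ends[n_exons] <- ends[n_exons] -
    (if (strand == "+") utr3_len else utr5_len)
  cds <- iv(cds_starts, cds_ends)
  u5 <- iv(); u3 <- iv()
  if (utr5_len > 0L) {
    u5 <- if (strand == "+") iv(starts[1L], starts[1L] + utr5_len - 1L)
          else iv(ends[n_exons] - utr5_len + 1L, ends[n_exons])
  }
  if (utr3_len > 0L) {
    u3 <- if (strand == "+") iv(ends[n_exons] - utr3_len + 1L, ends[n_exons])
          else iv(starts[1L], starts[1L] + utr3_len - 1L)
  }
  gene_model(gene_id, chrom, strand, exons, cds, u5, u3)
}

#' Random reference with an open reading frame under each gene
#'
#' Draws random background sequence and overwrites every CDS with sense
#' codons followed by a terminal stop, honoring strand, so gene templates
#' translate cleanly.
#'
#' @param genes named list of [gene_model()].
#' @param chrom_lengths named integer vector.
#' @param seed RNG seed.
#' @return a `Biostrings::DNAStringSet`.
#' @export
make_reference <- function(genes, chrom_lengths, seed = NULL) {
  with_seed(seed, {
    seqs <- lapply(chrom_lengths, function(len)
      paste(sample(BASES, len, replace = TRUE), collapse = ""))
    sense <- setdiff(names(Biostrings::GENETIC_CODE),
                     c("TAA", "TAG", "TGA"))
    for (g in genes) {
      n_codon <- iv_length(g$cds) %/% 3L
      orf <- paste(c("ATG", sample(sense, n_codon - 2L, replace = TRUE),
                     "TAA"), collapse = "")
      if (g$strand == "-") orf <- revcomp(orf)
      # write the ORF across CDS segments in genomic order
      segs <- iv_sort(g$cds)
      off <- 0L
      s <- seqs[[g$chrom]]
      for (i in seq_len(nrow(segs))) {
        len <- segs$end[i] - segs$start[i] + 1L
        substring(s, segs$start[i], segs$end[i]) <-
          substring(orf, off + 1L, off + len)
        off <- off + len
      }
      seqs[[g$chrom]] <- s
    }
    Biostrings::DNAStringSet(unlist(seqs))
  })
}

#' Simulate genotypes for one annotated gene window
#'
#' Runs [simulate_locus()] over the gene's window, maps mutations to genomic
#' coordinates and reference/derived bases, pairs diploids, injects
#' missingness, and records the generating truth (site classes,
#' codon-level consequences, true per-class diversity before missingness).
#'
#' @param gene a [gene_model()].
#' @param partition the gene's `region_partition`.
#' @param ref reference `DNAStringSet`.
#' @param config a [sim_config()] (its `L` is overridden by the window
#'   length).
#' @param samples sample names (diploids, in deme order).
#' @return list `matrix` (a `genotype_matrix`), `truth`.
#' @export
simulate_gene_dataset <- function(gene, partition, ref, config, samples) {
  config$L <- as.integer(sum(partition$class_lengths))
  sim <- simulate_locus(config)
  offset <- partition$window[["start"]]
  gpos <- as.integer(offset + sim$positions - 1L)
  chrom_seq <- ref[[gene$chrom]]
  ref_bases <- strsplit(as.character(
    Biostrings::subseq(chrom_seq, offset,
                       partition$window[["end"]])), "")[[1]][sim$positions]
  alt_bases <- with_seed(
    if (is.null(config$seed)) NULL else config$seed + 1L,
    draw_alt_alleles(ref_bases, config$kappa))
  gm_full <- haplotypes_to_matrix(sim$haplotypes, sim$positions, gene$chrom,
                                  offset, ref_bases, alt_bases, samples)
  gm <- inject_missingness(gm_full, config$missing_rate,
                           seed = if (is.null(config$seed)) NULL
                                  else config$seed + 2L)
  cls <- if (length(gpos)) classify_site(partition, gpos) else character()
  cons <- vapply(seq_along(gpos), function(i)
    annotate_variant(gene, partition, ref, gpos[i], ref_bases[i],
                     alt_bases[i]), "")
  true_pi_class <- vapply(c("total", "genic", "exon", "intron", "intergenic"),
    function(gcl) {
      keep_cls <- switch(gcl, total = SITE_CLASSES,
                         genic = c("exon", "intron", "utr5", "utr3"),
                         gcl)
      len <- sum(partition$class_lengths[intersect(keep_cls, SITE_CLASSES)])
      if (len == 0) return(NA_real_)
      keep <- cls %in% keep_cls
      mean_pairwise_diff(sim$haplotypes[, keep, drop = FALSE]) / len
    }, 0)
  list(matrix = gm,
       truth = list(positions = gpos, site_class = cls, consequence = cons,
                    pi_per_site = true_pi_class,
                    realized_missing = mean(geno_missing(gm)),
                    sim = sim$truth))
}

#' Write a simulated dataset as VCF + GFF3 + FASTA + panel + truth
#'
#' Files parse cleanly back through [read_vcf()] and [load_annotation()];
#' round-tripping reproduces the genotype matrix exactly.
#'
#' @param gm a `genotype_matrix`.
#' @param genes named list of [gene_model()].
#' @param ref reference `DNAStringSet`.
#' @param panel panel data.frame.
#' @param dir output directory (created if needed).
#' @param truth optional list serialized to `truth.json`.
#' @return invisible named vector of file paths.
#' @export
write_fixture <- function(gm, genes, ref, panel, dir, truth = NULL) {
  if (!dir.exists(dir) &&
      !dir.create(dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create directory ", dir)
  paths <- c(vcf = file.path(dir, "variants.vcf"),
             gff = file.path(dir, "annotation.gff3"),
             fasta = file.path(dir, "reference.fa"),
             panel = file.path(dir, "panel.tsv"),
             truth = file.path(dir, "truth.json"))
  write_vcf(gm, paths[["vcf"]])
  write_gff3(genes, paths[["gff"]])
  Biostrings::writeXStringSet(ref, paths[["fasta"]])
  utils::write.table(panel, paths[["panel"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(truth))
    jsonlite::write_json(truth, paths[["truth"]], auto_unbox = TRUE,
                         digits = NA)
  invisible(paths)
}

#' Write a genotype matrix as VCF v4.2
#'
#' @param gm a `genotype_matrix`.
#' @param path output file.
#' @export
write_vcf <- function(gm, path) {
  gt <- matrix("./.", nrow = n_sites(gm), ncol = length(gm$samples))
  called <- !geno_missing(gm)
  gt[called] <- paste0(gm$a1[called], "/", gm$a2[called])
  header <- c("##fileformat=VCFv4.2",
              "##source=tasrdiv",
              '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", gm$samples), collapse = "\t"))
  body <- vapply(seq_len(n_sites(gm)), function(i)
    paste(c(gm$sites$chrom[i], gm$sites$pos[i], gm$sites$id[i],
            gm$sites$ref[i], gm$sites$alt[i], ".", "PASS", ".", "GT",
            gt[i, ]), collapse = "\t"), "")
  writeLines(c(header, body), path)
  invisible(path)
}
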