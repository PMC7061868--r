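#' Cohort simulation configuration
#'
#' Defaults emulate a 26-sample resequencing cohort: 8 hard-seeded (H),
#' 12 soft-seeded (S) and 6 unassigned samples over 8 chromosomes
#' (chromosome 1 longest), ~1 SNP per kb, Balding-Nichols between-
#' population differentiation F = 0.26, 2% missing calls, and one large
#' injected sweep on chromosome 1 (16.33-42.53 Mb, 10-fold diversity
#' reduction in H).
#'
#' @param n_chromosomes Number of chromosomes.
#' @param chrom_lengths Named lengths in bp; default 45 Mb for chr1 and
#'   40 Mb for the rest.
#' @param snp_density_kb Expected SNPs per kb.
#' @param n_h,n_s,n_other Samples per population (H, S, unassigned).
#' @param fst Balding-Nichols differentiation parameter in `[0, 1)`.
#' @param sweeps Data frame with `chrom`, `start`, `end`, `reduction`
#'   (target fold-reduction in diversity), `population` (affected label);
#'   `NULL` for none.
#' @param missing_rate Per-call Bernoulli missingness rate.
#' @param ld_rho First-order genotype autocorrelation in `[0, 1)`; 0
#'   (default) gives unlinked sites, positive values give LD for decay
#'   analyses.
#' @param seed Integer seed; all outputs are deterministic given it.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_chromosomes = 8,
                          chrom_lengths = NULL,
                          snp_density_kb = 1.0,
                          n_h = 8, n_s = 12, n_other = 6,
                          fst = 0.26,
                          sweeps = data.frame(
                            chrom = "chr1", start = 16330001L,
                            end = 42530000L, reduction = 10,
                            population = "H",
                            stringsAsFactors = FALSE),
                          missing_rate = 0.02,
                          ld_rho = 0,
                          seed = 1) {
  if (is.null(chrom_lengths)) {
    chrom_lengths <- setNames(c(45e6, rep(40e6, n_chromosomes - 1)),
                              paste0("chr", seq_len(n_chromosomes)))
  }
  stopifnot(length(chrom_lengths) == n_chromosomes,
            all(chrom_lengths > 0), snp_density_kb > 0,
            fst >= 0, fst < 1, missing_rate >= 0, missing_rate < 1,
            ld_rho >= 0, ld_rho < 1)
  if (!is.null(sweeps) && nrow(sweeps)) {
    stopifnot(all(sweeps$chrom %in% names(chrom_lengths)),
              all(sweeps$start >= 1),
              all(sweeps$end <= chrom_lengths[sweeps$chrom]),
              all(sweeps$reduction >= 1),
              all(sweeps$population %in% c("H", "S")))
  }
  structure(list(n_chromosomes = n_chromosomes,
                 chrom_lengths = chrom_lengths,
                 snp_density_kb = snp_density_kb,
                 n_h = n_h, n_s = n_s, n_other = n_other,
                 fst = fst, sweeps = sweeps,
                 missing_rate = missing_rate, ld_rho = ld_rho,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

## Push an allele frequency toward its nearest boundary so the expected
## heterozygosity 2p(1-p) drops by `reduction`-fold.
sweep_shift_freq <- function(p, reduction) {
  h <- 2 * p * (1 - p) / reduction
  root <- sqrt(pmax(0, 1 - 2 * h))
  ifelse(p <= 0.5, (1 - root) / 2, (1 + root) / 2)
}

#' Simulate a two-population cohort with injected sweeps
#'
#' Balding-Nichols model: ancestral frequencies are Uniform(0.05, 0.95);
#' each population's frequency is Beta-distributed around the ancestral
#' value with the configured F; genotypes are Binomial(2, freq) per
#' sample; unassigned samples draw from the ancestral frequencies.
#' Inside sweep intervals the affected population's frequencies are
#' pushed toward fixation to achieve the configured diversity reduction.
#' Site positions are uniform at the configured density.  Also emits toy
#' gene models (~2-kb genes on a 10-kb grid), a random gene-to-pathway
#' map, and the ground truth needed by [evaluate_recovery()].
#'
#' @param cfg A [cohort_config()].
#' @return List with `gm` (a [genotype_matrix()]), `genes` (data frame as
#'   from [read_gff3_genes()]), `pathway_map` (data frame `gene`,
#'   `pathway`), `truth` (list: `freqs` data frame, `sweeps`, `fst`).
#' @export
simulate_cohort <- function(cfg = cohort_config()) {
  stopifnot(inherits(cfg, "cohort_config"))
  set.seed(cfg$seed)
  n_tot <- cfg$n_h + cfg$n_s + cfg$n_other
  samples <- c(sprintf("H%02d", seq_len(cfg$n_h)),
               sprintf("S%02d", seq_len(cfg$n_s)),
               sprintf("U%02d", seq_len(cfg$n_other)))
  pops <- setNames(rep(c("H", "S", "unassigned"),
                       c(cfg$n_h, cfg$n_s, cfg$n_other)), samples)
  rows_h <- seq_len(cfg$n_h)
  rows_s <- cfg$n_h + seq_len(cfg$n_s)
  rows_o <- cfg$n_h + cfg$n_s + seq_len(cfg$n_other)

  all_sites <- list(); all_calls <- list(); all_freqs <- list()
  for (chr in names(cfg$chrom_lengths)) {
    len <- cfg$chrom_lengths[[chr]]
    m <- round(len / 1000 * cfg$snp_density_kb)
    pos <- sort(sample.int(len, m))
    p_anc <- runif(m, 0.05, 0.95)
    if (cfg$fst > 0) {
      theta <- (1 - cfg$fst) / cfg$fst
      p_h <- rbeta(m, p_anc * theta, (1 - p_anc) * theta)
      p_s <- rbeta(m, p_anc * theta, (1 - p_anc) * theta)
    } else {
      p_h <- p_anc; p_s <- p_anc
    }
    if (!is.null(cfg$sweeps) && nrow(cfg$sweeps)) {
      sw <- cfg$sweeps[cfg$sweeps$chrom == chr, , drop = FALSE]
      for (i in seq_len(nrow(sw))) {
        in_sw <- pos >= sw$start[i] & pos <= sw$end[i]
        if (sw$population[i] == "H") {
          p_h[in_sw] <- sweep_shift_freq(p_h[in_sw], sw$reduction[i])
        } else {
          p_s[in_sw] <- sweep_shift_freq(p_s[in_sw], sw$reduction[i])
        }
      }
    }
    calls <- matrix(NA_integer_, nrow = n_tot, ncol = m)
    calls[rows_h, ] <- rbinom(cfg$n_h * m, 2,
                              rep(p_h, each = cfg$n_h))
    calls[rows_s, ] <- rbinom(cfg$n_s * m, 2,
                              rep(p_s, each = cfg$n_s))
    if (cfg$n_other > 0) {
      calls[rows_o, ] <- rbinom(cfg$n_other * m, 2,
                                rep(p_anc, each = cfg$n_other))
    }
    if (cfg$ld_rho > 0 && m > 1) {
      for (j in 2:m) {
        copy <- runif(n_tot) < cfg$ld_rho
        calls[copy, j] <- calls[copy, j - 1]
      }
    }
    if (cfg$missing_rate > 0) {
      calls[runif(n_tot * m) < cfg$missing_rate] <- NA_integer_
    }
    ref <- sample(c("A", "C", "G", "T"), m, replace = TRUE)
    alt <- vapply(ref, function(b) sample(setdiff(c("A", "C", "G", "T"),
                                                  b), 1), character(1))
    all_sites[[chr]] <- data.frame(chrom = chr, pos = pos, ref = ref,
                                   alt = unname(alt),
                                   stringsAsFactors = FALSE)
    all_calls[[chr]] <- calls
    all_freqs[[chr]] <- data.frame(chrom = chr, pos = pos,
                                   p_anc = p_anc, p_h = p_h, p_s = p_s)
  }
  sites <- do.call(rbind, all_sites)
  calls <- do.call(cbind, all_calls)
  rownames(sites) <- NULL
  gm <- genotype_matrix(calls, sites, samples = samples,
                        populations = pops)

  ## toy gene annotation: a 2-kb gene every 10 kb
  genes <- do.call(rbind, lapply(names(cfg$chrom_lengths), function(chr) {
    starts <- seq(1001, cfg$chrom_lengths[[chr]] - 3000, by = 10000)
    data.frame(chrom = chr, start = as.integer(starts),
               end = as.integer(starts + 2228),
               strand = rep_len(c("+", "-"), length(starts)),
               gene_id = sprintf("gene_%s_%05d", chr,
                                 seq_along(starts)),
               stringsAsFactors = FALSE)
  }))
  pathway_map <- data.frame(
    gene = genes$gene_id,
    pathway = sprintf("path%02d", sample.int(20, nrow(genes),
                                             replace = TRUE)),
    stringsAsFactors = FALSE)
  truth <- list(freqs = do.call(rbind, all_freqs),
                sweeps = cfg$sweeps, fst = cfg$fst)
  list(gm = gm, genes = genes, pathway_map = pathway_map, truth = truth)
}

#' Write a simulated cohort to disk
#'
#' Emits VCF v4.2, a headerless popmap TSV, a chromosome-length TSV
#' (header `chrom`, `length`), GFF3 gene models, a pathway-map TSV and a
#' truth JSON, named `cohort.vcf`, `popmap.tsv`, `chroms.tsv`,
#' `genes.gff3`, `pathways.tsv`, `truth.json`.
#'
#' @param sim Result of [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @param chrom_lengths Named lengths written to `chroms.tsv` (defaults
#'   to the spans implied by the simulated truth).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_cohort <- function(sim, dir, chrom_lengths = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(vcf = file.path(dir, "cohort.vcf"),
             popmap = file.path(dir, "popmap.tsv"),
             chroms = file.path(dir, "chroms.tsv"),
             gff = file.path(dir, "genes.gff3"),
             pathways = file.path(dir, "pathways.tsv"),
             truth = file.path(dir, "truth.json"))
  write_vcf(sim$gm, paths["vcf"])
  keep <- sim$gm$populations != "unassigned"
  write_popmap(sim$gm$populations[keep], paths["popmap"])
  if (is.null(chrom_lengths)) {
    chrom_lengths <- tapply(sim$truth$freqs$pos, sim$truth$freqs$chrom,
                            max)
  }
  utils::write.table(data.frame(chrom = names(chrom_lengths),
                                length = as.numeric(chrom_lengths)),
                     paths["chroms"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_gff3(sim$genes, paths["gff"])
  utils::write.table(sim$pathway_map, paths["pathways"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  truth <- sim$truth
  truth$freqs <- NULL  # keep the JSON small; sweeps and F suffice
  jsonlite::write_json(truth, paths["truth"], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}

#' Write gene models as GFF3
#' @param genes Data frame with `chrom`, `start`, `end`, `strand`,
#'   `gene_id`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(genes, path) {
  con <- file(path, "wt")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (nrow(genes)) {
    writeLines(paste(genes$chrom, "popsweep", "gene", genes$start,
                     genes$end, ".", genes$strand, ".",
                     paste0("ID=", genes$gene_id), sep = "\t"), con)
  }
  invisible(path)
}

#' Simulate sequence evolution under the K2P model on a tree
#'
#' Sites evolve independently along a tree with branch lengths in
#' expected substitutions per site; the transition/transversion rate
#' ratio `kappa = alpha/beta` shapes the substitution process.
#'
#' @param tree A `phylo` tree with branch lengths.
#' @param length Sequence length in sites.
#' @param ts_tv_ratio Rate ratio `kappa` (default 2).
#' @param seed Integer seed.
#' @return Named character vector of tip sequences.
#' @export
simulate_alignment <- function(tree, length, ts_tv_ratio = 2, seed = 1) {
  stopifnot(inherits(tree, "phylo"), length > 0)
  n_col <- as.integer(length)
  kappa <- ts_tv_ratio
  beta <- 1 / (kappa + 2); alpha <- kappa / (kappa + 2)
  bases <- c("A", "G", "C", "T")          # transitions: A<->G, C<->T
  p_matrix <- function(t) {
    e1 <- exp(-4 * beta * t)
    e2 <- exp(-2 * (alpha + beta) * t)
    pts <- 0.25 + 0.25 * e1 - 0.5 * e2
    ptv <- 0.25 - 0.25 * e1               # each transversion target
    psame <- 1 - pts - 2 * ptv
    m <- matrix(ptv, 4, 4)
    m[1, 2] <- m[2, 1] <- m[3, 4] <- m[4, 3] <- pts
    diag(m) <- psame
    m
  }
  set.seed(seed)
  n_tip <- base::length(tree$tip.label)
  n_node <- tree$Nnode
  seqs <- matrix(NA_integer_, nrow = n_tip + n_node, ncol = n_col)
  root <- n_tip + 1
  seqs[root, ] <- sample.int(4, n_col, replace = TRUE)
  tree_cw <- ape::reorder.phylo(tree, "cladewise")
  edges <- tree_cw$edge
  bl <- tree_cw$edge.length
  for (k in seq_len(nrow(edges))) {
    parent <- edges[k, 1]; child <- edges[k, 2]
    P <- p_matrix(bl[k])
    out <- integer(n_col)
    for (s in 1:4) {
      at <- which(seqs[parent, ] == s)
      if (length(at)) {
        out[at] <- sample.int(4, length(at), replace = TRUE,
                              prob = P[s, ])
      }
    }
    seqs[child, ] <- out
  }
  tips <- vapply(seq_len(n_tip), function(i) {
    paste(bases[seqs[i, ]], collapse = "")
  }, character(1))
  setNames(tips, tree$tip.label)
}

#' Evaluate sweep-call recovery against simulated truth
#'
#' Base-level comparison of called regions with true sweep intervals:
#' sensitivity is the fraction of true sweep bases covered by calls, the
#' false-discovery rate is the fraction of called bases outside the
#' truth, and the boundary error is the mean absolute offset between each
#' called region's endpoints and the nearest true interval's endpoints.
#'
#' @param called Data frame of called regions (`chrom`, `start`, `end`).
#' @param truth Data frame of true sweep intervals (same columns), or the
#'   `truth` element of [simulate_cohort()] output.
#' @return List with `sensitivity`, `fdr` (`NA` when nothing is called),
#'   `boundary_error_bp`, `true_bases`, `called_bases`, `covered_bases`.
#' @export
evaluate_recovery <- function(called, truth) {
  if (is.list(truth) && !is.data.frame(truth) && !is.null(truth$sweeps)) {
    truth <- truth$sweeps
  }
  true_bases <- sum(truth$end - truth$start + 1)
  if (is.null(called) || nrow(called) == 0) {
    return(list(sensitivity = 0, fdr = NA_real_,
                boundary_error_bp = NA_real_,
                true_bases = true_bases, called_bases = 0,
                covered_bases = 0))
  }
  called_bases <- sum(called$end - called$start + 1)
  covered <- 0
  for (i in seq_len(nrow(called))) {
    tt <- truth[truth$chrom == called$chrom[i], , drop = FALSE]
    if (!nrow(tt)) next
    ov <- pmax(0, pmin(tt$end, called$end[i]) -
                 pmax(tt$start, called$start[i]) + 1)
    covered <- covered + sum(ov)
  }
  bnd <- vapply(seq_len(nrow(called)), function(i) {
    tt <- truth[truth$chrom == called$chrom[i], , drop = FALSE]
    if (!nrow(tt)) return(NA_real_)
    min(abs(tt$start - called$start[i]) + abs(tt$end - called$end[i])) / 2
  }, numeric(1))
  list(sensitivity = covered / true_bases,
       fdr = (called_bases - covered) / called_bases,
       boundary_error_bp = mean(bnd, na.rm = TRUE),
       true_bases = true_bases, called_bases = called_bases,
       covered_bases = covered)
}
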