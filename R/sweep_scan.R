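#' Permutation-derived cut-off for the diversity ratio
#'
#' Population labels are permuted across the labelled samples `n_perm`
#' times; the windowed diversity ratio is recomputed genome-wide for each
#' permutation and pooled; the cut-off is the `(1 - alpha)` quantile of
#' the pooled permuted values.  Under an exchangeable null this controls
#' the per-window type-I rate at `alpha`.
#'
#' @param gm A [genotype_matrix()].
#' @param windows Window data frame from [make_windows()].
#' @param pop_a,pop_b The two population labels; the permuted statistic is
#'   the ratio `pi(num)/pi(den)` with group sizes matching the observed
#'   labelling.
#' @param numerator_pop,denominator_pop Orientation of the ratio (defaults
#'   `pop_b` over `pop_a`, i.e. the ratio used to scan for sweeps in
#'   `pop_a`).
#' @param n_perm Number of permutations (at least 2; values below 100 give
#'   a warning because the quantile becomes unstable).
#' @param alpha Upper-tail probability of the cut-off.
#' @param seed Integer seed; the cut-off is reproducible given the seed.
#' @param min_snps Mask windows with fewer segregating sites.
#' @param ratio_cap Cap for degenerate ratios.
#' @return The cut-off value, with attributes `n_values` (pooled values
#'   used) and `alpha`.
#' @export
permutation_cutoff <- function(gm, windows, pop_a = "H", pop_b = "S",
                               numerator_pop = pop_b,
                               denominator_pop = pop_a,
                               n_perm = 100, alpha = 0.05, seed = 1,
                               min_snps = 10, ratio_cap = 100) {
  if (n_perm < 2) stop("n_perm must be at least 2")
  if (n_perm < 100) warning("n_perm < 100 gives an unstable quantile")
  ia <- pop_index(gm, pop_a); ib <- pop_index(gm, pop_b)
  if (identical(pop_a, pop_b)) stop("two distinct populations required")
  labelled <- c(ia, ib)
  n_num <- if (identical(numerator_pop, pop_a)) length(ia) else length(ib)

  ## precompute per-chromosome structures once
  chroms <- unique(windows$chrom)
  X0 <- gm$calls; X0[is.na(X0)] <- 0L
  M <- (!is.na(gm$calls)) + 0L
  prep <- lapply(chroms, function(chr) {
    sel <- which(gm$sites$chrom == chr)
    w <- windows[windows$chrom == chr, , drop = FALSE]
    pos <- gm$sites$pos[sel]
    list(sel = sel, w = w, pos = pos,
         lo = findInterval(w$start - 1L, pos),
         hi = findInterval(w$end, pos),
         L = w$end - w$start + 1)
  })

  ## segregating-site mask from the observed labelling (fixed across
  ## permutations: masking is a property of the scan, not the labels)
  cnt_all <- pop_site_counts(gm$calls, labelled)
  seg_all <- cnt_all$an >= 2 & cnt_all$ac > 0 & cnt_all$ac < cnt_all$an

  set.seed(seed)
  pooled <- vector("list", n_perm)
  for (b in seq_len(n_perm)) {
    perm <- sample(labelled)
    rows_num <- perm[seq_len(n_num)]
    rows_den <- perm[-seq_len(n_num)]
    ind <- matrix(0L, nrow = n_samples(gm), ncol = 2)
    ind[rows_num, 1] <- 1L
    ind[rows_den, 2] <- 1L
    AC <- crossprod(X0, ind)            # sites x 2 alt-allele sums
    NM <- crossprod(M, ind)             # sites x 2 non-missing counts
    vals <- numeric(0)
    for (p in prep) {
      an1 <- 2 * NM[p$sel, 1]; an2 <- 2 * NM[p$sel, 2]
      c1 <- pi_site_contrib(AC[p$sel, 1], an1)
      c2 <- pi_site_contrib(AC[p$sel, 2], an2)
      cs1 <- c(0, cumsum(c1)); cs2 <- c(0, cumsum(c2))
      css <- c(0, cumsum(seg_all[p$sel] + 0))
      pin <- (cs1[p$hi + 1L] - cs1[p$lo + 1L]) / p$L
      pid <- (cs2[p$hi + 1L] - cs2[p$lo + 1L]) / p$L
      nsn <- css[p$hi + 1L] - css[p$lo + 1L]
      r <- diversity_ratio(pi_num = pin, pi_den = pid, cap = ratio_cap)
      vals <- c(vals, as.numeric(r)[nsn >= min_snps & !is.na(r)])
    }
    pooled[[b]] <- vals
  }
  pooled <- unlist(pooled)
  if (!length(pooled)) stop("no usable permuted window values")
  structure(unname(quantile(pooled, 1 - alpha, names = FALSE)),
            n_values = length(pooled), alpha = alpha)
}

#' Select the top fraction of windows by a statistic
#'
#' A window is selected when its value is at least the `(1 - fraction)`
#' empirical quantile, defined by rank: the threshold is the
#' `ceiling(fraction * n)`-th largest defined value, and all ties at the
#' threshold are included.  Undefined values are excluded before ranking
#' and never selected.
#'
#' @param values Numeric vector.
#' @param fraction Fraction in `(0, 1)`.
#' @return Logical selection vector with attribute `threshold`.
#' @export
top_fraction_windows <- function(values, fraction = 0.05) {
  stopifnot(fraction > 0, fraction < 1)
  defined <- !is.na(values)
  if (!any(defined)) {
    return(structure(rep(FALSE, length(values)), threshold = NA_real_))
  }
  k <- ceiling(fraction * sum(defined))
  thr <- sort(values[defined], decreasing = TRUE)[k]
  structure(defined & values >= thr, threshold = thr)
}

#' Call candidate sweep windows for each population
#'
#' A window is a candidate for population X when the diversity ratio
#' (other population over X) reaches `ratio_cutoff` and the window passes
#' the FST rule; the combination operator defaults to conjunction.
#' Masked windows (too few SNPs) are never called.
#'
#' @param stats Window-statistics table from [window_stats()].
#' @param ratio_cutoff Cut-off for the diversity ratio, typically from
#'   [permutation_cutoff()].
#' @param fst_rule Either `list(type = "top_fraction", fraction = 0.05)`
#'   (FST in the genome-wide top fraction) or
#'   `list(type = "threshold", value = 0.55)`.
#' @param operator `"and"` (default) or `"or"`.
#' @return Named list with one data frame of candidate windows per
#'   population (the rows of `stats` that were called), each with the
#'   per-window ratio oriented for that population in column
#'   `ratio_for_pop`.
#' @export
call_candidate_windows <- function(stats, ratio_cutoff,
                                   fst_rule = list(type = "top_fraction",
                                                   fraction = 0.05),
                                   operator = c("and", "or")) {
  operator <- match.arg(operator)
  pa <- attr(stats, "pop_a"); pb <- attr(stats, "pop_b")
  usable <- !stats$masked
  fst_pass <- switch(fst_rule$type,
    top_fraction = {
      v <- stats$fst; v[!usable] <- NA
      as.logical(top_fraction_windows(v, fst_rule$fraction))
    },
    threshold = !is.na(stats$fst) & stats$fst >= fst_rule$value,
    stop("unknown fst_rule type: ", fst_rule$type))
  comb <- if (operator == "and") `&` else `|`
  ## sweep in population a is flagged by reduced pi_a, i.e. high pi_b/pi_a
  ratio_ba <- ifelse(!is.na(stats$pi_a) & stats$pi_a > 0,
                     stats$pi_b / stats$pi_a,
                     ifelse(stats$pi_b > 0, Inf, NA_real_))
  ratio_ab <- ifelse(!is.na(stats$pi_b) & stats$pi_b > 0,
                     stats$pi_a / stats$pi_b,
                     ifelse(stats$pi_a > 0, Inf, NA_real_))
  sel_a <- usable & !is.na(ratio_ba) & ratio_ba >= ratio_cutoff
  sel_b <- usable & !is.na(ratio_ab) & ratio_ab >= ratio_cutoff
  call_a <- comb(sel_a, fst_pass) & usable
  call_b <- comb(sel_b, fst_pass) & usable
  res_a <- stats[call_a, , drop = FALSE]
  res_a$ratio_for_pop <- ratio_ba[call_a]
  res_b <- stats[call_b, , drop = FALSE]
  res_b$ratio_for_pop <- ratio_ab[call_b]
  out <- setNames(list(res_a, res_b), c(pa, pb))
  attr(out, "fst_rule") <- fst_rule
  attr(out, "ratio_cutoff") <- ratio_cutoff
  attr(out, "operator") <- operator
  out
}

#' Merge candidate windows into sweep regions
#'
#' Overlapping windows, and windows separated by at most `merge_gap_bp`,
#' are merged; the default gap equals the scan step so adjacent sliding
#' windows coalesce.  Summary statistics are averaged over the source
#' windows of each region.
#'
#' @param windows Data frame with `chrom`, `start`, `end` and optionally
#'   `ratio_for_pop`, `fst`, `tajd_a`, `tajd_b`.
#' @param merge_gap_bp Maximum gap (bp) between merged windows.
#' @param population Optional label recorded on the result.
#' @return Data frame of nonoverlapping regions sorted by chromosome and
#'   start, with `length_bp`, `length_mb` (half-up, 2 decimals),
#'   `n_windows` and available statistic summaries.
#' @export
merge_regions <- function(windows, merge_gap_bp = 10000,
                          population = NA_character_) {
  cols <- c("chrom", "start", "end")
  empty <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), length_bp = integer(0),
                      length_mb = numeric(0), n_windows = integer(0),
                      population = character(0))
  if (is.null(windows) || nrow(windows) == 0) return(empty)
  stopifnot(all(cols %in% names(windows)))
  chrom_f <- factor(windows$chrom, levels = unique(windows$chrom))
  ord <- order(chrom_f, windows$start)
  windows <- windows[ord, , drop = FALSE]
  out <- list()
  for (chr in levels(chrom_f)) {
    w <- windows[windows$chrom == chr, , drop = FALSE]
    if (!nrow(w)) next
    grp <- cumsum(c(1, as.integer(
      w$start[-1] > cummax(w$end)[-nrow(w)] + merge_gap_bp + 1)))
    for (g in unique(grp)) {
      ww <- w[grp == g, , drop = FALSE]
      reg <- data.frame(chrom = chr, start = min(ww$start),
                        end = max(ww$end), stringsAsFactors = FALSE)
      reg$length_bp <- reg$end - reg$start + 1
      reg$length_mb <- round_half_up(reg$length_bp / 1e6, 2)
      reg$n_windows <- nrow(ww)
      if ("ratio_for_pop" %in% names(ww)) {
        reg$mean_ratio <- mean(ww$ratio_for_pop[is.finite(ww$ratio_for_pop)])
        reg$max_ratio <- suppressWarnings(
          max(ww$ratio_for_pop[is.finite(ww$ratio_for_pop)]))
      }
      if ("fst" %in% names(ww)) reg$mean_fst <- mean(ww$fst, na.rm = TRUE)
      if ("tajd_a" %in% names(ww)) {
        reg$mean_tajd_a <- mean(ww$tajd_a, na.rm = TRUE)
      }
      if ("tajd_b" %in% names(ww)) {
        reg$mean_tajd_b <- mean(ww$tajd_b, na.rm = TRUE)
      }
      reg$population <- population
      out[[length(out) + 1]] <- reg
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Read gene features from a GFF3 file
#'
#' @param path Path to a GFF3 file.
#' @param feature Feature type to keep (default `"gene"`).
#' @return Data frame with `chrom`, `start`, `end`, `strand`, `gene_id`
#'   (the `ID` attribute, falling back to the raw attribute string).
#' @export
read_gff3_genes <- function(path, feature = "gene") {
  gff <- ape::read.gff(path, GFF3 = TRUE)
  gff <- gff[gff$type == feature, , drop = FALSE]
  id <- sub("^.*ID=([^;]+).*$", "\\1", gff$attributes)
  data.frame(chrom = as.character(gff$seqid), start = gff$start,
             end = gff$end, strand = as.character(gff$strand),
             gene_id = id, stringsAsFactors = FALSE)
}

#' Annotate sweep regions with overlapping genes
#'
#' A gene belongs to a region when its span overlaps the region by at
#' least one bp.
#'
#' @param regions Data frame from [merge_regions()].
#' @param genes Data frame from [read_gff3_genes()].
#' @return `regions` with added `n_genes` and `genes`
#'   (comma-separated gene IDs) columns and attribute `total_genes`
#'   (number of unique genes across all regions).  A chromosome present in
#'   `regions` but absent from `genes` raises a warning.
#' @export
annotate_regions <- function(regions, genes) {
  if (nrow(regions) == 0) {
    regions$n_genes <- integer(0)
    regions$genes <- character(0)
    attr(regions, "total_genes") <- 0L
    return(regions)
  }
  missing_chr <- setdiff(unique(regions$chrom), unique(genes$chrom))
  if (length(missing_chr)) {
    warning("no gene features on chromosome(s): ",
            paste(missing_chr, collapse = ", "), " (",
            sum(regions$chrom %in% missing_chr), " region(s) unmatched)")
  }
  hit_ids <- character(0)
  regions$n_genes <- 0L
  regions$genes <- ""
  for (i in seq_len(nrow(regions))) {
    g <- genes[genes$chrom == regions$chrom[i] &
                 genes$start <= regions$end[i] &
                 genes$end >= regions$start[i], , drop = FALSE]
    regions$n_genes[i] <- nrow(g)
    regions$genes[i] <- paste(g$gene_id, collapse = ",")
    hit_ids <- c(hit_ids, g$gene_id)
  }
  attr(regions, "total_genes") <- length(unique(hit_ids))
  regions
}

#' Hypergeometric pathway enrichment
#'
#' Upper-tail hypergeometric test per pathway: the probability of drawing
#' at least `k` pathway genes when sampling `n` region genes from a
#' background of `N` genes containing `K` pathway members.  P-values are
#' adjusted by the configured correction (default Benjamini-Hochberg) and
#' flagged at adjusted p < 0.05.
#'
#' @param region_genes Character vector of gene IDs in the region set;
#'   must be a subset of `background_genes`.
#' @param background_genes Character vector of background gene IDs.
#' @param pathway_map Data frame with columns `gene` and `pathway` (extra
#'   columns ignored), or a path to such a TSV with a header.
#' @param correction Method passed to [stats::p.adjust()].
#' @param alpha Significance level for the `significant` flag.
#' @return Data frame with one row per pathway (pathways with no
#'   background member are skipped): `pathway`, `k`, `K`, `n`, `N`,
#'   `p_value`, `p_adjusted`, `significant`, sorted by p-value.
#' @export
enrich_hypergeometric <- function(region_genes, background_genes,
                                  pathway_map, correction = "BH",
                                  alpha = 0.05) {
  empty <- data.frame(pathway = character(0), k = integer(0),
                      K = integer(0), n = integer(0), N = integer(0),
                      p_value = numeric(0), p_adjusted = numeric(0),
                      significant = logical(0))
  if (length(region_genes) == 0) return(empty)
  if (is.character(pathway_map) && length(pathway_map) == 1) {
    pathway_map <- utils::read.table(pathway_map, sep = "\t",
                                     header = TRUE,
                                     stringsAsFactors = FALSE)
  }
  stopifnot(all(c("gene", "pathway") %in% names(pathway_map)),
            nrow(pathway_map) > 0)
  region_genes <- unique(region_genes)
  background_genes <- unique(background_genes)
  out_of_bg <- setdiff(region_genes, background_genes)
  if (length(out_of_bg)) {
    stop("region genes absent from the background: ",
         paste(utils::head(out_of_bg, 5), collapse = ", "))
  }
  N <- length(background_genes)
  n <- length(region_genes)
  pm <- pathway_map[pathway_map$gene %in% background_genes, , drop = FALSE]
  paths <- unique(pm$pathway)
  if (!length(paths)) return(empty)
  rows <- lapply(paths, function(pw) {
    members <- unique(pm$gene[pm$pathway == pw])
    K <- length(members)
    k <- length(intersect(members, region_genes))
    p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(pathway = pw, k = k, K = K, n = n, N = N, p_value = p,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$p_adjusted <- p.adjust(res$p_value, method = correction)
  res$significant <- res$p_adjusted < alpha
  res[order(res$p_value), , drop = FALSE]
}

#' Write regions as BED (0-based half-open)
#' @param regions Data frame with `chrom`, `start`, `end` (1-based
#'   inclusive internal coordinates).
#' @param path Output path.
#' @param name Optional feature-name vector.
#' @return `path`, invisibly.
#' @export
write_regions_bed <- function(regions, path, name = NULL) {
  bed <- data.frame(chrom = regions$chrom,
                    start = regions$start - 1L,
                    end = regions$end)
  if (!is.null(name)) bed$name <- name
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
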