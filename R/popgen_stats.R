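#' Sliding-window specification
#'
#' Defaults are 100-kb windows advanced in 10-kb steps, the standard scan
#' resolution for cohort-scale sweep detection.
#'
#' @param size_bp Window size in bp.
#' @param step_bp Step between window starts in bp; must not exceed
#'   `size_bp`.
#' @return An object of class `window_spec`.
#' @export
window_spec <- function(size_bp = 100000L, step_bp = 10000L) {
  stopifnot(size_bp > 0, step_bp > 0, step_bp <= size_bp)
  structure(list(size_bp = as.integer(size_bp),
                 step_bp = as.integer(step_bp)),
            class = "window_spec")
}

#' Enumerate sliding windows over chromosomes
#'
#' Windows start at position 1, advance by `step_bp`, and are emitted only
#' when fully contained in the chromosome.
#'
#' @param chrom_lengths Named numeric vector of chromosome lengths in bp.
#' @param spec A [window_spec()].
#' @return Data frame with columns `chrom`, `start`, `end`
#'   (1-based inclusive), ordered by chromosome then start.
#' @export
make_windows <- function(chrom_lengths, spec = window_spec()) {
  stopifnot(all(chrom_lengths > 0), !is.null(names(chrom_lengths)))
  out <- lapply(names(chrom_lengths), function(chr) {
    len <- chrom_lengths[[chr]]
    if (len < spec$size_bp) {
      return(data.frame(chrom = character(0), start = integer(0),
                        end = integer(0)))
    }
    starts <- seq.int(1L, len - spec$size_bp + 1L, by = spec$step_bp)
    data.frame(chrom = chr, start = as.integer(starts),
               end = as.integer(starts + spec$size_bp - 1L),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

## Per-site nucleotide-diversity contribution: unbiased expected
## heterozygosity (n/(n-1)) * 2p(1-p); 0 where fewer than 2 allele copies.
pi_site_contrib <- function(ac, an) {
  p <- ifelse(an > 0, ac / an, 0)
  ifelse(an >= 2, 2 * p * (1 - p) * an / (an - 1), 0)
}

## Standard Tajima (1989) constants for allele-copy count n (may be a
## real-valued mean when missingness makes n vary across sites).
tajima_constants <- function(n) {
  if (n < 3) return(NULL)
  i <- seq_len(ceiling(n) - 1)
  ## harmonic sums at real-valued n by linear interpolation between
  ## integer copy counts; exact at integer n
  a1_at <- function(nn) sum(1 / seq_len(nn - 1))
  a2_at <- function(nn) sum(1 / seq_len(nn - 1)^2)
  nlo <- floor(n)
  if (nlo == n) {
    a1 <- a1_at(n); a2 <- a2_at(n)
  } else {
    w <- n - nlo
    a1 <- (1 - w) * a1_at(nlo) + w * a1_at(nlo + 1)
    a2 <- (1 - w) * a2_at(nlo) + w * a2_at(nlo + 1)
  }
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, a2 = a2, e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

## Tajima's D from total pairwise diversity, segregating-site count and
## allele-copy count.
tajimas_d_value <- function(pi_total, S, n) {
  if (is.na(S) || S < 1 || is.na(n) || n < 3) return(NA_real_)
  k <- tajima_constants(n)
  (pi_total - S / k$a1) / sqrt(k$e1 * S + k$e2 * S * (S - 1))
}

## Hudson (ratio-of-sums) per-site numerator/denominator.
hudson_site <- function(ac1, an1, ac2, an2) {
  ok <- an1 >= 2 & an2 >= 2
  p1 <- ifelse(ok, ac1 / an1, 0)
  p2 <- ifelse(ok, ac2 / an2, 0)
  num <- (p1 - p2)^2 -
    ifelse(ok, p1 * (1 - p1) / (an1 - 1), 0) -
    ifelse(ok, p2 * (1 - p2) / (an2 - 1), 0)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  list(num = ifelse(ok, num, 0), den = ifelse(ok, den, 0), ok = ok)
}

## Weir & Cockerham (1984) per-site variance components for two
## populations, using observed heterozygote proportions.
wc_site <- function(ac1, nm1, het1, ac2, nm2, het2) {
  ok <- nm1 >= 2 & nm2 >= 2
  n1 <- ifelse(ok, nm1, 2); n2 <- ifelse(ok, nm2, 2)
  p1 <- ac1 / (2 * n1); p2 <- ac2 / (2 * n2)
  h1 <- het1 / n1; h2 <- het2 / n2
  nbar <- (n1 + n2) / 2
  nc <- n1 + n2 - (n1^2 + n2^2) / (n1 + n2)
  pbar <- (n1 * p1 + n2 * p2) / (n1 + n2)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / nbar
  hbar <- (n1 * h1 + n2 * h2) / (n1 + n2)
  a <- nbar / nc *
    (s2 - (pbar * (1 - pbar) - s2 / 2 - hbar / 4) / (nbar - 1))
  b <- nbar / (nbar - 1) *
    (pbar * (1 - pbar) - s2 / 2 - hbar * (2 * nbar - 1) / (4 * nbar))
  cc <- hbar / 2
  list(a = ifelse(ok, a, 0), bc = ifelse(ok, b + cc, 0), ok = ok)
}

## Windowed sums of a per-site quantity given sorted positions: cumulative
## sums queried at findInterval ranges, O(1) per window.
window_sums <- function(x, pos, starts, ends) {
  cs <- c(0, cumsum(as.numeric(x)))
  lo <- findInterval(starts - 1L, pos)
  hi <- findInterval(ends, pos)
  cs[hi + 1L] - cs[lo + 1L]
}

#' Nucleotide diversity in one window
#'
#' Per-site diversity: the sum over window sites of the unbiased expected
#' heterozygosity `(n_i/(n_i-1)) 2 p_i (1-p_i)` divided by the window
#' length.  This equals the mean pairwise difference per site among the
#' non-missing allele copies.
#'
#' @param gm A [genotype_matrix()].
#' @param window List or one-row data frame with `chrom`, `start`, `end`.
#' @param population Population label.
#' @return Per-site diversity, or `NA` if fewer than two samples of the
#'   population carry calls in the window.
#' @export
window_pi <- function(gm, window, population) {
  idx <- pop_index(gm, population)
  if (length(idx) < 2) return(NA_real_)
  sel <- gm$sites$chrom == window$chrom & gm$sites$pos >= window$start &
    gm$sites$pos <= window$end
  cnt <- pop_site_counts(gm$calls[, sel, drop = FALSE], idx)
  if (sum(sel) > 0 && !any(cnt$an >= 2)) return(NA_real_)
  L <- window$end - window$start + 1
  sum(pi_site_contrib(cnt$ac, cnt$an)) / L
}

#' Tajima's D in one window
#'
#' Computed from the total pairwise diversity and the number of
#' segregating sites, with the standard constants evaluated at the mean
#' non-missing allele-copy count over segregating sites.
#'
#' @inheritParams window_pi
#' @return The statistic, or `NA` when the window holds no segregating
#'   site or fewer than three allele copies.
#' @export
window_tajimas_d <- function(gm, window, population) {
  idx <- pop_index(gm, population)
  sel <- gm$sites$chrom == window$chrom & gm$sites$pos >= window$start &
    gm$sites$pos <= window$end
  cnt <- pop_site_counts(gm$calls[, sel, drop = FALSE], idx)
  seg <- cnt$an >= 2 & cnt$ac > 0 & cnt$ac < cnt$an
  S <- sum(seg)
  if (S == 0) return(NA_real_)
  pi_total <- sum(pi_site_contrib(cnt$ac, cnt$an))
  nbar <- mean(cnt$an[seg])
  tajimas_d_value(pi_total, S, nbar)
}

#' FST between two populations in one window
#'
#' Multi-site ratio-of-sums estimator; `"hudson"` (default, least
#' sensitive to unequal sample sizes) or `"weir-cockerham"`.  Negative
#' estimates are reported as computed.
#'
#' @inheritParams window_pi
#' @param pop_a,pop_b Population labels.
#' @param estimator `"hudson"` or `"weir-cockerham"`.
#' @return The estimate, or `NA` when no site is usable (at least two
#'   genotyped samples per population).
#' @export
window_fst <- function(gm, window, pop_a, pop_b, estimator = "hudson") {
  estimator <- match.arg(estimator, c("hudson", "weir-cockerham"))
  ia <- pop_index(gm, pop_a); ib <- pop_index(gm, pop_b)
  sel <- gm$sites$chrom == window$chrom & gm$sites$pos >= window$start &
    gm$sites$pos <= window$end
  ca <- pop_site_counts(gm$calls[, sel, drop = FALSE], ia)
  cb <- pop_site_counts(gm$calls[, sel, drop = FALSE], ib)
  if (estimator == "hudson") {
    h <- hudson_site(ca$ac, ca$an, cb$ac, cb$an)
    if (sum(h$den) == 0) return(NA_real_)
    sum(h$num) / sum(h$den)
  } else {
    w <- wc_site(ca$ac, ca$nm, ca$het, cb$ac, cb$nm, cb$het)
    tot <- sum(w$a) + sum(w$bc)
    if (tot == 0) return(NA_real_)
    sum(w$a) / tot
  }
}

#' Between-population diversity ratio
#'
#' Elementwise `pi_num / pi_den`.  A zero denominator with a positive
#' numerator is capped at `cap` and flagged; `0/0` is undefined.
#'
#' @param stats Data frame of window statistics from [window_stats()], or
#'   `NULL` when `pi_num`/`pi_den` are given directly.
#' @param numerator_pop,denominator_pop Population labels naming which of
#'   the two diversity columns is the numerator.
#' @param cap Cap applied when the denominator is zero.
#' @param pi_num,pi_den Optional numeric vectors overriding `stats`.
#' @return Numeric vector of ratios with attribute `capped` (logical
#'   vector) and `orientation`.
#' @export
diversity_ratio <- function(stats = NULL, numerator_pop = NULL,
                            denominator_pop = NULL, cap = 100,
                            pi_num = NULL, pi_den = NULL) {
  if (is.null(pi_num) || is.null(pi_den)) {
    stopifnot(!is.null(stats))
    pa <- attr(stats, "pop_a"); pb <- attr(stats, "pop_b")
    col_of <- function(pop) {
      if (identical(pop, pa)) return(stats$pi_a)
      if (identical(pop, pb)) return(stats$pi_b)
      stop("population '", pop, "' not present in the statistics table")
    }
    pi_num <- col_of(numerator_pop)
    pi_den <- col_of(denominator_pop)
  }
  ratio <- ifelse(pi_den > 0, pi_num / pi_den,
                  ifelse(pi_num > 0, cap, NA_real_))
  capped <- !is.na(ratio) & pi_den == 0 & pi_num > 0
  ratio <- pmin(ratio, cap)
  structure(ratio, capped = capped,
            orientation = paste0(numerator_pop %||% "num", "/",
                                 denominator_pop %||% "den"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Windowed statistics table for two populations
#'
#' The pipeline's central intermediate: per window, SNP counts, nucleotide
#' diversity (per site and per kb), Tajima's D per population, FST and the
#' diversity ratio.  Computed with cumulative-sum aggregation so the whole
#' genome is a single vectorized pass.
#'
#' @param gm A [genotype_matrix()].
#' @param windows Window data frame from [make_windows()].
#' @param pop_a,pop_b Population labels (conventionally `"H"` and `"S"`).
#' @param estimator FST estimator, `"hudson"` or `"weir-cockerham"`.
#' @param min_snps Windows with fewer segregating sites (across the two
#'   populations) than this are flagged `masked` and excluded from sweep
#'   scans; a variance-control threshold.
#' @param ratio_cap Cap for the diversity ratio.
#' @return Data frame with one row per window and attributes `pop_a`,
#'   `pop_b`, `ratio_orientation` (`"pi_a/pi_b"`).
#' @export
window_stats <- function(gm, windows, pop_a = "H", pop_b = "S",
                         estimator = "hudson", min_snps = 10,
                         ratio_cap = 100) {
  estimator <- match.arg(estimator, c("hudson", "weir-cockerham"))
  ia <- pop_index(gm, pop_a); ib <- pop_index(gm, pop_b)
  res <- vector("list", length(unique(windows$chrom)))
  chroms <- unique(windows$chrom)
  for (k in seq_along(chroms)) {
    chr <- chroms[k]
    w <- windows[windows$chrom == chr, , drop = FALSE]
    sel <- which(gm$sites$chrom == chr)
    pos <- gm$sites$pos[sel]
    ca <- pop_site_counts(gm$calls[, sel, drop = FALSE], ia)
    cb <- pop_site_counts(gm$calls[, sel, drop = FALSE], ib)
    contrib_a <- pi_site_contrib(ca$ac, ca$an)
    contrib_b <- pi_site_contrib(cb$ac, cb$an)
    seg_a <- ca$an >= 2 & ca$ac > 0 & ca$ac < ca$an
    seg_b <- cb$an >= 2 & cb$ac > 0 & cb$ac < cb$an
    seg_any <- seg_a | seg_b
    L <- w$end - w$start + 1
    ws <- function(x) window_sums(x, pos, w$start, w$end)
    S_a <- ws(seg_a); S_b <- ws(seg_b)
    pi_tot_a <- ws(contrib_a); pi_tot_b <- ws(contrib_b)
    an_seg_a <- ws(ca$an * seg_a); an_seg_b <- ws(cb$an * seg_b)
    tajd_a <- mapply(tajimas_d_value, pi_tot_a, S_a,
                     ifelse(S_a > 0, an_seg_a / pmax(S_a, 1), NA))
    tajd_b <- mapply(tajimas_d_value, pi_tot_b, S_b,
                     ifelse(S_b > 0, an_seg_b / pmax(S_b, 1), NA))
    if (estimator == "hudson") {
      h <- hudson_site(ca$ac, ca$an, cb$ac, cb$an)
      fnum <- ws(h$num); fden <- ws(h$den)
    } else {
      wcs <- wc_site(ca$ac, ca$nm, ca$het, cb$ac, cb$nm, cb$het)
      fnum <- ws(wcs$a); fden <- ws(wcs$a) + ws(wcs$bc)
    }
    fst <- ifelse(fden > 0, fnum / fden, NA_real_)
    pi_a <- pi_tot_a / L; pi_b <- pi_tot_b / L
    ratio <- diversity_ratio(pi_num = pi_a, pi_den = pi_b, cap = ratio_cap)
    n_snps <- ws(seg_any)
    res[[k]] <- data.frame(
      chrom = w$chrom, start = w$start, end = w$end,
      n_snps = as.integer(n_snps),
      n_snps_a = as.integer(S_a), n_snps_b = as.integer(S_b),
      pi_a = pi_a, pi_b = pi_b,
      pi_a_kb = pi_a * 1000, pi_b_kb = pi_b * 1000,
      tajd_a = as.numeric(tajd_a), tajd_b = as.numeric(tajd_b),
      fst = fst, ratio = as.numeric(ratio),
      masked = n_snps < min_snps,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  attr(out, "pop_a") <- pop_a
  attr(out, "pop_b") <- pop_b
  attr(out, "ratio_orientation") <- "pi_a/pi_b"
  attr(out, "estimator") <- estimator
  attr(out, "min_snps") <- min_snps
  out
}

#' Write a window-statistics table as TSV
#' @param stats Data frame from [window_stats()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_window_stats <- function(stats, path) {
  utils::write.table(stats, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Genome-pooled FST across all sites
#'
#' Single ratio-of-sums estimate over every usable site (the "genome-wide
#' average" complement to the window-averaged mean of [window_stats()]).
#'
#' @param gm A [genotype_matrix()].
#' @param pop_a,pop_b Population labels.
#' @param estimator `"hudson"` or `"weir-cockerham"`.
#' @return A single FST estimate.
#' @export
genome_fst <- function(gm, pop_a = "H", pop_b = "S",
                       estimator = "hudson") {
  estimator <- match.arg(estimator, c("hudson", "weir-cockerham"))
  ia <- pop_index(gm, pop_a); ib <- pop_index(gm, pop_b)
  ca <- pop_site_counts(gm$calls, ia)
  cb <- pop_site_counts(gm$calls, ib)
  if (estimator == "hudson") {
    h <- hudson_site(ca$ac, ca$an, cb$ac, cb$an)
    sum(h$num) / sum(h$den)
  } else {
    w <- wc_site(ca$ac, ca$nm, ca$het, cb$ac, cb$nm, cb$het)
    sum(w$a) / (sum(w$a) + sum(w$bc))
  }
}
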