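# Shared fixtures and independent oracles, built in code at test time.

# Quick genotype-matrix builder: calls is samples x sites.
make_gm <- function(calls, pos = NULL, chrom = "chr1", ref = NULL,
                    alt = NULL, populations = NULL, samples = NULL) {
  calls <- as.matrix(calls)
  m <- ncol(calls)
  if (is.null(pos)) pos <- seq_len(m) * 100L
  if (is.null(ref)) ref <- rep("A", m)
  if (is.null(alt)) alt <- rep("G", m)
  if (is.null(samples)) samples <- paste0("s", seq_len(nrow(calls)))
  rownames(calls) <- samples
  if (!is.null(populations) && is.null(names(populations))) {
    populations <- setNames(populations, samples)
  }
  genotype_matrix(calls,
                  data.frame(chrom = rep_len(chrom, m), pos = pos,
                             ref = ref, alt = alt),
                  samples = samples, populations = populations)
}

# Random toy cohort (independent of the package simulator).
random_gm <- function(n_a = 4, n_b = 5, n_sites = 20, seed = 1,
                      missing_rate = 0.1, span = 10000L) {
  set.seed(seed)
  n <- n_a + n_b
  p <- runif(n_sites, 0.1, 0.9)
  calls <- matrix(rbinom(n * n_sites, 2, rep(p, each = n)), nrow = n)
  if (missing_rate > 0) {
    calls[runif(n * n_sites) < missing_rate] <- NA_integer_
  }
  pos <- sort(sample.int(span, n_sites))
  make_gm(calls, pos = pos,
          populations = rep(c("H", "S"), c(n_a, n_b)))
}

# Brute-force nucleotide diversity: mean pairwise allele difference per
# site, enumerating every pair of non-missing allele copies.
pi_bruteforce <- function(gm, chrom, start, end, population) {
  rows <- which(gm$populations == population)
  sel <- which(gm$sites$chrom == chrom & gm$sites$pos >= start &
                 gm$sites$pos <= end)
  total <- 0
  for (j in sel) {
    g <- gm$calls[rows, j]
    g <- g[!is.na(g)]
    alleles <- unlist(lapply(g, function(x) c(rep(1, x), rep(0, 2 - x))))
    n <- length(alleles)
    if (n < 2) next
    diff <- 0
    for (i in seq_len(n - 1)) {
      diff <- diff + sum(abs(alleles[i] - alleles[(i + 1):n]))
    }
    total <- total + diff / choose(n, 2)
  }
  total / (end - start + 1)
}

# Independent Tajima's D evaluation from first principles.
tajd_oracle <- function(pi_total, S, n) {
  a1 <- sum(1 / seq_len(n - 1))
  a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  (pi_total - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

# Exact upper-tail hypergeometric probability by enumeration.
hyper_oracle <- function(k, K, n, N) {
  j <- k:min(K, n)
  sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
}

# A complete-data genotype matrix realising given alt-allele counts
# (one column per count, n diploid samples): deterministic SFS toys.
gm_from_counts <- function(counts, n_samples, population = "H") {
  calls <- sapply(counts, function(ac) {
    g <- integer(n_samples)
    full <- ac %/% 2
    if (full > 0) g[seq_len(full)] <- 2L
    if (ac %% 2 == 1) g[full + 1] <- 1L
    g
  })
  make_gm(matrix(calls, nrow = n_samples),
          pos = seq_along(counts) * 10L,
          populations = rep(population, n_samples))
}
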