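test_that("make_windows emits only fully contained windows", {
  w <- make_windows(c(chr1 = 250000), window_spec(100000, 10000))
  expect_equal(nrow(w), 16)
  expect_equal(w$start, seq(1L, 150001L, by = 10000L))
  expect_equal(w$end - w$start + 1, rep(100000, 16))
  expect_equal(nrow(make_windows(c(chr1 = 99999))), 0)
  w1 <- make_windows(c(chr1 = 100000))
  expect_equal(nrow(w1), 1)
  expect_equal(c(w1$start, w1$end), c(1, 100000))
})

test_that("window_pi matches hand-derived values and the pairwise oracle", {
  # monomorphic window
  gm0 <- make_gm(matrix(0L, 4, 5), populations = rep("H", 4))
  expect_equal(window_pi(gm0, list(chrom = "chr1", start = 1, end = 1000),
                         "H"), 0)
  # one segregating site, 4 allele copies, p = 0.5, 1-kb window
  gm1 <- make_gm(matrix(c(0L, 2L), 2, 1), pos = 500L,
                 populations = rep("H", 2))
  expect_equal(window_pi(gm1, list(chrom = "chr1", start = 1, end = 1000),
                         "H"), (4 / 3) * 0.5 / 1000)
  # random toys: frequency formula == brute-force mean pairwise difference
  for (seed in 1:20) {
    gm <- random_gm(4, 4, n_sites = 20, seed = seed, missing_rate = 0.15,
                    span = 5000L)
    win <- list(chrom = "chr1", start = 1, end = 5000)
    expect_equal(window_pi(gm, win, "H"),
                 pi_bruteforce(gm, "chr1", 1, 5000, "H"),
                 tolerance = 1e-12)
  }
})

test_that("window Tajima's D matches the constants formula and has the right sign", {
  win <- list(chrom = "chr1", start = 1, end = 1000)
  # no segregating site -> undefined
  gm0 <- make_gm(matrix(0L, 4, 3), populations = rep("H", 4))
  expect_true(is.na(window_tajimas_d(gm0, win, "H")))
  # n = 4 copies (2 diploids), one singleton site
  gm1 <- gm_from_counts(1, n_samples = 2)
  d <- window_tajimas_d(gm1, win, "H")
  pi_tot <- (4 / 3) * 2 * 0.25 * 0.75
  expect_equal(d, tajd_oracle(pi_tot, 1, 4), tolerance = 1e-12)
  # excess singletons -> D < 0; intermediate-frequency excess -> D > 0
  gm_rare <- gm_from_counts(rep(1, 12), n_samples = 10)
  gm_mid <- gm_from_counts(rep(10, 12), n_samples = 10)
  expect_lt(window_tajimas_d(gm_rare, win, "H"), 0)
  expect_gt(window_tajimas_d(gm_mid, win, "H"), 0)
  # SFS toys across sample sizes agree with the oracle
  for (n in c(3, 5, 8)) {
    counts <- c(1, 2, n, 2 * n - 1)
    gm <- gm_from_counts(counts, n_samples = n)
    an <- 2 * n
    pi_tot <- sum((an / (an - 1)) * 2 * (counts / an) * (1 - counts / an))
    expect_equal(window_tajimas_d(gm, win, "H"),
                 tajd_oracle(pi_tot, length(counts), an),
                 tolerance = 1e-12)
  }
})

test_that("FST estimators match closed forms and detect fixation", {
  win <- list(chrom = "chr1", start = 1, end = 1000)
  # fixed difference -> Hudson FST = 1
  gm_fix <- make_gm(matrix(rep(c(2L, 2L, 0L, 0L), 2), 4, 2),
                    populations = c("H", "H", "S", "S"))
  expect_equal(window_fst(gm_fix, win, "H", "S"), 1)
  # single site, hand-evaluated Hudson numerator / denominator
  gm1 <- make_gm(matrix(c(2L, 1L, 0L, 1L, 0L, 0L), 6, 1), pos = 10L,
                 populations = c("H", "H", "H", "S", "S", "S"))
  p1 <- 3 / 6; p2 <- 1 / 6
  num <- (p1 - p2)^2 - p1 * (1 - p1) / 5 - p2 * (1 - p2) / 5
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  expect_equal(window_fst(gm1, win, "H", "S"), num / den,
               tolerance = 1e-12)
  # Weir-Cockerham single-site closed form (r = 2, with observed het)
  n1 <- 3; n2 <- 3; h1 <- 1 / 3; h2 <- 1 / 3
  nbar <- 3; nc <- 6 - (9 + 9) / 6
  pbar <- (n1 * p1 + n2 * p2) / 6
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / nbar
  hbar <- (n1 * h1 + n2 * h2) / 6
  a <- nbar / nc * (s2 - (pbar * (1 - pbar) - s2 / 2 - hbar / 4) / (nbar - 1))
  b <- nbar / (nbar - 1) *
    (pbar * (1 - pbar) - s2 / 2 - hbar * (2 * nbar - 1) / (4 * nbar))
  expect_equal(window_fst(gm1, win, "H", "S", "weir-cockerham"),
               a / (a + b + hbar / 2), tolerance = 1e-12)
  # identical allele-frequency panels -> FST near zero
  set.seed(9)
  p <- runif(300, 0.2, 0.8)
  calls <- matrix(rbinom(20 * 300, 2, rep(p, each = 20)), nrow = 20)
  gm0 <- make_gm(calls, pos = sort(sample.int(1e6, 300)),
                 populations = rep(c("H", "S"), each = 10))
  expect_lt(abs(window_fst(gm0, list(chrom = "chr1", start = 1, end = 1e6),
                           "H", "S")), 0.02)
})

test_that("diversity ratio caps degenerate denominators and flags them", {
  r <- diversity_ratio(pi_num = c(0.4, 0.2, 0), pi_den = c(0.1, 0, 0))
  expect_equal(as.numeric(r), c(4, 100, NA))
  expect_equal(attr(r, "capped"), c(FALSE, TRUE, FALSE))
})

test_that("vectorized window table agrees with single-window functions", {
  gm <- random_gm(6, 6, n_sites = 200, seed = 11, missing_rate = 0.1,
                  span = 50000L)
  w <- make_windows(c(chr1 = 50000), window_spec(10000, 5000))
  st <- window_stats(gm, w, "H", "S", min_snps = 1)
  for (i in seq_len(nrow(st))) {
    win <- st[i, ]
    expect_equal(st$pi_a[i], window_pi(gm, win, "H"), tolerance = 1e-12)
    expect_equal(st$pi_b[i], window_pi(gm, win, "S"), tolerance = 1e-12)
    expect_equal(st$fst[i], window_fst(gm, win, "H", "S"),
                 tolerance = 1e-12)
    expect_equal(st$tajd_a[i], window_tajimas_d(gm, win, "H"),
                 tolerance = 1e-10)
  }
})

test_that("window statistics are invariant under sample reordering", {
  gm <- random_gm(5, 5, n_sites = 100, seed = 3, span = 20000L)
  perm <- sample(10)
  gmp <- make_gm(gm$calls[perm, ], pos = gm$sites$pos,
                 populations = gm$populations[perm],
                 samples = gm$samples[perm])
  w <- make_windows(c(chr1 = 20000), window_spec(10000, 10000))
  st1 <- window_stats(gm, w, "H", "S", min_snps = 1)
  st2 <- window_stats(gmp, w, "H", "S", min_snps = 1)
  expect_equal(st1$pi_a, st2$pi_a)
  expect_equal(st1$fst, st2$fst)
  expect_equal(st1$tajd_b, st2$tajd_b)
})
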