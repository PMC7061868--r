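test_that("top-fraction selection uses the ceiling rank rule with ties", {
  set.seed(5)
  x <- sample(seq(1, 200) / 10)          # 200 distinct values
  sel <- top_fraction_windows(x, 0.05)
  expect_equal(sum(sel), 10)
  expect_true(all(x[sel] >= attr(sel, "threshold")))
  # all values equal -> everything selected
  sel_eq <- top_fraction_windows(rep(2, 7), 0.05)
  expect_equal(sum(sel_eq), 7)
  # 10 windows at fraction 0.05 -> ceiling gives 1
  expect_equal(sum(top_fraction_windows(1:10, 0.05)), 1)
  # undefined values are excluded and never selected
  expect_equal(sum(top_fraction_windows(c(NA, 1, 2), 0.5)), 1)
})

test_that("permutation cut-off is reproducible and guards its inputs", {
  cfg <- cohort_config(n_chromosomes = 1, chrom_lengths = c(chr1 = 2e6),
                       sweeps = NULL, seed = 2)
  sim <- simulate_cohort(cfg)
  w <- make_windows(cfg$chrom_lengths)
  c1 <- permutation_cutoff(sim$gm, w, n_perm = 100, seed = 42)
  c2 <- permutation_cutoff(sim$gm, w, n_perm = 100, seed = 42)
  expect_identical(as.numeric(c1), as.numeric(c2))
  expect_error(permutation_cutoff(sim$gm, w, n_perm = 1), "at least 2")
  gm_single <- sim$gm
  gm_single$populations[] <- "H"
  expect_error(suppressWarnings(
    permutation_cutoff(gm_single, w, n_perm = 10)), "no samples|distinct")
})

test_that("candidate calling is a conjunction of ratio and FST evidence", {
  st <- data.frame(chrom = "chr1",
                   start = seq(1, 91, 10), end = seq(10, 100, 10),
                   pi_a = c(0.001, 0.0001, rep(0.001, 8)),
                   pi_b = rep(0.001, 10),
                   fst = c(0.9, 0.05, seq(0.1, 0.8, length.out = 8)),
                   masked = rep(FALSE, 10))
  attr(st, "pop_a") <- "H"; attr(st, "pop_b") <- "S"
  # window 2 has ratio 10 for H but tiny FST: conjunction rejects it
  cand <- call_candidate_windows(st, ratio_cutoff = 2,
                                 fst_rule = list(type = "threshold",
                                                 value = 0.55))
  expect_equal(nrow(cand$H), 0)
  expect_equal(nrow(cand$S), 0)
  # disjunction would accept it for H
  cand_or <- call_candidate_windows(st, 2,
                                    list(type = "threshold", value = 0.55),
                                    operator = "or")
  expect_true(2 %in% which(st$start %in% cand_or$H$start))
  # nothing passes both -> empty call set
  cand0 <- call_candidate_windows(st, ratio_cutoff = 50,
                                  fst_rule = list(type = "threshold",
                                                  value = 0.99))
  expect_equal(nrow(cand0$H) + nrow(cand0$S), 0)
})

test_that("region merging joins overlaps, respects gaps and reports Mb lengths", {
  w <- data.frame(chrom = "chr1", start = c(1, 10001), end = c(100000, 110000))
  reg <- merge_regions(w, merge_gap_bp = 10000)
  expect_equal(nrow(reg), 1)
  expect_equal(c(reg$start, reg$end), c(1, 110000))
  # the 16.33-42.53 Mb interval reports as 26.20 Mb
  big <- merge_regions(data.frame(chrom = "chr1", start = 16330001,
                                  end = 42530000))
  expect_equal(big$length_mb, 26.2)
  # two windows 5 Mb apart stay separate at a 10-kb gap
  far <- merge_regions(data.frame(chrom = "chr1",
                                  start = c(1, 5e6), end = c(1e5, 5.1e6)),
                       merge_gap_bp = 10000)
  expect_equal(nrow(far), 2)
  # idempotent, and covered bases are conserved
  set.seed(8)
  ws <- data.frame(chrom = "chr1", start = sort(sample.int(1e6, 30)) )
  ws$end <- ws$start + 9999
  r1 <- merge_regions(ws, 5000)
  r2 <- merge_regions(r1, 5000)
  expect_equal(r1[, c("chrom", "start", "end")],
               r2[, c("chrom", "start", "end")])
  union_bases <- length(unique(unlist(Map(seq, ws$start, ws$end))))
  expect_gte(sum(r1$length_bp), union_bases)   # merging only adds gap bases
  # and with a zero merge gap the union is conserved exactly
  r0 <- merge_regions(ws, 0)
  expect_equal(sum(r0$length_bp), union_bases)
})

test_that("sweep candidates concentrate on an injected sweep", {
  cfg <- cohort_config(n_chromosomes = 1, chrom_lengths = c(chr1 = 10e6),
                       sweeps = data.frame(chrom = "chr1",
                                           start = 4000001L,
                                           end = 6000000L,
                                           reduction = 10,
                                           population = "H"),
                       seed = 5)
  sim <- simulate_cohort(cfg)
  w <- make_windows(cfg$chrom_lengths)
  st <- window_stats(sim$gm, w)
  cut <- permutation_cutoff(sim$gm, w, n_perm = 100, seed = 6)
  cand <- call_candidate_windows(st, cut)
  expect_gt(nrow(cand$H), 0)
  in_sweep <- cand$H$start >= 3.9e6 & cand$H$end <= 6.1e6
  expect_gt(mean(in_sweep), 0.9)
})

test_that("gene annotation uses 1-bp overlap and warns on chromosome mismatch", {
  genes <- data.frame(chrom = "chr1",
                      start = c(100, 5000, 9000, 20000, 30001),
                      end = c(900, 6000, 9500, 21000, 31000),
                      strand = "+",
                      gene_id = paste0("g", 1:5))
  reg <- data.frame(chrom = "chr1", start = 4000, end = 30001,
                    length_bp = 26002, length_mb = 0.03, n_windows = 1,
                    population = "H")
  ann <- annotate_regions(reg, genes)
  # g5 overlaps the region boundary by exactly 1 bp and is included
  expect_equal(ann$n_genes, 4)
  expect_true(grepl("g5", ann$genes))
  expect_false(grepl("g1", ann$genes))
  reg2 <- data.frame(chrom = "chrX", start = 1, end = 10,
                     length_bp = 10, length_mb = 0, n_windows = 1,
                     population = "H")
  expect_warning(annotate_regions(reg2, genes), "chrX")
})

test_that("GFF3 written by the simulator reads back identically", {
  sim <- simulate_cohort(cohort_config(n_chromosomes = 2,
                                       chrom_lengths = c(chr1 = 2e5,
                                                         chr2 = 1e5),
                                       sweeps = NULL, seed = 3))
  path <- tempfile(fileext = ".gff3")
  write_gff3(sim$genes, path)
  back <- read_gff3_genes(path)
  expect_equal(back$gene_id, sim$genes$gene_id)
  expect_equal(back$start, sim$genes$start)
  expect_equal(back$end, sim$genes$end)
})

test_that("hypergeometric enrichment matches exact combinatorics", {
  # all five region genes inside a five-gene pathway of a 20-gene background
  bg <- paste0("g", 1:20)
  pm <- data.frame(gene = bg[1:5], pathway = "pw1")
  res <- enrich_hypergeometric(bg[1:5], bg, pm)
  expect_equal(res$p_value, 1 / choose(20, 5), tolerance = 1e-12)
  # pathway equal to the whole background is never enriched
  pm_all <- data.frame(gene = bg, pathway = "pwAll")
  expect_equal(enrich_hypergeometric(bg[1:4], bg, pm_all)$p_value, 1)
  # empty region set -> no tests
  expect_equal(nrow(enrich_hypergeometric(character(0), bg, pm)), 0)
  # random instances against the enumeration oracle
  set.seed(13)
  for (i in 1:25) {
    N <- sample(10:30, 1)
    bgx <- paste0("x", seq_len(N))
    K <- sample(2:(N - 1), 1)
    n <- sample(2:(N - 1), 1)
    pmx <- data.frame(gene = sample(bgx, K), pathway = "pw")
    region <- sample(bgx, n)
    res <- enrich_hypergeometric(region, bgx, pmx)
    k <- length(intersect(region, pmx$gene))
    expect_equal(res$p_value, hyper_oracle(k, K, n, N), tolerance = 1e-12)
  }
  # region genes outside the background are rejected
  expect_error(enrich_hypergeometric("ghost", bg, pm), "background")
})
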