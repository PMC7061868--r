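test_that("pseudo-sequences honour genotype codes, het policy and missingness", {
  calls <- rbind(c(0L, 0L, 0L), c(2L, 2L, 2L), c(1L, NA, 0L))
  gm <- make_gm(calls, ref = c("A", "C", "G"), alt = c("G", "T", "C"))
  seqs <- genotypes_to_sequences(gm, seed = 1)
  expect_equal(unname(seqs[1]), "ACG")
  expect_equal(unname(seqs[2]), "GTC")
  # missing call becomes a gap
  expect_equal(unname(substr(seqs[3], 2, 2)), "-")
  # same seed -> same het resolution; iupac policy writes ambiguity codes
  expect_identical(seqs, genotypes_to_sequences(gm, seed = 1))
  iup <- genotypes_to_sequences(gm, het_policy = "iupac")
  expect_equal(unname(substr(iup[3], 1, 1)), "R")  # A/G het
})

test_that("K2P distances match the closed form and flag saturation", {
  # identical sequences
  d0 <- k2p_distance_matrix(c(a = "ACGTACGT", b = "ACGTACGT"))
  expect_equal(d0["a", "b"], 0)
  # exactly P = 0.1 transitions, Q = 0.05 transversions over 1000 sites
  s1 <- strrep("A", 1000)
  s2 <- paste0(strrep("G", 100), strrep("C", 50), strrep("A", 850))
  d <- k2p_distance_matrix(c(x = s1, y = s2))
  expect_equal(d["x", "y"], -0.5 * log(0.75 * sqrt(0.90)),
               tolerance = 1e-12)
  expect_equal(round(d["x", "y"], 4), 0.1702)
  # P = 0.5, Q = 0 saturates
  s3 <- paste0(strrep("G", 500), strrep("A", 500))
  dsat <- k2p_distance_matrix(c(x = s1, y = s3))
  expect_true(is.na(dsat["x", "y"]))
  expect_equal(nrow(attr(dsat, "saturated")), 1)
  # gap columns are excluded pairwise
  dg <- k2p_distance_matrix(c(x = "AC-T", y = "ACGT"))
  expect_equal(dg["x", "y"], 0)
})

test_that("K2P agrees with an independent implementation on random alignments", {
  tree <- ape::rtree(6, br = function(n) runif(n, 0.01, 0.2))
  seqs <- simulate_alignment(tree, 2000, seed = 3)
  d_pkg <- k2p_distance_matrix(seqs)
  bin <- ape::as.DNAbin(do.call(rbind, strsplit(tolower(seqs), "")))
  d_ref <- as.matrix(ape::dist.dna(bin, model = "K80",
                                   pairwise.deletion = TRUE))
  expect_equal(d_pkg[rownames(d_ref), colnames(d_ref)], d_ref,
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("NJ recovers additive trees exactly and solves the 3-taxon case", {
  # 3 taxa: branch lengths from the three-point equations
  dm <- matrix(c(0, 5, 9, 5, 0, 10, 9, 10, 0), 3, 3,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- nj_tree(dm)
  x <- (5 + 9 - 10) / 2
  bl <- setNames(tr$edge.length[match(1:3, tr$edge[, 2])], tr$tip.label)
  expect_equal(unname(bl["a"]), x)
  expect_equal(unname(bl["b"]), 5 - x)
  expect_equal(unname(bl["c"]), 9 - x)
  # additive matrices from random trees: topology and path lengths
  for (n_taxa in 4:8) {
    set.seed(n_taxa)
    true_tree <- ape::rtree(n_taxa, br = function(n) runif(n, 0.5, 2))
    dm <- cophenetic(true_tree)
    est <- nj_tree(dm)
    expect_equal(ape::dist.topo(ape::unroot(true_tree), est), 0,
                 ignore_attr = TRUE)
    expect_equal(cophenetic(est)[rownames(dm), colnames(dm)], dm,
                 tolerance = 1e-8)
  }
  # undefined entries are a named error
  dmna <- dm; dmna[1, 2] <- dmna[2, 1] <- NA
  expect_error(nj_tree(dmna), "undefined")
})

test_that("bootstrap gives full support for a clean two-clade split", {
  set.seed(2)
  # two clades of 4, long internal branch, short terminal branches
  tree <- ape::read.tree(text = paste0(
    "((a1:0.01,a2:0.01,a3:0.01,a4:0.01):0.5,",
    "(b1:0.01,b2:0.01,b3:0.01,b4:0.01):0.5);"))
  seqs <- simulate_alignment(tree, 1500, seed = 9)
  dm <- k2p_distance_matrix(seqs)
  est <- nj_tree(dm, sequences = seqs, bootstrap_n = 100, seed = 1)
  a_tips <- paste0("a", 1:4)
  mrca_sub <- ape::keep.tip(est, a_tips)
  expect_equal(sort(mrca_sub$tip.label), sort(a_tips))
  expect_true(any(est$node.label >= 99))
})

test_that("genotype PCA separates clusters and obeys spectral properties", {
  set.seed(12)
  m <- 300
  p1 <- runif(m, 0.05, 0.95); p2 <- runif(m, 0.05, 0.95)
  c1 <- matrix(rbinom(8 * m, 2, rep(p1, each = 8)), nrow = 8)
  c2 <- matrix(rbinom(8 * m, 2, rep(p2, each = 8)), nrow = 8)
  gm <- make_gm(rbind(c1, c2), pos = sort(sample.int(1e6, m)),
                populations = rep(c("H", "S"), each = 8))
  pca <- genotype_pca(gm, 4)
  pc1 <- pca$scores[, 1]
  expect_true(all(pc1[1:8] * mean(pc1[1:8]) > 0) &&
                all(pc1[9:16] * mean(pc1[9:16]) > 0) &&
                sign(mean(pc1[1:8])) != sign(mean(pc1[9:16])))
  expect_true(all(diff(pca$var_frac) <= 1e-12))
  expect_lte(sum(pca$var_frac), 1 + 1e-12)
  # duplicated sample -> identical scores
  gm_dup <- make_gm(rbind(c1[1, ], c1[1, ], c2[1:3, ]),
                    pos = sort(sample.int(1e6, m)))
  pd <- genotype_pca(gm_dup, 2)
  expect_equal(pd$scores[1, ], pd$scores[2, ], tolerance = 1e-9)
  # monomorphic-only input is an error
  expect_error(genotype_pca(make_gm(matrix(0L, 3, 5))), "monomorphic")
})

test_that("membership assignment applies the strict 0.7 rule", {
  q <- rbind(s1 = c(0.8, 0.1, 0.1),
             s2 = c(0.6, 0.3, 0.1),
             s3 = c(0.7, 0.2, 0.1))
  colnames(q) <- c("Q1", "Q2", "Q3")
  mem <- assign_membership(q)
  expect_equal(unname(mem), c("Q1", "mixed", "mixed"))
  expect_error(assign_membership(rbind(s1 = c(0.5, 0.2))), "sum")
})
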