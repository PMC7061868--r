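IUPAC_HET <- c(AC = "M", CA = "M", AG = "R", GA = "R", AT = "W", TA = "W",
               CG = "S", GC = "S", CT = "Y", TC = "Y", GT = "K", TG = "K")

#' Convert genotypes to pseudo-sequences
#'
#' Bridges the SNP matrix to nucleotide-distance models: per sample, one
#' base per SNP column.  Heterozygotes are resolved by `het_policy`:
#' `"random"` draws one allele (reproducible given `seed`);
#' `"iupac"` writes the ambiguity code, which the distance computation
#' treats as a gap.  Missing calls become `-` and are excluded pairwise.
#'
#' @param gm A [genotype_matrix()].
#' @param het_policy `"random"` or `"iupac"`.
#' @param seed Seed for the random-allele policy.
#' @return Named character vector of equal-length sequences.
#' @export
genotypes_to_sequences <- function(gm, het_policy = c("random", "iupac"),
                                   seed = 1) {
  het_policy <- match.arg(het_policy)
  m <- n_sites(gm)
  n <- n_samples(gm)
  ref <- gm$sites$ref; alt <- gm$sites$alt
  chars <- matrix("-", nrow = n, ncol = m)
  refm <- matrix(ref, nrow = n, ncol = m, byrow = TRUE)
  altm <- matrix(alt, nrow = n, ncol = m, byrow = TRUE)
  hom_ref <- which(gm$calls == 0L)
  hom_alt <- which(gm$calls == 2L)
  chars[hom_ref] <- refm[hom_ref]
  chars[hom_alt] <- altm[hom_alt]
  het <- which(gm$calls == 1L)
  if (length(het)) {
    if (het_policy == "random") {
      set.seed(seed)
      pick_alt <- runif(length(het)) < 0.5
      chars[het] <- ifelse(pick_alt, altm[het], refm[het])
    } else {
      chars[het] <- IUPAC_HET[paste0(refm[het], altm[het])]
    }
  }
  setNames(apply(chars, 1, paste, collapse = ""), gm$samples)
}

#' Kimura two-parameter distance matrix
#'
#' For each sequence pair, transitions (P) and transversions (Q) are
#' counted over columns where both sequences carry an unambiguous base
#' (pairwise deletion), and
#' `d = -1/2 ln[(1 - 2P - Q) sqrt(1 - 2Q)]` substitutions per site.
#' Saturated pairs (`1 - 2P - Q <= 0` or `1 - 2Q <= 0`) are undefined
#' (`NA`) and flagged.
#'
#' @param sequences Named character vector of equal-length sequences.
#' @return Symmetric numeric matrix with zero diagonal and attribute
#'   `saturated` (two-column matrix of label pairs with undefined
#'   distances).
#' @export
k2p_distance_matrix <- function(sequences) {
  n <- length(sequences)
  stopifnot(n >= 2)
  lens <- nchar(sequences)
  if (length(unique(lens)) != 1) stop("sequences must have equal length")
  labs <- names(sequences)
  if (is.null(labs)) labs <- paste0("seq", seq_len(n))
  chars <- do.call(rbind, strsplit(toupper(sequences), ""))
  valid <- chars %in% c("A", "C", "G", "T")
  dim(valid) <- dim(chars)
  purine <- chars == "A" | chars == "G"
  d <- matrix(0, n, n, dimnames = list(labs, labs))
  sat <- NULL
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ok <- valid[i, ] & valid[j, ]
      L <- sum(ok)
      if (L == 0) { d[i, j] <- d[j, i] <- NA; next }
      diff <- ok & chars[i, ] != chars[j, ]
      ts <- sum(diff & (purine[i, ] == purine[j, ]))
      tv <- sum(diff) - ts
      P <- ts / L; Q <- tv / L
      w1 <- 1 - 2 * P - Q; w2 <- 1 - 2 * Q
      if (w1 <= 0 || w2 <= 0) {
        d[i, j] <- d[j, i] <- NA
        sat <- rbind(sat, c(labs[i], labs[j]))
      } else {
        d[i, j] <- d[j, i] <- -0.5 * log(w1 * sqrt(w2))
      }
    }
  }
  attr(d, "saturated") <- sat
  d
}

#' Neighbour-joining tree with optional bootstrap support
#'
#' Standard Saitou-Nei agglomeration (via [ape::nj()]) on a distance
#' matrix; exact on additive distances.  When `bootstrap_n > 0`,
#' alignment columns are resampled with replacement, the K2P distances
#' and tree are recomputed, and support is the percentage of replicate
#' trees containing each split, attached as internal-node labels.
#'
#' @param dm Symmetric distance matrix (e.g. [k2p_distance_matrix()]).
#' @param sequences Sequences used to rebuild distances for the
#'   bootstrap; required when `bootstrap_n > 0`.
#' @param bootstrap_n Number of bootstrap replicates (0 = none).
#' @param seed Seed for column resampling.
#' @return An unrooted `phylo` tree; with bootstrap, node labels hold
#'   support percentages.
#' @export
nj_tree <- function(dm, sequences = NULL, bootstrap_n = 0, seed = 1) {
  stopifnot(nrow(dm) >= 3)
  if (any(is.na(dm))) {
    bad <- which(is.na(dm) & upper.tri(dm), arr.ind = TRUE)
    stop("undefined distances for pair(s): ",
         paste(rownames(dm)[bad[, 1]], colnames(dm)[bad[, 2]],
               sep = "-", collapse = ", "))
  }
  tree <- ape::nj(stats::as.dist(dm))
  if (bootstrap_n > 0) {
    stopifnot(!is.null(sequences))
    chars <- do.call(rbind, strsplit(toupper(sequences), ""))
    set.seed(seed)
    reps <- vector("list", bootstrap_n)
    for (b in seq_len(bootstrap_n)) {
      cols <- sample.int(ncol(chars), replace = TRUE)
      seqs_b <- setNames(apply(chars[, cols, drop = FALSE], 1, paste,
                               collapse = ""), names(sequences))
      db <- k2p_distance_matrix(seqs_b)
      db[is.na(db)] <- max(db, na.rm = TRUE) * 2  # saturation fallback
      reps[[b]] <- ape::nj(stats::as.dist(db))
    }
    cl <- ape::prop.clades(tree, reps, rooted = FALSE)
    cl[is.na(cl)] <- 0
    tree$node.label <- round(100 * cl / bootstrap_n)
  }
  tree
}

#' Genotype principal component analysis
#'
#' Monomorphic sites are dropped; genotype codes are centred per site and
#' scaled by `sqrt(p(1-p))` with `p` the observed alternate-allele
#' frequency (the convention of standard population-structure PCA);
#' missing calls are mean-imputed.  Scores come from the singular value
#' decomposition of the standardized matrix.
#'
#' @param gm A [genotype_matrix()].
#' @param n_components Number of components to return.
#' @return List of class `genotype_pca`: `scores` (samples x components),
#'   `var_frac` (non-increasing variance fractions, sum <= 1),
#'   `n_sites_used`.
#' @export
genotype_pca <- function(gm, n_components = 3) {
  stopifnot(n_samples(gm) >= 2)
  X <- gm$calls
  p <- colMeans(X, na.rm = TRUE) / 2
  poly <- !is.na(p) & p > 0 & p < 1
  if (!any(poly)) stop("all sites are monomorphic")
  X <- X[, poly, drop = FALSE]
  p <- p[poly]
  mu <- 2 * p
  for (j in seq_len(ncol(X))) {
    miss <- is.na(X[, j])
    if (any(miss)) X[miss, j] <- mu[j]
  }
  Xs <- sweep(sweep(X, 2, mu, "-"), 2, sqrt(p * (1 - p)), "/")
  sv <- svd(Xs)
  k <- min(n_components, length(sv$d))
  scores <- sv$u[, seq_len(k), drop = FALSE] %*% diag(sv$d[seq_len(k)],
                                                      nrow = k)
  rownames(scores) <- gm$samples
  colnames(scores) <- paste0("PC", seq_len(k))
  structure(list(scores = scores,
                 var_frac = sv$d[seq_len(k)]^2 / sum(sv$d^2),
                 n_sites_used = ncol(X)),
            class = "genotype_pca")
}

#' Assign samples to clusters from admixture proportions
#'
#' A sample is assigned to its argmax cluster only when the maximum
#' membership proportion strictly exceeds `threshold`; otherwise it is
#' `"mixed"`.
#'
#' @param q_matrix Numeric matrix or data frame, samples in rows and
#'   clusters in columns; each row must sum to 1 within `tol`.
#' @param threshold Membership threshold (default 0.7, strict).
#' @param tol Row-sum tolerance.
#' @return Named character vector: cluster name or `"mixed"` per sample.
#' @export
assign_membership <- function(q_matrix, threshold = 0.7, tol = 0.01) {
  q <- as.matrix(q_matrix)
  if (is.null(colnames(q))) colnames(q) <- paste0("Q", seq_len(ncol(q)))
  if (is.null(rownames(q))) rownames(q) <- paste0("sample", seq_len(nrow(q)))
  bad <- abs(rowSums(q) - 1) > tol
  if (any(bad)) {
    stop("membership rows do not sum to 1: ",
         paste(rownames(q)[bad], collapse = ", "))
  }
  best <- max.col(q, ties.method = "first")
  out <- ifelse(q[cbind(seq_len(nrow(q)), best)] > threshold,
                colnames(q)[best], "mixed")
  setNames(out, rownames(q))
}

#' Read an admixture-proportion (Q) matrix from TSV
#'
#' First column sample ID, remaining numeric columns cluster proportions;
#' a header row is expected.
#'
#' @param path Path to the TSV.
#' @return Numeric matrix with sample rownames.
#' @export
read_qmatrix <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  q <- as.matrix(tab[, -1, drop = FALSE])
  rownames(q) <- tab[[1]]
  q
}

#' Write a distance matrix in square PHYLIP format
#' @param dm Symmetric distance matrix with dimnames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_phylip <- function(dm, path) {
  con <- file(path, "wt")
  on.exit(close(con))
  writeLines(format(nrow(dm)), con)
  labs <- sprintf("%-10s", rownames(dm))
  for (i in seq_len(nrow(dm))) {
    writeLines(paste(labs[i],
                     paste(sprintf("%.6f", dm[i, ]), collapse = " ")),
               con)
  }
  invisible(path)
}
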