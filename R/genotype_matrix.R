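#' Construct a genotype matrix
#'
#' The central in-memory container of the package: a cohort of diploid
#' samples typed at an ordered set of biallelic SNP sites.  Calls count
#' alternate-allele copies (0 = reference homozygote, 1 = heterozygote,
#' 2 = alternate homozygote, `NA` = missing).
#'
#' @param calls Integer matrix, samples in rows and sites in columns, with
#'   entries in `{0, 1, 2, NA}`.
#' @param sites Data frame with columns `chrom`, `pos` (1-based), `ref`,
#'   `alt`; one row per column of `calls`.  Positions must be strictly
#'   increasing within a chromosome (rows are sorted if not).
#' @param samples Character vector of sample IDs, one per row of `calls`.
#' @param populations Named character vector mapping sample ID to a
#'   population label; samples not named default to `"unassigned"`.
#'
#' @return An object of class `genotype_matrix`: a list with elements
#'   `samples`, `populations`, `sites` and `calls`.
#' @export
genotype_matrix <- function(calls, sites, samples = rownames(calls),
                            populations = NULL) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  if (is.null(samples)) {
    samples <- paste0("sample", seq_len(nrow(calls)))
  }
  samples <- as.character(samples)
  stopifnot(nrow(calls) == length(samples))
  sites <- as.data.frame(sites, stringsAsFactors = FALSE)
  stopifnot(all(c("chrom", "pos", "ref", "alt") %in% names(sites)))
  sites$chrom <- as.character(sites$chrom)
  sites$pos <- as.integer(sites$pos)
  sites$ref <- toupper(as.character(sites$ref))
  sites$alt <- toupper(as.character(sites$alt))
  if (ncol(calls) != nrow(sites)) {
    stop("calls has ", ncol(calls), " columns but sites has ",
         nrow(sites), " rows")
  }
  if (nrow(sites) > 0) {
    bad <- !(sites$ref %in% c("A", "C", "G", "T")) |
      !(sites$alt %in% c("A", "C", "G", "T")) | sites$ref == sites$alt
    if (any(bad)) {
      stop("non-biallelic-SNP site(s) at rows: ",
           paste(utils::head(which(bad), 5), collapse = ", "))
    }
    ## sort by chromosome (order of first appearance) then position
    chrom_f <- factor(sites$chrom, levels = unique(sites$chrom))
    ord <- order(chrom_f, sites$pos)
    if (is.unsorted(ord)) {
      sites <- sites[ord, , drop = FALSE]
      calls <- calls[, ord, drop = FALSE]
    }
    dup <- unlist(tapply(sites$pos, factor(sites$chrom,
                                           levels = unique(sites$chrom)),
                         function(p) duplicated(p)), use.names = FALSE)
    if (any(dup)) stop("duplicated positions within a chromosome")
  }
  if (length(calls) > 0 && any(!is.na(calls))) {
    rng <- range(calls, na.rm = TRUE)
    if (rng[1] < 0 || rng[2] > 2) stop("calls must be in {0, 1, 2, NA}")
  }
  pops <- rep("unassigned", length(samples))
  names(pops) <- samples
  if (!is.null(populations)) {
    unknown <- setdiff(names(populations), samples)
    if (length(unknown)) {
      stop("population labels given for samples absent from the matrix: ",
           paste(unknown, collapse = ", "))
    }
    pops[names(populations)] <- as.character(populations)
  }
  rownames(calls) <- samples
  rownames(sites) <- NULL
  structure(list(samples = samples, populations = pops,
                 sites = sites, calls = calls),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  tab <- table(x$populations)
  cat("genotype_matrix: ", length(x$samples), " samples x ",
      nrow(x$sites), " biallelic SNP sites\n", sep = "")
  cat("populations: ",
      paste(names(tab), tab, sep = "=", collapse = ", "), "\n", sep = "")
  if (nrow(x$sites)) {
    cat("chromosomes: ", paste(unique(x$sites$chrom), collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}

#' Number of sites / samples in a genotype matrix
#' @param gm A [genotype_matrix()].
#' @return Integer count.
#' @export
n_sites <- function(gm) nrow(gm$sites)

#' @rdname n_sites
#' @export
n_samples <- function(gm) length(gm$samples)

#' Row indices of the samples belonging to a population
#' @param gm A [genotype_matrix()].
#' @param population Population label to look up.
#' @return Integer vector of row indices into `gm$calls`.
#' @export
pop_index <- function(gm, population) {
  idx <- which(gm$populations == population)
  if (!length(idx)) stop("no samples labelled '", population, "'")
  unname(idx)
}

#' Subset a genotype matrix by site index
#' @param gm A [genotype_matrix()].
#' @param idx Integer or logical index over sites.
#' @return A `genotype_matrix` restricted to the selected sites.
#' @export
subset_sites <- function(gm, idx) {
  genotype_matrix(gm$calls[, idx, drop = FALSE],
                  gm$sites[idx, , drop = FALSE],
                  samples = gm$samples,
                  populations = gm$populations)
}

## Per-site allele / genotype counts for a sample subset.
## Returns alt-allele count (ac), non-missing allele copies (an),
## heterozygote count (het) and non-missing genotype count (nm).
pop_site_counts <- function(calls, rows) {
  sub <- calls[rows, , drop = FALSE]
  nm <- colSums(!is.na(sub))
  ac <- colSums(sub, na.rm = TRUE)
  het <- colSums(sub == 1L, na.rm = TRUE)
  list(ac = ac, an = 2L * nm, het = het, nm = nm)
}
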