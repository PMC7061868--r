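#' Read a population map
#'
#' Two-column headerless TSV: sample ID, population label.
#'
#' @param path Path to the TSV file.
#' @return Named character vector mapping sample to label.
#' @export
read_popmap <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE,
                           col.names = c("sample", "population"))
  setNames(as.character(tab$population), as.character(tab$sample))
}

#' Write a population map
#' @param populations Named character vector (sample -> label).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_popmap <- function(populations, path) {
  utils::write.table(data.frame(sample = names(populations),
                                population = unname(populations)),
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read biallelic SNP genotypes from a VCF file
#'
#' Parses a VCF (v4.2) with vcfR, drops multi-allelic and non-SNP records
#' with a message, and returns a [genotype_matrix()].  Genotypes are read
#' from the GT field; phased and unphased separators are treated alike and
#' any genotype containing `.` is coded missing.
#'
#' @param path Path to a VCF file (plain or gzipped).
#' @param popmap Optional population map: a named character vector as
#'   returned by [read_popmap()], or a path to a two-column TSV.  Samples
#'   not covered are labelled `"unassigned"`; popmap samples absent from
#'   the VCF are an error.
#' @return A [genotype_matrix()].
#' @export
read_vcf <- function(path, popmap = NULL) {
  if (!file.exists(path)) stop("VCF file not found: ", path)
  vcf <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
                  error = function(e) {
                    stop("failed to parse VCF '", path, "': ",
                         conditionMessage(e), call. = FALSE)
                  })
  samples <- colnames(vcf@gt)[-1]
  if (is.null(samples)) samples <- character(0)
  fix <- vcf@fix
  n_rec <- nrow(fix)
  if (is.null(n_rec)) n_rec <- 0L
  if (n_rec > 0) {
    ref <- toupper(fix[, "REF"])
    alt <- toupper(fix[, "ALT"])
    snp <- ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
    n_drop <- sum(!snp)
    if (n_drop > 0) {
      message("read_vcf: dropped ", n_drop,
              " multi-allelic or non-SNP record(s)")
    }
    fix <- fix[snp, , drop = FALSE]
    gt <- vcf@gt[snp, -1, drop = FALSE]
    ## GT is the first colon-separated field
    gt_field <- matrix(gsub("|", "/", sub(":.*$", "", gt), fixed = TRUE),
                       nrow = nrow(gt), ncol = ncol(gt))
    code <- matrix(NA_integer_, nrow = nrow(gt_field), ncol = ncol(gt_field))
    code[gt_field == "0/0"] <- 0L
    code[gt_field == "0/1" | gt_field == "1/0"] <- 1L
    code[gt_field == "1/1"] <- 2L
    calls <- t(code)
    sites <- data.frame(chrom = fix[, "CHROM"],
                        pos = as.integer(fix[, "POS"]),
                        ref = toupper(fix[, "REF"]),
                        alt = toupper(fix[, "ALT"]),
                        stringsAsFactors = FALSE)
  } else {
    calls <- matrix(integer(0), nrow = length(samples), ncol = 0)
    sites <- data.frame(chrom = character(0), pos = integer(0),
                        ref = character(0), alt = character(0))
  }
  pops <- NULL
  if (!is.null(popmap)) {
    if (is.character(popmap) && length(popmap) == 1 && is.null(names(popmap))) {
      popmap <- read_popmap(popmap)
    }
    absent <- setdiff(names(popmap), samples)
    if (length(absent)) {
      stop("popmap sample(s) absent from VCF: ",
           paste(absent, collapse = ", "))
    }
    pops <- popmap
  }
  genotype_matrix(calls, sites, samples = samples, populations = pops)
}

#' Write a genotype matrix as plain-text VCF v4.2
#'
#' Emits a minimal sites+GT VCF that round-trips exactly through
#' [read_vcf()].  Missing genotypes are written as `./.`.
#'
#' @param gm A [genotype_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gm, path) {
  con <- tryCatch(file(path, open = "wt"),
                  error = function(e) stop("cannot write '", path, "': ",
                                           conditionMessage(e), call. = FALSE))
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=popsweep",
               paste0("##FORMAT=<ID=GT,Number=1,Type=String,",
                      "Description=\"Genotype\">")), con)
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                     "FILTER", "INFO", "FORMAT", gm$samples),
                   collapse = "\t"), con)
  m <- n_sites(gm)
  if (m > 0) {
    gt_str <- matrix(".", nrow = nrow(gm$calls), ncol = m)
    gt_str[] <- c("0/0", "0/1", "1/1")[gm$calls + 1L]
    gt_str[is.na(gm$calls)] <- "./."
    body <- vapply(seq_len(m), function(j) {
      paste(c(gm$sites$chrom[j], gm$sites$pos[j], ".",
              gm$sites$ref[j], gm$sites$alt[j], ".", "PASS", ".",
              "GT", gt_str[, j]), collapse = "\t")
    }, character(1))
    writeLines(body, con)
  }
  invisible(path)
}

#' Site filter configuration
#'
#' Defaults follow common resequencing practice for cohort SNP panels:
#' minor allele frequency strictly greater than 0.05, at least half of the
#' samples genotyped ("loci integrity"), and no more than two SNPs in any
#' 5-bp window.
#'
#' @param min_maf Minimum minor allele frequency (exclusive), in `[0, 0.5)`.
#' @param min_integrity Minimum fraction of non-missing genotypes
#'   (inclusive), in `[0, 1]`.
#' @param cluster_window_bp Width of the SNP-cluster window in bp.
#' @param cluster_max_snps Maximum SNPs tolerated in any such window.
#' @return An object of class `site_filter_config`.
#' @export
site_filter_config <- function(min_maf = 0.05, min_integrity = 0.5,
                               cluster_window_bp = 5L,
                               cluster_max_snps = 2L) {
  stopifnot(min_maf >= 0, min_maf < 0.5,
            min_integrity >= 0, min_integrity <= 1,
            cluster_window_bp >= 1, cluster_max_snps >= 1)
  structure(list(min_maf = min_maf, min_integrity = min_integrity,
                 cluster_window_bp = as.integer(cluster_window_bp),
                 cluster_max_snps = as.integer(cluster_max_snps)),
            class = "site_filter_config")
}

#' Filter sites of a genotype matrix
#'
#' Applies, in order of attribution, the minor-allele-frequency rule
#' (MAF strictly greater than `min_maf`, computed on non-missing alleles),
#' the integrity rule (fraction of non-missing genotypes at least
#' `min_integrity`) and the SNP-cluster rule (every SNP inside any
#' `cluster_window_bp`-bp span holding more than `cluster_max_snps` SNPs
#' is removed — the whole cluster, not just the excess, which makes the
#' filter deterministic and idempotent).  Cluster windows are evaluated on
#' the full input site list.
#'
#' @param gm A [genotype_matrix()].
#' @param cfg A [site_filter_config()].
#' @return A list with elements `gm` (the filtered matrix) and `report`
#'   (data frame of per-rule removal counts plus input/retained totals).
#' @export
filter_sites <- function(gm, cfg = site_filter_config()) {
  stopifnot(inherits(gm, "genotype_matrix"),
            inherits(cfg, "site_filter_config"))
  m <- n_sites(gm)
  if (m == 0) {
    report <- data.frame(rule = c("maf", "integrity", "cluster"),
                         removed = c(0L, 0L, 0L))
    return(list(gm = gm, report = rbind(report,
      data.frame(rule = c("input", "retained"), removed = c(0L, 0L)))))
  }
  cnt <- pop_site_counts(gm$calls, seq_len(n_samples(gm)))
  p <- ifelse(cnt$an > 0, cnt$ac / cnt$an, NA_real_)
  maf <- pmin(p, 1 - p)
  integrity <- cnt$nm / n_samples(gm)
  fails_maf <- is.na(maf) | maf <= cfg$min_maf
  fails_int <- integrity < cfg$min_integrity

  ## cluster rule on the full input site list, per chromosome
  fails_clu <- logical(m)
  for (chr in unique(gm$sites$chrom)) {
    idx <- which(gm$sites$chrom == chr)
    pos <- gm$sites$pos[idx]
    hi <- findInterval(pos + cfg$cluster_window_bp - 1L, pos)
    n_in <- hi - seq_along(pos) + 1L
    bad <- which(n_in > cfg$cluster_max_snps)
    if (length(bad)) {
      marked <- unique(unlist(lapply(bad, function(i) i:hi[i])))
      fails_clu[idx[marked]] <- TRUE
    }
  }

  rm_maf <- fails_maf
  rm_int <- fails_int & !fails_maf
  rm_clu <- fails_clu & !fails_maf & !fails_int
  keep <- !(rm_maf | rm_int | rm_clu)
  report <- data.frame(
    rule = c("maf", "integrity", "cluster", "input", "retained"),
    removed = c(sum(rm_maf), sum(rm_int), sum(rm_clu), m, sum(keep)))
  list(gm = subset_sites(gm, keep), report = report)
}

#' Per-sample heterozygosity percentage
#'
#' `H (%) = 100 * (number of heterozygous calls) / (number of non-missing
#' calls)` per sample, optionally restricted to one genomic window (used
#' for scanning heterozygosity across candidate sweep regions).
#'
#' @param gm A [genotype_matrix()].
#' @param chrom,start,end Optional window restriction (1-based inclusive).
#' @return Named numeric vector of percentages; `NA` for a sample with no
#'   non-missing call in scope.
#' @export
sample_heterozygosity <- function(gm, chrom = NULL, start = NULL,
                                  end = NULL) {
  stopifnot(inherits(gm, "genotype_matrix"), n_sites(gm) > 0)
  calls <- gm$calls
  if (!is.null(chrom)) {
    sel <- gm$sites$chrom == chrom
    if (!is.null(start)) sel <- sel & gm$sites$pos >= start
    if (!is.null(end)) sel <- sel & gm$sites$pos <= end
    calls <- calls[, sel, drop = FALSE]
  }
  nm <- rowSums(!is.na(calls))
  het <- rowSums(calls == 1L, na.rm = TRUE)
  out <- ifelse(nm > 0, 100 * het / nm, NA_real_)
  setNames(out, gm$samples)
}

#' Variant density per kb
#'
#' @param count Number of variants.
#' @param span_kb Span in kilobases; must be positive.
#' @param decimals Decimal places for half-up rounding.
#' @return Density per kb, rounded half-up.
#' @export
variant_density <- function(count, span_kb, decimals = 1) {
  if (any(span_kb <= 0)) stop("span_kb must be positive")
  round_half_up(count / span_kb, decimals)
}

#' Write a site-filter report as TSV
#' @param report Report data frame from [filter_sites()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_filter_report <- function(report, path) {
  utils::write.table(report, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
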