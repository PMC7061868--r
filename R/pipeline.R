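#' Percentage of a whole
#'
#' `100 * part / whole`, rounded half-up at `decimals`.
#'
#' @param part,whole Quantities; `whole` must be positive.
#' @param decimals Decimal places.
#' @return The percentage.
#' @export
percent_of <- function(part, whole, decimals = 2) {
  if (any(whole <= 0)) stop("whole must be positive")
  round_half_up(100 * part / whole, decimals)
}

#' Pipeline configuration
#'
#' Collects input paths, population labels and stage parameters for
#' [run_pipeline()].  Can also be loaded from a YAML or JSON file with
#' [read_pipeline_config()].
#'
#' @param vcf,popmap,chrom_lengths Paths to the cohort VCF, the
#'   two-column popmap TSV and the chromosome-length TSV (header columns
#'   `chrom`, `length`).
#' @param gff,pathway_map,q_matrix Optional paths: GFF3 gene models,
#'   gene-to-pathway TSV, admixture-proportion TSV.
#' @param out_dir Output directory.
#' @param pop_a,pop_b Population labels (defaults `"H"`, `"S"`).
#' @param window_size_bp,window_step_bp Scan window geometry.
#' @param min_maf,min_integrity,cluster_window_bp,cluster_max_snps Site
#'   filter parameters (see [site_filter_config()]).
#' @param alpha,n_perm,fst_fraction,fst_threshold,merge_gap_bp,min_snps,
#'   sweep_operator Sweep-scan parameters; when `fst_threshold` is not
#'   `NA` it replaces the top-fraction FST rule.
#' @param ld_max_distance_kb,ld_bin_width_kb,ld_n_perm LD parameters.
#' @param bootstrap_n Tree bootstrap replicates.
#' @param membership_threshold Cluster-assignment threshold.
#' @param seed Master seed recorded in the manifest and used by every
#'   stochastic stage.
#' @param stages Character vector of stages to run, any of `"filter"`,
#'   `"stats"`, `"sweep"`, `"ld"`, `"tree"`, `"pca"`, `"enrich"`,
#'   `"membership"`.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(vcf, popmap, chrom_lengths,
                            gff = NULL, pathway_map = NULL,
                            q_matrix = NULL,
                            out_dir = "popsweep_out",
                            pop_a = "H", pop_b = "S",
                            window_size_bp = 100000,
                            window_step_bp = 10000,
                            min_maf = 0.05, min_integrity = 0.5,
                            cluster_window_bp = 5, cluster_max_snps = 2,
                            alpha = 0.05, n_perm = 100,
                            fst_fraction = 0.05, fst_threshold = NA,
                            merge_gap_bp = window_step_bp,
                            min_snps = 10,
                            sweep_operator = "and",
                            ld_max_distance_kb = 1000,
                            ld_bin_width_kb = 10, ld_n_perm = 200,
                            bootstrap_n = 100,
                            membership_threshold = 0.7,
                            seed = 1,
                            stages = c("filter", "stats", "sweep", "ld",
                                       "tree", "pca", "enrich",
                                       "membership")) {
  cfg <- mget(names(formals()))  # stable ordering for the manifest
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from YAML or JSON
#'
#' Keys mirror the arguments of [pipeline_config()].
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  vals <- if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    stop("config must be .yaml, .yml or .json")
  }
  do.call(pipeline_config, vals)
}

#' Run the full analysis pipeline
#'
#' Executes site filtering, windowed statistics, the sweep scan, LD
#' decay, the NJ tree, PCA, enrichment and membership assignment (each
#' stage skippable via `cfg$stages`), writing TSV/BED/Newick/JSON outputs
#' plus a `manifest.json` recording the package version, parameters,
#' seeds and per-stage row counts.  Re-running with an identical
#' configuration reproduces every output byte for byte.
#'
#' @param cfg A [pipeline_config()].
#' @return Invisibly, a list with the manifest and the paths written.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  required <- c(vcf = cfg$vcf, popmap = cfg$popmap,
                chroms = cfg$chrom_lengths)
  optional <- unlist(list(gff = cfg$gff, pathway_map = cfg$pathway_map,
                          q_matrix = cfg$q_matrix))
  if (is.null(optional)) optional <- character(0)
  missing_in <- required[!file.exists(required)]
  if (length(missing_in)) {
    stop("missing input file(s): ",
         paste(names(missing_in), missing_in, sep = "=",
               collapse = ", "))
  }
  missing_opt <- optional[!is.na(optional) & !file.exists(optional)]
  if (length(missing_opt)) {
    stop("missing input file(s): ",
         paste(names(missing_opt), missing_opt, sep = "=",
               collapse = ", "))
  }
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  counts <- list()
  n_warnings <- 0L
  note <- function(stage) message("[popsweep] stage: ", stage)

  popmap <- read_popmap(cfg$popmap)
  gm <- read_vcf(cfg$vcf, popmap)
  counts$input_sites <- n_sites(gm)
  counts$input_samples <- n_samples(gm)
  cl_tab <- utils::read.table(cfg$chrom_lengths, header = TRUE,
                              sep = "\t", stringsAsFactors = FALSE)
  chrom_lengths <- setNames(cl_tab$length, cl_tab$chrom)

  if ("filter" %in% cfg$stages) {
    note("filter")
    fl <- filter_sites(gm, site_filter_config(cfg$min_maf,
                                              cfg$min_integrity,
                                              cfg$cluster_window_bp,
                                              cfg$cluster_max_snps))
    gm <- fl$gm
    paths$filter_report <- file.path(cfg$out_dir, "filter_report.tsv")
    write_filter_report(fl$report, paths$filter_report)
    counts$filtered_sites <- n_sites(gm)
    het <- sample_heterozygosity(gm)
    paths$heterozygosity <- file.path(cfg$out_dir, "heterozygosity.tsv")
    utils::write.table(data.frame(sample = names(het),
                                  heterozygosity_pct = unname(het)),
                       paths$heterozygosity, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }

  windows <- make_windows(chrom_lengths,
                          window_spec(cfg$window_size_bp,
                                      cfg$window_step_bp))
  stats <- NULL
  if ("stats" %in% cfg$stages || "sweep" %in% cfg$stages) {
    note("stats")
    stats <- window_stats(gm, windows, cfg$pop_a, cfg$pop_b,
                          min_snps = cfg$min_snps)
    paths$window_stats <- file.path(cfg$out_dir, "window_stats.tsv")
    write_window_stats(stats, paths$window_stats)
    counts$windows <- nrow(stats)
  }

  regions <- list()
  if ("sweep" %in% cfg$stages) {
    note("sweep")
    cutoff <- permutation_cutoff(gm, windows, cfg$pop_a, cfg$pop_b,
                                 n_perm = cfg$n_perm, alpha = cfg$alpha,
                                 seed = cfg$seed,
                                 min_snps = cfg$min_snps)
    fst_rule <- if (!is.na(cfg$fst_threshold)) {
      list(type = "threshold", value = cfg$fst_threshold)
    } else {
      list(type = "top_fraction", fraction = cfg$fst_fraction)
    }
    cand <- call_candidate_windows(stats, cutoff, fst_rule,
                                   operator = cfg$sweep_operator)
    genes <- NULL
    if (!is.null(cfg$gff)) genes <- read_gff3_genes(cfg$gff)
    for (pop in names(cand)) {
      reg <- merge_regions(cand[[pop]], cfg$merge_gap_bp, pop)
      if (!is.null(genes) && nrow(reg)) {
        reg <- withCallingHandlers(annotate_regions(reg, genes),
          warning = function(w) {
            n_warnings <<- n_warnings + 1L
            invokeRestart("muffleWarning")
          })
      }
      regions[[pop]] <- reg
      tag <- paste0("sweep_regions_", pop)
      paths[[tag]] <- file.path(cfg$out_dir, paste0(tag, ".tsv"))
      utils::write.table(reg, paths[[tag]], sep = "\t", quote = FALSE,
                         row.names = FALSE)
      paths[[paste0(tag, "_bed")]] <-
        file.path(cfg$out_dir, paste0(tag, ".bed"))
      write_regions_bed(reg, paths[[paste0(tag, "_bed")]])
      counts[[paste0("regions_", pop)]] <- nrow(reg)
    }
    counts$ratio_cutoff <- as.numeric(cutoff)
  }

  if ("enrich" %in% cfg$stages && !is.null(cfg$pathway_map) &&
      length(regions) && !is.null(cfg$gff)) {
    note("enrich")
    genes <- read_gff3_genes(cfg$gff)
    pm <- utils::read.table(cfg$pathway_map, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE)
    for (pop in names(regions)) {
      reg <- regions[[pop]]
      gset <- if (nrow(reg) && "genes" %in% names(reg)) {
        unique(unlist(strsplit(reg$genes[nzchar(reg$genes)], ",")))
      } else character(0)
      enr <- enrich_hypergeometric(gset, genes$gene_id, pm)
      tag <- paste0("enrichment_", pop)
      paths[[tag]] <- file.path(cfg$out_dir, paste0(tag, ".tsv"))
      utils::write.table(enr, paths[[tag]], sep = "\t", quote = FALSE,
                         row.names = FALSE)
      counts[[tag]] <- nrow(enr)
    }
  }

  if ("ld" %in% cfg$stages) {
    note("ld")
    for (pop in c(cfg$pop_a, cfg$pop_b)) {
      prs <- pairwise_r2(gm, pop, cfg$ld_max_distance_kb)
      curve <- ld_decay_curve(prs, cfg$ld_bin_width_kb,
                              cfg$ld_max_distance_kb, pop)
      tag <- paste0("ld_curve_", pop)
      paths[[tag]] <- file.path(cfg$out_dir, paste0(tag, ".tsv"))
      write_ld_curve(curve, paths[[tag]])
      counts[[tag]] <- nrow(curve)
    }
    cmpr <- compare_ld_decay(gm, cfg$pop_a, cfg$pop_b,
                             n_perm = cfg$ld_n_perm, seed = cfg$seed,
                             max_distance_kb = cfg$ld_max_distance_kb,
                             bin_width_kb = cfg$ld_bin_width_kb)
    paths$ld_comparison <- file.path(cfg$out_dir, "ld_comparison.json")
    jsonlite::write_json(cmpr[c("statistic", "p_value",
                                "faster_population", "n_perm")],
                         paths$ld_comparison, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }

  if ("tree" %in% cfg$stages) {
    note("tree")
    seqs <- genotypes_to_sequences(gm, seed = cfg$seed)
    dm <- k2p_distance_matrix(seqs)
    paths$distances <- file.path(cfg$out_dir, "k2p_distances.phy")
    write_phylip(dm, paths$distances)
    tree <- nj_tree(dm, sequences = seqs, bootstrap_n = cfg$bootstrap_n,
                    seed = cfg$seed)
    paths$tree <- file.path(cfg$out_dir, "nj_tree.nwk")
    ape::write.tree(tree, paths$tree)
    counts$tree_tips <- length(tree$tip.label)
  }

  if ("pca" %in% cfg$stages) {
    note("pca")
    pca <- genotype_pca(gm, n_components = 3)
    paths$pca <- file.path(cfg$out_dir, "pca_scores.tsv")
    utils::write.table(
      cbind(data.frame(sample = rownames(pca$scores)),
            as.data.frame(pca$scores),
            data.frame(population = gm$populations[rownames(pca$scores)])),
      paths$pca, sep = "\t", quote = FALSE, row.names = FALSE)
    counts$pca_var_frac <- pca$var_frac
  }

  if ("membership" %in% cfg$stages && !is.null(cfg$q_matrix)) {
    note("membership")
    q <- read_qmatrix(cfg$q_matrix)
    mem <- assign_membership(q, cfg$membership_threshold)
    paths$membership <- file.path(cfg$out_dir, "membership.tsv")
    utils::write.table(data.frame(sample = names(mem),
                                  cluster = unname(mem)),
                       paths$membership, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    counts$membership <- length(mem)
  }

  manifest <- list(
    package = "popsweep",
    version = as.character(utils::packageVersion("popsweep")),
    seed = cfg$seed,
    parameters = cfg[setdiff(names(cfg), "stages")],
    stages_run = cfg$stages,
    counts = counts,
    n_warnings = n_warnings)
  paths$manifest <- file.path(cfg$out_dir, "manifest.json")
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null",
                       force = TRUE)
  invisible(list(manifest = manifest, paths = paths,
                 regions = regions))
}
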