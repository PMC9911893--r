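#' Percentage of a count, rounded half-up to one decimal
#'
#' @param part,whole Counts with \code{0 <= part <= whole}, \code{whole > 0}.
#' @return \code{100 * part / whole} rounded half-up to one decimal.
#' @export
summary_percentages <- function(part, whole) {
  if (any(whole <= 0)) stop("whole must be > 0", call. = FALSE)
  if (any(part > whole) || any(part < 0))
    stop("part must be in [0, whole]", call. = FALSE)
  floor(1000 * part / whole + 0.5) / 10
}

.default_config <- list(
  simulate = NULL, input_dir = NULL, focal_species = "MC",
  ingroup = c("MC", "MD"), ks_method = "YN00", ks_bounds = c(0.05, 1.5),
  ortholog_ks_bounds = c(0, 1.5), trough = 0.6, n_bins = 200,
  min_block_pairs = 5, max_gap = 25, evalue_max = 1e-5, tandem_window = 5,
  min_support = 0.5, min_orthogroup_genes = 4, require_outgroup = TRUE,
  min_component_n = 50, p_adj_cutoff = 0.05, q_cutoff = 0.2, seed = 1)

#' Build and validate a pipeline configuration
#'
#' Either \code{simulate} (a list of \code{\link{simulation_params}}
#' arguments) or \code{input_dir} (a directory in the layout written by
#' \code{\link{write_dataset}}) must be supplied. Unknown keys are
#' rejected. All thresholds default to the standard analysis constants:
#' Ks window (0.05, 1.5), trough 0.6, 200 bins, blocks of >= 5 anchors at
#' E-value <= 1e-5, tandem window 5, support >= 0.5, orthogroups of >= 4
#' genes, BH cutoffs 0.05/0.2.
#' @param ... Overrides of the defaults.
#' @export
pipeline_config <- function(...) {
  over <- list(...)
  if (length(over) == 1 && is.null(names(over)) && is.list(over[[1]]))
    over <- over[[1]]
  unknown <- setdiff(names(over), names(.default_config))
  if (length(unknown) > 0)
    stop(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  cfg <- utils::modifyList(.default_config, over, keep.null = TRUE)
  if (is.null(cfg$simulate) && is.null(cfg$input_dir))
    stop("config needs either 'simulate' or 'input_dir'", call. = FALSE)
  stopifnot(cfg$ks_bounds[1] < cfg$ks_bounds[2],
            cfg$trough == "auto" ||
              (cfg$trough > cfg$ks_bounds[1] && cfg$trough < cfg$ks_bounds[2]),
            cfg$min_block_pairs >= 1, cfg$n_bins >= 2,
            cfg$min_support >= 0 && cfg$min_support <= 1,
            cfg$tandem_window >= 0, cfg$evalue_max > 0)
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#' @param path YAML file of \code{\link{pipeline_config}} keys.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  pipeline_config(yaml::read_yaml(path))
}

.load_inputs <- function(cfg) {
  if (!is.null(cfg$simulate)) {
    params <- do.call(simulation_params,
                      utils::modifyList(cfg$simulate,
                                        list(seed = cfg$seed), keep.null = TRUE))
    ds <- simulate_genome(params)
    return(list(genes = ds$genes, cds = ds$cds, pairs = ds$pairs,
                trees = lapply(ds$trees, parse_tree),
                orthogroups = ds$orthogroups, tf_tables = ds$tf_tables,
                go_table = ds$go_table, dataset = ds))
  }
  dir <- cfg$input_dir
  need <- file.path(dir, c("cds.fasta", "gene_positions.tsv", "pairs.tsv",
                           "gene_trees.tsv", "orthogroups.tsv",
                           "tf_families.tsv", "go_annotations.tsv"))
  missing <- need[!file.exists(need)]
  if (length(missing) > 0)
    stop(sprintf("missing input file: %s", missing[1]), call. = FALSE)
  tf_raw <- utils::read.delim(file.path(dir, "tf_families.tsv"),
                              stringsAsFactors = FALSE)
  tf_tables <- lapply(split(tf_raw, tf_raw$species), function(x)
    x[, c("gene_id", "family")])
  list(genes = read_gene_positions(file.path(dir, "gene_positions.tsv")),
       cds = read_fasta(file.path(dir, "cds.fasta")),
       pairs = read_pairs(file.path(dir, "pairs.tsv")),
       trees = read_gene_trees(file.path(dir, "gene_trees.tsv")),
       orthogroups = utils::read.delim(file.path(dir, "orthogroups.tsv"),
                                       stringsAsFactors = FALSE),
       tf_tables = tf_tables,
       go_table = read_two_col(file.path(dir, "go_annotations.tsv"),
                               c("gene_id", "term")),
       dataset = NULL)
}

#' Run the whole WGD retention pipeline
#'
#' Executes the stages in dependency order — Ks estimation for the focal
#' genome's homolog pairs, tandem flagging and collinear-block chaining,
#' Ks-class block separation and trough-split Gaussian peak fitting,
#' gene-tree duplication-event retention with sigma/rho assignment,
#' TF-family statistics, and GO enrichment of the retained sets — writing
#' every intermediate as TSV/JSON under \code{outdir} and returning a
#' summary report. Identical config and inputs give identical outputs.
#'
#' @param config A \code{\link{pipeline_config}} (or a list/YAML path
#'   coercible to one).
#' @param outdir Output directory.
#' @return The summary report (list), invisibly written as
#'   \code{report.json}.
#' @export
run_pipeline <- function(config, outdir) {
  if (is.character(config)) config <- read_pipeline_config(config)
  if (!inherits(config, "pipeline_config")) config <- pipeline_config(config)
  cfg <- config
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  inp <- .load_inputs(cfg)
  genes <- inp$genes
  species_of <- stats::setNames(genes$species, genes$gene_id)
  focal <- cfg$focal_species
  focal_genes <- genes[genes$species == focal, , drop = FALSE]

  # stage: Ks for within-focal homolog pairs
  fp <- inp$pairs[species_of[inp$pairs$gene_a] == focal &
                    species_of[inp$pairs$gene_b] == focal, , drop = FALSE]
  ks_table <- ks_for_pairs(fp, inp$cds, method = cfg$ks_method)
  utils::write.table(ks_table, file.path(outdir, "ks.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  # stage: tandem flags + collinear blocks + Ks classes
  anchors <- anchors_from_pairs(fp, genes)
  tandem <- detect_tandem(fp, genes, window = cfg$tandem_window)
  chained <- chain_blocks(anchors, min_pairs = cfg$min_block_pairs,
                          max_gap = cfg$max_gap,
                          evalue_max = cfg$evalue_max, tandem = tandem)
  classified <- classify_blocks(
    chained, ks_table,
    young_range = c(cfg$ks_bounds[1], if (cfg$trough == "auto") 0.6 else cfg$trough),
    old_range = c(if (cfg$trough == "auto") 0.6 else cfg$trough, cfg$ks_bounds[2]))
  utils::write.table(classified$blocks, file.path(outdir, "blocks.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    classified$anchors[, c("block_id", "gene_a", "gene_b", "ks")],
    file.path(outdir, "anchors.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)

  # stage: WGD peaks from the Ks of anchors inside blocks
  block_ks <- classified$anchors$ks
  block_ks <- block_ks[!is.na(block_ks) & block_ks > cfg$ks_bounds[1] &
                         block_ks < cfg$ks_bounds[2]]
  peaks <- tryCatch(
    fit_wgd_peaks(block_ks, trough = cfg$trough, n_bins = cfg$n_bins,
                  range = cfg$ks_bounds, min_n = cfg$min_component_n),
    error = function(e) conditionMessage(e))
  if (inherits(peaks, "mixture_fit")) {
    jsonlite::write_json(
      list(components = peaks$components, trough = peaks$trough,
           n = peaks$n),
      file.path(outdir, "peaks.json"), auto_unbox = TRUE, digits = NA)
    # per-subset densities for external plotting of the fitted curves
    parts <- split_at_trough(block_ks, if (identical(cfg$trough, "auto"))
      peaks$trough else cfg$trough)
    dens <- do.call(rbind, lapply(c("young", "old"), function(k) {
      h <- ks_histogram(parts[[k]], n_bins = cfg$n_bins,
                        range = range(parts[[k]]))
      data.frame(subset = k, mid = h$mids, density = h$density)
    }))
    utils::write.table(dens, file.path(outdir, "ks_density.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  # stage: duplication events and retention
  cand <- do.call(rbind, lapply(names(inp$trees), function(og)
    find_duplication_nodes(inp$trees[[og]], og)))
  og_genes <- split(inp$orthogroups$gene_id, inp$orthogroups$orthogroup)
  events <- filter_events(cand, species_of, focal,
                          ingroup = cfg$ingroup,
                          min_genes = cfg$min_orthogroup_genes,
                          require_outgroup = cfg$require_outgroup,
                          min_support = cfg$min_support,
                          orthogroup_genes = og_genes)
  events <- drop_tandem_events(events, genes, species_of, focal,
                               window = cfg$tandem_window)
  events <- event_mean_ks(events, ks_table, species_of, focal,
                          lo = cfg$ks_bounds[1], hi = cfg$ks_bounds[2])
  events <- assign_to_wgd(events, classified, species_of, focal)
  utils::write.table(events_as_table(events), file.path(outdir, "events.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  retained <- retained_gene_sets(events, species_of, focal,
                                 total_genes = nrow(focal_genes))
  writeLines(retained$sigma, file.path(outdir, "sigma_retained.txt"))
  writeLines(retained$rho, file.path(outdir, "rho_retained.txt"))

  # stage: TF family statistics and retention table
  tf_stats <- NULL
  tf_ret <- NULL
  if (length(inp$tf_tables) > 0 && focal %in% names(inp$tf_tables)) {
    counts <- family_count_matrix(inp$tf_tables)
    tf_stats <- tryCatch(tf_family_stats(counts, focal),
                         error = function(e) NULL)
    if (!is.null(tf_stats))
      utils::write.table(tf_stats, file.path(outdir, "tf_stats.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    tf_ret <- retention_table(inp$tf_tables[[focal]], retained$sigma,
                              retained$rho)
    utils::write.table(tf_ret, file.path(outdir, "tf_retention.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  # stage: GO enrichment of retained sets
  enr <- lapply(list(sigma = retained$sigma, rho = retained$rho),
                function(set) {
                  if (length(set) == 0) return(NULL)
                  suppressWarnings(
                    enrich(set, inp$go_table,
                           p_adj_cutoff = cfg$p_adj_cutoff,
                           q_cutoff = cfg$q_cutoff))
                })
  for (nm in names(enr)) if (!is.null(enr[[nm]]))
    utils::write.table(enr[[nm]],
                       file.path(outdir, sprintf("enrichment_%s.tsv", nm)),
                       sep = "\t", quote = FALSE, row.names = FALSE)

  status_counts <- as.list(table(events$status))
  report <- list(
    config = unclass(cfg)[!vapply(unclass(cfg), is.null, logical(1))],
    n_genes_focal = nrow(focal_genes),
    n_pairs_focal = nrow(fp),
    n_ks_valid = sum(ks_table$valid),
    n_tandem_pairs = sum(tandem),
    n_blocks = nrow(classified$blocks),
    n_blocks_young = sum(classified$blocks$ks_class == "young"),
    n_blocks_old = sum(classified$blocks$ks_class == "old"),
    peaks = if (inherits(peaks, "mixture_fit"))
      list(components = peaks$components, trough = peaks$trough)
    else list(error = peaks),
    n_candidate_events = nrow(cand),
    event_status = status_counts,
    retained = retained$summary,
    tf_retention = tf_ret,
    enrichment_hits = lapply(enr, function(e)
      if (is.null(e)) 0L else sum(e$significant)),
    package_version = as.character(utils::packageVersion("wgdretain")))
  jsonlite::write_json(report, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(list(report = report, events = events, retained = retained,
                 classified = classified, ks_table = ks_table,
                 peaks = peaks, tf_stats = tf_stats, tf_retention = tf_ret,
                 enrichment = enr, dataset = inp$dataset))
}
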