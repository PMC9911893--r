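#' Parameters for the synthetic genome-evolution simulator
#'
#' Defines the study conditions the simulator emulates: a focal species and
#' a close sister that share a nested pair of whole-genome duplications
#' (younger at Ks ~ 0.27, older at Ks ~ 0.97), one or more unduplicated
#' outgroups, elevated duplicate retention in designated transcription-factor
#' families, tandem duplications, and close interspecies orthologs
#' (Ks ~ 0.02).
#'
#' @param n_species Total species count (>= 3): focal "MC", sister "MD",
#'   then outgroups "OG1", "OG2", ...
#' @param n_chromosomes Ancestral chromosome count.
#' @param genes_per_chromosome Ancestral genes per chromosome (>= 10;
#'   collinear blocks of five anchors are unreachable below that).
#' @param wgd_events List of events ordered by strictly increasing
#'   \code{ks_depth}; each a list with \code{name}, \code{ks_depth}
#'   (expected pairwise synonymous divergence of the duplicates),
#'   \code{retention_prob_background} and \code{retention_prob_tf}.
#' @param tandem_rate Probability per ancestral gene of carrying a tandem
#'   duplicate (at divergence \code{tandem_ks}).
#' @param tandem_ks Expected Ks of tandem duplicate pairs.
#' @param ortholog_ks Expected Ks between focal and sister orthologs.
#' @param outgroup_ks Expected Ks between ingroup and the first outgroup.
#' @param kappa Transition/transversion rate ratio of the mutation process.
#' @param omega dN/dS ratio applied on every branch.
#' @param n_tf_families,tf_family_size Number and size (in ancestral genes)
#'   of designated TF families; remaining genes form equally sized
#'   background families.
#' @param codon_length Two integers: range of CDS lengths in codons.
#' @param low_support_frac Fraction of internal gene-tree nodes drawn with
#'   support below 0.5 (exercises the support filter).
#' @param seed Integer seed; fully determines the dataset.
#' @return A validated \code{simulation_params} list.
#' @export
simulation_params <- function(n_species = 3, n_chromosomes = 5,
                              genes_per_chromosome = 120,
                              wgd_events = list(
                                list(name = "sigma", ks_depth = 0.27,
                                     retention_prob_background = 0.25,
                                     retention_prob_tf = 0.5),
                                list(name = "rho", ks_depth = 0.97,
                                     retention_prob_background = 0.10,
                                     retention_prob_tf = 0.5)),
                              tandem_rate = 0.05, tandem_ks = 0.10,
                              ortholog_ks = 0.02, outgroup_ks = 1.3,
                              kappa = 2, omega = 0.2,
                              n_tf_families = 5, tf_family_size = 12,
                              codon_length = c(150, 250),
                              low_support_frac = 0.15, seed = 1) {
  p <- list(n_species = n_species, n_chromosomes = n_chromosomes,
            genes_per_chromosome = genes_per_chromosome,
            wgd_events = wgd_events, tandem_rate = tandem_rate,
            tandem_ks = tandem_ks, ortholog_ks = ortholog_ks,
            outgroup_ks = outgroup_ks, kappa = kappa, omega = omega,
            n_tf_families = n_tf_families, tf_family_size = tf_family_size,
            codon_length = codon_length,
            low_support_frac = low_support_frac, seed = seed)
  validate_sim_params(p)
  class(p) <- "simulation_params"
  p
}

validate_sim_params <- function(p) {
  if (p$genes_per_chromosome < 10)
    stop("genes_per_chromosome must be >= 10 (blocks of >= 5 anchors unreachable)",
         call. = FALSE)
  if (p$n_species < 3)
    stop("n_species must be >= 3 (focal, sister, >= 1 outgroup)", call. = FALSE)
  depths <- vapply(p$wgd_events, function(e) e$ks_depth, numeric(1))
  if (length(depths) > 1 && any(diff(depths) <= 0))
    stop("wgd_events must have strictly increasing ks_depth", call. = FALSE)
  probs <- c(unlist(lapply(p$wgd_events, function(e)
    c(e$retention_prob_background, e$retention_prob_tf))),
    p$tandem_rate, p$low_support_frac)
  if (any(probs < 0 | probs > 1))
    stop("all probabilities must be in [0, 1]", call. = FALSE)
  if (any(depths >= 2 * .saturation_limit) ||
      p$outgroup_ks >= 2 * .saturation_limit)
    stop("ks depths beyond the saturation limit", call. = FALSE)
  if (max(depths) >= p$outgroup_ks)
    stop("outgroup_ks must exceed the deepest WGD", call. = FALSE)
  if (p$ortholog_ks >= min(depths))
    stop("ortholog_ks must be shallower than the youngest WGD", call. = FALSE)
  if (p$seed != as.integer(p$seed))
    stop("seed must be an integer", call. = FALSE)
  invisible(p)
}

# unique one-letter suffix per event, chronological (deepest-first) order
.event_suffixes <- function(events) {
  nm <- vapply(events, function(e) toupper(substr(e$name, 1, 1)), character(1))
  if (anyDuplicated(nm)) nm <- LETTERS[seq_along(events)]
  nm
}

.draw_support <- function(low_frac) {
  if (stats::runif(1) < low_frac) round(stats::runif(1, 0, 0.49), 2)
  else round(stats::runif(1, 0.5, 1), 2)
}

#' Simulate a two-WGD genome with ground-truth labels
#'
#' Runs the full generative model described in
#' \code{\link{simulation_params}}: an ancestral gene order is duplicated
#' once per WGD event (the duplicated chromosome appended as a new
#' chromosome, lost genes removed and ranks recomputed, so collinear blocks
#' survive), duplicates are retained with family-appropriate probabilities,
#' codon sequences evolve along the true gene tree with kappa bias and
#' omega-scaled nonsynonymous rates, and every simulated gene pair carries a
#' ground-truth label (sigma / rho / tandem / ortholog).
#'
#' @param params A \code{\link{simulation_params}} object.
#' @return A \code{wgd_dataset}: \code{genes} (gene table with species,
#'   chromosome, rank, coordinates, family, copy), \code{cds} (named
#'   character vector), \code{pairs} (within-species homology pairs),
#'   \code{trees} (named newick strings per orthogroup),
#'   \code{orthogroups}, \code{tf_tables} (per species), \code{go_table},
#'   \code{true_pair_labels}, \code{truth} (true depths and realised
#'   retention fractions), and \code{params}.
#' @export
simulate_genome <- function(params) {
  stopifnot(inherits(params, "simulation_params"))
  with_seed(params$seed, .simulate_genome_impl(params))
}

.simulate_genome_impl <- function(p) {
  events_desc <- rev(p$wgd_events)          # chronological: deepest first
  suffixes <- .event_suffixes(events_desc)
  depths <- vapply(events_desc, function(e) e$ks_depth, numeric(1))
  names(depths) <- vapply(events_desc, function(e) e$name, character(1))
  E <- length(events_desc)

  ingroup <- c("MC", "MD")
  outgroups <- paste0("OG", seq_len(p$n_species - 2))
  n_fam <- p$n_chromosomes * p$genes_per_chromosome
  fam_id <- sprintf("fam%04d", seq_len(n_fam))
  fam_chrom <- rep(paste0("c", seq_len(p$n_chromosomes)),
                   each = p$genes_per_chromosome)
  fam_rank <- rep(seq_len(p$genes_per_chromosome) - 1L, p$n_chromosomes)

  # family grouping: designated TF families plus background families
  n_tf_genes <- p$n_tf_families * p$tf_family_size
  if (n_tf_genes > n_fam)
    stop("n_tf_families * tf_family_size exceeds the gene count", call. = FALSE)
  shuffled <- sample(n_fam)
  fam_group <- character(n_fam)
  fam_group[shuffled[seq_len(n_tf_genes)]] <-
    rep(sprintf("TF%02d", seq_len(p$n_tf_families)), each = p$tf_family_size)
  rest <- shuffled[-seq_len(n_tf_genes)]
  fam_group[rest] <- sprintf("BG%02d", ((seq_along(rest) - 1) %/%
                                          p$tf_family_size) + 1)
  fam_is_tf <- startsWith(fam_group, "TF")

  # retention draws: copy ids are "0" plus event suffixes in chronological
  # order; copy "0RS" descends from the rho duplicate and the sigma duplicate
  fam_copies <- vector("list", n_fam)
  ret_attempt <- matrix(0, E, 2, dimnames = list(names(depths), c("bg", "tf")))
  ret_kept <- ret_attempt
  for (f in seq_len(n_fam)) {
    copies <- "0"
    for (ei in seq_len(E)) {
      pr <- if (fam_is_tf[f]) events_desc[[ei]]$retention_prob_tf
            else events_desc[[ei]]$retention_prob_background
      col <- if (fam_is_tf[f]) "tf" else "bg"
      kept <- stats::runif(length(copies)) < pr
      ret_attempt[ei, col] <- ret_attempt[ei, col] + length(copies)
      ret_kept[ei, col] <- ret_kept[ei, col] + sum(kept)
      if (any(kept))
        copies <- c(copies, paste0(copies[kept], suffixes[ei]))
    }
    fam_copies[[f]] <- copies
  }
  fam_tandem <- stats::runif(n_fam) < p$tandem_rate

  # gene tables: ingroup species share layout (WGDs precede speciation)
  u_sp <- p$ortholog_ks / 2
  u_tand <- p$tandem_ks / 2
  u_og <- p$outgroup_ks / 2 + 0.15 * (seq_along(outgroups) - 1)

  gene_rows <- list()
  add_gene <- function(species, gene, chrom, fam, copy) {
    gene_rows[[length(gene_rows) + 1]] <<-
      data.frame(gene_id = gene, species = species, chromosome = chrom,
                 family = fam, copy = copy, stringsAsFactors = FALSE)
  }
  gid <- function(sp, f, copy) sprintf("%s_%s_%s", sp, fam_id[f], copy)
  for (sp in ingroup) {
    for (f in seq_len(n_fam)) {
      for (copy in fam_copies[[f]]) {
        suff <- sub("^0", "", copy)
        chrom <- paste0(fam_chrom[f], suff)
        add_gene(sp, gid(sp, f, copy), chrom, fam_id[f], copy)
        if (copy == "0" && fam_tandem[f])
          add_gene(sp, gid(sp, f, "0T"), chrom, fam_id[f], "0T")
      }
    }
  }
  for (sp in outgroups)
    for (f in seq_len(n_fam))
      add_gene(sp, gid(sp, f, "0"), fam_chrom[f], fam_id[f], "0")
  genes <- do.call(rbind, gene_rows)

  # ranks: ancestral order within each chromosome variant; a tandem copy
  # sits immediately after its source gene
  fam_of <- match(genes$family, fam_id)
  ord <- order(genes$species, genes$chromosome, fam_rank[fam_of],
               genes$copy == "0T")
  genes <- genes[ord, , drop = FALSE]
  key <- paste(genes$species, genes$chromosome)
  genes$rank <- stats::ave(seq_len(nrow(genes)), key,
                           FUN = function(i) seq_along(i) - 1L)
  genes$start <- genes$rank * 2000L + 1L
  genes$end <- genes$start + 999L
  genes$strand <- "+"
  rownames(genes) <- NULL

  # gene trees and sequence evolution, one family at a time
  lens <- sample(seq(p$codon_length[1], p$codon_length[2]), n_fam,
                 replace = TRUE)
  leaf <- function(sp, gene) list(leaf = TRUE, species = sp, gene = gene,
                                  depth = 0)
  mk_node <- function(depth, children)
    list(leaf = FALSE, depth = depth, support = .draw_support(p$low_support_frac),
         children = children)

  trees <- stats::setNames(vector("list", n_fam), fam_id)
  cds <- list()
  label_rows <- list()
  for (f in seq_len(n_fam)) {
    copies <- fam_copies[[f]]
    terminal <- function(copy) {
      sub <- lapply(ingroup, function(sp) leaf(sp, gid(sp, f, copy)))
      if (copy == "0" && fam_tandem[f]) {
        tand <- lapply(ingroup, function(sp) leaf(sp, gid(sp, f, "0T")))
        mk_node(u_tand, list(mk_node(u_sp, list(sub[[1]], sub[[2]])),
                             mk_node(u_sp, list(tand[[1]], tand[[2]]))))
      } else mk_node(u_sp, sub)
    }
    build <- function(ids, ei) {
      if (length(ids) == 1 && ei > E) return(terminal(ids))
      if (ei > E) stop("unpartitioned copies")  # cannot happen
      with_suf <- grepl(suffixes[ei], sub("^0", "", ids), fixed = TRUE)
      if (any(with_suf) && any(!with_suf))
        mk_node(depths[ei] / 2, list(build(ids[!with_suf], ei + 1),
                                     build(ids[with_suf], ei + 1)))
      else build(ids, ei + 1)
    }
    tree <- build(copies, 1)
    for (j in seq_along(outgroups))
      tree <- mk_node(u_og[j], list(tree, leaf(outgroups[j],
                                               gid(outgroups[j], f, "0"))))
    trees[[f]] <- tree_to_newick(tree)

    # evolve sequences down the tree
    root_seq <- random_cds(lens[f])
    walk <- function(node, seq_here, depth_here) {
      if (node$leaf) { cds[[node$gene]] <<- seq_here; return(invisible()) }
      for (ch in node$children) {
        bl <- depth_here - ch$depth
        walk(ch, evolve_cds(seq_here, bl, bl * p$omega, p$kappa), ch$depth)
      }
    }
    walk(tree, root_seq, tree$depth)

    # ground-truth labels: within-species pairs for the focal species and
    # same-copy orthologs between focal and sister
    all_copies <- c(copies, if (fam_tandem[f]) "0T")
    if (length(all_copies) > 1) {
      cmb <- utils::combn(all_copies, 2)
      for (k in seq_len(ncol(cmb))) {
        ev <- .copy_divergence_event(cmb[1, k], cmb[2, k], suffixes,
                                     names(depths))
        label_rows[[length(label_rows) + 1]] <- data.frame(
          gene_a = gid("MC", f, cmb[1, k]), gene_b = gid("MC", f, cmb[2, k]),
          label = ev, stringsAsFactors = FALSE)
      }
    }
    for (copy in all_copies)
      label_rows[[length(label_rows) + 1]] <- data.frame(
        gene_a = gid("MC", f, copy), gene_b = gid("MD", f, copy),
        label = "ortholog", stringsAsFactors = FALSE)
  }
  cds <- unlist(cds)
  labels <- do.call(rbind, label_rows)
  canon <- labels$gene_a > labels$gene_b
  tmp <- labels$gene_a[canon]
  labels$gene_a[canon] <- labels$gene_b[canon]
  labels$gene_b[canon] <- tmp

  # homology pairs: all within-family, within-species pairs (ingroup)
  pair_rows <- list()
  for (sp in ingroup) {
    sub <- genes[genes$species == sp, , drop = FALSE]
    for (fam in split(sub$gene_id, sub$family)) {
      if (length(fam) < 2) next
      cmb <- utils::combn(sort(fam), 2)
      pair_rows[[length(pair_rows) + 1]] <- data.frame(
        gene_a = cmb[1, ], gene_b = cmb[2, ], stringsAsFactors = FALSE)
    }
  }
  pairs <- do.call(rbind, pair_rows)
  pairs$evalue <- 10^-stats::runif(nrow(pairs), 20, 180)
  pairs$bitscore <- round(stats::runif(nrow(pairs), 100, 2000), 1)

  orthogroups <- data.frame(orthogroup = genes$family, gene_id = genes$gene_id,
                            species = genes$species, stringsAsFactors = FALSE)

  # TF annotation (only TF families are annotated, as with real TF scans)
  tf_tables <- lapply(stats::setNames(nm = c(ingroup, outgroups)), function(sp) {
    sub <- genes[genes$species == sp & fam_is_tf[match(genes$family, fam_id)], ]
    data.frame(gene_id = sub$gene_id,
               family = fam_group[match(sub$family, fam_id)],
               stringsAsFactors = FALSE)
  })

  # GO annotation for the focal species; one term enriched in TF genes
  mc <- genes[genes$species == "MC", , drop = FALSE]
  terms <- sprintf("GO:%07d", seq_len(30))
  go_rows <- lapply(seq_len(nrow(mc)), function(i) {
    tf <- fam_is_tf[match(mc$family[i], fam_id)]
    tset <- sample(terms, sample(1:4, 1))
    if (stats::runif(1) < (if (tf) 0.6 else 0.05))
      tset <- union(tset, "GO:0009999")
    data.frame(gene_id = mc$gene_id[i], term = tset, stringsAsFactors = FALSE)
  })
  go_table <- do.call(rbind, go_rows)

  truth <- list(
    events = data.frame(
      name = names(depths), ks_depth = unname(depths),
      retention_prob_background = vapply(events_desc, function(e)
        e$retention_prob_background, numeric(1)),
      retention_prob_tf = vapply(events_desc, function(e)
        e$retention_prob_tf, numeric(1)),
      realized_retention_bg = ret_kept[, "bg"] / pmax(ret_attempt[, "bg"], 1),
      realized_retention_tf = ret_kept[, "tf"] / pmax(ret_attempt[, "tf"], 1),
      stringsAsFactors = FALSE),
    family_groups = data.frame(family = fam_id, group = fam_group,
                               is_tf = fam_is_tf, stringsAsFactors = FALSE))

  structure(list(genes = genes, cds = cds, pairs = pairs,
                 trees = unlist(trees), orthogroups = orthogroups,
                 tf_tables = tf_tables, go_table = go_table,
                 true_pair_labels = labels, truth = truth, params = p),
            class = "wgd_dataset")
}

# event at which two copy lineages diverged; copy ids are "0" plus event
# suffixes in chronological order ("0T" marks the tandem duplicate)
.copy_divergence_event <- function(c1, c2, suffixes, event_names) {
  s1 <- strsplit(sub("^0", "", c1), "")[[1]]
  s2 <- strsplit(sub("^0", "", c2), "")[[1]]
  depth_rank <- function(ch) {
    if (ch == "T") return(length(suffixes) + 1)  # shallowest
    match(ch, suffixes)
  }
  n <- max(length(s1), length(s2))
  for (i in seq_len(n)) {
    a <- if (i <= length(s1)) s1[i] else NA
    b <- if (i <= length(s2)) s2[i] else NA
    if (identical(a, b)) next
    cand <- c(a, b)
    cand <- cand[!is.na(cand)]
    r <- min(vapply(cand, depth_rank, numeric(1)))  # deepest event wins
    return(if (r > length(suffixes)) "tandem" else event_names[r])
  }
  stop("identical copy ids have no divergence event")
}

tree_to_newick <- function(node) {
  render <- function(nd, parent_depth) {
    if (nd$leaf)
      return(sprintf("%s|%s:%g", nd$species, nd$gene, parent_depth))
    inner <- paste(vapply(nd$children, render, character(1),
                          parent_depth = nd$depth), collapse = ",")
    sprintf("(%s)%g:%g", inner, nd$support, parent_depth - nd$depth)
  }
  if (node$leaf) stop("tree has a single leaf")
  inner <- paste(vapply(node$children, render, character(1),
                        parent_depth = node$depth), collapse = ",")
  sprintf("(%s)%g;", inner, node$support)
}

#' Write a synthetic dataset to a directory
#'
#' Emits the same plain-text formats the pipeline reads: CDS FASTA,
#' gene-position TSV, homology-pair TSV, gene-tree TSV (orthogroup id +
#' newick), orthogroup TSV, per-species TF-family TSV, gene-to-GO TSV, and
#' ground-truth TSVs.
#' @param dataset A \code{wgd_dataset}.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the directory path.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "wgd_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_fasta(dataset$cds, file.path(dir, "cds.fasta"))
  utils::write.table(
    dataset$genes[, c("species", "chromosome", "start", "end", "strand",
                      "gene_id")],
    file.path(dir, "gene_positions.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(dataset$pairs, file.path(dir, "pairs.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(paste(names(dataset$trees), unname(dataset$trees), sep = "\t"),
             file.path(dir, "gene_trees.tsv"))
  utils::write.table(dataset$orthogroups, file.path(dir, "orthogroups.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  tf <- do.call(rbind, lapply(names(dataset$tf_tables), function(sp)
    cbind(species = sp, dataset$tf_tables[[sp]])))
  utils::write.table(tf, file.path(dir, "tf_families.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(dataset$go_table, file.path(dir, "go_annotations.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(dataset$true_pair_labels,
                     file.path(dir, "truth_pair_labels.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(dataset$truth$events, file.path(dir, "truth_events.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Look up the ground-truth label of a gene pair
#'
#' The label map is symmetric: the pair is looked up in canonical order.
#' @param labels The \code{true_pair_labels} table of a dataset.
#' @param gene_a,gene_b Gene ids.
#' @return The label string, or \code{"none"} if the pair is unlabeled.
#' @export
true_pair_label <- function(labels, gene_a, gene_b) {
  a <- pmin(gene_a, gene_b)
  b <- pmax(gene_a, gene_b)
  i <- match(paste(a, b), paste(labels$gene_a, labels$gene_b))
  ifelse(is.na(i), "none", labels$label[i])
}
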