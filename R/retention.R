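# Gene-tree duplication events and WGD retention assignment.
#
# A node of a rooted gene tree is a duplication under the species-overlap
# criterion (the species sets of its child clades intersect). Candidate
# events are filtered on orthogroup composition, branch support, tandem
# status and mean cross-child Ks, then assigned to the younger (sigma) or
# older (rho) WGD through the Ks class of the syntenic block containing a
# cross-child anchor pair.

.event_statuses <- c("candidate", "accepted", "rejected_support",
                     "rejected_tandem", "rejected_ks",
                     "rejected_composition", "rejected_nonsyntenic")

#' Find candidate duplication nodes in a gene tree
#'
#' Applies the species-overlap criterion to every internal node of a rooted
#' gene tree: a node is a duplication iff the species sets of its two child
#' clades intersect. Polytomies are reported with \code{polytomy = TRUE}
#' (they are later rejected as composition failures, since duplication
#' nodes are assumed binary).
#'
#' @param tree Annotated \code{phylo} from \code{\link{read_tree}} /
#'   \code{\link{parse_tree}}.
#' @param orthogroup_id Identifier carried into the result.
#' @return Data frame of candidate events: \code{orthogroup_id, node_id,
#'   support, polytomy} and list-columns \code{child_a_genes,
#'   child_b_genes} (gene ids per child branch; for polytomies the first
#'   two overlapping children).
#' @export
find_duplication_nodes <- function(tree, orthogroup_id = "OG") {
  if (!ape::is.rooted(tree))
    stop("tree is unrooted; root it first (e.g. midpoint rooting)",
         call. = FALSE)
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  # genes and species below every node
  clade_tips <- vector("list", ntip + nnode)
  for (i in seq_len(ntip)) clade_tips[[i]] <- i
  edge <- tree$edge[order(tree$edge[, 1], decreasing = TRUE), , drop = FALSE]
  for (k in seq_len(nrow(edge))) {
    par <- edge[k, 1]; ch <- edge[k, 2]
    clade_tips[[par]] <- c(clade_tips[[par]], clade_tips[[ch]])
  }
  rows <- list()
  for (nd in (ntip + 1):(ntip + nnode)) {
    children <- tree$edge[tree$edge[, 1] == nd, 2]
    if (length(children) < 2) next
    found <- NULL
    for (i in seq_along(children)) {
      for (j in seq_along(children)) {
        if (j <= i) next
        sa <- tree$leaf_species[clade_tips[[children[i]]]]
        sb <- tree$leaf_species[clade_tips[[children[j]]]]
        if (length(intersect(sa, sb)) > 0) { found <- c(i, j); break }
      }
      if (!is.null(found)) break
    }
    if (is.null(found)) next
    sup <- if (nd - ntip <= length(tree$support)) tree$support[nd - ntip]
           else NA_real_
    rows[[length(rows) + 1]] <- data.frame(
      orthogroup_id = orthogroup_id, node_id = nd,
      support = sup, polytomy = length(children) > 2,
      child_a_genes = I(list(tree$leaf_gene[clade_tips[[children[found[1]]]]])),
      child_b_genes = I(list(tree$leaf_gene[clade_tips[[children[found[2]]]]])),
      stringsAsFactors = FALSE)
  }
  out <- if (length(rows) == 0) {
    data.frame(orthogroup_id = character(0), node_id = integer(0),
               support = numeric(0), polytomy = logical(0),
               child_a_genes = I(list()), child_b_genes = I(list()),
               stringsAsFactors = FALSE)
  } else do.call(rbind, rows)
  out$status <- rep("candidate", nrow(out))
  out
}

#' Filter candidate duplication events
#'
#' Rejects events whose orthogroup has fewer than \code{min_genes} genes or
#' (optionally) lacks a gene from outside the ingroup
#' (\code{rejected_composition}); events where either child branch lacks a
#' focal-species gene or the node is a polytomy
#' (\code{rejected_composition}); and events with support below
#' \code{min_support} (\code{rejected_support}; support exactly at the
#' threshold is kept).
#'
#' @param candidates Candidate table from \code{\link{find_duplication_nodes}}.
#' @param species_of Named character vector mapping gene id to species.
#' @param focal_species Focal species name (e.g. \code{"MC"}).
#' @param ingroup Species forming the focal clade; a "non-ingroup" gene is
#'   required when \code{require_outgroup}.
#' @param min_genes Minimum orthogroup size (default 4).
#' @param require_outgroup Require at least one non-ingroup gene.
#' @param min_support Support threshold on the 0-1 scale (default 0.5).
#' @param orthogroup_genes Optional named list giving the full gene set per
#'   orthogroup; defaults to the union of genes seen in the tree's
#'   candidates per orthogroup.
#' @return The table with \code{status} set; unrejected events stay
#'   \code{"candidate"}.
#' @export
filter_events <- function(candidates, species_of, focal_species,
                          ingroup = focal_species, min_genes = 4,
                          require_outgroup = TRUE, min_support = 0.5,
                          orthogroup_genes = NULL) {
  if (nrow(candidates) == 0) return(candidates)
  if (is.null(orthogroup_genes)) {
    all_genes <- tapply(
      seq_len(nrow(candidates)), candidates$orthogroup_id,
      function(i) unique(unlist(c(candidates$child_a_genes[i],
                                  candidates$child_b_genes[i]))))
    orthogroup_genes <- as.list(all_genes)
  }
  for (i in seq_len(nrow(candidates))) {
    if (candidates$status[i] != "candidate") next
    og <- orthogroup_genes[[candidates$orthogroup_id[i]]]
    ga <- candidates$child_a_genes[[i]]
    gb <- candidates$child_b_genes[[i]]
    sp_og <- species_of[og]
    comp_ok <- length(og) >= min_genes &&
      (!require_outgroup || any(!(sp_og %in% ingroup))) &&
      any(species_of[ga] == focal_species) &&
      any(species_of[gb] == focal_species) &&
      !candidates$polytomy[i]
    if (!comp_ok) {
      candidates$status[i] <- "rejected_composition"
    } else if (is.na(candidates$support[i]) ||
               candidates$support[i] < min_support) {
      candidates$status[i] <- "rejected_support"
    }
  }
  candidates
}

#' Reject events whose duplicates are tandem
#'
#' An event is \code{rejected_tandem} iff any focal-species cross-child
#' gene pair is tandem (same chromosome, rank distance within the window).
#' @param events Event table (still \code{"candidate"} rows are examined).
#' @param genes Focal-genome gene table (\code{gene_id, species,
#'   chromosome, rank}).
#' @param species_of Named gene-to-species map.
#' @param focal_species Focal species name.
#' @param window Tandem rank window (default 5).
#' @export
drop_tandem_events <- function(events, genes, species_of, focal_species,
                               window = 5) {
  for (i in seq_len(nrow(events))) {
    if (events$status[i] != "candidate") next
    prs <- .cross_child_focal_pairs(events[i, ], species_of, focal_species)
    if (nrow(prs) == 0) next
    if (any(detect_tandem(prs, genes, window = window)))
      events$status[i] <- "rejected_tandem"
  }
  events
}

.cross_child_focal_pairs <- function(event, species_of, focal_species) {
  ga <- event$child_a_genes[[1]]
  gb <- event$child_b_genes[[1]]
  ga <- ga[species_of[ga] == focal_species]
  gb <- gb[species_of[gb] == focal_species]
  if (length(ga) == 0 || length(gb) == 0)
    return(data.frame(gene_a = character(0), gene_b = character(0),
                      stringsAsFactors = FALSE))
  expand.grid(gene_a = ga, gene_b = gb, stringsAsFactors = FALSE)
}

#' Mean Ks across a duplication node
#'
#' Arithmetic mean of the valid Ks values of all focal-species cross-child
#' gene pairs (one gene in each child branch). Events with no valid pair or
#' a mean outside the exclusive (\code{lo}, \code{hi}) window are
#' \code{rejected_ks}.
#' @param events Event table.
#' @param ks_table Ks estimates (\code{gene_a, gene_b, ks, valid}).
#' @inheritParams drop_tandem_events
#' @param lo,hi Exclusive bounds on the event mean Ks (defaults 0.05, 1.50).
#' @return Events with a \code{mean_ks} column and updated status.
#' @export
event_mean_ks <- function(events, ks_table, species_of, focal_species,
                          lo = 0.05, hi = 1.50) {
  events$mean_ks <- NA_real_
  for (i in seq_len(nrow(events))) {
    if (events$status[i] != "candidate") next
    prs <- .cross_child_focal_pairs(events[i, ], species_of, focal_species)
    ks <- lookup_pair_ks(ks_table, prs$gene_a, prs$gene_b)
    ks <- ks[!is.na(ks)]
    if (length(ks) == 0) {
      events$status[i] <- "rejected_ks"
      next
    }
    m <- mean(ks)
    events$mean_ks[i] <- m
    if (m <= lo || m >= hi) events$status[i] <- "rejected_ks"
  }
  events
}

#' Assign duplication events to a WGD via syntenic-block Ks class
#'
#' An event is assigned sigma if at least one focal cross-child pair is an
#' anchor of a young-class block, rho for an old-class block. If pairs hit
#' both classes, the class of the anchor whose Ks is nearest the event's
#' mean Ks wins. Events with no cross-child pair anchored in any
#' classified block are \code{rejected_nonsyntenic}; surviving events
#' become \code{accepted}.
#' @param events Event table (after Ks filtering).
#' @param classified Result of \code{\link{classify_blocks}}.
#' @inheritParams drop_tandem_events
#' @return Events with a \code{wgd} column in
#'   \{\code{sigma}, \code{rho}, \code{unassigned}\} and final statuses.
#' @export
assign_to_wgd <- function(events, classified, species_of, focal_species) {
  anchors <- classified$anchors
  cls <- classified$blocks$ks_class[match(anchors$block_id,
                                          classified$blocks$block_id)]
  akey <- paste(pmin(anchors$gene_a, anchors$gene_b),
                pmax(anchors$gene_a, anchors$gene_b))
  events$wgd <- rep("unassigned", nrow(events))
  for (i in seq_len(nrow(events))) {
    if (events$status[i] != "candidate") next
    prs <- .cross_child_focal_pairs(events[i, ], species_of, focal_species)
    pkey <- paste(pmin(prs$gene_a, prs$gene_b), pmax(prs$gene_a, prs$gene_b))
    hit <- which(akey %in% pkey & cls %in% c("young", "old"))
    if (length(hit) == 0) {
      events$status[i] <- "rejected_nonsyntenic"
      next
    }
    hcls <- cls[hit]
    hks <- anchors$ks[hit]
    hks[is.na(hks)] <- Inf
    if (all(hcls == "young")) {
      events$wgd[i] <- "sigma"
    } else if (all(hcls == "old")) {
      events$wgd[i] <- "rho"
    } else {
      near <- which.min(abs(hks - events$mean_ks[i]))
      events$wgd[i] <- if (hcls[near] == "young") "sigma" else "rho"
    }
    events$status[i] <- "accepted"
  }
  events
}

#' Retained gene sets per WGD
#'
#' Union of focal-species genes over accepted events per WGD, with counts
#' and percentages of the total focal gene count. Sigma and rho sets may
#' overlap; both raw and deduplicated union counts are reported.
#' @param events Final event table.
#' @param species_of Named gene-to-species map.
#' @param focal_species Focal species name.
#' @param total_genes Total focal-genome gene count for the percentages.
#' @return List with \code{sigma}, \code{rho} (gene-id vectors),
#'   \code{union}, and a \code{summary} data frame (set, n, percent).
#' @export
retained_gene_sets <- function(events, species_of, focal_species,
                               total_genes) {
  acc <- events[events$status == "accepted", , drop = FALSE]
  collect <- function(which_wgd) {
    sub <- acc[acc$wgd == which_wgd, , drop = FALSE]
    g <- as.character(unique(unlist(c(sub$child_a_genes, sub$child_b_genes))))
    g <- g[!is.na(g) & species_of[g] == focal_species]
    sort(g)
  }
  sig <- collect("sigma")
  rho <- collect("rho")
  uni <- sort(union(sig, rho))
  summary <- data.frame(
    set = c("sigma", "rho", "union"),
    n = c(length(sig), length(rho), length(uni)),
    percent = c(summary_percentages(length(sig), total_genes),
                summary_percentages(length(rho), total_genes),
                summary_percentages(length(uni), total_genes)),
    stringsAsFactors = FALSE)
  list(sigma = sig, rho = rho, union = uni, summary = summary)
}

#' Serialize an event table for TSV output
#'
#' Flattens the gene-set list-columns to semicolon-joined strings.
#' @param events Event table.
#' @export
events_as_table <- function(events) {
  data.frame(
    orthogroup = events$orthogroup_id, node = events$node_id,
    support = events$support, mean_ks = events$mean_ks,
    wgd = events$wgd, status = events$status,
    genes_a = vapply(events$child_a_genes, paste, character(1),
                     collapse = ";"),
    genes_b = vapply(events$child_b_genes, paste, character(1),
                     collapse = ";"),
    stringsAsFactors = FALSE)
}
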