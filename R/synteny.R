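#' Flag tandem duplicate pairs
#'
#' A homology pair is tandem iff both genes are in the same species, on the
#' same chromosome, and within \code{window} gene ranks of each other
#' (inclusive; strand-ignored).
#' @param pairs Data frame with \code{gene_a}, \code{gene_b}.
#' @param genes Gene table with \code{gene_id, species, chromosome, rank}.
#' @param window Rank-distance window (default 5).
#' @return Logical vector, one flag per pair row.
#' @export
detect_tandem <- function(pairs, genes, window = 5) {
  ia <- match(pairs$gene_a, genes$gene_id)
  ib <- match(pairs$gene_b, genes$gene_id)
  if (anyNA(ia) || anyNA(ib)) {
    missing <- c(pairs$gene_a[is.na(ia)], pairs$gene_b[is.na(ib)])
    stop(sprintf("unknown gene id: %s", missing[1]), call. = FALSE)
  }
  genes$species[ia] == genes$species[ib] &
    genes$chromosome[ia] == genes$chromosome[ib] &
    abs(genes$rank[ia] - genes$rank[ib]) <= window
}

# canonical anchor order used by both the DP chainer and the brute-force
# oracle: ascending rank_a, then rank_b
.anchor_order <- function(a) order(a$rank_a, a$rank_b)

# longest chain among anchors of one chromosome pair and one orientation;
# successor needs both rank gaps in (0, max_gap]. Among equally long chains
# the lexicographically smallest index sequence (in canonical order) wins.
.best_chain <- function(rank_a, rank_b, max_gap, inverted) {
  n <- length(rank_a)
  if (n == 0) return(integer(0))
  rb <- if (inverted) -rank_b else rank_b
  dp <- rep(1L, n)        # longest chain starting at i
  nxt <- rep(NA_integer_, n)
  for (i in n:1) {
    for (j in seq_len(n)[-seq_len(i)]) {
      ga <- rank_a[j] - rank_a[i]
      gb <- rb[j] - rb[i]
      if (ga < 1 || ga > max_gap || gb < 1 || gb > max_gap) next
      cand <- 1L + dp[j]
      if (cand > dp[i]) { dp[i] <- cand; nxt[i] <- j }
      # ties: j increasing, first hit is lexicographically smallest
    }
  }
  best <- max(dp)
  start <- which(dp == best)[1]
  chain <- integer(0)
  i <- start
  while (!is.na(i)) { chain <- c(chain, i); i <- nxt[i] }
  chain
}

#' Chain collinear anchors into syntenic blocks
#'
#' Within each chromosome pair, finds maximal chains of anchors whose gene
#' ranks are strictly monotone on both axes (increasing, or decreasing on
#' the B axis for inverted blocks) with rank gaps at most \code{max_gap},
#' by dynamic programming with chain score = anchor count. Chains are
#' extracted greedily best-first; each anchor joins at most one block, and
#' chains shorter than \code{min_pairs} are discarded. Tandem-flagged
#' anchors and self-pairs are removed before chaining.
#'
#' @param anchors Data frame with \code{gene_a, gene_b, chrom_a, chrom_b,
#'   rank_a, rank_b, evalue} (optional \code{ks}).
#' @param min_pairs Minimum anchors per block (default 5).
#' @param max_gap Maximum rank gap between consecutive anchors (default 25).
#' @param evalue_max E-value threshold on anchors (default 1e-5).
#' @param tandem Optional logical vector flagging tandem anchors to exclude.
#' @return List with \code{blocks} (block_id, chrom_a, chrom_b, n_anchors,
#'   orientation) and \code{anchors} (block_id plus the input columns).
#' @export
chain_blocks <- function(anchors, min_pairs = 5, max_gap = 25,
                         evalue_max = 1e-5, tandem = NULL) {
  keep <- anchors$gene_a != anchors$gene_b
  if (!is.null(anchors$evalue)) keep <- keep & anchors$evalue <= evalue_max
  if (!is.null(tandem)) keep <- keep & !tandem
  anchors <- anchors[keep, , drop = FALSE]
  blocks <- list()
  block_anchors <- list()
  bid <- 0L
  for (grp in split(anchors, paste(anchors$chrom_a, anchors$chrom_b))) {
    grp <- grp[.anchor_order(grp), , drop = FALSE]
    repeat {
      if (nrow(grp) < min_pairs) break
      fwd <- .best_chain(grp$rank_a, grp$rank_b, max_gap, inverted = FALSE)
      rev_ <- .best_chain(grp$rank_a, grp$rank_b, max_gap, inverted = TRUE)
      use_fwd <- length(fwd) >= length(rev_)  # tie prefers same orientation
      chain <- if (use_fwd) fwd else rev_
      if (length(chain) < min_pairs) break
      bid <- bid + 1L
      taken <- grp[chain, , drop = FALSE]
      taken$block_id <- bid
      block_anchors[[bid]] <- taken
      blocks[[bid]] <- data.frame(
        block_id = bid, chrom_a = taken$chrom_a[1], chrom_b = taken$chrom_b[1],
        n_anchors = length(chain),
        orientation = if (use_fwd) "same" else "inverted",
        stringsAsFactors = FALSE)
      grp <- grp[-chain, , drop = FALSE]
    }
  }
  if (bid == 0L)
    return(list(blocks = data.frame(block_id = integer(0),
                                    chrom_a = character(0),
                                    chrom_b = character(0),
                                    n_anchors = integer(0),
                                    orientation = character(0),
                                    stringsAsFactors = FALSE),
                anchors = cbind(anchors[0, , drop = FALSE],
                                block_id = integer(0))))
  list(blocks = do.call(rbind, blocks),
       anchors = do.call(rbind, block_anchors))
}

#' Join gene ranks onto a homology-pair table
#'
#' Builds the anchor table \code{\link{chain_blocks}} consumes.
#' @param pairs Homology pairs (\code{gene_a, gene_b, evalue, bitscore}).
#' @param genes Gene table with \code{gene_id, chromosome, rank}.
#' @export
anchors_from_pairs <- function(pairs, genes) {
  ia <- match(pairs$gene_a, genes$gene_id)
  ib <- match(pairs$gene_b, genes$gene_id)
  if (anyNA(ia) || anyNA(ib))
    stop("pair references a gene absent from the gene table", call. = FALSE)
  cbind(pairs,
        data.frame(chrom_a = genes$chromosome[ia], rank_a = genes$rank[ia],
                   chrom_b = genes$chromosome[ib], rank_b = genes$rank[ib],
                   stringsAsFactors = FALSE))
}

#' Classify syntenic blocks into WGD age classes by median Ks
#'
#' The block's median Ks over anchors with valid estimates falls in the
#' young window (exclusive), the old window (left-closed: exactly the
#' trough value 0.6 classifies old), or neither (unclassified). Blocks with
#' no valid anchor Ks are unclassified with a warning.
#' @param chained Result of \code{\link{chain_blocks}}.
#' @param ks_table Ks estimates (\code{gene_a, gene_b, ks, valid}).
#' @param young_range,old_range Ks windows; defaults (0.05, 0.6) and
#'   (0.6, 1.5).
#' @return \code{chained} with \code{median_ks} and \code{ks_class} columns
#'   on \code{blocks} and a \code{ks} column on \code{anchors}.
#' @export
classify_blocks <- function(chained, ks_table,
                            young_range = c(0.05, 0.6),
                            old_range = c(0.6, 1.5)) {
  blocks <- chained$blocks
  anchors <- chained$anchors
  anchors$ks <- lookup_pair_ks(ks_table, anchors$gene_a, anchors$gene_b)
  med <- vapply(blocks$block_id, function(b) {
    v <- anchors$ks[anchors$block_id == b]
    v <- v[!is.na(v)]
    if (length(v) == 0) NA_real_ else stats::median(v)
  }, numeric(1))
  if (any(is.na(med)) && nrow(blocks) > 0)
    warning(sprintf("%d block(s) with no valid anchor Ks left unclassified",
                    sum(is.na(med))))
  cls <- rep("unclassified", nrow(blocks))
  cls[!is.na(med) & med > young_range[1] & med < young_range[2]] <- "young"
  cls[!is.na(med) & med >= old_range[1] & med < old_range[2]] <- "old"
  blocks$median_ks <- med
  blocks$ks_class <- cls
  list(blocks = blocks, anchors = anchors)
}

# symmetric Ks lookup for gene pairs; NA when absent or invalid
lookup_pair_ks <- function(ks_table, gene_a, gene_b) {
  ka <- pmin(ks_table$gene_a, ks_table$gene_b)
  kb <- pmax(ks_table$gene_a, ks_table$gene_b)
  keys <- paste(ka, kb)
  vals <- ifelse(ks_table$valid, ks_table$ks, NA_real_)
  i <- match(paste(pmin(gene_a, gene_b), pmax(gene_a, gene_b)), keys)
  vals[i]
}
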