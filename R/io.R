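#' Read a FASTA file of sequences
#'
#' Order-preserving; the header token before the first whitespace is the id.
#' Duplicate ids and empty sequences are rejected rather than repaired.
#' @param path FASTA file.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  x <- Biostrings::readBStringSet(path)
  if (length(x) == 0) stop("FASTA file contains no records", call. = FALSE)
  ids <- sub("\\s.*$", "", names(x))
  if (anyDuplicated(ids))
    stop(sprintf("duplicate FASTA id: %s", ids[duplicated(ids)][1]),
         call. = FALSE)
  seqs <- as.character(x)
  if (any(nchar(seqs) == 0))
    stop(sprintf("empty sequence for id: %s", ids[nchar(seqs) == 0][1]),
         call. = FALSE)
  stats::setNames(seqs, ids)
}

#' Write sequences to FASTA
#' @param seqs Named character vector.
#' @param path Output file.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), path)
  invisible(path)
}

#' Read a gene-position table and assign ranks
#'
#' TSV with columns \code{species, chromosome, start, end, strand, gene_id}.
#' Genes are ranked 0-based per (species, chromosome) by ascending start,
#' ties broken by gene id; strand is ignored for ranking.
#' @param path TSV file.
#' @return Data frame of gene stubs with a \code{rank} column.
#' @export
read_gene_positions <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  g <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("species", "chromosome", "start", "end", "strand", "gene_id")
  if (!all(need %in% names(g)))
    stop(sprintf("gene-position table must have columns: %s",
                 paste(need, collapse = ", ")), call. = FALSE)
  dup <- duplicated(g[, c("species", "chromosome", "start", "gene_id")])
  if (any(dup))
    stop(sprintf("duplicate gene record: %s", g$gene_id[dup][1]), call. = FALSE)
  if (anyDuplicated(g$gene_id))
    stop(sprintf("gene id appears twice: %s",
                 g$gene_id[duplicated(g$gene_id)][1]), call. = FALSE)
  g <- g[order(g$species, g$chromosome, g$start, g$gene_id), , drop = FALSE]
  key <- paste(g$species, g$chromosome)
  g$rank <- stats::ave(seq_len(nrow(g)), key,
                       FUN = function(i) seq_along(i) - 1L)
  rownames(g) <- NULL
  g
}

#' Read a newick gene tree with branch supports
#'
#' Leaf labels must be \code{"<species>|<gene_id>"}; internal node labels
#' are read as numeric supports and rescaled to [0, 1] (values above 1 are
#' treated as percentages and divided by 100).
#' @param path Newick file (first tree is read).
#' @return An \code{ape} \code{phylo} with a numeric \code{support} vector
#'   (one entry per internal node) and \code{leaf_species} /
#'   \code{leaf_gene} attributes.
#' @export
read_tree <- function(path) {
  tr <- tryCatch(suppressWarnings(ape::read.tree(path)),
                 error = function(e) stop(sprintf("unparseable newick: %s",
                                                  conditionMessage(e)),
                                          call. = FALSE))
  if (is.null(tr)) stop("unparseable newick", call. = FALSE)
  if (inherits(tr, "multiPhylo")) tr <- tr[[1]]
  annotate_tree(tr)
}

# attach supports and leaf species/gene parsing to a phylo object
annotate_tree <- function(tr) {
  if (!all(grepl("|", tr$tip.label, fixed = TRUE)))
    stop("leaf label without 'species|gene' delimiter", call. = FALSE)
  sup <- suppressWarnings(as.numeric(tr$node.label))
  sup <- ifelse(!is.na(sup) & sup > 1, sup / 100, sup)
  tr$support <- sup
  tr$leaf_species <- sub("\\|.*$", "", tr$tip.label)
  tr$leaf_gene <- sub("^[^|]*\\|", "", tr$tip.label)
  tr
}

#' Parse a newick string into an annotated gene tree
#' @param text Newick string.
#' @export
parse_tree <- function(text) {
  tr <- ape::read.tree(text = text)
  if (is.null(tr)) stop("unparseable newick", call. = FALSE)
  annotate_tree(tr)
}

#' Read a gene-tree table (orthogroup id, newick per line)
#' @param path Two-column TSV without header: orthogroup id, newick.
#' @return Named list of annotated \code{phylo} objects.
#' @export
read_gene_trees <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(parts) != 2
  if (any(bad))
    stop(sprintf("malformed gene-tree line %d", which(bad)[1]), call. = FALSE)
  ids <- vapply(parts, `[`, character(1), 1)
  stats::setNames(lapply(parts, function(x) parse_tree(x[2])), ids)
}

#' Write a tree to newick, restoring percent or unit supports as stored
#' @param tree An annotated \code{phylo}.
#' @param path Output file.
#' @export
write_tree <- function(tree, path) {
  ape::write.tree(tree, path)
  invisible(path)
}

#' Read homology pairs (BLAST outfmt-6-like or minimal 4-column TSV)
#'
#' Accepts the 12-column tabular format (qseqid sseqid pident length
#' mismatch gapopen qstart qend sstart send evalue bitscore) or a headered
#' 4-column TSV (gene_a, gene_b, evalue, bitscore). Only the four
#' \code{HomologyPair} fields are retained; self-pairs are rejected.
#' @param path Input file.
#' @param evalue_max Optional E-value cutoff applied on read.
#' @return Data frame with \code{gene_a, gene_b, evalue, bitscore}.
#' @export
read_pairs <- function(path, evalue_max = NULL) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  first <- readLines(path, n = 1)
  ncol1 <- length(strsplit(first, "\t", fixed = TRUE)[[1]])
  if (ncol1 == 12) {
    raw <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
    out <- data.frame(gene_a = raw[[1]], gene_b = raw[[2]],
                      evalue = as.numeric(raw[[11]]),
                      bitscore = as.numeric(raw[[12]]),
                      stringsAsFactors = FALSE)
  } else {
    out <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("gene_a", "gene_b", "evalue", "bitscore")
    if (!all(need %in% names(out)))
      stop("pair table must be 12-column tabular or have columns gene_a, gene_b, evalue, bitscore",
           call. = FALSE)
    out <- out[, need]
  }
  if (any(is.na(out$evalue)) || any(out$evalue < 0))
    stop("invalid E-value in pair table", call. = FALSE)
  if (any(out$gene_a == out$gene_b))
    stop("self-pair in homology table", call. = FALSE)
  if (!is.null(evalue_max)) out <- out[out$evalue <= evalue_max, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read a two-column gene-to-label TSV (TF family or GO term tables)
#' @param path Headered TSV whose first two columns are gene id and label.
#' @param col_names Names to assign to the two columns.
#' @return Data frame with the two named columns.
#' @export
read_two_col <- function(path, col_names = c("gene_id", "label")) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (ncol(x) < 2) stop("expected at least two columns", call. = FALSE)
  out <- x[, 1:2]
  names(out) <- col_names
  out
}
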