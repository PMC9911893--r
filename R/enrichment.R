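# GO over-representation of a gene set against the genomic background:
# one-sided hypergeometric tail per term, Benjamini-Hochberg adjustment,
# and the conventional significance cutoffs (p_adj < 0.05, q < 0.2; the
# q-value is approximated by the BH-adjusted p, i.e. pi0 = 1).

#' Close gene annotations under term ancestry (true-path rule)
#'
#' Every gene annotated to a term becomes annotated to all the term's
#' ancestors. Idempotent; cycles in the edge table are an error.
#' @param gene_terms Data frame \code{gene_id, term}.
#' @param parent_edges Data frame \code{child, parent} (acyclic).
#' @return Expanded \code{gene_id, term} data frame (unique rows).
#' @export
propagate_annotations <- function(gene_terms, parent_edges) {
  if (is.null(parent_edges) || nrow(parent_edges) == 0) return(gene_terms)
  parents_of <- split(parent_edges$parent, parent_edges$child)
  anc_cache <- new.env(parent = emptyenv())
  ancestors <- function(term, stack = character(0)) {
    if (term %in% stack)
      stop(sprintf("cycle in term hierarchy at %s", term), call. = FALSE)
    hit <- anc_cache[[term]]
    if (!is.null(hit)) return(hit)
    ps <- parents_of[[term]]
    out <- if (is.null(ps)) character(0)
    else unique(c(ps, unlist(lapply(ps, ancestors, stack = c(stack, term)))))
    anc_cache[[term]] <- out
    out
  }
  rows <- lapply(seq_len(nrow(gene_terms)), function(i) {
    terms <- c(gene_terms$term[i], ancestors(gene_terms$term[i]))
    data.frame(gene_id = gene_terms$gene_id[i], term = terms,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  unique(out)
}

#' One-sided hypergeometric tail probability
#'
#' \eqn{P(X \ge k)} for drawing \code{n} genes from a background of
#' \code{N} of which \code{K} carry the term (Fisher's exact test for
#' over-representation).
#' @param k Term-positive genes in the set.
#' @param K Term-positive genes in the background.
#' @param n Set size.
#' @param N Background size.
#' @export
hypergeom_tail <- function(k, K, n, N) {
  if (any(k < 0 | K < 0 | n < 0 | N < 0) || any(K > N) || any(n > N) ||
      any(k > pmin(n, K)))
    stop("invalid hypergeometric bounds", call. = FALSE)
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' \code{p_adj(i) = min_{j >= rank(i)} (m p_(j) / j)}, capped at 1,
#' returned in the input order.
#' @param pvals Raw p-values in (0, 1].
#' @export
bh_adjust <- function(pvals) {
  if (any(pvals <= 0 | pvals > 1)) stop("p-values must be in (0, 1]",
                                        call. = FALSE)
  stats::p.adjust(pvals, method = "BH")
}

#' GO over-representation of a gene set
#'
#' Tests each term annotated to at least one set gene with the one-sided
#' hypergeometric tail against the annotated background; adjusts with BH.
#' Genes without any annotation are excluded from both set and background.
#'
#' @param gene_set Gene ids of interest.
#' @param annotations Data frame \code{gene_id, term}.
#' @param background Background gene ids (default: all annotated genes).
#'   Must contain every annotated set gene.
#' @param p_adj_cutoff,q_cutoff Significance cutoffs (defaults 0.05, 0.2);
#'   the q-value is the BH-adjusted p (pi0 = 1 surrogate).
#' @param parent_edges Optional \code{child, parent} edges; when supplied,
#'   annotations are propagated to ancestors first.
#' @return Data frame sorted by ascending p: \code{term, k, n, K, N, p,
#'   p_adj, significant}.
#' @export
enrich <- function(gene_set, annotations, background = NULL,
                   p_adj_cutoff = 0.05, q_cutoff = 0.2,
                   parent_edges = NULL) {
  if (!is.null(parent_edges))
    annotations <- propagate_annotations(annotations, parent_edges)
  annotated <- unique(annotations$gene_id)
  if (is.null(background)) background <- annotated
  background <- intersect(unique(background), annotated)
  set <- intersect(unique(gene_set), background)
  if (!all(intersect(gene_set, annotated) %in% background))
    stop("background must contain every annotated set gene", call. = FALSE)
  N <- length(background)
  n <- length(set)
  if (n == 0) {
    warning("no annotated genes in the set; empty enrichment result")
    return(data.frame(term = character(0), k = integer(0), n = integer(0),
                      K = integer(0), N = integer(0), p = numeric(0),
                      p_adj = numeric(0), significant = logical(0),
                      stringsAsFactors = FALSE))
  }
  ann <- annotations[annotations$gene_id %in% background, , drop = FALSE]
  ann <- unique(ann)
  K_tab <- table(ann$term)
  set_ann <- ann[ann$gene_id %in% set, , drop = FALSE]
  k_tab <- table(set_ann$term)
  terms <- names(k_tab)
  k <- as.integer(k_tab)
  K <- as.integer(K_tab[terms])
  p <- hypergeom_tail(k, K, n, N)
  p_adj <- bh_adjust(p)
  out <- data.frame(term = terms, k = k, n = n, K = K, N = N, p = p,
                    p_adj = p_adj,
                    significant = p_adj < p_adj_cutoff & p_adj < q_cutoff,
                    stringsAsFactors = FALSE)
  out <- out[order(out$p, out$term), , drop = FALSE]
  rownames(out) <- NULL
  out
}
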