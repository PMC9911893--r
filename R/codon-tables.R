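# Internal codon machinery shared by the Ks estimators and the simulator:
# the standard genetic code, single-nucleotide codon neighbourhoods, and
# per-codon synonymous site fractions under optional kappa / codon-frequency
# weighting. Everything is precomputed once per session and cached.

.NUC <- c("T", "C", "A", "G")
.codon_cache <- new.env(parent = emptyenv())

# transition pairs: A<->G, C<->T
.is_transition <- function(from, to) {
  (from == "A" & to == "G") | (from == "G" & to == "A") |
    (from == "C" & to == "T") | (from == "T" & to == "C")
}

codon_tables <- function() {
  if (!is.null(.codon_cache$tab)) return(.codon_cache$tab)
  g <- expand.grid(p3 = .NUC, p2 = .NUC, p1 = .NUC,
                   stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  codons <- paste0(g$p1, g$p2, g$p3)
  code <- Biostrings::GENETIC_CODE  # standard code, table 1
  aa <- unname(code[codons])
  stop_codon <- aa == "*"

  n <- length(codons)
  nt <- cbind(g$p1, g$p2, g$p3)
  # 9 single-nucleotide neighbours per codon (3 positions x 3 alternatives)
  nb_idx <- matrix(0L, n, 9)
  nb_pos <- matrix(0L, n, 9)
  nb_ts <- matrix(FALSE, n, 9)
  nb_syn <- matrix(FALSE, n, 9)
  nb_stop <- matrix(FALSE, n, 9)
  idx_of <- stats::setNames(seq_len(n), codons)
  for (i in seq_len(n)) {
    k <- 0L
    for (p in 1:3) {
      for (b in setdiff(.NUC, nt[i, p])) {
        k <- k + 1L
        trip <- nt[i, ]
        trip[p] <- b
        j <- idx_of[[paste0(trip[1], trip[2], trip[3])]]
        nb_idx[i, k] <- j
        nb_pos[i, k] <- p
        nb_ts[i, k] <- .is_transition(nt[i, p], b)
        nb_syn[i, k] <- aa[i] == aa[j]
        nb_stop[i, k] <- stop_codon[j]
      }
    }
  }
  # fourfold-degenerate third position: all three pos-3 changes synonymous
  fourfold3 <- vapply(seq_len(n), function(i) {
    sel <- nb_pos[i, ] == 3L
    !stop_codon[i] && all(nb_syn[i, sel])
  }, logical(1))

  tab <- list(codons = codons, aa = aa, stop = stop_codon, nt = nt,
              idx_of = idx_of, nb_idx = nb_idx, nb_pos = nb_pos,
              nb_ts = nb_ts, nb_syn = nb_syn, nb_stop = nb_stop,
              fourfold3 = fourfold3)
  .codon_cache$tab <- tab
  tab
}

codon_index <- function(codons) {
  tab <- codon_tables()
  idx <- tab$idx_of[codons]
  unname(idx)
}

# Per-codon synonymous site count (0..3). Each of the three positions
# contributes the weighted fraction of its non-stop single-nucleotide
# changes that are synonymous; weights are kappa^is_transition times the
# frequency pi of the target codon. S + N = 3 per codon by construction.
syn_site_counts <- function(kappa = 1, pi = NULL) {
  tab <- codon_tables()
  n <- length(tab$codons)
  if (is.null(pi)) pi <- rep(1, n)
  out <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (tab$stop[i]) next
    s <- 0
    for (p in 1:3) {
      sel <- tab$nb_pos[i, ] == p & !tab$nb_stop[i, ]
      if (!any(sel)) next  # position with only stop alternatives: no site
      w <- ifelse(tab$nb_ts[i, sel], kappa, 1) * pi[tab$nb_idx[i, sel]]
      tw <- sum(w)
      if (tw <= 0) next
      s <- s + sum(w[tab$nb_syn[i, sel]]) / tw
    }
    out[i] <- s
  }
  out
}

.syn_sites_ng86 <- function() {
  if (is.null(.codon_cache$s_ng86)) .codon_cache$s_ng86 <- syn_site_counts()
  .codon_cache$s_ng86
}

# Weighted-average synonymous / nonsynonymous difference counts between two
# codons, averaging over all substitution orders (NG86-style pathway
# averaging). Pathways through stop codons are dropped; steps are weighted
# kappa^is_transition * omega^is_nonsynonymous. If every pathway passes
# through a stop codon, each differing position is classified directly from
# the starting codon (degenerate fallback, affects no sense-codon pair under
# the standard code at <= 2 differences).
codon_pair_diffs <- function(ci, cj, kappa = 1, omega = 1) {
  tab <- codon_tables()
  if (ci == cj) return(c(sd = 0, nd = 0))
  pos <- which(tab$nt[ci, ] != tab$nt[cj, ])
  perms <- switch(as.character(length(pos)),
    "1" = list(pos),
    "2" = list(pos, pos[2:1]),
    "3" = lapply(list(c(1,2,3), c(1,3,2), c(2,1,3),
                      c(2,3,1), c(3,1,2), c(3,2,1)),
                 function(o) pos[o]))
  tot_w <- 0; sd <- 0; nd <- 0
  for (path in perms) {
    cur <- ci
    w <- 1; s <- 0; ns <- 0
    ok <- TRUE
    for (p in path) {
      trip <- tab$nt[cur, ]
      trip[p] <- tab$nt[cj, p]
      nxt <- tab$idx_of[[paste0(trip[1], trip[2], trip[3])]]
      if (tab$stop[nxt]) { ok <- FALSE; break }
      syn <- tab$aa[cur] == tab$aa[nxt]
      ts <- .is_transition(tab$nt[cur, p], tab$nt[cj, p])
      w <- w * (if (ts) kappa else 1) * (if (syn) 1 else omega)
      if (syn) s <- s + 1 else ns <- ns + 1
      cur <- nxt
    }
    if (!ok) next
    tot_w <- tot_w + w
    sd <- sd + w * s
    nd <- nd + w * ns
  }
  if (tot_w == 0) {
    # all pathways blocked by stops: classify each position independently
    s <- 0; ns <- 0
    for (p in pos) {
      trip <- tab$nt[ci, ]
      trip[p] <- tab$nt[cj, p]
      nxt <- tab$idx_of[[paste0(trip[1], trip[2], trip[3])]]
      if (tab$aa[ci] == tab$aa[nxt]) s <- s + 1 else ns <- ns + 1
    }
    return(c(sd = s, nd = ns))
  }
  c(sd = sd / tot_w, nd = nd / tot_w)
}

# 64 x 64 NG86 (kappa = omega = 1) difference matrices, cached.
.ng86_diff_tables <- function() {
  if (!is.null(.codon_cache$ng86_diff)) return(.codon_cache$ng86_diff)
  tab <- codon_tables()
  n <- length(tab$codons)
  sd <- matrix(NA_real_, n, n)
  nd <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) {
    if (tab$stop[i]) next
    for (j in seq_len(n)) {
      if (tab$stop[j]) next
      d <- codon_pair_diffs(i, j)
      sd[i, j] <- d["sd"]
      nd[i, j] <- d["nd"]
    }
  }
  .codon_cache$ng86_diff <- list(sd = sd, nd = nd)
  .codon_cache$ng86_diff
}

# Jukes-Cantor style multiple-hit correction for proportions of differences.
jc_correct <- function(p) {
  arg <- 1 - 4 * p / 3
  if (arg <= 0) return(NA_real_)
  -0.75 * log(arg)
}

# split a CDS string into codons
split_codons <- function(cds) {
  nc <- nchar(cds)
  if (nc %% 3 != 0) stop("CDS length is not a multiple of 3", call. = FALSE)
  substring(cds, seq(1, nc, 3), seq(3, nc, 3))
}
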