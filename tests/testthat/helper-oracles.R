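# Independent brute-force oracles. These share no code with the package
# internals: strings and explicit enumeration only.

# ---- NG86 enumeration oracle ----
oracle_ng86 <- function(codons_a, codons_b) {
  code <- Biostrings::GENETIC_CODE
  nucs <- c("A", "C", "G", "T")
  syn_sites_codon <- function(codon) {
    s <- 0
    for (p in 1:3) {
      alts <- setdiff(nucs, substr(codon, p, p))
      ns <- 0; nv <- 0
      for (b in alts) {
        mut <- codon
        substr(mut, p, p) <- b
        if (code[[mut]] == "*") next
        nv <- nv + 1
        if (code[[mut]] == code[[codon]]) ns <- ns + 1
      }
      if (nv > 0) s <- s + ns / nv
    }
    s
  }
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (rest in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
    out
  }
  diffs_codon <- function(ca, cb) {
    pos <- which(strsplit(ca, "")[[1]] != strsplit(cb, "")[[1]])
    if (length(pos) == 0) return(c(0, 0))
    tot <- 0; sd <- 0; nd <- 0
    for (path in perms(pos)) {
      cur <- ca; s <- 0; n <- 0; ok <- TRUE
      for (p in path) {
        nxt <- cur
        substr(nxt, p, p) <- substr(cb, p, p)
        if (code[[nxt]] == "*") { ok <- FALSE; break }
        if (code[[nxt]] == code[[cur]]) s <- s + 1 else n <- n + 1
        cur <- nxt
      }
      if (ok) { tot <- tot + 1; sd <- sd + s; nd <- nd + n }
    }
    if (tot == 0) {
      s <- 0; n <- 0
      for (p in pos) {
        nxt <- ca
        substr(nxt, p, p) <- substr(cb, p, p)
        if (code[[nxt]] == code[[ca]]) s <- s + 1 else n <- n + 1
      }
      return(c(s, n))
    }
    c(sd / tot, nd / tot)
  }
  S <- 0; Sd <- 0; Nd <- 0
  L <- length(codons_a)
  for (i in seq_len(L)) {
    S <- S + (syn_sites_codon(codons_a[i]) + syn_sites_codon(codons_b[i])) / 2
    d <- diffs_codon(codons_a[i], codons_b[i])
    Sd <- Sd + d[1]; Nd <- Nd + d[2]
  }
  N <- 3 * L - S
  jc <- function(p) if (1 - 4 * p / 3 <= 0) NA_real_ else -0.75 * log(1 - 4 * p / 3)
  list(S = S, N = N, Sd = Sd, Nd = Nd, ds = jc(Sd / S), dn = jc(Nd / N))
}

new_codon_alignment_for_test <- function(ca, cb)
  wgdretain:::new_codon_alignment(ca, cb, "a", "b")

# random sense-codon alignment (no stops, so every column is counted)
random_sense_codons <- function(n) {
  code <- Biostrings::GENETIC_CODE
  sense <- names(code)[code != "*"]
  sample(sense, n, replace = TRUE)
}

# ---- brute-force chain enumeration oracle ----
# Mirrors the published extraction rule: repeatedly take the longest chain
# (ties: same orientation first, then lexicographically smallest index
# sequence in canonical rank_a/rank_b order), remove its anchors, stop when
# the best chain is shorter than min_pairs.
oracle_chain_blocks <- function(anchors, min_pairs, max_gap) {
  pair_key <- function(a) paste(a$gene_a, a$gene_b)
  best_chain_bf <- function(a, inverted) {
    n <- nrow(a)
    if (n == 0) return(integer(0))
    ra <- a$rank_a
    rb <- if (inverted) -a$rank_b else a$rank_b
    chains <- list()
    rec <- function(chain) {
      chains[[length(chains) + 1]] <<- chain
      last <- chain[length(chain)]
      for (j in seq_len(n)) {
        if (j <= last) next
        ga <- ra[j] - ra[last]; gb <- rb[j] - rb[last]
        if (ga >= 1 && ga <= max_gap && gb >= 1 && gb <= max_gap)
          rec(c(chain, j))
      }
    }
    for (i in seq_len(n)) rec(i)
    lens <- lengths(chains)
    cands <- chains[lens == max(lens)]
    keys <- vapply(cands, function(ch)
      paste(sprintf("%06d", ch), collapse = ","), character(1))
    cands[[order(keys)[1]]]
  }
  out <- list()
  for (grp in split(anchors, paste(anchors$chrom_a, anchors$chrom_b))) {
    grp <- grp[order(grp$rank_a, grp$rank_b), , drop = FALSE]
    repeat {
      if (nrow(grp) < min_pairs) break
      fwd <- best_chain_bf(grp, inverted = FALSE)
      rev_ <- best_chain_bf(grp, inverted = TRUE)
      chain <- if (length(fwd) >= length(rev_)) fwd else rev_
      if (length(chain) < min_pairs) break
      out[[length(out) + 1]] <- pair_key(grp[chain, , drop = FALSE])
      grp <- grp[-chain, , drop = FALSE]
    }
  }
  out
}

# ---- hypergeometric exhaustive-summation oracle ----
oracle_hyper_tail <- function(k, K, n, N) {
  i <- k:min(n, K)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# ---- species-overlap duplication oracle (via ape clade extraction) ----
oracle_duplication_nodes <- function(tree) {
  ntip <- length(tree$tip.label)
  species <- sub("\\|.*$", "", tree$tip.label)
  tips_below <- function(node) {
    if (node <= ntip) return(node)
    unlist(lapply(tree$edge[tree$edge[, 1] == node, 2], tips_below))
  }
  dups <- integer(0)
  for (nd in (ntip + 1):(ntip + tree$Nnode)) {
    ch <- tree$edge[tree$edge[, 1] == nd, 2]
    if (length(ch) < 2) next
    hit <- FALSE
    for (i in seq_along(ch)) for (j in seq_along(ch)) {
      if (j <= i) next
      if (length(intersect(species[tips_below(ch[i])],
                           species[tips_below(ch[j])])) > 0) hit <- TRUE
    }
    if (hit) dups <- c(dups, nd)
  }
  dups
}
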