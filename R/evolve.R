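# Codon sequence evolution for the synthetic-data generator. Substitutions
# are single-nucleotide changes applied codon by codon: synonymous and
# nonsynonymous event counts are Poisson with means target_ds * S_i and
# target_dn * N_i (S_i, N_i the codon's kappa-weighted synonymous /
# nonsynonymous site counts), each event choosing a kappa-biased non-stop
# neighbour of the appropriate class. Realised dS and dN therefore match
# their targets in expectation, which is what the counting estimators need.

# run code with a private RNG stream, restoring the caller's state
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

# random CDS of `length_codons` sense codons (uniform over the 61)
random_cds <- function(length_codons) {
  tab <- codon_tables()
  sense <- which(!tab$stop)
  paste0(tab$codons[sample(sense, length_codons, replace = TRUE)],
         collapse = "")
}

.saturation_limit <- 3  # substitutions per site beyond any correctable range

# Evolve one codon-index vector by expected per-site divergence (ds, dn).
evolve_codon_idx <- function(x, ds, dn, kappa) {
  tab <- codon_tables()
  s_sites <- syn_site_counts(kappa = kappa)
  n_sites <- 3 - s_sites
  k_syn <- stats::rpois(length(x), ds * s_sites[x])
  k_non <- stats::rpois(length(x), dn * n_sites[x])
  hit <- which(k_syn + k_non > 0)
  for (i in hit) {
    events <- sample(c(rep(TRUE, k_syn[i]), rep(FALSE, k_non[i])))
    cur <- x[i]
    for (syn in events) {
      sel <- tab$nb_syn[cur, ] == syn & !tab$nb_stop[cur, ]
      if (!any(sel)) next  # codon drifted to a class with no such neighbour
      w <- ifelse(tab$nb_ts[cur, sel], kappa, 1)
      cand <- tab$nb_idx[cur, sel]
      cur <- if (length(cand) == 1) cand else sample(cand, 1, prob = w)
    }
    x[i] <- cur
  }
  x
}

evolve_cds <- function(cds, ds, dn, kappa) {
  x <- codon_index(split_codons(cds))
  paste0(codon_tables()$codons[evolve_codon_idx(x, ds, dn, kappa)],
         collapse = "")
}

#' Simulate a diverged codon sequence pair
#'
#' Generates a random ancestral coding sequence and evolves two descendant
#' copies so that their expected synonymous divergence is \code{target_ds}
#' and nonsynonymous divergence \code{target_dn} (half on each lineage).
#' Substitutions are kappa-biased single-nucleotide changes under the
#' standard genetic code; stop codons are never introduced.
#'
#' @param length_codons Number of codons (>= 1).
#' @param target_ds,target_dn Expected pairwise dS and dN (>= 0). Targets at
#'   or beyond 3 substitutions per site signal saturation and are rejected.
#' @param kappa Transition/transversion rate ratio (> 0).
#' @param seed Optional integer seed (private RNG stream).
#' @return List with elements \code{a} and \code{b}, the two CDS strings.
#' @export
evolve_codon_pair <- function(length_codons, target_ds, target_dn,
                              kappa = 2, seed = NULL) {
  if (length_codons < 1) stop("length_codons must be >= 1", call. = FALSE)
  if (target_ds < 0 || target_dn < 0)
    stop("targets must be >= 0", call. = FALSE)
  if (target_ds >= .saturation_limit || target_dn >= .saturation_limit)
    stop(sprintf(
      "saturation: target divergence >= %d substitutions per site cannot be represented",
      .saturation_limit), call. = FALSE)
  if (kappa <= 0) stop("kappa must be > 0", call. = FALSE)
  with_seed(seed, {
    anc <- random_cds(length_codons)
    list(a = evolve_cds(anc, target_ds / 2, target_dn / 2, kappa),
         b = evolve_cds(anc, target_ds / 2, target_dn / 2, kappa))
  })
}
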