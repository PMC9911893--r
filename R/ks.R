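#' Back-thread a protein alignment onto coding sequences
#'
#' Converts a pairwise amino-acid alignment into a codon alignment by
#' replacing each aligned residue with its source codon (pal2nal-style).
#' Columns containing a gap, an ambiguous base (N), or a stop codon in either
#' sequence are excluded from site counting.
#'
#' @param protein_aln_a,protein_aln_b Aligned amino-acid strings of equal
#'   length; gaps as \code{-}.
#' @param cds_a,cds_b Ungapped coding sequences; each must be exactly three
#'   times the length of its ungapped protein.
#' @param gene_a,gene_b Identifiers used in error messages and carried into
#'   downstream estimates.
#' @return An object of class \code{codon_alignment}: aligned codon vectors
#'   (\code{codons_a}, \code{codons_b}, gaps as \code{"---"}), a logical
#'   \code{counted} flag per column, and the gene ids.
#' @export
backthread_codon_alignment <- function(protein_aln_a, protein_aln_b,
                                       cds_a, cds_b,
                                       gene_a = "a", gene_b = "b") {
  if (nchar(protein_aln_a) != nchar(protein_aln_b))
    stop("protein alignments have unequal length", call. = FALSE)
  thread_one <- function(prot_aln, cds, gene) {
    aa <- strsplit(prot_aln, "", fixed = TRUE)[[1]]
    ungapped <- sum(aa != "-")
    if (nchar(cds) != 3L * ungapped)
      stop(sprintf("CDS length of '%s' (%d) is not 3 x ungapped protein length (%d)",
                   gene, nchar(cds), ungapped), call. = FALSE)
    codons <- split_codons(toupper(cds))
    out <- character(length(aa))
    k <- 0L
    code <- Biostrings::GENETIC_CODE
    for (i in seq_along(aa)) {
      if (aa[i] == "-") {
        out[i] <- "---"
      } else {
        k <- k + 1L
        cod <- codons[k]
        if (!grepl("N", cod, fixed = TRUE)) {
          tr <- unname(code[cod])
          if (is.na(tr))
            stop(sprintf("invalid codon '%s' in '%s'", cod, gene), call. = FALSE)
          if (!identical(tr, toupper(aa[i])) && toupper(aa[i]) != "X")
            stop(sprintf("codon '%s' of '%s' translates to '%s', not aligned residue '%s'",
                         cod, gene, tr, aa[i]), call. = FALSE)
        }
        out[i] <- cod
      }
    }
    out
  }
  ca <- thread_one(protein_aln_a, cds_a, gene_a)
  cb <- thread_one(protein_aln_b, cds_b, gene_b)
  new_codon_alignment(ca, cb, gene_a, gene_b)
}

new_codon_alignment <- function(codons_a, codons_b, gene_a, gene_b) {
  tab <- codon_tables()
  no_gap <- codons_a != "---" & codons_b != "---"
  has_n <- grepl("N", codons_a, fixed = TRUE) | grepl("N", codons_b, fixed = TRUE)
  is_stop <- rep(FALSE, length(codons_a))
  sel <- no_gap & !has_n
  if (any(sel)) {
    ia <- codon_index(codons_a[sel])
    ib <- codon_index(codons_b[sel])
    if (anyNA(ia) || anyNA(ib))
      stop("alignment contains characters other than ACGTN-", call. = FALSE)
    is_stop[sel] <- tab$stop[ia] | tab$stop[ib]
  }
  structure(list(codons_a = codons_a, codons_b = codons_b,
                 counted = no_gap & !has_n & !is_stop,
                 gene_a = gene_a, gene_b = gene_b),
            class = "codon_alignment")
}

#' Codon alignment of two equal-length coding sequences
#'
#' Trivial back-translation alignment for gene pairs whose coding sequences
#' have identical length (no indels). General protein alignment is an
#' external input; see \code{\link{backthread_codon_alignment}}.
#' @param cds_a,cds_b Coding sequences of equal length (multiple of 3).
#' @inheritParams backthread_codon_alignment
#' @export
align_codons_equal <- function(cds_a, cds_b, gene_a = "a", gene_b = "b") {
  if (nchar(cds_a) != nchar(cds_b))
    stop(sprintf("sequences '%s' and '%s' differ in length; supply a protein alignment",
                 gene_a, gene_b), call. = FALSE)
  new_codon_alignment(split_codons(toupper(cds_a)), split_codons(toupper(cds_b)),
                      gene_a, gene_b)
}

# named character vector of sequences (XStringSet keeps names on coercion;
# plain character vectors must already be named)
.cds_vector <- function(cds) {
  if (!is.character(cds)) cds <- as.character(cds)
  if (is.null(names(cds)))
    stop("cds must be named by gene id", call. = FALSE)
  cds
}

.counted_indices <- function(aln) {
  sel <- aln$counted
  list(ia = codon_index(aln$codons_a[sel]), ib = codon_index(aln$codons_b[sel]))
}

.ks_row <- function(aln, method, S, N, Sd, Nd, kappa, ka, ks, valid) {
  data.frame(gene_a = aln$gene_a, gene_b = aln$gene_b, method = method,
             S = S, N = N, Sd = Sd, Nd = Nd, kappa = kappa,
             ka = ka, ks = ks, valid = valid, stringsAsFactors = FALSE)
}

#' Nei-Gojobori (1986) Ks/Ka estimate
#'
#' Counting estimator with equal mutation rates: per-codon synonymous site
#' fractions from the nine single-nucleotide neighbours, pathway-averaged
#' difference counts, and Jukes-Cantor correction
#' \eqn{d = -3/4 \log(1 - 4p/3)}. When \eqn{p > 3/4} the correction is
#' undefined and the estimate is returned with \code{valid = FALSE}
#' (saturation is never silently clamped).
#'
#' @param aln A \code{codon_alignment}.
#' @return One-row data frame with columns \code{gene_a, gene_b, method, S,
#'   N, Sd, Nd, kappa, ka, ks, valid} (kappa is \code{NA} for NG86).
#' @export
ng86 <- function(aln) {
  stopifnot(inherits(aln, "codon_alignment"))
  idx <- .counted_indices(aln)
  L <- length(idx$ia)
  if (L < 1) stop("no counted codons in alignment", call. = FALSE)
  s_tab <- .syn_sites_ng86()
  S <- (sum(s_tab[idx$ia]) + sum(s_tab[idx$ib])) / 2
  N <- 3 * L - S
  d <- .ng86_diff_tables()
  Sd <- sum(d$sd[cbind(idx$ia, idx$ib)])
  Nd <- sum(d$nd[cbind(idx$ia, idx$ib)])
  ds <- jc_correct(Sd / S)
  dn <- jc_correct(Nd / N)
  .ks_row(aln, "NG86", S, N, Sd, Nd, NA_real_, dn, ds,
          valid = !is.na(ds) && !is.na(dn))
}

# kappa (ts/tv rate ratio) from fourfold-degenerate third positions with a
# K80 correction; falls back to `fallback` when fewer than min_sites usable
# sites exist or the correction is undefined.
estimate_kappa_4fold <- function(ia, ib, min_sites = 10, fallback = 2) {
  tab <- codon_tables()
  sel <- tab$fourfold3[ia] & tab$fourfold3[ib] &
    tab$nt[ia, 1] == tab$nt[ib, 1] & tab$nt[ia, 2] == tab$nt[ib, 2]
  n <- sum(sel)
  if (n < min_sites) return(fallback)
  a3 <- tab$nt[ia[sel], 3]
  b3 <- tab$nt[ib[sel], 3]
  diff <- a3 != b3
  P <- sum(diff & .is_transition(a3, b3)) / n
  Q <- sum(diff & !.is_transition(a3, b3)) / n
  a1 <- 1 - 2 * P - Q
  a2 <- 1 - 2 * Q
  if (a1 <= 0 || a2 <= 0) return(fallback)
  alpha_t <- -0.5 * log(a1) + 0.25 * log(a2)
  beta_t <- -0.25 * log(a2)
  if (beta_t <= 0 || alpha_t <= 0) return(fallback)
  alpha_t / beta_t
}

#' Yang-Nielsen (2000) style Ks/Ka estimate
#'
#' Approximate counting method accounting for transition/transversion bias
#' and codon usage: codon frequencies from the F3x4 model, kappa estimated
#' from fourfold-degenerate third positions (K80-corrected), kappa- and
#' frequency-weighted synonymous site counting, and multi-hit substitution
#' pathways weighted by \code{kappa^ts * omega^nonsyn} with omega updated
#' iteratively until the difference counts converge (relative change
#' < 1e-6, at most 100 iterations).
#'
#' @param aln A \code{codon_alignment} with at least 10 counted codons.
#' @return One-row data frame as for \code{\link{ng86}}, with the estimated
#'   kappa. \code{valid = FALSE} on saturation or non-convergence.
#' @export
yn00 <- function(aln) {
  stopifnot(inherits(aln, "codon_alignment"))
  idx <- .counted_indices(aln)
  L <- length(idx$ia)
  if (L < 10)
    stop("yn00 requires at least 10 counted codons (method unstable below)",
         call. = FALSE)
  tab <- codon_tables()

  # F3x4 codon frequencies pooled over both sequences
  nt_all <- rbind(tab$nt[idx$ia, , drop = FALSE], tab$nt[idx$ib, , drop = FALSE])
  pos_freq <- vapply(1:3, function(p) {
    f <- table(factor(nt_all[, p], levels = .NUC))
    as.numeric(f) / sum(f)
  }, numeric(4))  # 4 x 3
  rownames(pos_freq) <- .NUC
  pi <- pos_freq[tab$nt[, 1], 1] * pos_freq[tab$nt[, 2], 2] *
    pos_freq[tab$nt[, 3], 3]
  pi[tab$stop] <- 0
  pi <- pi / sum(pi)

  kappa <- estimate_kappa_4fold(idx$ia, idx$ib)
  s_tab <- syn_site_counts(kappa = kappa, pi = pi)
  S <- (sum(s_tab[idx$ia]) + sum(s_tab[idx$ib])) / 2
  N <- 3 * L - S

  pairs <- paste(idx$ia, idx$ib)
  up <- !duplicated(pairs)
  ui <- idx$ia[up]; uj <- idx$ib[up]
  cnt <- as.numeric(table(pairs)[pairs[up]])

  omega <- 0.5
  prev <- c(-1, -1)
  converged <- FALSE
  ds <- NA_real_; dn <- NA_real_; Sd <- NA_real_; Nd <- NA_real_
  for (it in seq_len(100)) {
    d <- vapply(seq_along(ui), function(k)
      codon_pair_diffs(ui[k], uj[k], kappa = kappa, omega = omega),
      numeric(2))
    Sd <- sum(d[1, ] * cnt)
    Nd <- sum(d[2, ] * cnt)
    ds <- jc_correct(Sd / S)
    dn <- jc_correct(Nd / N)
    if (is.na(ds) || is.na(dn))  # saturation
      return(.ks_row(aln, "YN00", S, N, Sd, Nd, kappa, dn, ds, valid = FALSE))
    if (max(abs(c(Sd, Nd) - prev)) < 1e-6 * max(prev, 1)) {
      converged <- TRUE
      break
    }
    prev <- c(Sd, Nd)
    omega <- if (ds <= 0) 1 else max(dn / ds, 1e-6)
  }
  if (!converged)
    warning(sprintf("yn00 did not converge for pair (%s, %s)",
                    aln$gene_a, aln$gene_b))
  .ks_row(aln, "YN00", S, N, Sd, Nd, kappa, dn, ds, valid = converged)
}

#' Ks estimate for one gene pair
#'
#' Convenience wrapper: trivially aligns two equal-length coding sequences
#' and applies the configured estimator.
#' @param cds_a,cds_b Coding sequences (equal length).
#' @param method \code{"YN00"} (default, the pipeline's estimator) or
#'   \code{"NG86"} (cross-check mode).
#' @inheritParams backthread_codon_alignment
#' @export
ks_estimate <- function(cds_a, cds_b, method = c("YN00", "NG86"),
                        gene_a = "a", gene_b = "b") {
  method <- match.arg(method)
  aln <- align_codons_equal(cds_a, cds_b, gene_a, gene_b)
  if (method == "YN00") yn00(aln) else ng86(aln)
}

#' Filter Ks estimates to an exclusive range
#'
#' Retains estimates with \code{lo < ks < hi} (strict bounds) and drops
#' invalid (saturated) estimates. Defaults are the standard (0.05, 1.50)
#' window that removes allelic noise and saturated pairs.
#' @param estimates Data frame of Ks estimates (needs \code{ks}, \code{valid}).
#' @param lo,hi Exclusive bounds, \code{lo < hi}.
#' @export
filter_ks <- function(estimates, lo = 0.05, hi = 1.50) {
  if (lo >= hi) stop("lo must be < hi", call. = FALSE)
  if (nrow(estimates) == 0) return(estimates)
  keep <- estimates$valid & !is.na(estimates$ks) &
    estimates$ks > lo & estimates$ks < hi
  estimates[keep, , drop = FALSE]
}

#' Ks of single-copy orthologs between two species
#'
#' Orthogroups with exactly one member in each of the two species contribute
#' one ortholog pair; pairs are aligned by trivial back-translation (equal
#' length) and estimated with the configured method. The interspecies
#' ortholog peak can sit below the paralog filter's lower bound, so this
#' workflow takes its own bounds (default exclusive (0, 1.5)).
#'
#' @param orthogroups Data frame with columns \code{orthogroup},
#'   \code{gene_id}, \code{species}.
#' @param species_pair Character vector of two species names.
#' @param cds Named character vector (or \code{DNAStringSet}) of coding
#'   sequences keyed by gene id.
#' @param method Estimator, as in \code{\link{ks_estimate}}.
#' @param bounds Exclusive Ks bounds applied to the result.
#' @return Data frame of Ks estimates (possibly empty).
#' @export
single_copy_ortholog_ks <- function(orthogroups, species_pair, cds,
                                    method = c("YN00", "NG86"),
                                    bounds = c(0, 1.5)) {
  method <- match.arg(method)
  if (length(species_pair) != 2)
    stop("species_pair must name exactly two species", call. = FALSE)
  cds <- .cds_vector(cds)
  rows <- list()
  for (og in split(orthogroups, orthogroups$orthogroup)) {
    ga <- og$gene_id[og$species == species_pair[1]]
    gb <- og$gene_id[og$species == species_pair[2]]
    if (length(ga) != 1 || length(gb) != 1) next
    if (nchar(cds[[ga]]) != nchar(cds[[gb]])) next  # needs external alignment
    rows[[length(rows) + 1]] <-
      ks_estimate(cds[[ga]], cds[[gb]], method, ga, gb)
  }
  if (length(rows) == 0)
    return(.ks_row(list(gene_a = character(0), gene_b = character(0)),
                   character(0), numeric(0), numeric(0), numeric(0),
                   numeric(0), numeric(0), numeric(0), numeric(0),
                   logical(0)))
  out <- do.call(rbind, rows)
  filter_ks(out, bounds[1], bounds[2])
}

#' Ks estimates for a table of gene pairs
#'
#' Applies \code{\link{ks_estimate}} to every row of a homology-pair table,
#' skipping pairs whose sequences differ in length (those need an external
#' protein alignment).
#' @param pairs Data frame with columns \code{gene_a}, \code{gene_b}.
#' @param cds Named character vector of coding sequences.
#' @inheritParams single_copy_ortholog_ks
#' @export
ks_for_pairs <- function(pairs, cds, method = c("YN00", "NG86")) {
  method <- match.arg(method)
  cds <- .cds_vector(cds)
  rows <- vector("list", nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    ga <- pairs$gene_a[i]; gb <- pairs$gene_b[i]
    if (is.na(match(ga, names(cds))) || is.na(match(gb, names(cds))))
      stop(sprintf("no CDS for pair (%s, %s)", ga, gb), call. = FALSE)
    if (nchar(cds[[ga]]) != nchar(cds[[gb]])) next
    rows[[i]] <- ks_estimate(cds[[ga]], cds[[gb]], method, ga, gb)
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0) stop("no estimable pairs", call. = FALSE)
  do.call(rbind, rows)
}
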