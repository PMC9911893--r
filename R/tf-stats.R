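#' Transcription-factor family count matrix across species
#'
#' @param tf_tables Named list (one per species) of data frames with
#'   columns \code{gene_id}, \code{family}. A gene annotated to two
#'   different families is an error; a family absent from a species counts
#'   0; a family absent everywhere is excluded.
#' @return Integer matrix, families x species.
#' @export
family_count_matrix <- function(tf_tables) {
  for (sp in names(tf_tables)) {
    t <- tf_tables[[sp]]
    conflict <- tapply(t$family, t$gene_id, function(f) length(unique(f)) > 1)
    if (any(conflict))
      stop(sprintf("gene %s annotated to conflicting families in %s",
                   names(conflict)[conflict][1], sp), call. = FALSE)
  }
  fams <- sort(unique(unlist(lapply(tf_tables, function(t) t$family))))
  m <- vapply(tf_tables, function(t) {
    tab <- tapply(t$gene_id, factor(t$family, levels = fams),
                  function(g) length(unique(g)))
    as.integer(ifelse(is.na(tab), 0L, tab))
  }, integer(length(fams)))
  if (is.null(dim(m))) m <- matrix(m, nrow = length(fams))
  rownames(m) <- fams
  colnames(m) <- names(tf_tables)
  m
}

#' Screen TF families for the z-score analysis
#'
#' A family is screened out as \code{too_few} if any species has fewer than
#' \code{min_members} genes, and as \code{non_normal} if its cross-species
#' counts fail the Shapiro-Wilk normality test at \code{alpha_normal} (a
#' zero-variance family is treated as non-normal, since no z-score is
#' defined for it).
#' @param counts Family x species count matrix
#'   (\code{\link{family_count_matrix}}).
#' @param min_members Minimum per-species family size (default 10).
#' @param alpha_normal Shapiro-Wilk significance level (default 0.05).
#' @return Data frame per family: \code{family, W, p_normal, screened_out}
#'   (\code{"no"}, \code{"too_few"} or \code{"non_normal"}).
#' @export
screen_families <- function(counts, min_members = 10, alpha_normal = 0.05) {
  if (ncol(counts) < 3)
    stop("at least 3 species are required for the normality screen",
         call. = FALSE)
  out <- data.frame(family = rownames(counts), W = NA_real_,
                    p_normal = NA_real_, screened_out = "no",
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(counts))) {
    x <- counts[i, ]
    if (any(x < min_members)) {
      out$screened_out[i] <- "too_few"
      next
    }
    if (stats::sd(x) == 0) {
      out$screened_out[i] <- "non_normal"
      next
    }
    sw <- stats::shapiro.test(x)
    out$W[i] <- unname(sw$statistic)
    out$p_normal[i] <- sw$p.value
    if (sw$p.value < alpha_normal) out$screened_out[i] <- "non_normal"
  }
  out
}

#' Gene-count z-score of the focal species
#'
#' \eqn{z = (x - \mu)/\sigma} with the sample (n-1) standard deviation.
#' @param x Focal-species gene count of the family.
#' @param counts Cross-species gene counts of the family (including the
#'   focal species).
#' @param sd_type \code{"sample"} (n-1, default) or \code{"population"} (n).
#' @export
zscore <- function(x, counts, sd_type = c("sample", "population")) {
  sd_type <- match.arg(sd_type)
  mu <- mean(counts)
  s <- stats::sd(counts)
  if (sd_type == "population")
    s <- sqrt(mean((counts - mu)^2))
  if (is.na(s) || s == 0) stop("zero standard deviation", call. = FALSE)
  (x - mu) / s
}

#' Per-family TF statistics table
#'
#' Combines the screen and the focal-species z-score; families with
#' \code{z > z_flag} are flagged as enlarged.
#' @inheritParams screen_families
#' @param focal_species Column of \code{counts} holding the focal species.
#' @param z_flag Flagging threshold (default 1.5).
#' @export
tf_family_stats <- function(counts, focal_species, min_members = 10,
                            alpha_normal = 0.05, z_flag = 1.5) {
  scr <- screen_families(counts, min_members, alpha_normal)
  scr$mu <- rowMeans(counts)
  scr$sigma <- apply(counts, 1, stats::sd)
  scr$x <- counts[, focal_species]
  scr$z <- NA_real_
  ok <- scr$screened_out == "no"
  scr$z[ok] <- (scr$x[ok] - scr$mu[ok]) / scr$sigma[ok]
  scr$flagged <- !is.na(scr$z) & scr$z > z_flag
  scr
}

#' Per-family WGD retention table
#'
#' For each TF family of the focal genome, counts members retained after
#' the sigma event, the rho event, and their union, with the union
#' percentage of the family size (one decimal).
#' @param tf_table Focal-species gene-to-family table
#'   (\code{gene_id, family}).
#' @param sigma_set,rho_set Retained gene-id sets from
#'   \code{\link{retained_gene_sets}}.
#' @param families Optional family subset/order (default: all in
#'   \code{tf_table}).
#' @return Data frame per family: \code{family, n_genome, n_sigma, n_rho,
#'   n_union, fraction_union}.
#' @export
retention_table <- function(tf_table, sigma_set, rho_set, families = NULL) {
  if (is.null(families)) families <- sort(unique(tf_table$family))
  rows <- lapply(families, function(f) {
    members <- unique(tf_table$gene_id[tf_table$family == f])
    ns <- sum(members %in% sigma_set)
    nr <- sum(members %in% rho_set)
    nu <- sum(members %in% union(sigma_set, rho_set))
    data.frame(family = f, n_genome = length(members), n_sigma = ns,
               n_rho = nr, n_union = nu,
               fraction_union = summary_percentages(nu, length(members)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Range of union retention fractions across families
#' @param rows Result of \code{\link{retention_table}}.
#' @return Named numeric: \code{min}, \code{max}.
#' @export
retention_fraction_range <- function(rows) {
  if (nrow(rows) == 0) stop("no retention rows", call. = FALSE)
  c(min = min(rows$fraction_union), max = max(rows$fraction_union))
}
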