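#' Common-dispersion negative binomial likelihood ratio tests
#'
#' Gene-level differential expression is tested with a negative binomial
#' (NB) model whose variance is a quadratic function of the mean,
#' \eqn{V(\mu) = \mu + \phi \mu^2}; \eqn{\phi = 0} recovers the Poisson
#' model. A single dispersion \eqn{\phi} is shared by all genes.
#'
#' `estimate_common_dispersion()` maximizes, over \eqn{\phi \ge 0}, the
#' sum across genes and groups of the NB log-likelihood *conditional on
#' the group sum*, which eliminates the per-gene mean nuisance
#' parameters. (Plain ML jointly over the thousands of per-gene means is
#' inconsistent for \eqn{\phi} at a fixed number of lanes and
#' underestimates it noticeably.) Conditioning assumes lanes within a
#' group have equal expected library sizes, which holds after
#' between-lane normalization. Genes with zero counts in every lane are
#' excluded.
#'
#' `nb_lrt()` tests each gene by comparing a full model with one mean
#' per group against a null model with a single mean. Normalization
#' offsets \eqn{o_{ji}} (the log-scale amount normalization *adds* to a
#' count, as returned by [counts_to_offsets()]) enter the raw-count
#' model with a minus sign, \eqn{\mu_{ji} = e^{\beta - o_{ji}}}, so that
#' testing raw counts plus offsets approximates testing the normalized
#' counts themselves; \eqn{\beta} is fitted by iteratively reweighted
#' updates. The
#' statistic \eqn{2(\ell_{full} - \ell_{null})} is referred to a
#' chi-square with (groups - 1) degrees of freedom.
#'
#' @param counts Counts tibble (`gene_id` plus one column per lane).
#' @param groups Group of each lane: a character/factor vector aligned
#'   to the lane columns, or a lane-metadata tibble whose `condition`
#'   column is used.
#' @param interval Search interval for \eqn{\phi} (default `c(0, 5)`).
#' @return `estimate_common_dispersion()`: the scalar \eqn{\hat\phi}.
#' @export
#' @examples
#' sim <- simulate_counts(sim_config(n_genes = 400, phi = 0.1, seed = 3))
#' estimate_common_dispersion(sim$counts, sim$meta)
estimate_common_dispersion <- function(counts, groups, interval = c(0, 5)) {
  validate_counts(counts, integer_counts = FALSE)
  mat <- counts_matrix(counts)
  grp <- resolve_groups(groups, colnames(mat))
  mat <- mat[rowSums(mat) > 0, , drop = FALSE]
  if (nrow(mat) == 0) stop("all genes have zero counts in every lane", call. = FALSE)
  if (all(table(grp) <= 1)) {
    warning("no within-group replication; dispersion unidentifiable, returning 0")
    return(0)
  }
  obj <- function(phi) nb_cond_loglik(phi, mat, grp)
  lo <- max(interval[1], 1e-6)
  opt <- optimize(obj, interval = c(lo, interval[2]), maximum = TRUE, tol = 1e-6)
  if (obj(lo) >= opt$objective) 0 else opt$maximum
}

#' @rdname estimate_common_dispersion
#' @param phi Common dispersion \eqn{\phi \ge 0}, typically from
#'   [estimate_common_dispersion()].
#' @param offsets Optional log-scale offset tibble with the shape of
#'   `counts` (see [counts_to_offsets()]); `NULL` for none.
#' @return `nb_lrt()`: an object of class `nb_de`; see [tidy.nb_de()].
#' @export
nb_lrt <- function(counts, groups, phi, offsets = NULL) {
  validate_counts(counts)
  stopifnot(is.numeric(phi), length(phi) == 1, phi >= 0)
  mat <- counts_matrix(counts)
  grp <- resolve_groups(groups, colnames(mat))
  g <- nlevels(grp)
  if (g < 2) stop("need at least two groups", call. = FALSE)
  off <- NULL
  if (!is.null(offsets)) {
    if (!identical(dim(offsets), dim(counts)) ||
        !identical(offsets$gene_id, counts$gene_id)) {
      stop("offsets must share the shape and gene ids of counts", call. = FALSE)
    }
    off <- -as.matrix(offsets[, -1, drop = FALSE])
  }
  mu_full <- fitted_means(mat, grp, phi, off)
  mu_null <- fitted_means(mat, factor(rep("all", ncol(mat))), phi, off)
  stat <- pmax(0, 2 * (rowSums(nb_loglik(mat, mu_full, phi)) -
                       rowSums(nb_loglik(mat, mu_null, phi))))
  df <- g - 1L
  res <- tibble::tibble(
    gene_id = rownames(mat),
    lrt_stat = unname(stat),
    df = df,
    p_value = pchisq(unname(stat), df = df, lower.tail = FALSE)
  )
  structure(
    list(results = res, phi = phi, groups = grp,
         lane_ids = colnames(mat), offsets_used = !is.null(off)),
    class = "nb_de"
  )
}

#' Differential expression in one call
#'
#' Convenience wrapper: estimates the common dispersion (unless given)
#' and runs the NB likelihood ratio test per gene.
#'
#' @inheritParams nb_lrt
#' @param phi Common dispersion; estimated from the data when `NULL`.
#' @return An `nb_de` object.
#' @export
test_de <- function(counts, groups, offsets = NULL, phi = NULL) {
  if (is.null(phi)) phi <- estimate_common_dispersion(counts, groups)
  nb_lrt(counts, groups, phi, offsets = offsets)
}

#' Multiple-testing adjustment of p-values
#'
#' Bonferroni (`min(1, p * m)`) or Benjamini-Hochberg step-up adjusted
#' p-values, with an explicit family size `m` so a subset of a larger
#' family can be adjusted correctly.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @param method `"bh"` (default) or `"bonferroni"`.
#' @param m Family size (defaults to `length(p)`).
#' @return Numeric vector of adjusted p-values.
#' @export
#' @examples
#' adjust_pvalues(1e-5, "bonferroni", m = 5690)
adjust_pvalues <- function(p, method = c("bh", "bonferroni"), m = length(p)) {
  method <- match.arg(method)
  if (any(p < 0 | p > 1)) stop("p-values must be in [0, 1]", call. = FALSE)
  p.adjust(p, method = c(bh = "BH", bonferroni = "bonferroni")[[method]], n = m)
}

#' @export
print.nb_de <- function(x, ...) {
  cat("Negative binomial LRT (common dispersion)\n")
  cat(sprintf("  genes: %d   lanes: %d   groups: %d   df: %d\n",
              nrow(x$results), length(x$lane_ids), nlevels(x$groups),
              x$results$df[1]))
  cat(sprintf("  phi_hat: %.4g   offsets: %s\n", x$phi,
              if (x$offsets_used) "yes" else "no"))
  print(x$results, n = 5)
  invisible(x)
}

#' Tidy and summarize an NB differential expression fit
#'
#' `tidy()` returns the per-gene table (LRT statistic, degrees of
#' freedom, raw and adjusted p-values); `glance()` a one-row model
#' summary.
#'
#' @param x An `nb_de` object from [nb_lrt()] or [test_de()].
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.nb_de <- function(x, ...) {
  dplyr::mutate(x$results,
    p_bonferroni = adjust_pvalues(.data$p_value, "bonferroni"),
    p_bh = adjust_pvalues(.data$p_value, "bh")
  )
}

#' @rdname tidy.nb_de
#' @export
glance.nb_de <- function(x, ...) {
  tibble::tibble(
    n_genes = nrow(x$results),
    n_lanes = length(x$lane_ids),
    n_groups = nlevels(x$groups),
    df = x$results$df[1],
    phi_hat = x$phi,
    n_signif_bh_05 = sum(adjust_pvalues(x$results$p_value, "bh") <= 0.05)
  )
}

# ---- internal ---------------------------------------------------------

resolve_groups <- function(groups, lane_ids) {
  if (is.data.frame(groups)) {
    grp <- as.character(lane_conditions(groups, lane_ids))
  } else {
    if (length(groups) != length(lane_ids)) {
      stop("'groups' must have one entry per lane", call. = FALSE)
    }
    grp <- as.character(groups)
  }
  factor(grp, levels = unique(grp))
}

# NB log-likelihood of counts conditional on their group sums: with
# size r = 1/phi and n lanes in a group, the r-dependent part is
#   sum_i lgamma(y_i + r) - n lgamma(r) + lgamma(n r) - lgamma(z + n r).
nb_cond_loglik <- function(phi, mat, grp) {
  r <- 1 / phi
  tot <- 0
  for (g in levels(grp)) {
    Y <- mat[, grp == g, drop = FALSE]
    n <- ncol(Y)
    if (n < 2) next  # a single lane carries no dispersion information
    z <- rowSums(Y)
    tot <- tot + sum(rowSums(lgamma(Y + r)) - n * lgamma(r) +
                       lgamma(n * r) - lgamma(z + n * r))
  }
  tot
}

# Elementwise NB log-likelihood; phi = 0 is the Poisson limit.
nb_loglik <- function(y, mu, phi) {
  if (phi <= 0) stats::dpois(y, lambda = mu, log = TRUE)
  else stats::dnbinom(y, size = 1 / phi, mu = mu, log = TRUE)
}

group_mean_matrix <- function(mat, grp) {
  mu <- matrix(0, nrow(mat), ncol(mat), dimnames = dimnames(mat))
  for (g in levels(grp)) {
    idx <- which(grp == g)
    mu[, idx] <- rowMeans(mat[, idx, drop = FALSE])
  }
  mu
}

# ML fitted means per gene and group. Without offsets these are the
# group sample means exactly; with offsets, beta solves the score
# equation sum (y - mu) / (1 + phi * mu) = 0 by fixed-point updates.
fitted_means <- function(mat, grp, phi, off = NULL) {
  if (is.null(off)) return(group_mean_matrix(mat, grp))
  mu <- matrix(0, nrow(mat), ncol(mat), dimnames = dimnames(mat))
  for (g in levels(grp)) {
    idx <- which(grp == g)
    Y <- mat[, idx, drop = FALSE]
    O <- off[, idx, drop = FALSE]
    beta <- log((rowSums(Y) + 0.1) / length(idx)) - rowMeans(O)
    for (it in seq_len(50)) {
      M <- exp(beta + O)
      w <- 1 / (1 + phi * M)
      step <- log(pmax(rowSums(Y * w), 1e-12) / pmax(rowSums(M * w), 1e-12))
      beta <- pmax(beta + step, -30)
      if (max(abs(step)) < 1e-10) break
    }
    mu[, idx] <- exp(beta + O)
  }
  mu
}
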