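#' Configure the RNA-Seq count simulator
#'
#' Builds the configuration for [simulate_counts()]. The simulator
#' emulates the features of real lane-level RNA-Seq count data that
#' drive GC-content normalization benchmarks: a library-specific,
#' unimodal GC-content effect on the log scale (lanes sequencing the
#' same library share the effect exactly; libraries differ), per-lane
#' sequencing-depth factors, negative binomial over-dispersion, and
#' optional known true fold-changes between conditions.
#'
#' The GC effect for library \eqn{\ell} is the concave quadratic
#' \eqn{f_\ell(x) = c_\ell (x - m_\ell)^2} centred to mean zero over the
#' simulated genes, with peak \eqn{m_\ell} and curvature
#' \eqn{c_\ell \le 0} (a convex curvature is rejected). The mean count
#' of gene j in lane i is
#' \eqn{\mu_{ji} = d_i \exp(a_j + f_{\ell(i)}(x_j) + \beta_{j,c(i)} \log 2)}
#' and counts are drawn NB with variance \eqn{\mu + \phi \mu^2}.
#'
#' @param n_genes Number of genes (default 2000).
#' @param n_libraries Number of libraries (default 4, each a biological
#'   replicate culture).
#' @param lanes_per_library Lanes sequencing each library (default 2,
#'   giving the default 4 x 2 = 8 replicate-lane design).
#' @param conditions Condition of each library (default: all `"A"`, a
#'   null design with no differential expression).
#' @param phi NB dispersion (default 0.078, a typical estimate for
#'   replicated yeast lanes).
#' @param gc_bias_peak,gc_bias_curvature Per-library peak location and
#'   curvature of the quadratic GC effect; `NULL` (default) draws peaks
#'   uniformly in \[0.35, 0.6\] and curvatures uniformly in \[-10, -4\]
#'   (log-scale units), a strong, clearly library-specific effect.
#'   Set `gc_bias_curvature = 0` for no GC bias.
#' @param depth_factors Per-lane depth multipliers; `NULL` draws them
#'   uniformly in \[0.7, 1.4\].
#' @param true_lfc Per-gene true log2 fold-changes: a vector (applied to
#'   every non-reference condition) or a genes x conditions matrix whose
#'   first column (reference) is zero. Default: no differential
#'   expression.
#' @param baseline_meanlog,baseline_sdlog Parameters of the log-normal
#'   baseline expression \eqn{e^{a_j}} (defaults log(200) and 1.2, so
#'   counts span roughly 10 to 10^4 and the low-count filter is
#'   non-trivial).
#' @param gc_shape1,gc_shape2,gc_range Gene GC fractions are drawn
#'   Beta(`gc_shape1`, `gc_shape2`) rescaled to `gc_range`
#'   (defaults Beta(2, 2) on \[0.2, 0.8\]).
#' @param seed Mandatory integer seed; the same configuration and seed
#'   reproduce counts exactly.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_genes = 2000, n_libraries = 4, lanes_per_library = 2,
                       conditions = NULL, phi = 0.078,
                       gc_bias_peak = NULL, gc_bias_curvature = NULL,
                       depth_factors = NULL, true_lfc = NULL,
                       baseline_meanlog = log(200), baseline_sdlog = 1.2,
                       gc_shape1 = 2, gc_shape2 = 2, gc_range = c(0.2, 0.8),
                       seed) {
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1) {
    stop("a scalar integer 'seed' is required", call. = FALSE)
  }
  if (is.null(conditions)) conditions <- rep("A", n_libraries)
  if (length(conditions) != n_libraries) {
    stop("'conditions' must have one entry per library", call. = FALSE)
  }
  if (!is.null(gc_bias_curvature)) {
    gc_bias_curvature <- rep_len(gc_bias_curvature, n_libraries)
    if (any(gc_bias_curvature > 0)) {
      stop("gc_bias_curvature must be <= 0 (the GC effect is concave/unimodal)",
           call. = FALSE)
    }
  }
  if (!is.null(gc_bias_peak)) gc_bias_peak <- rep_len(gc_bias_peak, n_libraries)
  stopifnot(phi >= 0, n_genes >= 1, n_libraries >= 1, lanes_per_library >= 1)
  structure(
    list(n_genes = n_genes, n_libraries = n_libraries,
         lanes_per_library = lanes_per_library, conditions = conditions,
         phi = phi, gc_bias_peak = gc_bias_peak,
         gc_bias_curvature = gc_bias_curvature, depth_factors = depth_factors,
         true_lfc = true_lfc, baseline_meanlog = baseline_meanlog,
         baseline_sdlog = baseline_sdlog, gc_shape1 = gc_shape1,
         gc_shape2 = gc_shape2, gc_range = gc_range, seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' Simulate RNA-Seq counts with library-specific GC bias
#'
#' Draws a genes-by-lanes count table under the model described in
#' [sim_config()], together with the gene features, lane metadata and
#' true fold-change table needed by the normalization, testing and
#' evaluation functions.
#'
#' @param config A [sim_config()] object.
#' @return A list with tibbles `counts` (gene_id plus one column per
#'   lane), `features` (`gene_id`, `gc`, `length_bp`), `meta`
#'   (`lane_id`, `condition`, `library`, `flowcell`, `protocol`),
#'   `truth` (`gene_id` plus one true-log2-fold-change column per
#'   condition), and `baseline` (`gene_id`, `log_mean` = the baseline
#'   log expression \eqn{a_j}, handy for calibration checks).
#' @export
#' @examples
#' sim <- simulate_counts(sim_config(n_genes = 100, seed = 1))
#' sim$counts
simulate_counts <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  J <- config$n_genes
  n_lib <- config$n_libraries
  L <- n_lib * config$lanes_per_library
  cond_levels <- unique(config$conditions)

  gene_id <- sprintf("gene_%04d", seq_len(J))
  gc <- config$gc_range[1] +
    diff(config$gc_range) * rbeta(J, config$gc_shape1, config$gc_shape2)
  length_bp <- pmax(200L, as.integer(round(exp(rnorm(J, log(1200), 0.45)))))
  a <- rnorm(J, config$baseline_meanlog, config$baseline_sdlog)

  peaks <- config$gc_bias_peak %||% runif(n_lib, 0.35, 0.6)
  curv <- config$gc_bias_curvature %||% runif(n_lib, -10, -4)
  depth <- config$depth_factors %||% runif(L, 0.7, 1.4)
  if (length(depth) != L) stop("'depth_factors' must have one entry per lane", call. = FALSE)

  beta <- true_lfc_matrix(config$true_lfc, J, cond_levels)

  lib_of_lane <- rep(seq_len(n_lib), each = config$lanes_per_library)
  lane_id <- sprintf("lib%d_lane%d", lib_of_lane,
                     sequence(rep(config$lanes_per_library, n_lib)))
  meta <- tibble::tibble(
    lane_id = lane_id,
    condition = config$conditions[lib_of_lane],
    library = sprintf("lib%d", lib_of_lane),
    flowcell = sprintf("fc%d", ((seq_len(L) - 1) %% 2) + 1),
    protocol = ifelse(lib_of_lane == n_lib & n_lib > 1, "P2", "P1")
  )

  # library GC effects, centred so they do not change overall depth
  f_lib <- vapply(seq_len(n_lib), function(l) {
    f <- curv[l] * (gc - peaks[l])^2
    f - mean(f)
  }, numeric(J))

  mat <- matrix(0L, J, L, dimnames = list(gene_id, lane_id))
  for (i in seq_len(L)) {
    l <- lib_of_lane[i]
    mu <- depth[i] * exp(a + f_lib[, l] + beta[, meta$condition[i]] * log(2))
    mat[, i] <- if (config$phi <= 0) rpois(J, mu)
                else rnbinom(J, size = 1 / config$phi, mu = mu)
  }

  list(
    counts = matrix_to_counts(mat),
    features = tibble::tibble(gene_id = gene_id, gc = gc, length_bp = length_bp),
    meta = meta,
    truth = tibble::as_tibble(cbind(
      tibble::tibble(gene_id = gene_id),
      tibble::as_tibble(beta)
    )),
    baseline = tibble::tibble(gene_id = gene_id, log_mean = a)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

true_lfc_matrix <- function(true_lfc, J, cond_levels) {
  beta <- matrix(0, J, length(cond_levels),
                 dimnames = list(NULL, cond_levels))
  if (is.null(true_lfc)) return(beta)
  if (is.matrix(true_lfc)) {
    if (nrow(true_lfc) != J || ncol(true_lfc) != length(cond_levels)) {
      stop("'true_lfc' matrix must be genes x conditions", call. = FALSE)
    }
    beta[] <- true_lfc
  } else {
    if (length(true_lfc) != J) stop("'true_lfc' must have one entry per gene", call. = FALSE)
    if (length(cond_levels) < 2) {
      stop("'true_lfc' needs at least two conditions to apply to", call. = FALSE)
    }
    beta[, -1] <- true_lfc
  }
  if (any(beta[, 1] != 0)) {
    stop("the first (reference) condition must have zero log-fold-change", call. = FALSE)
  }
  beta
}
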