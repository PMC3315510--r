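#' Enumerate balanced null splits of replicate lanes
#'
#' All unordered partitions of `2n` replicate lanes into two groups of
#' `n`, the "null pseudo-datasets" used to measure fold-change bias, MSE
#' and Type I error when no differential expression is expected. There
#' are \eqn{\binom{2n}{n}/2} such partitions (35 for 8 lanes, 10 for 6);
#' mirror duplicates are removed by pinning the lexicographically
#' smallest lane in `group_a`, and enumeration is lexicographic.
#'
#' @param lane_ids Character vector of an even number of lane ids.
#' @return A tibble with integer `split` and list-columns `group_a`,
#'   `group_b` of lane ids.
#' @export
#' @examples
#' nrow(enumerate_balanced_splits(paste0("L", 1:8)))
enumerate_balanced_splits <- function(lane_ids) {
  lane_ids <- as.character(lane_ids)
  n2 <- length(lane_ids)
  if (n2 < 2 || n2 %% 2 != 0) stop("need an even number (>= 2) of lanes", call. = FALSE)
  if (anyDuplicated(lane_ids)) stop("duplicate lane ids", call. = FALSE)
  n <- n2 %/% 2
  sorted <- sort(lane_ids)
  first <- sorted[1]
  rest <- sorted[-1]
  if (n == 1) {
    ga <- list(first)
  } else {
    companions <- combn(rest, n - 1)
    ga <- lapply(seq_len(ncol(companions)), function(i) c(first, companions[, i]))
  }
  tibble::tibble(
    split = seq_along(ga),
    group_a = ga,
    group_b = lapply(ga, function(a) setdiff(sorted, a))
  )
}

#' Per-gene log-fold-change between two sets of lanes
#'
#' Expression log-fold-changes are estimated as log-ratios of average
#' (normalized) read counts between the two groups:
#' \eqn{\log_b((\bar y_A + \delta) / (\bar y_B + \delta))}. The small
#' constant `delta` guards against zero group means.
#'
#' @param counts Counts tibble.
#' @param group_a,group_b Character vectors of lane ids.
#' @param base Logarithm base (default 2).
#' @param delta Constant added to each group mean (default 0.5).
#' @return A tibble with `gene_id` and `lfc`.
#' @export
estimate_log_fold_change <- function(counts, group_a, group_b, base = 2, delta = 0.5) {
  validate_counts(counts, integer_counts = FALSE)
  mat <- counts_matrix(counts)
  bad <- setdiff(c(group_a, group_b), colnames(mat))
  if (length(bad) > 0) stop("unknown lanes: ", paste(bad, collapse = ", "), call. = FALSE)
  if (length(group_a) == 0 || length(group_b) == 0) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  ma <- rowMeans(mat[, group_a, drop = FALSE])
  mb <- rowMeans(mat[, group_b, drop = FALSE])
  tibble::tibble(
    gene_id = rownames(mat),
    lfc = unname(log((ma + delta) / (mb + delta), base = base))
  )
}

#' Fold-change bias and MSE over null splits
#'
#' For each gene, `bias` is the mean of the per-split log-fold-changes
#' and `mse` the mean of their squares, over all supplied balanced
#' splits; under the null the truth is zero, so both should be small
#' after adequate normalization.
#'
#' @param counts Counts tibble of normalized counts.
#' @param splits Splits tibble from [enumerate_balanced_splits()].
#' @inheritParams estimate_log_fold_change
#' @return A tibble with `gene_id`, `bias`, `mse`.
#' @export
bias_mse_over_splits <- function(counts, splits, base = 2, delta = 0.5) {
  if (nrow(splits) < 1) stop("need at least one split", call. = FALSE)
  lfcs <- purrr::map(seq_len(nrow(splits)), function(i) {
    estimate_log_fold_change(counts, splits$group_a[[i]], splits$group_b[[i]],
                             base = base, delta = delta)$lfc
  })
  lfc_mat <- do.call(cbind, lfcs)
  tibble::tibble(
    gene_id = counts$gene_id,
    bias = rowMeans(lfc_mat),
    mse = rowMeans(lfc_mat^2)
  )
}

#' Fold-change bias against a gold-standard reference
#'
#' When an external technology provides reference log-fold-changes
#' (e.g. qRT-PCR), per-gene bias is the difference between the estimate
#' and the reference.
#'
#' @inheritParams estimate_log_fold_change
#' @param reference_lfc Numeric vector of reference log-fold-changes
#'   aligned to the genes of `counts`.
#' @return A tibble with `gene_id`, `lfc`, `reference_lfc`, `bias`.
#' @export
bias_vs_reference <- function(counts, group_a, group_b, reference_lfc,
                              base = 2, delta = 0.5) {
  if (length(reference_lfc) != nrow(counts)) {
    stop("reference_lfc must align with the genes of counts", call. = FALSE)
  }
  est <- estimate_log_fold_change(counts, group_a, group_b, base = base, delta = delta)
  dplyr::mutate(est, reference_lfc = reference_lfc, bias = .data$lfc - reference_lfc)
}

#' Actual vs nominal Type I error
#'
#' The actual Type I error at nominal level \eqn{\alpha} is the
#' proportion of genes with unadjusted p-value \eqn{\le \alpha}
#' (the p-value ECDF evaluated on the grid).
#'
#' @param p_values Numeric vector of unadjusted p-values.
#' @param alphas Nominal levels; default 200 points uniform on (0, 0.2].
#' @return A tibble with `alpha` and `actual`, non-decreasing in `alpha`.
#' @export
type_i_error_curve <- function(p_values, alphas = default_alpha_grid()) {
  if (any(p_values < 0 | p_values > 1)) stop("p-values must be in [0, 1]", call. = FALSE)
  if (any(alphas <= 0 | alphas > 1)) stop("alphas must be in (0, 1]", call. = FALSE)
  alphas <- sort(alphas)
  tibble::tibble(
    alpha = alphas,
    actual = vapply(alphas, function(a) mean(p_values <= a), numeric(1))
  )
}

#' @rdname type_i_error_curve
#' @export
default_alpha_grid <- function() seq(0.001, 0.2, length.out = 200)

#' Worst-case envelope area of Type I error curves
#'
#' Summarizes a family of Type I error curves (one per null
#' pseudo-dataset) by the area between the most conservative and most
#' anti-conservative deviations from the nominal level: the trapezoidal
#' integral over \eqn{\alpha} of max minus min across curves of
#' (actual - nominal). Smaller areas mean the test holds its level more
#' uniformly across pseudo-datasets.
#'
#' @param curves A list of curves from [type_i_error_curve()], all on
#'   the same alpha grid.
#' @return The scalar envelope area.
#' @export
worst_case_envelope_area <- function(curves) {
  if (length(curves) < 2) stop("need at least two curves", call. = FALSE)
  grid <- curves[[1]]$alpha
  dev <- vapply(curves, function(cv) {
    if (!isTRUE(all.equal(cv$alpha, grid))) {
      stop("curves must share the same alpha grid", call. = FALSE)
    }
    cv$actual - cv$alpha
  }, numeric(length(grid)))
  gap <- apply(dev, 1, max) - apply(dev, 1, min)
  trapezoid(grid, gap)
}

#' GC-stratified summaries of a per-gene statistic
#'
#' Stratifies a per-gene value (log-count, log-ratio, DE indicator,
#' p-value, ...) into `K` equally-sized GC bins and summarizes each bin
#' by its quartiles and mean; for a 0/1 indicator the mean is the
#' proportion (e.g. proportion of genes called DE per GC stratum).
#'
#' @param values Numeric vector aligned to `features`, or a two-column
#'   data frame (`gene_id`, value).
#' @param features Gene-feature tibble with `gene_id` and `gc`.
#' @param K Number of GC strata (default 10).
#' @return A tibble with one row per bin: `bin`, `n`, `gc_mid`, `q1`,
#'   `median`, `q3`, `mean`.
#' @export
gc_stratified_summary <- function(values, features, K = 10) {
  if (is.data.frame(values)) {
    stopifnot(ncol(values) >= 2, "gene_id" %in% names(values))
    val_col <- setdiff(names(values), "gene_id")[1]
    v <- values[[val_col]][match(features$gene_id, values$gene_id)]
  } else {
    if (length(values) != nrow(features)) {
      stop("values must align with features", call. = FALSE)
    }
    v <- values
  }
  bins <- make_gc_bins(features, K)
  tibble::tibble(gc = bins$gc, bin = bins$bin, value = v) |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(
      n = dplyr::n(),
      gc_mid = median(.data$gc),
      q1 = quantile(.data$value, 0.25, names = FALSE),
      median = median(.data$value),
      q3 = quantile(.data$value, 0.75, names = FALSE),
      mean = mean(.data$value),
      .groups = "drop"
    )
}

#' Lowess fit of a per-gene statistic against GC-content
#'
#' The smoother behind count-vs-GC diagnostic curves. `gc_lowess()`
#' returns the fitted curve; `gc_lowess_range()` the range (max - min)
#' of the fitted values, a scalar measure of how strongly the statistic
#' depends on GC-content.
#'
#' @param values Numeric per-gene vector.
#' @param gc GC fractions aligned to `values`.
#' @param f Lowess smoother span (default 2/3).
#' @return `gc_lowess()`: tibble with `gc` and `fit` (sorted by `gc`);
#'   `gc_lowess_range()`: a scalar.
#' @export
gc_lowess <- function(values, gc, f = 2/3) {
  stopifnot(length(values) == length(gc))
  fit <- lowess(gc, values, f = f)
  tibble::tibble(gc = fit$x, fit = fit$y)
}

#' @rdname gc_lowess
#' @export
gc_lowess_range <- function(values, gc, f = 2/3) {
  diff(range(gc_lowess(values, gc, f = f)$fit))
}

trapezoid <- function(x, y) sum(diff(x) * (head(y, -1) + y[-1]) / 2)
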