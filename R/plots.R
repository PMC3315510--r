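#' Diagnostic plot: read count vs GC-content per lane
#'
#' Lowess fits of gene-level `log(count + delta)` against GC-content,
#' one curve per lane, coloured by library when metadata are supplied.
#' Lanes sequencing the same library should trace the same curve; curves
#' differing between libraries are the signature of a sample-specific
#' GC effect.
#'
#' @param counts Counts tibble.
#' @param features Gene-feature tibble covering the genes of `counts`.
#' @param meta Optional lane metadata (used to colour by `library`).
#' @param delta Log-offset constant (default 1).
#' @param f Lowess span (default 2/3).
#' @return A ggplot object.
#' @export
plot_gc_bias <- function(counts, features, meta = NULL, delta = 1, f = 2/3) {
  validate_counts(counts, integer_counts = FALSE)
  features <- align_features(features, counts)
  curves <- counts |>
    tidyr::pivot_longer(-"gene_id", names_to = "lane_id", values_to = "count") |>
    dplyr::left_join(features[, c("gene_id", "gc")], by = "gene_id") |>
    dplyr::group_by(.data$lane_id) |>
    dplyr::reframe(gc_lowess(log(.data$count + delta), .data$gc, f = f))
  if (!is.null(meta)) {
    curves <- dplyr::left_join(curves, meta[, c("lane_id", "library")], by = "lane_id")
    aes <- ggplot2::aes(x = .data$gc, y = .data$fit, group = .data$lane_id,
                        colour = .data$library)
  } else {
    aes <- ggplot2::aes(x = .data$gc, y = .data$fit, colour = .data$lane_id)
  }
  ggplot2::ggplot(curves, aes) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "GC-content", y = sprintf("lowess of log(count + %g)", delta)) +
    ggplot2::theme_minimal()
}

#' Diagnostic plot: a per-gene statistic stratified by GC-content
#'
#' Per-bin median and interquartile ribbon of a gene-level statistic
#' (e.g. a between-lane log-ratio) against GC stratum: the stratified
#' summary view used to judge whether fold-changes depend on GC.
#'
#' @param values Numeric per-gene vector, or a (`gene_id`, value) data
#'   frame.
#' @param features Gene-feature tibble with `gene_id` and `gc`.
#' @param K Number of GC strata (default 10).
#' @return A ggplot object.
#' @export
plot_gc_stratified <- function(values, features, K = 10) {
  summ <- gc_stratified_summary(values, features, K = K)
  ggplot2::ggplot(summ, ggplot2::aes(x = .data$gc_mid, y = .data$median)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$q1, ymax = .data$q3),
                         alpha = 0.3) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "GC-content (stratum median)", y = "median (IQR ribbon)") +
    ggplot2::theme_minimal()
}

#' Diagnostic plot: Type I error deviation envelope
#'
#' Plots, for a family of Type I error curves (one per null
#' pseudo-dataset), every deviation curve (actual - nominal) against the
#' nominal level, with the worst-case envelope shaded.
#'
#' @param curves List of tibbles from [type_i_error_curve()] on a
#'   shared grid.
#' @return A ggplot object.
#' @export
plot_type_i_error <- function(curves) {
  if (is.null(names(curves))) names(curves) <- seq_along(curves)
  long <- purrr::imap(curves, function(cv, id) {
    dplyr::mutate(cv, curve = id, deviation = .data$actual - .data$alpha)
  }) |> purrr::list_rbind()
  env <- long |>
    dplyr::group_by(.data$alpha) |>
    dplyr::summarise(lo = min(.data$deviation), hi = max(.data$deviation),
                     .groups = "drop")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$alpha)) +
    ggplot2::geom_ribbon(
      data = env,
      mapping = ggplot2::aes(x = .data$alpha, ymin = .data$lo, ymax = .data$hi),
      alpha = 0.25, inherit.aes = FALSE) +
    ggplot2::geom_line(ggplot2::aes(y = .data$deviation, group = .data$curve),
                       linewidth = 0.2, alpha = 0.6) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::labs(x = "nominal Type I error", y = "actual - nominal") +
    ggplot2::theme_minimal()
}

#' @describeIn tidy.nb_de Histogram of unadjusted p-values; a flat
#'   histogram is expected under the null.
#' @param object An `nb_de` object.
#' @export
autoplot.nb_de <- function(object, ...) {
  ggplot2::ggplot(object$results, ggplot2::aes(x = .data$p_value)) +
    ggplot2::geom_histogram(breaks = seq(0, 1, by = 0.05),
                            fill = "grey70", colour = "white") +
    ggplot2::labs(x = "unadjusted p-value", y = "genes") +
    ggplot2::theme_minimal()
}
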