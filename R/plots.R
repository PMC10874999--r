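#' Scatter plot of instrument effects
#'
#' Outcome against exposure effects per instrument with SE error bars;
#' one fitted line per estimator (through the origin for IVW and the
#' weighted median, with intercept for MR-Egger).
#'
#' @param insts An `mr_harmonized` tibble.
#' @param results Optional [mr_estimate()] table supplying slopes to draw.
#' @return A ggplot object.
#' @export
plot_mr_scatter <- function(insts, results = NULL) {
  df <- tibble::as_tibble(insts)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$beta_exp, y = .data$beta_out)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$beta_out - .data$se_out,
                                        ymax = .data$beta_out + .data$se_out),
                           linewidth = 0.2, colour = "grey55") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$beta_exp - .data$se_exp,
                                         xmax = .data$beta_exp + .data$se_exp),
                            linewidth = 0.2, colour = "grey55") +
    ggplot2::geom_point(size = 1.4) +
    ggplot2::labs(x = "SNP effect on exposure", y = "SNP effect on outcome") +
    ggplot2::theme_bw()
  if (!is.null(results) && nrow(results) > 0) {
    egger_int <- 0
    lines <- dplyr::mutate(results,
                           intercept = ifelse(.data$method == "egger",
                                              NA_real_, 0))
    p <- p + ggplot2::geom_abline(
      data = dplyr::mutate(lines, intercept = ifelse(is.na(.data$intercept),
                                                     egger_int, .data$intercept)),
      ggplot2::aes(slope = .data$beta, intercept = .data$intercept,
                   colour = .data$method)) +
      ggplot2::labs(colour = "Method")
  }
  p
}

#' Funnel plot of per-SNP causal estimates
#'
#' Precision (1/SE of the Wald ratio) against the ratio estimate;
#' symmetry about the pooled estimate is expected in the absence of
#' directional pleiotropy.
#'
#' @param x An `mr_harmonized` tibble or a [funnel_data()] table.
#' @param pooled Optional pooled estimate to mark with a vertical line.
#' @return A ggplot object.
#' @export
plot_funnel <- function(x, pooled = NULL) {
  df <- if (all(c("ratio", "precision") %in% names(x))) {
    tibble::as_tibble(x)
  } else {
    funnel_data(x)
  }
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$ratio, y = .data$precision)) +
    ggplot2::geom_point(size = 1.4) +
    ggplot2::labs(x = "Per-SNP causal estimate", y = "Precision (1/SE)") +
    ggplot2::theme_bw()
  if (!is.null(pooled)) {
    p <- p + ggplot2::geom_vline(xintercept = pooled, linetype = "dashed")
  }
  p
}

#' Forest plot of the leave-one-out analysis
#'
#' One row per excluded SNP showing the re-estimated causal effect and its
#' 95\% interval (log scale), so single influential instruments stand out.
#'
#' @param loo A [leave_one_out()] table.
#' @return A ggplot object.
#' @export
plot_leave_one_out <- function(loo) {
  df <- dplyr::mutate(loo,
                      lo = .data$beta - Z95 * .data$se,
                      hi = .data$beta + Z95 * .data$se)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$beta,
                                   y = stats::reorder(.data$snp_id_excluded,
                                                      .data$beta))) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dotted") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$lo, xmax = .data$hi),
                            height = 0, linewidth = 0.3) +
    ggplot2::geom_point(size = 1.2) +
    ggplot2::labs(x = "IVW estimate excluding SNP", y = "Excluded SNP") +
    ggplot2::theme_bw()
}

#' @describeIn run_analysis Plot a fitted report: `type = "scatter"`,
#'   `"funnel"` or `"loo"`.
#' @param object An `mr_report`.
#' @param type Which diagnostic to draw.
#' @method autoplot mr_report
#' @export
autoplot.mr_report <- function(object, type = c("scatter", "funnel", "loo"),
                               ...) {
  type <- rlang::arg_match(type)
  switch(type,
         scatter = plot_mr_scatter(object$harmonized, object$results),
         funnel = plot_funnel(object$funnel,
                              pooled = object$results$beta[
                                match("ivw_re", object$results$method)]),
         loo = plot_leave_one_out(object$loo))
}
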