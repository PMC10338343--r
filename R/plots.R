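# ggplot2 visualizations for the fitted-result classes.

#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_line geom_col
#'   geom_errorbar geom_boxplot geom_hline scale_y_log10 scale_x_log10
#'   labs theme_bw facet_wrap stat_function
NULL

#' @export
ggplot2::autoplot

#' Plot a burst-and-steady-state fit
#'
#' Pooled P_relative observations with the fitted cleavage curve.
#'
#' @param object A [fit_burst()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.piwikit_burst_fit <- function(object, ...) {
  dat <- attr(object, "data")
  p <- ggplot(dat, aes(x = .data$time_min, y = .data$p_relative)) +
    geom_point(alpha = 0.6) +
    labs(x = "time (min)", y = expression(P[relative]),
         subtitle = sprintf("k = %.3g min^-1", object$k)) +
    theme_bw()
  if (isTRUE(object$converged)) {
    e <- object$e_relative; k2 <- object$k2; k3 <- object$k3
    p <- p + stat_function(fun = function(t) burst_fraction(t, e, k2, k3),
                           color = "firebrick")
  }
  p
}

#' Plot per-site dissociation constants
#'
#' Median-of-starts Kd per site type on a log scale.
#'
#' @param object A [fit_kd_mle()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.piwikit_kd_fit <- function(object, ...) {
  ggplot(as_tibble(object),
         aes(x = stats::reorder(.data$site, .data$kd_pm), y = .data$kd_pm)) +
    geom_point(size = 2) +
    scale_y_log10() +
    labs(x = NULL, y = expression(K[d] ~ "(pM)")) +
    theme_bw()
}

#' Plot fraction cleaved per pairing configuration
#'
#' Median over replicate pairings with the bootstrap confidence interval.
#'
#' @param object A [fraction_cleaved()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.piwikit_fcleaved <- function(object, ...) {
  ggplot(as_tibble(object),
         aes(x = .data$configuration, y = .data$f_cleaved)) +
    geom_col(fill = "grey70") +
    geom_errorbar(aes(ymin = .data$ci_lo, ymax = .data$ci_hi), width = 0.2) +
    geom_hline(yintercept = 0, linetype = 2) +
    labs(x = "pairing configuration", y = expression(f[cleaved])) +
    theme_bw()
}

#' Plot escape-simulation trajectories
#'
#' Mean fraction of competent guides versus substitution count, per guide
#' class.
#'
#' @param object A [simulate_escape()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.piwikit_trajectories <- function(object, ...) {
  n_guides <- attr(object, "n_guides")
  long <- as_tibble(object) |>
    pivot_longer(cols = c("n_pirna", "n_sirna"), names_to = "class",
                 values_to = "n") |>
    mutate(class = ifelse(.data$class == "n_pirna", "piRNA (26 nt)",
                          "siRNA (21 nt)")) |>
    group_by(.data$class, .data$step) |>
    summarize(frac = mean(.data$n / n_guides), .groups = "drop")
  ggplot(long, aes(x = .data$step, y = .data$frac, color = .data$class)) +
    geom_line() +
    labs(x = "substitutions", y = "fraction of competent guides",
         color = NULL) +
    theme_bw()
}

#' Plot the ensemble coefficient distribution
#'
#' Box plots of the 400 fitted coefficients per feature.
#'
#' @param object A [fit_cleavage_ensemble()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.piwikit_ensemble <- function(object, ...) {
  td <- tidy(object) |> filter(.data$feature != "beta0")
  td$feature <- factor(td$feature, levels = paste0("x", 1:35))
  ggplot(td, aes(x = .data$feature, y = .data$estimate)) +
    geom_boxplot(outlier.size = 0.4) +
    geom_hline(yintercept = 0, linetype = 2) +
    labs(x = NULL, y = "coefficient") +
    theme_bw() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Plot shared k-mer fractions against k
#'
#' @param report A [shared_kmer_fraction()] result.
#' @return A ggplot.
#' @export
plot_kmer_overlap <- function(report) {
  ggplot(report, aes(x = .data$k, y = .data$fraction)) +
    geom_line() + geom_point() +
    labs(x = "k", y = "fraction of transcripts with a shared k-mer") +
    theme_bw()
}
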