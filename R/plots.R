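#' Replicate-concordance scatter plot
#'
#' Plots replicate 1 against replicate 2 intensities on log axes, the
#' standard view of a duplicate-synthesized array, optionally highlighting
#' the top-k peptides of a ranked profile (the tagged substrates of a
#' discovery plot).
#'
#' @param table A signal table with two replicates per peptide.
#' @param profile Optional ranked profile whose `top_k` peptides are
#'   highlighted and labelled.
#' @param max_points Subsample cap for rendering speed (default 50,000).
#' @param seed Seed for the subsample.
#' @return A ggplot object.
#' @export
plot_replicate_concordance <- function(table, profile = NULL,
                                       max_points = 50000L, seed = 1L) {
  wide <- table |>
    dplyr::arrange(.data$peptide, .data$replicate) |>
    dplyr::summarise(S1 = .data$intensity[1], S2 = .data$intensity[2],
                     .by = "peptide")
  if (nrow(wide) > max_points) {
    set.seed(seed)
    keep_top <- if (!is.null(profile)) {
      profile$peptide[profile$top_k]
    } else character()
    idx <- union(which(wide$peptide %in% keep_top),
                 sample(nrow(wide), max_points))
    wide <- wide[idx, ]
  }
  p <- ggplot2::ggplot(wide, ggplot2::aes(x = .data$S1, y = .data$S2)) +
    ggplot2::geom_point(alpha = 0.3, size = 0.5) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "replicate 1 intensity", y = "replicate 2 intensity") +
    ggplot2::theme_minimal()
  if (!is.null(profile)) {
    top <- dplyr::semi_join(wide,
                            dplyr::filter(profile, .data$top_k),
                            by = "peptide")
    p <- p +
      ggplot2::geom_point(data = top, colour = "red", size = 1.5) +
      ggplot2::geom_text(data = top, ggplot2::aes(label = .data$peptide),
                         size = 2.5, vjust = -0.6, colour = "red")
  }
  p
}

#' Kinetic trace with the extracted linear window
#'
#' @param trace A kinetic trace.
#' @param window Optional result of [extract_linear_rate()]; the fitted
#'   window is shaded and the fitted line drawn.
#' @return A ggplot object.
#' @export
plot_kinetic_trace <- function(trace, window = NULL) {
  p <- ggplot2::ggplot(trace, ggplot2::aes(x = .data$time_s, y = .data$a340)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.7) +
    ggplot2::labs(x = "time (s)", y = "A340") +
    ggplot2::theme_minimal()
  if (!is.null(window)) {
    in_win <- trace$time_s >= window$window_start_s &
      trace$time_s <= window$window_end_s
    fit <- stats::lm(a340 ~ time_s, data = trace[in_win, ])
    p <- p +
      ggplot2::annotate("rect",
                        xmin = window$window_start_s,
                        xmax = window$window_end_s,
                        ymin = -Inf, ymax = Inf,
                        alpha = 0.08, fill = "blue") +
      ggplot2::geom_abline(intercept = stats::coef(fit)[1],
                           slope = stats::coef(fit)[2],
                           colour = "blue", linetype = 2)
  }
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Michaelis-Menten curve over the rate observations
#'
#' @param object A converged `mm_fit`.
#' @param ... Unused.
#' @return A ggplot object: observed rates, fitted hyperbola, and the
#'   (Km, Vmax/2) reference lines.
#' @method autoplot mm_fit
#' @export
autoplot.mm_fit <- function(object, ...) {
  if (object$status != "converged") {
    stop("cannot plot a not-detectable fit", call. = FALSE)
  }
  s_grid <- seq(0, max(object$data$substrate_conc) * 1.05, length.out = 200)
  curve <- tibble::tibble(
    substrate_conc = s_grid,
    rate = predict(object, tibble::tibble(substrate_conc = s_grid))
  )
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$substrate_conc, y = .data$rate)) +
    ggplot2::geom_line(data = curve, colour = "blue") +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$Km, linetype = 3) +
    ggplot2::geom_hline(yintercept = object$Vmax / 2, linetype = 3) +
    ggplot2::labs(x = "substrate (uM)", y = "rate (pmol/s)",
                  title = sprintf("Vmax = %.3g pmol/s, Km = %.3g uM",
                                  object$Vmax, object$Km)) +
    ggplot2::theme_minimal()
}

#' Positional-enrichment heat map
#'
#' @param enrichment Output of [positional_enrichment()].
#' @return A ggplot object (position x residue tile map of log2 enrichment).
#' @export
plot_enrichment <- function(enrichment) {
  ggplot2::ggplot(enrichment,
                  ggplot2::aes(x = factor(.data$position), y = .data$residue,
                               fill = .data$enrichment_log2)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "steelblue", mid = "white",
                                  high = "firebrick", midpoint = 0) +
    ggplot2::labs(x = "position", y = "residue", fill = "log2 enrichment") +
    ggplot2::theme_minimal()
}
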