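# broom-style tidiers and ggplot2 autoplot methods for the fitted objects.

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy an LL4 dose-response fit
#'
#' @param x An `ll4_fit`.
#' @param ... Unused.
#' @return One row per parameter: `term`, `estimate`.
#' @export
tidy.ll4_fit <- function(x, ...) {
  tibble::tibble(term = c("b", "c", "d", "e"),
                 estimate = c(x$b, x$c, x$d, x$e))
}

#' @rdname tidy.ll4_fit
#' @export
glance.ll4_fit <- function(x, ...) {
  tibble::tibble(rss = x$rss, converged = x$converged,
                 n_points_used = x$n_points_used,
                 ic50_rel = x$e,
                 ic50_abs = tryCatch(ic50_from_fit(x, "absolute"),
                                     error = function(e) NA_real_))
}

#' Tidy a synergy surface into a long cell table
#'
#' @param x A `synergy_surface`.
#' @param ... Unused.
#' @return Long tibble: `conc_a`, `conc_b`, `delta` (percentage points).
#' @export
tidy.synergy_surface <- function(x, ...) {
  expand.grid(conc_a = x$dosesA, conc_b = x$dosesB) |>
    tibble::as_tibble() |>
    dplyr::mutate(delta = as.vector(x$delta))
}

#' @rdname tidy.synergy_surface
#' @export
glance.synergy_surface <- function(x, ...) {
  tibble::tibble(model = x$model, drug_a = x$drugA, drug_b = x$drugB,
                 summary_mean = x$summary_mean, peak_score = x$peak_score,
                 classification = classify_score(x$peak_score))
}

#' Tidy a checkerboard into a long well table
#'
#' @param x A `checkerboard_matrix`.
#' @param ... Unused.
#' @return Long tibble: `conc_a`, `conc_b`, `replicate`, `viability`.
#' @export
tidy.checkerboard_matrix <- function(x, ...) {
  nr <- dim(x$viability)[3]
  grid <- expand.grid(i = seq_along(x$dosesA), j = seq_along(x$dosesB),
                      replicate = seq_len(nr))
  tibble::tibble(
    conc_a = x$dosesA[grid$i],
    conc_b = x$dosesB[grid$j],
    replicate = grid$replicate,
    viability = x$viability[cbind(grid$i, grid$j, grid$replicate)]
  )
}

#' Plot a fitted dose-response curve over its data
#'
#' @param object An `ll4_fit`.
#' @param ... Unused.
#' @return A ggplot: points (data), line (fitted curve), log10 dose axis.
#' @export
autoplot.ll4_fit <- function(object, ...) {
  dat <- object$data |> dplyr::filter(.data$conc > 0)
  grid <- tibble::tibble(
    conc = exp(seq(log(min(dat$conc)), log(max(dat$conc)), length.out = 200)))
  grid$viability <- predict(object, grid)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$conc, y = .data$viability)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = grid, colour = "steelblue") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "dose (nM)", y = "%viability") +
    ggplot2::theme_minimal()
}

#' Plot a synergy surface as a dose-grid heatmap
#'
#' @param object A `synergy_surface`.
#' @param ... Unused.
#' @return A ggplot heatmap of per-cell scores (red = synergy).
#' @export
autoplot.synergy_surface <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$conc_a),
                                   y = factor(.data$conc_b),
                                   fill = .data$delta)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "seagreen", mid = "white",
                                  high = "firebrick", midpoint = 0) +
    ggplot2::labs(x = paste(object$drugA, "(nM)"),
                  y = paste(object$drugB, "(nM)"),
                  fill = paste(object$model, "Δ"),
                  title = sprintf("%s synergy surface (mean %.1f, peak %.1f)",
                                  object$model, object$summary_mean,
                                  object$peak_score)) +
    ggplot2::theme_minimal()
}

#' Volcano plot of a contrast result
#'
#' @param r A `contrast_result` with `log_fc` and `adj_p` (or `q_value`).
#' @param adj_p_max Significance cutoff drawn on the plot (default 0.05).
#' @return A ggplot.
#' @export
plot_volcano <- function(r, adj_p_max = 0.05) {
  padj <- if ("adj_p" %in% names(r)) r$adj_p else r$q_value
  df <- tibble::tibble(log_fc = r$log_fc, padj = padj,
                       hit = padj < adj_p_max)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$log_fc,
                                   y = -log10(pmax(.data$padj, 1e-300)),
                                   colour = .data$hit)) +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "log2 fold change", y = "-log10 adjusted p") +
    ggplot2::theme_minimal()
}
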