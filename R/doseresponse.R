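# Four-parameter log-logistic dose-response model and fitting.
#
# The model is f(x) = c + (d - c) / (1 + (x / e)^b): d is the zero-dose
# asymptote (%viability of untreated cells), c the infinite-dose asymptote,
# e the inflection dose (relative IC50) and b the Hill slope. With b > 0 the
# curve is non-increasing in dose, the orientation of a viability readout.

#' Evaluate a four-parameter log-logistic curve
#'
#' @param x Dose vector (same units as `e`; zero allowed).
#' @param b Hill slope (dimensionless, > 0 for a decreasing viability curve).
#' @param c Lower (infinite-dose) asymptote.
#' @param d Upper (zero-dose) asymptote.
#' @param e Inflection dose (> 0); the dose of half-maximal effect.
#' @return Predicted response at each dose.
#' @export
ll4 <- function(x, b, c, d, e) {
  stopifnot(e > 0)
  c + (d - c) / (1 + (x / e)^b)
}

# Inverse of ll4 on the response scale: the dose producing response y.
# Defined for y strictly between the asymptotes.
ll4_inverse <- function(y, b, c, d, e) {
  out <- rep(NA_real_, length(y))
  ok <- y > c & y < d
  out[ok] <- e * ((d - c) / (y[ok] - c) - 1)^(1 / b)
  out[y >= d] <- 0
  out
}

#' Normalize raw per-well signal to percent viability
#'
#' Scales an arbitrary-unit readout (e.g. luminescence) so that the mean of
#' the designated control wells maps to exactly 100% viability.
#'
#' @param raw_signal Numeric vector of per-well signal.
#' @param control_wells Integer indices of the untreated control wells
#'   (at least two, with positive mean signal).
#' @return Numeric vector of %viability, same length as `raw_signal`.
#' @examples
#' normalize_viability(c(2000, 2000, 1500, 500), control_wells = 1:2)
#' @export
normalize_viability <- function(raw_signal, control_wells) {
  if (length(control_wells) < 2) {
    abort("need at least 2 control wells")
  }
  ctrl <- mean(raw_signal[control_wells])
  if (!is.finite(ctrl) || ctrl <= 0) {
    abort("control mean must be positive")
  }
  100 * raw_signal / ctrl
}

ll4_rss <- function(par, x, y, penalty = 1e6) {
  # par = (b, c, d, log e); soft penalty keeps c <= d without breaking the
  # box-constrained optimizer.
  pred <- par[2] + (par[3] - par[2]) / (1 + (x / exp(par[4]))^par[1])
  sum((y - pred)^2) + penalty * max(0, par[2] - par[3])^2
}

#' Fit a four-parameter log-logistic (LL4) dose-response curve
#'
#' Bounded nonlinear least squares with a deterministic multi-start: `e`
#' starts on a log-spaced grid across the nonzero dose range crossed with
#' Hill slopes 0.5, 1, 2 and 4; the best residual sum of squares wins, ties
#' broken by the smaller slope then the smaller inflection dose.
#'
#' @param data A data frame with columns `conc` (dose, nM, zero allowed) and
#'   `viability` (percent). Replicates are passed as extra rows.
#' @param lower,upper Box constraints as named vectors with elements `b`,
#'   `c`, `d`, `e`. Defaults: b in \[0.2, 10\], 0 <= c <= d <= 120, e within
#'   \[min nonzero dose / 10, max dose x 10\].
#' @return An object of class `ll4_fit` with fields `b`, `c`, `d`, `e`,
#'   `rss`, `converged`, `n_points_used`, plus the data used.
#' @examples
#' d <- tibble::tibble(conc = c(0, 10, 50, 200, 1000, 5000),
#'                     viability = ll4(c(0, 10, 50, 200, 1000, 5000),
#'                                     b = 1, c = 0, d = 100, e = 300))
#' fit_ll4(d)
#' @export
fit_ll4 <- function(data, lower = NULL, upper = NULL) {
  stopifnot(is.data.frame(data), all(c("conc", "viability") %in% names(data)))
  x <- as.numeric(data$conc)
  y <- as.numeric(data$viability)
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]
  y <- y[keep]
  nz <- sort(unique(x[x > 0]))
  if (length(nz) < 4) {
    abort("need at least 4 distinct nonzero doses to fit an LL4 curve")
  }
  if (diff(range(y)) < 1e-12) {
    # degenerate: flat data carries no dose-response signal
    fit <- new_ll4_fit(b = 1, c = min(y), d = min(y), e = stats::median(nz),
                       rss = 0, converged = FALSE, n = length(y), x = x, y = y)
    return(fit)
  }
  lo <- c(b = 0.2, c = 0, d = 0, e = min(nz) / 10)
  hi <- c(b = 10, c = 120, d = 120, e = max(nz) * 10)
  if (!is.null(lower)) lo[names(lower)] <- lower
  if (!is.null(upper)) hi[names(upper)] <- upper

  e_grid <- exp(seq(log(min(nz)), log(max(nz)), length.out = 7))
  b_grid <- c(0.5, 1, 2, 4)
  d0 <- min(max(y), hi["d"])
  c0 <- max(min(y), lo["c"])

  best <- NULL
  for (e0 in e_grid) {
    for (b0 in b_grid) {
      par0 <- c(max(lo["b"], min(b0, hi["b"])), c0, d0,
                log(max(lo["e"], min(e0, hi["e"]))))
      res <- tryCatch(
        optim(par0, ll4_rss, x = x, y = y, method = "L-BFGS-B",
              lower = c(lo["b"], lo["c"], lo["d"], log(lo["e"])),
              upper = c(hi["b"], hi["c"], hi["d"], log(hi["e"])),
              control = list(factr = 1e2, maxit = 500)),
        error = function(e) NULL
      )
      if (is.null(res)) next
      if (is.null(best) ||
          res$value < best$value - 1e-12 ||
          (abs(res$value - best$value) <= 1e-12 &&
           (res$par[1] < best$par[1] - 1e-12 ||
            (abs(res$par[1] - best$par[1]) <= 1e-12 &&
             res$par[4] < best$par[4])))) {
        best <- res
      }
    }
  }
  if (is.null(best)) {
    abort("LL4 optimisation failed from every start")
  }
  # derivative-free polish from the winner; L-BFGS-B aborts its line search
  # on numerically perfect fits, so convergence is judged on the polish too
  pol <- tryCatch(
    optim(best$par, ll4_rss, x = x, y = y, method = "Nelder-Mead",
          control = list(maxit = 2000, reltol = 1e-14)),
    error = function(e) NULL
  )
  converged <- best$convergence == 0
  if (!is.null(pol)) {
    in_box <- all(pol$par >= c(lo["b"], lo["c"], lo["d"], log(lo["e"])) - 1e-9) &&
      all(pol$par <= c(hi["b"], hi["c"], hi["d"], log(hi["e"])) + 1e-9)
    if (in_box && pol$value <= best$value) {
      converged <- converged || pol$convergence == 0
      best <- pol
    } else if (pol$convergence == 0 &&
               pol$value >= best$value * (1 - 1e-6) - 1e-12) {
      # polish confirms the constrained optimum is a (near-)stationary point
      converged <- TRUE
    }
  }
  p <- best$par
  new_ll4_fit(b = unname(p[1]), c = unname(min(p[2], p[3])),
              d = unname(max(p[2], p[3])), e = unname(exp(p[4])),
              rss = best$value, converged = converged,
              n = length(y), x = x, y = y)
}

new_ll4_fit <- function(b, c, d, e, rss, converged, n, x, y) {
  structure(
    list(b = b, c = c, d = d, e = e, rss = rss, converged = converged,
         n_points_used = n, data = tibble::tibble(conc = x, viability = y)),
    class = "ll4_fit"
  )
}

#' @export
print.ll4_fit <- function(x, ...) {
  cat(sprintf(
    "LL4 fit: b=%.4g c=%.4g d=%.4g e=%.4g nM  (rss=%.4g, n=%d, %s)\n",
    x$b, x$c, x$d, x$e, x$rss, x$n_points_used,
    if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' @export
predict.ll4_fit <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$data$conc else {
    if (is.data.frame(newdata)) newdata$conc else as.numeric(newdata)
  }
  ll4(x, object$b, object$c, object$d, object$e)
}

#' Flag outlying dose-response points and refit once
#'
#' Points whose standardized residual against the fitted curve exceeds
#' `z_threshold` residual standard deviations are flagged and the curve is
#' refitted once without them. No iterative trimming is performed. If
#' removing the flagged points would leave fewer than 4 distinct nonzero
#' doses, nothing is removed and the original fit is returned with a
#' warning.
#'
#' @param data Data frame with `conc` and `viability` columns (the data the
#'   fit was built from).
#' @param fit A converged [fit_ll4()] result.
#' @param z_threshold Standardized-residual cutoff (default 3).
#' @return A list with `outlier` (logical mask over rows of `data`) and
#'   `fit` (the refitted, or original, `ll4_fit`).
#' @export
flag_outliers <- function(data, fit, z_threshold = 3) {
  stopifnot(inherits(fit, "ll4_fit"))
  if (!fit$converged) {
    abort("outlier detection needs a converged initial fit")
  }
  resid <- data$viability - predict(fit, data)
  dfree <- max(length(resid) - 4, 1)
  sigma <- sqrt(sum(resid^2) / dfree)
  if (sigma < 1e-12) {
    return(list(outlier = rep(FALSE, nrow(data)), fit = fit))
  }
  mask <- abs(resid) / sigma > z_threshold
  if (!any(mask)) {
    return(list(outlier = mask, fit = fit))
  }
  kept <- data[!mask, , drop = FALSE]
  if (length(unique(kept$conc[kept$conc > 0])) < 4) {
    warn("removing outliers would leave < 4 distinct nonzero doses; keeping all points")
    return(list(outlier = rep(FALSE, nrow(data)), fit = fit))
  }
  list(outlier = mask, fit = fit_ll4(kept))
}

#' Extract an IC50 from a fitted LL4 curve
#'
#' `mode = "relative"` returns the inflection dose `e` (the dose of
#' half-maximal fitted effect), which always exists; `mode = "absolute"`
#' solves the fitted curve for a response of exactly 50% of control, which
#' exists only when the asymptotes straddle 50.
#'
#' @param fit A converged [fit_ll4()] result.
#' @param mode `"relative"` (default) or `"absolute"`.
#' @return IC50 in the dose units of the fit (nM).
#' @export
ic50_from_fit <- function(fit, mode = c("relative", "absolute")) {
  stopifnot(inherits(fit, "ll4_fit"))
  mode <- match.arg(mode)
  if (!fit$converged) {
    abort("IC50 extraction needs a converged fit")
  }
  if (mode == "relative") {
    return(fit$e)
  }
  if (!(fit$c < 50 && fit$d > 50)) {
    abort("IC50 undefined: fitted asymptotes do not straddle 50% viability")
  }
  fit$e * ((fit$d - fit$c) / (50 - fit$c) - 1)^(1 / fit$b)
}

#' Fit LL4 curves for every drug in a long viability table
#'
#' Convenience wrapper that fits one curve per drug (and per cell line, if a
#' `cell_line` column is present) and returns a tidy table of parameter
#' estimates and IC50s.
#'
#' @param data Long-format data frame with columns `drug`, `conc`,
#'   `viability` and optionally `cell_line`.
#' @param outliers Apply single-pass outlier removal before reporting
#'   (default TRUE).
#' @param z_threshold Standardized-residual cutoff for the outlier pass.
#' @return A tibble with one row per drug (x cell line): `b`, `c`, `d`, `e`,
#'   `rss`, `converged`, `n_outliers`, `ic50_rel`, `ic50_abs` (NA when the
#'   absolute IC50 is undefined).
#' @export
fit_dose_response <- function(data, outliers = TRUE, z_threshold = 3) {
  stopifnot(is.data.frame(data), all(c("drug", "conc", "viability") %in% names(data)))
  keys <- intersect(c("drug", "cell_line"), names(data))
  data |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    tidyr::nest() |>
    dplyr::ungroup() |>
    dplyr::mutate(fit = purrr::map(.data$data, function(d) {
      f <- fit_ll4(d)
      n_out <- 0L
      if (outliers && f$converged) {
        o <- flag_outliers(d, f, z_threshold = z_threshold)
        n_out <- sum(o$outlier)
        f <- o$fit
      }
      tibble::tibble(
        b = f$b, c = f$c, d = f$d, e = f$e, rss = f$rss,
        converged = f$converged, n_outliers = n_out,
        ic50_rel = if (f$converged) ic50_from_fit(f, "relative") else NA_real_,
        ic50_abs = tryCatch(ic50_from_fit(f, "absolute"),
                            error = function(e) NA_real_)
      )
    })) |>
    dplyr::select(-"data") |>
    tidyr::unnest("fit")
}
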