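# Synergy scoring: the reduced-dose Bliss statistic for IC50/k
# combinations, and full checkerboard surfaces under the Bliss, ZIP and
# Loewe reference models. All scores are in percentage points of viability
# with positive values meaning synergy (observed combination viability
# below the null-model expectation).

#' Reduced-dose Bliss statistic for IC50/k combinations
#'
#' For a k-drug combination in which each drug is given at its IC50 divided
#' by k, the expected combination viability under independence is the
#' geometric mean of the single-agent viabilities measured at full IC50:
#' for two drugs \eqn{E_{exp} = \sqrt{E_A}\,\sqrt{E_B}}, and in general the
#' k-th root of the product. The Bliss score is
#' \eqn{S_{bliss} = E_{exp} - E_{obs}}: positive when the combination kills
#' more than expected (synergy), negative for antagonism.
#'
#' @param e_singles Numeric vector of 2 or 3 single-drug viabilities, as
#'   fractions of control in \[0, 1\] (percent inputs are divided by 100
#'   with a warning).
#' @param e_obs Observed viability of the reduced-dose combination
#'   (fraction, same unit handling).
#' @return A tibble of class `reduced_dose_bliss` with one row: `k`,
#'   `e_exp`, `e_obs`, `s_bliss` and the `verdict`
#'   (synergy/additive/antagonism).
#' @examples
#' bliss_reduced_dose(c(0.4, 0.6), 0.3)        # 2-drug synergy
#' bliss_reduced_dose(c(0.4, 0.6, 0.5), 0.49)  # 3-drug, near additive
#' @export
bliss_reduced_dose <- function(e_singles, e_obs) {
  if (length(e_singles) < 2 || length(e_singles) > 3) {
    abort("the reduced-dose Bliss statistic is defined for 2 or 3 drugs")
  }
  if (length(e_obs) != 1) abort("e_obs must be a single value")
  e <- as_fraction(e_singles, "single-drug viability")
  obs <- as_fraction(e_obs, "combination viability")
  k <- length(e)
  # geometric mean; identical components short-circuit so that
  # geometric-mean-consistent inputs give an exact zero score
  e_exp <- if (diff(range(e)) == 0) e[1] else prod(e)^(1 / k)
  s <- e_exp - obs
  verdict <- if (s > 0) "synergy" else if (s < 0) "antagonism" else "additive"
  out <- tibble::tibble(k = k, e_exp = e_exp, e_obs = obs, s_bliss = s,
                        verdict = verdict)
  class(out) <- c("reduced_dose_bliss", class(out))
  out
}

new_synergy_surface <- function(model, delta, dosesA, dosesB, drugA, drugB,
                                flagged = NULL) {
  dimnames(delta) <- list(dosesA, dosesB)
  pk <- peak_score(delta)
  structure(
    list(model = model, delta = delta, dosesA = dosesA, dosesB = dosesB,
         drugA = drugA, drugB = drugB,
         summary_mean = mean(delta), peak_score = pk$score,
         peak_window = pk$window, flagged = flagged),
    class = "synergy_surface"
  )
}

#' @export
print.synergy_surface <- function(x, ...) {
  cat(sprintf(
    "%s synergy surface %s x %s: mean %.2f, peak (3x3) %.2f -> %s\n",
    x$model, x$drugA, x$drugB, x$summary_mean, x$peak_score,
    classify_score(x$peak_score)))
  invisible(x)
}

#' Bliss excess surface over a checkerboard
#'
#' Scores every combination cell of a checkerboard against Bliss
#' independence: with fractional marginal viabilities fA, fB
#' (replicate-averaged zero-dose row/column) and observed fractional
#' combination viability f_obs, the score is `100 * (fA * fB - f_obs)`
#' percentage points; positive means the combination is more effective
#' than the independence product.
#'
#' @param m A [checkerboard_matrix()].
#' @return A `synergy_surface` with the per-cell score matrix over the
#'   nonzero-dose cells, `summary_mean` and the 3x3 `peak_score`.
#' @export
bliss_surface <- function(m) {
  stopifnot(inherits(m, "checkerboard_matrix"))
  v <- cb_mean(m) / 100
  fA <- v[, 1]
  fB <- v[1, ]
  expected <- outer(fA[-1], fB[-1])
  delta <- 100 * (expected - v[-1, -1, drop = FALSE])
  new_synergy_surface("Bliss", delta, m$dosesA[-1], m$dosesB[-1],
                      m$drugA, m$drugB)
}

# Two-parameter log-logistic fit on the inhibition scale (asymptotes fixed
# at y0 and 1): y(x) = (y0 + (x/e)^b) / (1 + (x/e)^b). Used by the ZIP
# model for marginal and partner-conditioned curves.
fit_zip_curve <- function(x, y, y0 = 0) {
  nz <- x > 0
  rss_fun <- function(par) {
    u <- (x[nz] / exp(par[2]))^par[1]
    sum((y[nz] - (y0 + u) / (1 + u))^2)
  }
  starts <- expand.grid(b = c(0.5, 1, 2, 4),
                        loge = log(exp(seq(log(min(x[nz])), log(max(x[nz])),
                                           length.out = 5))))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    res <- tryCatch(
      optim(c(starts$b[i], starts$loge[i]), rss_fun, method = "L-BFGS-B",
            lower = c(0.2, log(min(x[nz]) / 100)),
            upper = c(10, log(max(x[nz]) * 100)),
            control = list(factr = 1e2, maxit = 500)),
      error = function(e) NULL
    )
    if (!is.null(res) && (is.null(best) || res$value < best$value)) best <- res
  }
  if (is.null(best)) return(NULL)
  list(b = best$par[1], e = exp(best$par[2]), y0 = y0,
       predict = function(xx) {
         u <- (xx / exp(best$par[2]))^best$par[1]
         ifelse(xx == 0, y0, (y0 + u) / (1 + u))
       })
}

#' ZIP (zero interaction potency) synergy surface
#'
#' Implements the ZIP delta score: both monotherapy margins are fitted with
#' log-logistic curves on the fractional inhibition scale (asymptotes 0 and
#' 1); then for every row (partner dose fixed) and every column the
#' conditional combination response is refitted with the zero-dose
#' asymptote pinned to the partner's fitted effect. The per-cell delta is
#' the mean of the row- and column-conditional fitted inhibitions minus the
#' independence expectation `yA + yB - yA*yB` from the marginal fits, in
#' percentage points. A potency shift of either margin in the presence of
#' the partner therefore registers as synergy (positive) or antagonism
#' (negative).
#'
#' Margins need at least 4 nonzero doses to fit; with fewer the function
#' falls back to [bliss_surface()] with a warning.
#'
#' @param m A [checkerboard_matrix()].
#' @return A `synergy_surface` over the nonzero-dose cells.
#' @export
zip_surface <- function(m) {
  stopifnot(inherits(m, "checkerboard_matrix"))
  if (sum(m$dosesA > 0) < 4 || sum(m$dosesB > 0) < 4) {
    warn("fewer than 4 nonzero doses on a margin; falling back to the Bliss surface")
    return(bliss_surface(m))
  }
  v <- cb_mean(m) / 100
  y <- 1 - v  # fractional inhibition
  dosesA <- m$dosesA
  dosesB <- m$dosesB
  fitA <- fit_zip_curve(dosesA, y[, 1])
  fitB <- fit_zip_curve(dosesB, y[1, ])
  if (is.null(fitA) || is.null(fitB)) {
    abort("non-convergent marginal fit; cannot compute the ZIP surface")
  }
  nA <- length(dosesA)
  nB <- length(dosesB)
  # conditional fits: rows (drug A varying, B fixed) and columns
  row_fit <- matrix(NA_real_, nA - 1, nB - 1)
  for (j in 2:nB) {
    f <- fit_zip_curve(dosesA, y[, j], y0 = fitB$predict(dosesB[j]))
    row_fit[, j - 1] <- if (is.null(f)) y[-1, j] else f$predict(dosesA[-1])
  }
  col_fit <- matrix(NA_real_, nA - 1, nB - 1)
  for (i in 2:nA) {
    f <- fit_zip_curve(dosesB, y[i, ], y0 = fitA$predict(dosesA[i]))
    col_fit[i - 1, ] <- if (is.null(f)) y[i, -1] else f$predict(dosesB[-1])
  }
  yA <- fitA$predict(dosesA[-1])
  yB <- fitB$predict(dosesB[-1])
  independence <- outer(yA, yB, function(a, b) a + b - a * b)
  delta <- 100 * ((row_fit + col_fit) / 2 - independence)
  new_synergy_surface("ZIP", delta, dosesA[-1], dosesB[-1], m$drugA, m$drugB)
}

#' Loewe additivity synergy surface
#'
#' Fits LL4 curves to both monotherapy margins and, for every combination
#' cell (x1, x2), solves the Loewe dose-equivalence equation
#' `x1 / D1(y) + x2 / D2(y) = 1` for the additive expected viability `y*`,
#' where `Di(y)` is the inverse of drug i's fitted curve. The equation is
#' solved by bisection over the overlap of the two fitted effect ranges
#' (tolerance 1e-6, at most 200 iterations); cells where no root exists are
#' clamped to the nearest attainable effect and flagged. The score is
#' `y* - y_obs` in percentage points of viability, positive when the
#' observed combination viability falls below the additive expectation.
#'
#' A sham combination (a drug combined with itself, the surface generated
#' by one curve evaluated at x1 + x2) scores exactly additive, the defining
#' property of the Loewe model.
#'
#' @param m A [checkerboard_matrix()].
#' @return A `synergy_surface` over the nonzero-dose cells, with a
#'   `flagged` matrix marking clamped cells.
#' @export
loewe_surface <- function(m) {
  stopifnot(inherits(m, "checkerboard_matrix"))
  v <- cb_mean(m)
  dosesA <- m$dosesA
  dosesB <- m$dosesB
  fA <- fit_ll4(tibble::tibble(conc = dosesA, viability = v[, 1]))
  fB <- fit_ll4(tibble::tibble(conc = dosesB, viability = v[1, ]))
  lo <- max(fA$c, fB$c) + 1e-9
  hi <- min(fA$d, fB$d) - 1e-9
  if (lo >= hi) abort("fitted margins share no common effect range")
  g <- function(y, x1, x2) {
    x1 / ll4_inverse(y, fA$b, fA$c, fA$d, fA$e) +
      x2 / ll4_inverse(y, fB$b, fB$c, fB$d, fB$e) - 1
  }
  nA <- length(dosesA)
  nB <- length(dosesB)
  delta <- matrix(NA_real_, nA - 1, nB - 1)
  flagged <- matrix(FALSE, nA - 1, nB - 1)
  for (i in 2:nA) {
    for (j in 2:nB) {
      x1 <- dosesA[i]
      x2 <- dosesB[j]
      if (g(lo, x1, x2) >= 0) {
        # dose pair stronger than the fitted curves' attainable maximum
        ystar <- lo
        flagged[i - 1, j - 1] <- TRUE
      } else if (g(hi, x1, x2) <= 0) {
        ystar <- hi
        flagged[i - 1, j - 1] <- TRUE
      } else {
        a <- lo  # g(a) < 0
        b <- hi  # g(b) > 0
        for (it in seq_len(200)) {
          mid <- (a + b) / 2
          if (g(mid, x1, x2) > 0) b <- mid else a <- mid
          if (b - a < 1e-6) break
        }
        ystar <- (a + b) / 2
      }
      delta[i - 1, j - 1] <- ystar - v[i, j]
    }
  }
  new_synergy_surface("Loewe", delta, dosesA[-1], dosesB[-1],
                      m$drugA, m$drugB, flagged = flagged)
}

#' Score a checkerboard under a named reference model
#'
#' @param m A [checkerboard_matrix()].
#' @param model `"bliss"`, `"zip"` or `"loewe"`.
#' @return A `synergy_surface`.
#' @export
score_surface <- function(m, model = c("bliss", "zip", "loewe")) {
  model <- match.arg(model)
  switch(model,
         bliss = bliss_surface(m),
         zip = zip_surface(m),
         loewe = loewe_surface(m))
}

#' Most-synergistic-area peak of a score surface
#'
#' Returns the maximal mean over all contiguous `window` x `window`
#' sub-blocks of the score matrix (the "most synergistic area" convention
#' for reporting a combination's highest local score). Ties are broken by
#' the lowest dose indices in row-major order; if the matrix is smaller
#' than the window, the window shrinks to the matrix with a warning.
#'
#' @param s A `synergy_surface` or a bare score matrix.
#' @param window Window side length (default 3).
#' @return List with `score` (the window mean) and `window`, the
#'   (row, col) indices of the window's top-left cell.
#' @export
peak_score <- function(s, window = 3) {
  delta <- if (inherits(s, "synergy_surface")) s$delta else as.matrix(s)
  if (length(delta) == 0) abort("empty score surface")
  w <- min(window, nrow(delta), ncol(delta))
  if (w < window) warn("surface smaller than the requested window; window shrunk")
  best <- -Inf
  at <- c(1L, 1L)
  for (i in seq_len(nrow(delta) - w + 1)) {
    for (j in seq_len(ncol(delta) - w + 1)) {
      mu <- mean(delta[i:(i + w - 1), j:(j + w - 1)])
      if (mu > best + 1e-12) {
        best <- mu
        at <- c(i, j)
      }
    }
  }
  list(score = best, window = at)
}

#' Classify a synergy score
#'
#' Applies the standard interpretation thresholds for checkerboard synergy
#' scores: within \[-10, 10\] the interaction is likely additive, above 10
#' likely synergistic, below -10 likely antagonistic. Boundaries map to
#' additive.
#'
#' @param score Finite numeric score (vectorised).
#' @return Character vector: `"additive"`, `"synergistic"` or
#'   `"antagonistic"`.
#' @examples
#' classify_score(c(43.2, 0, -12))
#' @export
classify_score <- function(score) {
  if (any(!is.finite(score))) abort("scores must be finite")
  dplyr::case_when(
    score > 10 ~ "synergistic",
    score < -10 ~ "antagonistic",
    TRUE ~ "additive"
  )
}
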