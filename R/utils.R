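#' @keywords internal
"_PACKAGE"

#' @importFrom rlang .data abort warn %||%
#' @importFrom stats rnorm runif median sd quantile plogis optim p.adjust pt
#'   var mad qnorm pnorm setNames complete.cases
#' @importFrom utils head tail
NULL

# Derive a reproducible 31-bit seed for a named substream of a root seed, so
# adding a pipeline stage never perturbs another stage's draws.
substream_seed <- function(root_seed, name) {
  stopifnot(is.numeric(root_seed), length(root_seed) == 1L)
  h <- as.double(root_seed %% 2147483647)
  for (ch in utf8ToInt(paste0(name))) {
    h <- (h * 31 + ch) %% 2147483647
  }
  as.integer(h)
}

# Evaluate `code` under a local RNG state seeded by `seed`; the caller's RNG
# stream is untouched.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Viability is stored as percent at I/O boundaries and as a fraction of the
# untreated control internally. Inputs that look like percentages (values
# above 1) are rescaled with a warning where the contract asks for fractions.
as_fraction <- function(e, what = "viability") {
  if (any(!is.finite(e))) {
    abort(sprintf("non-finite %s values", what))
  }
  if (any(e > 1 + 1e-9)) {
    if (any(e > 100 + 1e-6)) {
      abort(sprintf("%s values above 100%% are not interpretable", what))
    }
    warn(sprintf("%s given in percent; dividing by 100", what))
    e <- e / 100
  }
  if (any(e < -1e-9)) {
    abort(sprintf("negative %s values", what))
  }
  pmin(pmax(e, 0), 1)
}

#' Ellipsoid tumor volume from two perpendicular caliper diameters
#'
#' Computes the xenograft tumour volume from two perpendicular diameters
#' measured by Vernier caliper, \eqn{V = \frac{4}{3}\pi\left(\frac{d_1 +
#' d_2}{4}\right)^3}. The two diameters enter symmetrically through their
#' mean radius.
#'
#' @param d1,d2 Perpendicular tumour diameters in mm (non-negative,
#'   vectorised).
#' @return Tumour volume(s) in mm^3.
#' @examples
#' tumor_volume(15, 15) # the usual 15 mm size-limit volume, ~1767 mm^3
#' @export
tumor_volume <- function(d1, d2) {
  if (any(d1 < 0) || any(d2 < 0)) {
    abort("tumour diameters must be non-negative")
  }
  (4 / 3) * pi * ((d1 + d2) / 4)^3
}
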