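# Seeded synthetic-data generator emulating the study design: monotherapy
# viability curves for three drugs, checkerboard combination surfaces with
# controllable interaction, and a 6-condition x 3-replicate proteomic
# intensity matrix with left-censored missingness and planted effects.

#' Configuration for the synthetic drug-combination study
#'
#' Bundles every knob of the synthetic study into one object. All
#' generators are pure functions of this configuration (including the
#' seed): the same config yields byte-identical data. Randomness flows
#' from the root `seed` through named substreams per generator, so e.g.
#' regenerating a checkerboard never perturbs the omics draws.
#'
#' Default drugs mimic the three agents of the motivating study: a
#' mitochondria-targeted antioxidant ("MitoQ"-like, IC50 ~500 nM), a
#' flavoprotein inhibitor ("DPI"-like, IC50 ~100 nM) and a vinca alkaloid
#' ("Vin"-like, IC50 ~5 nM), each with Hill-type viability curves spanning
#' the nM-to-uM range.
#'
#' @param seed Integer root seed.
#' @param drugs Named list of true LL4 parameter sets, each a list with
#'   `b`, `c`, `d`, `e` (see [ll4()]), plus a `dose_grid` of concentrations
#'   in nM that starts at 0 and is strictly increasing.
#' @param n_replicates Replicates per dose / per checkerboard cell
#'   (default 3, the study's triplicate design).
#' @param noise_cv Coefficient of variation of the multiplicative viability
#'   noise (>= 0). Noise is Gaussian on the scale factor, truncated so
#'   viability never goes negative (luminescence readouts scale with
#'   signal).
#' @param interaction_mode One of `"independent"`, `"synergy"`,
#'   `"antagonism"`, `"loewe_additive"`: the true interaction built into
#'   checkerboard surfaces.
#' @param delta Injected interaction strength in percentage points of
#'   viability, subtracted (synergy) or added (antagonism) on every true
#'   combination cell.
#' @param omics List of omics-generator settings; see
#'   [simulate_omics_study()]. Fields: `n_features`,
#'   `n_samples_per_condition`, `baseline_mean`, `baseline_sd`,
#'   `single_effect_fraction`, `single_effect_sd`,
#'   `combination_specific_fraction`, `combination_effect`, `replicate_sd`,
#'   `missing_location_quantile`, `missing_scale`.
#' @return A `synergy_study_config` list.
#' @export
synergy_study_config <- function(
    seed = 1L,
    drugs = list(
      MitoQ = list(b = 1.2, c = 0, d = 100, e = 500,
                   dose_grid = 500 * c(0, 2^(-5:2))),
      DPI   = list(b = 1.0, c = 0, d = 100, e = 100,
                   dose_grid = 100 * c(0, 2^(-5:2))),
      Vin   = list(b = 1.5, c = 0, d = 100, e = 5,
                   dose_grid = 5 * c(0, 2^(-5:2)))
    ),
    n_replicates = 3L,
    noise_cv = 0.05,
    interaction_mode = c("independent", "synergy", "antagonism", "loewe_additive"),
    delta = 0,
    omics = list()) {
  interaction_mode <- match.arg(interaction_mode)
  if (noise_cv < 0) abort("noise_cv must be >= 0")
  if (delta < 0) abort("delta must be >= 0 (use interaction_mode = 'antagonism')")
  for (nm in names(drugs)) {
    g <- drugs[[nm]]$dose_grid
    if (g[1] != 0 || any(diff(g) <= 0)) {
      abort(sprintf("dose grid of %s must start at 0 and be strictly increasing", nm))
    }
    if (drugs[[nm]]$e <= 0) abort(sprintf("drug %s: e must be > 0", nm))
  }
  om <- utils::modifyList(list(
    n_features = 2000L,
    n_samples_per_condition = 3L,
    baseline_mean = 25,
    baseline_sd = 3,
    single_effect_fraction = 0.10,
    single_effect_sd = 1.0,
    combination_specific_fraction = 0.10,
    combination_effect = 1.2,
    replicate_sd = 0.3,
    missing_location_quantile = 0.25,
    missing_scale = 1.0
  ), omics)
  if (om$n_samples_per_condition < 2) {
    abort("need at least 2 replicates per omics condition")
  }
  structure(
    list(seed = as.integer(seed), drugs = drugs,
         n_replicates = as.integer(n_replicates), noise_cv = noise_cv,
         interaction_mode = interaction_mode, delta = delta, omics = om),
    class = "synergy_study_config"
  )
}

# Noiseless true viability curve (percent) for one configured drug.
true_viability <- function(config, drug, dose) {
  p <- config$drugs[[drug]]
  ll4(dose, p$b, p$c, p$d, p$e)
}

# Multiplicative Gaussian noise factor matrix, truncated at zero viability.
noise_factors <- function(n, noise_cv) {
  pmax(1 + rnorm(n, sd = noise_cv), 0)
}

# Monotherapy viability matrix (dose x replicate), drawn from the drug's own
# substream so checkerboard margins can reproduce it exactly.
mono_matrix <- function(config, drug) {
  p <- config$drugs[[drug]]
  mu <- true_viability(config, drug, p$dose_grid)
  nr <- config$n_replicates
  with_seed(substream_seed(config$seed, paste0("mono:", drug)), {
    fac <- matrix(noise_factors(length(mu) * nr, config$noise_cv),
                  nrow = length(mu), ncol = nr)
    mu * fac
  })
}

#' Simulate a monotherapy dose-response experiment
#'
#' Generates %viability readouts for one drug over its configured dose grid
#' with multiplicative replicate noise: response = LL4(true params) x
#' (1 + eps), eps ~ N(0, noise_cv^2) truncated so viability stays
#' non-negative. Zero-dose (control) responses are centred at 100.
#'
#' @param config A [synergy_study_config()].
#' @param drug Name of a configured drug.
#' @return A tibble with columns `drug`, `conc` (nM), `replicate`,
#'   `viability` (percent).
#' @export
simulate_monotherapy <- function(config, drug) {
  stopifnot(inherits(config, "synergy_study_config"))
  if (!drug %in% names(config$drugs)) {
    abort(sprintf("unknown drug '%s'", drug))
  }
  g <- config$drugs[[drug]]$dose_grid
  if (sum(g > 0) < 5) abort("dose grid needs at least 5 nonzero doses")
  v <- mono_matrix(config, drug)
  tibble::tibble(
    drug = drug,
    conc = rep(g, times = config$n_replicates),
    replicate = rep(seq_len(config$n_replicates), each = length(g)),
    viability = as.vector(v)
  )
}

# Loewe-additive true surface: viability y* at (x1, x2) solves the dose
# equivalence equation x1/D1(y) + x2/D2(y) = 1 on the true curves.
loewe_true_surface <- function(pA, pB, dosesA, dosesB) {
  fA <- function(x) ll4(x, pA$b, pA$c, pA$d, pA$e)
  out <- outer(dosesA, dosesB, Vectorize(function(x1, x2) {
    if (x1 == 0 && x2 == 0) return(pA$d)
    if (x2 == 0) return(ll4(x1, pA$b, pA$c, pA$d, pA$e))
    if (x1 == 0) return(ll4(x2, pB$b, pB$c, pB$d, pB$e))
    lo <- max(pA$c, pB$c) + 1e-9
    hi <- min(pA$d, pB$d) - 1e-9
    g <- function(y) {
      x1 / ll4_inverse(y, pA$b, pA$c, pA$d, pA$e) +
        x2 / ll4_inverse(y, pB$b, pB$c, pB$d, pB$e) - 1
    }
    if (g(lo) >= 0) return(lo)  # stronger than the attainable maximum effect
    if (g(hi) <= 0) return(hi)  # weaker than the attainable minimum effect
    stats::uniroot(g, c(lo, hi), tol = 1e-9)$root
  }))
  out
}

#' Simulate a two-drug checkerboard viability matrix
#'
#' Builds a factorial dose grid (including the zero-dose margins) for two
#' configured drugs and simulates replicate %viability per cell. The
#' noiseless truth follows the configured `interaction_mode`:
#'
#' * `independent` — combination viability is the product of the fractional
#'   monotherapy viabilities (Bliss independence);
#' * `synergy` / `antagonism` — `delta` percentage points are subtracted /
#'   added on every true combination cell (clamped to \[0, 100\]);
#' * `loewe_additive` — the surface satisfies the Loewe dose-equivalence
#'   equation on the true curves.
#'
#' Margins reuse the monotherapy substreams, so the zero-dose row and
#' column reproduce [simulate_monotherapy()] for the same config.
#'
#' @param config A [synergy_study_config()].
#' @param drugA,drugB Names of configured drugs (row and column drug).
#' @return A `checkerboard_matrix` object: list with `drugA`, `drugB`,
#'   `dosesA`, `dosesB`, and `viability`, a 3-d array (doseA x doseB x
#'   replicate) of %viability.
#' @export
simulate_checkerboard <- function(config, drugA, drugB) {
  stopifnot(inherits(config, "synergy_study_config"))
  for (d in c(drugA, drugB)) {
    if (!d %in% names(config$drugs)) abort(sprintf("unknown drug '%s'", d))
  }
  pA <- config$drugs[[drugA]]
  pB <- config$drugs[[drugB]]
  dosesA <- pA$dose_grid
  dosesB <- pB$dose_grid
  nr <- config$n_replicates

  muA <- true_viability(config, drugA, dosesA)
  muB <- true_viability(config, drugB, dosesB)
  truth <- switch(config$interaction_mode,
    independent = 100 * outer(muA / 100, muB / 100),
    synergy = ,
    antagonism = {
      base <- 100 * outer(muA / 100, muB / 100)
      sgn <- if (config$interaction_mode == "synergy") -1 else 1
      combo <- outer(dosesA > 0, dosesB > 0)
      shifted <- base + sgn * config$delta * combo
      clamped <- combo & (shifted < 0 | shifted > 100)
      if (sum(clamped) > 0.5 * sum(combo)) {
        abort("delta clamps more than half of the combination cells; degenerate truth")
      }
      pmin(pmax(shifted, 0), 100)
    },
    loewe_additive = loewe_true_surface(pA, pB, dosesA, dosesB)
  )

  arr <- array(NA_real_, dim = c(length(dosesA), length(dosesB), nr),
               dimnames = list(dosesA, dosesB, NULL))
  with_seed(substream_seed(config$seed,
                           paste0("checker:", drugA, ":", drugB)), {
    fac <- array(noise_factors(length(truth) * nr, config$noise_cv),
                 dim = dim(arr))
    for (r in seq_len(nr)) arr[, , r] <- truth * fac[, , r]
  })
  # margins come from the monotherapy substreams so they reproduce
  # simulate_monotherapy() exactly; (0,0) is taken from drug A's stream
  mA <- mono_matrix(config, drugA)
  mB <- mono_matrix(config, drugB)
  arr[, 1, ] <- mA
  arr[1, 2:length(dosesB), ] <- mB[-1, ]

  checkerboard_matrix(drugA, drugB, dosesA, dosesB, arr)
}

#' Construct a checkerboard matrix object
#'
#' @param drugA,drugB Drug names (rows, columns).
#' @param dosesA,dosesB Dose vectors in nM, strictly increasing from 0.
#' @param viability A (doseA x doseB) matrix or (doseA x doseB x replicate)
#'   array of %viability.
#' @param cell_line Optional cell-line label.
#' @return A `checkerboard_matrix` object.
#' @export
checkerboard_matrix <- function(drugA, drugB, dosesA, dosesB, viability,
                                cell_line = NA_character_) {
  if (dosesA[1] != 0 || dosesB[1] != 0 ||
      any(diff(dosesA) <= 0) || any(diff(dosesB) <= 0)) {
    abort("dose vectors must be strictly increasing and start at 0")
  }
  if (length(dim(viability)) == 2) {
    viability <- array(viability, dim = c(dim(viability), 1L))
  }
  if (!all(dim(viability)[1:2] == c(length(dosesA), length(dosesB)))) {
    abort("viability dimensions do not match the dose grids")
  }
  dimnames(viability) <- list(dosesA, dosesB, NULL)
  structure(
    list(drugA = drugA, drugB = drugB, dosesA = dosesA, dosesB = dosesB,
         viability = viability, cell_line = cell_line),
    class = "checkerboard_matrix"
  )
}

#' @export
print.checkerboard_matrix <- function(x, ...) {
  cat(sprintf("Checkerboard: %s (%d doses) x %s (%d doses), %d replicate(s)\n",
              x$drugA, length(x$dosesA), x$drugB, length(x$dosesB),
              dim(x$viability)[3]))
  invisible(x)
}

# Replicate-averaged %viability matrix of a checkerboard.
cb_mean <- function(m) {
  apply(m$viability, c(1, 2), mean)
}

#' Simulate the six-condition proteomic study
#'
#' Generates a log2 intensity matrix over the conditions CTRL, M, D, V, MD
#' and MDV (vehicle, three monotherapies at IC50, the two-drug combination
#' at IC50/2 and the three-drug combination at IC50/3) with
#' `n_samples_per_condition` replicates each. Per feature, log2 intensity =
#' baseline + condition effect + replicate noise. Single-drug effects are
#' planted in a configured fraction of features; for all features except a
#' `combination_specific_fraction`, the combination effects are exactly
#' additive (MD = M + D, MDV = M + D + V on the log2 scale), so the
#' combination-minus-sum-of-singles contrast is null by construction.
#' Combination-specific features receive an extra positive effect on MD and
#' MDV only, emulating proteins induced specifically by the combination.
#'
#' Values are then censored missing with probability
#' `plogis(-(log2 intensity - location) / scale)` where `location` is a low
#' quantile of the generated intensities: the left-censoring typical of
#' label-free proteomics (low abundance is preferentially unobserved).
#'
#' @param config A [synergy_study_config()]; omics settings are read from
#'   `config$omics`.
#' @return A list with `matrix` (an [omics_matrix()] with censored values
#'   as NA), `complete` (the same matrix before censoring, the
#'   ground-truth intensities) and `truth`, a tibble with per-feature true
#'   condition means and the planted-effect flags.
#' @export
simulate_omics_study <- function(config) {
  stopifnot(inherits(config, "synergy_study_config"))
  om <- config$omics
  conds <- c("CTRL", "M", "D", "V", "MD", "MDV")
  nf <- om$n_features
  nr <- om$n_samples_per_condition

  with_seed(substream_seed(config$seed, "omics"), {
    baseline <- rnorm(nf, om$baseline_mean, om$baseline_sd)
    # planted single-drug effects (flag counts match fractions exactly)
    n_single <- round(om$single_effect_fraction * nf)
    eff <- sapply(c("M", "D", "V"), function(d) {
      idx <- sample.int(nf, n_single)
      e <- numeric(nf)
      e[idx] <- rnorm(n_single, 0, om$single_effect_sd)
      e
    })
    n_combo <- round(om$combination_specific_fraction * nf)
    combo_idx <- sample.int(nf, n_combo)
    combo_eff <- numeric(nf)
    combo_eff[combo_idx] <- om$combination_effect

    means <- cbind(
      CTRL = baseline,
      M = baseline + eff[, "M"],
      D = baseline + eff[, "D"],
      V = baseline + eff[, "V"],
      MD = baseline + eff[, "M"] + eff[, "D"] + combo_eff,
      MDV = baseline + eff[, "M"] + eff[, "D"] + eff[, "V"] + combo_eff
    )

    samples <- tibble::tibble(
      sample = paste0(rep(conds, each = nr), "_", rep(seq_len(nr), length(conds))),
      condition = rep(conds, each = nr),
      replicate = rep(seq_len(nr), length(conds))
    )
    values <- means[, samples$condition] +
      matrix(rnorm(nf * nrow(samples), 0, om$replicate_sd),
             nrow = nf)
    colnames(values) <- samples$sample
    rownames(values) <- sprintf("P%05d", seq_len(nf))

    loc <- quantile(values, om$missing_location_quantile)
    p_miss <- plogis(-(values - loc) / om$missing_scale)
    miss <- matrix(runif(length(values)) < p_miss, nrow = nf)
    observed_values <- values
    observed_values[miss] <- NA_real_

    truth <- tibble::as_tibble(means) |>
      dplyr::mutate(
        feature_id = rownames(values),
        is_combination_specific = combo_eff > 0,
        is_differential_M = eff[, "M"] != 0,
        is_differential_D = eff[, "D"] != 0,
        is_differential_V = eff[, "V"] != 0,
        .before = 1
      )

    list(
      matrix = omics_matrix(observed_values, samples, log2_scale = TRUE),
      complete = omics_matrix(values, samples, log2_scale = TRUE),
      truth = truth
    )
  })
}

#' Simulate gene/kinase-substrate set collections
#'
#' Draws `n_sets` random member sets over the configured omics features,
#' plus one designated "planted" set whose members are biased toward the
#' top of a reference ranking: a fraction `planted_set_bias` of its members
#' are taken from the very top of the ranking (in order), the rest drawn at
#' random. With `planted_set_bias = 1` the planted set is exactly the top-k
#' of the ranking; with 0 it is indistinguishable from the random sets.
#'
#' @param config A [synergy_study_config()].
#' @param n_sets Number of random sets (default 20).
#' @param set_size_range Integer range of set sizes (default c(5, 30); all
#'   sizes must be >= 3).
#' @param planted_set_bias Fraction in \[0, 1\] of planted-set members taken
#'   from the top of `ranking`.
#' @param ranking Character vector of feature ids in reference order
#'   (default: natural feature order of the omics generator).
#' @return A named list of character vectors (GMT-compatible); the planted
#'   set is named `"planted_set"`.
#' @export
simulate_gene_sets <- function(config, n_sets = 20, set_size_range = c(5, 30),
                               planted_set_bias = 0, ranking = NULL) {
  stopifnot(inherits(config, "synergy_study_config"))
  if (set_size_range[1] < 3) abort("set sizes must be >= 3")
  features <- if (is.null(ranking)) {
    sprintf("P%05d", seq_len(config$omics$n_features))
  } else {
    ranking
  }
  if (set_size_range[2] > length(features)) {
    abort("set size exceeds number of features")
  }
  with_seed(substream_seed(config$seed, "genesets"), {
    sizes <- sample(seq(set_size_range[1], set_size_range[2]), n_sets,
                    replace = TRUE)
    sets <- lapply(sizes, function(s) sample(features, s))
    names(sets) <- sprintf("random_set_%02d", seq_len(n_sets))
    k <- sizes[1]
    n_top <- round(planted_set_bias * k)
    planted <- c(head(features, n_top),
                 sample(setdiff(features, head(features, n_top)), k - n_top))
    sets$planted_set <- planted
    sets
  })
}
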