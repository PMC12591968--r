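# End-to-end orchestration: one configuration object drives simulate ->
# fit -> synergy-score -> omics-stats -> enrich, every output lands under
# one directory and is recorded with a content hash in a JSON manifest.

#' Build a pipeline run configuration
#'
#' Collects the parameters of every stage. Unknown keys are rejected so a
#' typo cannot silently fall back to a default. The whole configuration
#' (including the root seed, from which each stage derives its own
#' substream) is serialized into the run manifest.
#'
#' @param seed Root integer seed.
#' @param out_dir Output directory (created if needed).
#' @param simdata A [synergy_study_config()] or NULL to use the defaults
#'   with `seed`.
#' @param synergy List: `models` (subset of bliss/zip/loewe),
#'   `pairs` (list of drug-name pairs; default all configured pairs).
#' @param reduced_bliss List: `ic50_divisor_2` / `ic50_divisor_3` not
#'   needed — the stage measures component and combination viabilities at
#'   IC50/k from the generator truth; set `enabled = FALSE` to skip.
#' @param omics List: `min_valid`, `s0`, `sam_fdr`, `n_perm`,
#'   `adj_p_max`.
#' @param enrichment List: `n_sets`, `min_size`, `n_perm`, `fdr`,
#'   `planted_set_bias`.
#' @return A `run_config` list.
#' @export
run_config <- function(seed = 1L, out_dir = tempfile("synergy_run_"),
                       simdata = NULL, synergy = list(),
                       reduced_bliss = list(), omics = list(),
                       enrichment = list()) {
  check_keys <- function(x, allowed, block) {
    bad <- setdiff(names(x), allowed)
    if (length(bad)) {
      abort(sprintf("unknown %s config key(s): %s", block,
                    paste(bad, collapse = ", ")))
    }
    x
  }
  synergy <- utils::modifyList(
    list(models = c("bliss", "zip", "loewe"), pairs = NULL),
    check_keys(synergy, c("models", "pairs"), "synergy"))
  reduced_bliss <- utils::modifyList(
    list(enabled = TRUE),
    check_keys(reduced_bliss, "enabled", "reduced_bliss"))
  omics <- utils::modifyList(
    list(min_valid = 2, s0 = 0.1, sam_fdr = 0.05, n_perm = 250,
         adj_p_max = 0.05),
    check_keys(omics, c("min_valid", "s0", "sam_fdr", "n_perm", "adj_p_max"),
               "omics"))
  enrichment <- utils::modifyList(
    list(n_sets = 20, min_size = 3, n_perm = 1000, fdr = 0.1,
         planted_set_bias = 0.8),
    check_keys(enrichment,
               c("n_sets", "min_size", "n_perm", "fdr", "planted_set_bias"),
               "enrichment"))
  if (is.null(simdata)) simdata <- synergy_study_config(seed = seed)
  structure(
    list(seed = as.integer(seed), out_dir = out_dir, simdata = simdata,
         synergy = synergy, reduced_bliss = reduced_bliss, omics = omics,
         enrichment = enrichment),
    class = "run_config"
  )
}

#' Read a pipeline configuration from a YAML file
#'
#' The file may contain a top-level `seed` and `out_dir`, a `simdata`
#' block (fields of [synergy_study_config()] except `drugs`, plus a
#' nested `omics` block) and `synergy` / `reduced_bliss` / `omics` /
#' `enrichment` parameter blocks as in [run_config()]. Unknown keys are
#' rejected.
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- c("seed", "out_dir", "simdata", "synergy", "reduced_bliss",
             "omics", "enrichment")
  bad <- setdiff(names(y), known)
  if (length(bad)) {
    abort(sprintf("unknown config key(s): %s", paste(bad, collapse = ", ")))
  }
  seed <- y$seed %||% 1L
  sim <- NULL
  if (!is.null(y$simdata)) {
    sd_args <- y$simdata
    sd_args$seed <- sd_args$seed %||% seed
    sim <- do.call(synergy_study_config, sd_args)
  }
  run_config(seed = seed,
             out_dir = y$out_dir %||% tempfile("synergy_run_"),
             simdata = sim,
             synergy = y$synergy %||% list(),
             reduced_bliss = y$reduced_bliss %||% list(),
             omics = y$omics %||% list(),
             enrichment = y$enrichment %||% list())
}

#' Run the full drug-combination analysis pipeline
#'
#' Executes, as configured: data simulation (viability curves,
#' checkerboards, omics matrix, gene sets), monotherapy LL4 fitting and
#' IC50 extraction, checkerboard synergy scoring under the requested
#' reference models, the reduced-dose Bliss statistic for the IC50/2 and
#' IC50/3 combinations, the moderated-t synergy contrast with signature
#' selection, the SAM-style per-treatment tests, and pre-ranked set
#' enrichment on the contrast ranking. Every output file is written under
#' `config$out_dir` and recorded with an md5 content hash in
#' `manifest.json`; rerunning the same configuration reproduces identical
#' hashes.
#'
#' @param config A [run_config()].
#' @return The manifest as a list (invisibly also written to
#'   `manifest.json`): configuration echo, per-stage summaries, and the
#'   file/hash table.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(...) file.path(config$out_dir, ...)
  files <- character()
  record <- function(path) {
    files <<- c(files, path)
    path
  }
  sc <- config$simdata
  summaries <- list()

  # --- stage: simulate + fit monotherapies -------------------------------
  mono <- dplyr::bind_rows(lapply(names(sc$drugs), function(d) {
    simulate_monotherapy(sc, d)
  }))
  readr::write_csv(mono, record(out("monotherapy_viability.csv")))
  fits <- fit_dose_response(mono)
  readr::write_tsv(fits, record(out("ll4_fits.tsv")))
  summaries$doseresponse <- fits

  # --- stage: checkerboards + synergy surfaces ---------------------------
  pairs <- config$synergy$pairs
  if (is.null(pairs)) {
    nms <- names(sc$drugs)
    pairs <- utils::combn(nms, 2, simplify = FALSE)
  }
  surface_summaries <- list()
  for (p in pairs) {
    cb <- simulate_checkerboard(sc, p[1], p[2])
    write_viability_csv(cb, record(out(sprintf("checkerboard_%s_%s.csv",
                                               p[1], p[2]))))
    for (model in config$synergy$models) {
      s <- score_surface(cb, model)
      readr::write_tsv(tidy(s),
                       record(out(sprintf("surface_%s_%s_%s.tsv",
                                          model, p[1], p[2]))))
      surface_summaries[[length(surface_summaries) + 1]] <- glance(s)
    }
  }
  surf <- dplyr::bind_rows(surface_summaries)
  readr::write_tsv(surf, record(out("synergy_summary.tsv")))
  summaries$synergy <- surf

  # --- stage: reduced-dose Bliss at IC50/k -------------------------------
  if (isTRUE(config$reduced_bliss$enabled)) {
    rb <- reduced_dose_experiment(sc)
    readr::write_tsv(rb, record(out("reduced_bliss.tsv")))
    summaries$reduced_bliss <- rb
  }

  # --- stage: omics ------------------------------------------------------
  om <- simulate_omics_study(sc)
  write_omics_tsv(om$matrix, record(out("omics_log2_intensities.tsv")))
  readr::write_tsv(om$truth, record(out("omics_truth.tsv")))
  prep <- preprocess_regression(om$matrix, min_valid = config$omics$min_valid,
                                seed = substream_seed(config$seed, "impute"))
  fit <- fit_treatment_model(prep)
  contrast <- synergy_contrast(fit, "MD", c("M", "D"))
  readr::write_tsv(contrast, record(out("contrast_MD_vs_M_plus_D.tsv")))
  sig <- select_signature(contrast, adj_p_max = config$omics$adj_p_max)
  readr::write_tsv(sig, record(out("synergy_signature_up.tsv")))
  sam <- sam_one_sample_test(
    preprocess_perseus(om$matrix, min_valid = config$omics$min_valid,
                       seed = substream_seed(config$seed, "impute_perseus")),
    condition = "MD", s0 = config$omics$s0, fdr = config$omics$sam_fdr,
    n_perm = config$omics$n_perm,
    seed = substream_seed(config$seed, "sam"))
  readr::write_tsv(sam, record(out("sam_MD_vs_CTRL.tsv")))
  summaries$omics <- list(
    n_features_tested = nrow(contrast),
    n_signature_up = nrow(sig),
    n_sam_significant = sum(sam$significant)
  )

  # --- stage: enrichment -------------------------------------------------
  ranking <- rank_features(contrast)
  sets <- simulate_gene_sets(sc, n_sets = config$enrichment$n_sets,
                             planted_set_bias = config$enrichment$planted_set_bias,
                             ranking = names(ranking))
  write_gmt(sets, record(out("gene_sets.gmt")))
  enr <- preranked_gsea(ranking, sets,
                        min_size = config$enrichment$min_size,
                        n_perm = config$enrichment$n_perm,
                        seed = substream_seed(config$seed, "gsea"),
                        fdr = config$enrichment$fdr)
  readr::write_tsv(dplyr::select(enr, -"leading_edge"),
                   record(out("enrichment.tsv")))
  summaries$enrichment <- list(
    n_sets_tested = nrow(enr),
    n_significant = sum(enr$significant),
    planted_set_adj_p = enr$adj_p[enr$set == "planted_set"]
  )

  manifest <- list(
    seed = config$seed,
    interaction_mode = sc$interaction_mode,
    delta = sc$delta,
    summaries = list(
      synergy = surf,
      omics = summaries$omics,
      enrichment = summaries$enrichment
    ),
    files = tibble::tibble(
      file = basename(files),
      md5 = unname(tools::md5sum(files))
    )
  )
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  manifest$summaries$doseresponse <- fits
  manifest$summaries$reduced_bliss <- summaries$reduced_bliss
  invisible(manifest)
}

#' Reduced-dose combination experiment on the synthetic truth
#'
#' Emulates the study's reduced-dose design on the generator: measures
#' each drug's viability at its true IC50 (single agents), then the
#' combination viability with every drug at IC50/k, and scores the 2-drug
#' (first two configured drugs) and 3-drug combinations with
#' [bliss_reduced_dose()]. Under an `independent` truth the observed
#' combination viability is the product of the component viabilities at
#' the reduced doses; under `synergy`/`antagonism` the configured delta
#' shifts it.
#'
#' @param config A [synergy_study_config()].
#' @return Tibble with one row per combination (`k` = 2, 3): component
#'   viabilities, `e_exp`, `e_obs`, `s_bliss`, `verdict`.
#' @export
reduced_dose_experiment <- function(config) {
  stopifnot(inherits(config, "synergy_study_config"))
  nms <- names(config$drugs)
  if (length(nms) < 3) abort("the reduced-dose design needs 3 configured drugs")
  # fractional viability of drug `d` at dose x, on the true curve
  f <- function(d, x) true_viability(config, d, x) / 100
  ic50 <- vapply(nms, function(d) config$drugs[[d]]$e, numeric(1))
  noise <- function(mu, label) {
    with_seed(substream_seed(config$seed, paste0("reduced:", label)), {
      mu * noise_factors(1, config$noise_cv)
    })
  }
  score_combo <- function(drugs) {
    k <- length(drugs)
    # single agents measured at full IC50; combination at IC50/k each
    e_single <- vapply(drugs, function(d) {
      noise(f(d, ic50[[d]]), paste0("single:", d))
    }, numeric(1))
    combo_true <- prod(vapply(drugs, function(d) f(d, ic50[[d]] / k),
                              numeric(1)))
    combo_true <- switch(config$interaction_mode,
      synergy = max(combo_true - config$delta / 100, 0),
      antagonism = min(combo_true + config$delta / 100, 1),
      combo_true)
    e_obs <- min(noise(combo_true, paste(drugs, collapse = "+")), 1)
    res <- bliss_reduced_dose(pmin(e_single, 1), e_obs)
    dplyr::mutate(res, combination = paste(drugs, collapse = "+"),
                  .before = 1)
  }
  dplyr::bind_rows(score_combo(nms[1:2]), score_combo(nms[1:3]))
}
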