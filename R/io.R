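# Readers and writers for the pipeline's plain-text interchange formats:
# long viability CSV, checkerboard matrix CSV, wide intensity TSV
# (Fragpipe-like), GMT gene sets and result TSVs.

#' Write / read a long-format combination viability CSV
#'
#' The long dialect used by checkerboard import tools: one row per well
#' with `block_id`, `drug_row`, `drug_col`, `conc_r`, `conc_c` (nM) and
#' `response` (%viability). Monotherapy wells carry a zero partner dose.
#'
#' @param m A [checkerboard_matrix()].
#' @param path Output file.
#' @param block_id Integer block identifier (default 1).
#' @return `write_viability_csv()` returns `path` invisibly;
#'   `read_viability_csv()` returns a tibble of wells, and
#'   `read_checkerboard()` assembles one block into a
#'   [checkerboard_matrix()].
#' @export
write_viability_csv <- function(m, path, block_id = 1L) {
  stopifnot(inherits(m, "checkerboard_matrix"))
  nr <- dim(m$viability)[3]
  grid <- expand.grid(i = seq_along(m$dosesA), j = seq_along(m$dosesB),
                      r = seq_len(nr))
  df <- tibble::tibble(
    block_id = block_id,
    drug_row = m$drugA,
    drug_col = m$drugB,
    conc_r = m$dosesA[grid$i],
    conc_c = m$dosesB[grid$j],
    replicate = grid$r,
    response = m$viability[cbind(grid$i, grid$j, grid$r)]
  )
  readr::write_csv(df, path)
  invisible(path)
}

#' @rdname write_viability_csv
#' @param path Input file for the readers.
#' @export
read_viability_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}

#' @rdname write_viability_csv
#' @export
read_checkerboard <- function(path, block_id = 1L) {
  df <- read_viability_csv(path)
  df <- df[df$block_id == block_id, , drop = FALSE]
  if (nrow(df) == 0) abort(sprintf("no wells for block %s", block_id))
  dosesA <- sort(unique(df$conc_r))
  dosesB <- sort(unique(df$conc_c))
  if (!"replicate" %in% names(df)) {
    df$replicate <- stats::ave(df$conc_r, df$conc_r, df$conc_c, FUN = seq_along)
  }
  nr <- max(df$replicate)
  arr <- array(NA_real_, dim = c(length(dosesA), length(dosesB), nr))
  arr[cbind(match(df$conc_r, dosesA), match(df$conc_c, dosesB),
            df$replicate)] <- df$response
  checkerboard_matrix(df$drug_row[1], df$drug_col[1], dosesA, dosesB, arr)
}

#' Write a checkerboard as a dose-by-dose matrix CSV
#'
#' Replicate-averaged %viability with row-drug doses down the first column
#' and column-drug doses across the header, the "matrix format" accepted
#' by synergy-scoring tools.
#'
#' @param m A [checkerboard_matrix()].
#' @param path Output file.
#' @export
write_checkerboard_csv <- function(m, path) {
  stopifnot(inherits(m, "checkerboard_matrix"))
  v <- cb_mean(m)
  df <- tibble::as_tibble(v, .name_repair = ~as.character(m$dosesB))
  df <- dplyr::bind_cols(tibble::tibble(!!paste0(m$drugA, "_nM") := m$dosesA), df)
  readr::write_csv(df, path)
  invisible(path)
}

#' Write / read a wide intensity TSV
#'
#' Wide format resembling a combined-protein quantitation output: feature
#' id and annotation columns first, then one intensity column per sample
#' named `CONDITION_rep`. Missing values are written empty.
#'
#' @param m An [omics_matrix()].
#' @param path File path.
#' @return The reader returns an [omics_matrix()]; sample conditions and
#'   replicate indices are parsed from the column names.
#' @export
write_omics_tsv <- function(m, path) {
  stopifnot(inherits(m, "omics_matrix"))
  df <- dplyr::bind_cols(
    m$features,
    tibble::as_tibble(m$values)
  )
  readr::write_tsv(df, path)
  invisible(path)
}

#' @rdname write_omics_tsv
#' @param log2_scale Whether the stored intensities are log2 (default
#'   FALSE: raw intensities as instruments report them).
#' @param contaminant_prefixes Feature-id prefixes to drop on read
#'   (decoy/contaminant conventions; default `REV_` and `CON_`).
#' @export
read_omics_tsv <- function(path, log2_scale = FALSE,
                           contaminant_prefixes = c("REV_", "CON_")) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  sample_cols <- grep("^(CTRL|M|D|V|MD|MDV)_\\d+$", names(df), value = TRUE)
  if (length(sample_cols) == 0) abort("no sample columns named CONDITION_rep found")
  anno <- df[, setdiff(names(df), sample_cols), drop = FALSE]
  if (!"feature_id" %in% names(anno)) abort("need a feature_id column")
  keep <- !grepl(paste0("^(", paste(contaminant_prefixes, collapse = "|"), ")"),
                 anno$feature_id)
  values <- as.matrix(df[keep, sample_cols])
  rownames(values) <- anno$feature_id[keep]
  samples <- tibble::tibble(
    sample = sample_cols,
    condition = sub("_\\d+$", "", sample_cols),
    replicate = as.integer(sub("^.*_", "", sample_cols))
  )
  omics_matrix(values, samples, features = anno[keep, , drop = FALSE],
               log2_scale = log2_scale)
}

#' Write / read gene sets in GMT format
#'
#' One set per line: set name, description, then member ids, all
#' tab-separated.
#'
#' @param sets Named list of character vectors.
#' @param path File path.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, "na", sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_gmt
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1]]
    parts[-(1:2)]
  })
  names(sets) <- vapply(lines, function(l) {
    strsplit(l, "\t", fixed = TRUE)[[1]][1]
  }, character(1), USE.NAMES = FALSE)
  sets
}
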