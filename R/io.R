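# Cell-table I/O and unit arithmetic.
#
# The unit of data in these experiments is a counted cell in a follicle,
# so tables stay small and live in plain CSV (gzip-transparent). The
# fixed header is part of the contract; unknown extra columns round-trip.

#' Write a cell-record table to CSV
#'
#' Standard columns first (the fixed schema header), any extra columns
#' after; LF newlines; `.gz` paths are compressed transparently.
#'
#' @param cells cell-record data.frame.
#' @param path output path (`.csv` or `.csv.gz`).
#' @return `path`, invisibly.
#' @export
write_cells <- function(cells, path) {
  stopifnot(is.data.frame(cells))
  missing_cols <- setdiff(CELL_COLUMNS, names(cells))
  if (length(missing_cols)) {
    stop("cell table is missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  extra <- setdiff(names(cells), CELL_COLUMNS)
  out <- cells[, c(CELL_COLUMNS, extra), drop = FALSE]
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  utils::write.csv(out, con, row.names = FALSE, quote = FALSE, eol = "\n")
  invisible(path)
}

#' Read a cell-record table from CSV
#'
#' Validates the fixed schema, types the columns, normalizes color-state
#' strings to canonical fluorophore order, and reports malformed rows
#' with their line numbers.
#'
#' @param path CSV path (gzip transparent).
#' @return Typed cell-record data.frame.
#' @export
read_cells <- function(path) {
  if (!file.exists(path)) {
    stop("file not found: ", path, call. = FALSE)
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(CELL_COLUMNS, names(df))
  if (length(missing_cols)) {
    stop("missing required columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(df) == 0L) {
    return(df)
  }
  for (col in c("mouse_id", "tissue", "compartment", "follicle_id",
                "origin_genotype", "state", "clone_id")) {
    df[[col]] <- as.character(df[[col]])
  }
  day <- suppressWarnings(as.integer(df$day))
  bad <- which(is.na(day) | day < 0)
  if (length(bad)) {
    stop("invalid `day` on line(s) ",
         paste(bad + 1L, collapse = ", "), call. = FALSE)
  }
  df$day <- day
  df$foxp3 <- as.logical(df$foxp3)
  st <- vapply(seq_len(nrow(df)), function(i) {
    tryCatch(normalize_state(df$state[i]), error = function(e) {
      stop("line ", i + 1L, ": ", conditionMessage(e), call. = FALSE)
    })
  }, character(1))
  df$state <- st
  df
}

# --- unit arithmetic for the config layer -------------------------------
# Small, exact helpers validating experiment configuration against the
# wet-lab dosing scheme they emulate.

#' Dose per kilogram body weight
#' @param dose_ug dose in micrograms.
#' @param body_weight_g body weight in grams.
#' @return Dose in micrograms per kilogram.
#' @examples dose_per_kg(0.25, 25)  # 10 ug/kg
#' @export
dose_per_kg <- function(dose_ug, body_weight_g) {
  stopifnot(dose_ug >= 0, body_weight_g > 0)
  dose_ug / (body_weight_g / 1000)
}

#' Total gavage dose from volume and concentration
#' @param volume_ml volume in milliliters.
#' @param concentration_mg_per_ml concentration in mg/mL.
#' @return Dose in milligrams.
#' @examples gavage_dose_mg(0.5, 30)  # 15 mg tamoxifen
#' @export
gavage_dose_mg <- function(volume_ml, concentration_mg_per_ml) {
  stopifnot(volume_ml >= 0, concentration_mg_per_ml >= 0)
  volume_ml * concentration_mg_per_ml
}

#' Cells delivered in an injection
#' @param volume_ul injected volume in microliters.
#' @param cells_per_ml cell concentration per milliliter.
#' @return Number of cells.
#' @examples cells_delivered(200, 1e8)  # 20e6 cells
#' @export
cells_delivered <- function(volume_ul, cells_per_ml) {
  stopifnot(volume_ul >= 0, cells_per_ml >= 0)
  volume_ul / 1000 * cells_per_ml
}
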