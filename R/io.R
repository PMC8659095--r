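#' Read a delimited per-pose score table
#'
#' Reads comma- or tab-delimited text (sniffed from the header line) with one
#' row per scored pose and builds a [as_screen_table()] benchmark. Required
#' columns (after applying `schema` renames): `target`, `compound`, `label`,
#' and at least one score channel. Optional: `receptor`, `pose_rank`,
#' `rmsd`. Labels may be coded `active`/`inactive`, `1`/`0` or
#' `true`/`false`. Lower-is-better channels (energies) are negated on load so
#' downstream ranking is always by descending score.
#'
#' @param path Path to a delimited text file with a header.
#' @param channels Channel descriptions ([score_channels()]); by default every
#'   numeric column that is not a reserved column is taken as a generic
#'   higher-is-better channel.
#' @param schema Optional named character vector mapping canonical names to
#'   file column names, e.g. `c(compound = "ligand_id")`.
#' @return A `screen_tbl` covering all targets in the file.
#' @export
read_score_table <- function(path, channels = NULL, schema = NULL) {
  if (!file.exists(path)) {
    abort(glue::glue("file not found: {path}"), class = "screenaudit_io_error")
  }
  header <- readLines(path, n = 1L)
  delim <- if (grepl("\t", header)) "\t" else ","
  data <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
    progress = FALSE, locale = readr::locale(decimal_mark = "."))
  if (!is.null(schema)) {
    for (canon in names(schema)) {
      if (!schema[[canon]] %in% names(data)) {
        abort(glue::glue("schema column '{schema[[canon]]}' not in file"),
          class = "screenaudit_schema_error")
      }
      names(data)[names(data) == schema[[canon]]] <- canon
    }
  }
  missing_cols <- setdiff(c("target", "compound", "label"), names(data))
  if (length(missing_cols) > 0) {
    abort(glue::glue(
      "missing required column(s): {paste(missing_cols, collapse = ', ')}"
    ), class = "screenaudit_schema_error")
  }
  reserved <- c("target", "compound", "label", "receptor", "pose_rank", "rmsd")
  if (is.null(channels)) {
    cand <- setdiff(names(data), reserved)
    cand <- cand[vapply(data[cand], is.numeric, logical(1))]
    if (length(cand) == 0) {
      abort("no score channel columns found", class = "screenaudit_schema_error")
    }
    channels <- score_channels(cand)
  } else if (is.character(channels)) {
    channels <- score_channels(channels)
  }
  for (ch in channels$channel) {
    if (!ch %in% names(data)) {
      abort(glue::glue("missing required column(s): {ch}"),
        class = "screenaudit_schema_error")
    }
    if (!is.numeric(data[[ch]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(data[[ch]]))))
      abort(glue::glue(
        "non-numeric score in channel '{ch}' at data row(s) ",
        "{paste(head(bad, 5), collapse = ', ')}"
      ), class = "screenaudit_parse_error")
    }
  }
  as_screen_table(data, channels)
}

#' Read molecules from a SMILES file
#'
#' One record per line: a SMILES string, whitespace, then the compound name.
#' Unparsable SMILES are skipped and counted (see the `n_skipped` attribute);
#' a file with zero parsable records is an error, as are duplicate names.
#' Parsing is delegated to OpenBabel via the ChemmineOB package.
#'
#' @param path Path to a SMILES file.
#' @return Tibble with columns `compound`, `smiles`; attribute `n_skipped`
#'   counts rejected records.
#' @export
read_molecules <- function(path) {
  if (!file.exists(path)) {
    abort(glue::glue("file not found: {path}"), class = "screenaudit_io_error")
  }
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    abort("no records in SMILES file", class = "screenaudit_input_error")
  }
  smiles <- sub("\\s.*$", "", lines)
  name <- trimws(sub("^\\S+\\s*", "", lines))
  name[!nzchar(name)] <- paste0("mol", which(!nzchar(name)))
  ok <- vapply(smiles, smiles_parses, logical(1))
  n_skipped <- sum(!ok)
  if (n_skipped > 0) {
    warn(glue::glue("skipped {n_skipped} unparsable SMILES record(s)"))
  }
  out <- tibble(compound = name[ok], smiles = smiles[ok])
  if (nrow(out) == 0) {
    abort("no parsable records in SMILES file", class = "screenaudit_input_error")
  }
  if (anyDuplicated(out$compound)) {
    abort(glue::glue(
      "duplicate compound name(s): ",
      "{paste(unique(out$compound[duplicated(out$compound)]), collapse = ', ')}"
    ), class = "screenaudit_integrity_error")
  }
  attr(out, "n_skipped") <- n_skipped
  out
}

smiles_parses <- function(smi) {
  requireNamespace("ChemmineOB", quietly = TRUE) ||
    abort("ChemmineOB is required for SMILES parsing")
  n <- tryCatch(
    suppressMessages(suppressWarnings(
      ChemmineOB::forEachMol("SMILES", smi, function(m) {
        ChemmineOB::prop_OB(m)$formula
      })[[1]]
    )),
    error = function(e) ""
  )
  is.character(n) && nzchar(n)
}

#' Write and read metric results
#'
#' `write_results()` serializes a tibble of metric results (as produced by
#' [evaluate_screen()]) to CSV with full double precision, so a
#' write-then-read round trip preserves values to at least ten significant
#' digits. `read_results()` reads it back.
#'
#' @param results Tibble with columns `target`, `method`, `channel`,
#'   `metric`, `value` and optionally `alpha`, `ci_low`, `ci_high`, `n_boot`.
#' @param path Output (input) CSV path.
#' @return `write_results()` returns `path` invisibly; `read_results()`
#'   returns the tibble.
#' @export
write_results <- function(results, path) {
  cols <- c("target", "method", "channel", "metric", "alpha",
            "value", "ci_low", "ci_high", "n_boot")
  for (col in setdiff(cols, names(results))) results[[col]] <- NA
  out <- results[, cols]
  ok <- tryCatch({
    readr::write_csv(out, path)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) {
    abort(glue::glue("cannot write results to {path}"),
      class = "screenaudit_io_error")
  }
  invisible(path)
}

#' @rdname write_results
#' @export
read_results <- function(path) {
  if (!file.exists(path)) {
    abort(glue::glue("file not found: {path}"), class = "screenaudit_io_error")
  }
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(
      target = readr::col_character(),
      method = readr::col_character(),
      channel = readr::col_character(),
      metric = readr::col_character(),
      alpha = readr::col_double(),
      value = readr::col_double(),
      ci_low = readr::col_double(),
      ci_high = readr::col_double(),
      n_boot = readr::col_integer()
    ))
}
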