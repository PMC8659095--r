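#' Build a screen table from a data frame of scored poses
#'
#' The central container: one row per scored pose of one compound against one
#' receptor, with a binary activity label per compound. Score channels live
#' in their own numeric columns and are canonicalized at construction so that
#' higher always means "predicted more active" (lower-is-better channels such
#' as docking energies are negated). A `screen_tbl` is an ordinary tibble
#' with a `channels` attribute and can hold one target or a whole benchmark.
#'
#' @param data Data frame with columns `target`, `compound`, `label`, one
#'   numeric column per score channel, and optionally `receptor` (default
#'   `"r1"`), `pose_rank` (default: 1..K in file order within each
#'   (target, compound, receptor)), and `rmsd` (Angstroms, non-negative).
#' @param channels Channel descriptions from [score_channels()]; bare
#'   character vectors are accepted and treated as generic higher-is-better
#'   channels.
#' @param canonicalized Set to `TRUE` when the score columns are already
#'   higher-is-better (used internally and by the synthetic generator).
#' @return A `screen_tbl`: tibble with columns `target`, `compound`,
#'   `label` (`"active"`/`"inactive"`), `receptor`, `pose_rank`, optional
#'   `rmsd`, and one column per channel, plus a `channels` attribute.
#' @examples
#' df <- tibble::tibble(
#'   target = "T1", compound = c("a", "a", "b"),
#'   label = c(1, 1, 0), vina = c(-9.1, -7.3, -6.2)
#' )
#' tbl <- as_screen_table(df, channels = score_channel("vina", kind = "energy"))
#' screen_channels(tbl)
#' @export
as_screen_table <- function(data, channels, canonicalized = FALSE) {
  data <- as_tibble(data)
  if (is.character(channels)) channels <- score_channels(channels)
  required <- c("target", "compound", "label")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols) > 0) {
    abort(glue::glue(
      "missing required column(s): {paste(missing_cols, collapse = ', ')}"
    ), class = "screenaudit_schema_error")
  }
  data$target <- as.character(data$target)
  data$compound <- as.character(data$compound)
  data$label <- normalize_labels(data$label)
  if (!"receptor" %in% names(data)) data$receptor <- "r1"
  data$receptor <- as.character(data$receptor)
  if (!"pose_rank" %in% names(data)) {
    data <- data |>
      dplyr::group_by(.data$target, .data$compound, .data$receptor) |>
      dplyr::mutate(pose_rank = dplyr::row_number()) |>
      dplyr::ungroup()
  }
  if (any(data$pose_rank < 1 | data$pose_rank != round(data$pose_rank))) {
    abort("pose_rank must be a positive integer", class = "screenaudit_schema_error")
  }
  data$pose_rank <- as.integer(data$pose_rank)
  if ("rmsd" %in% names(data)) {
    if (any(!is.na(data$rmsd) & data$rmsd < 0)) {
      abort("rmsd must be non-negative", class = "screenaudit_schema_error")
    }
  }
  for (ch in channels$channel) {
    if (!ch %in% names(data)) {
      abort(glue::glue("channel column '{ch}' not found"),
        class = "screenaudit_schema_error")
    }
    if (!is.numeric(data[[ch]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(data[[ch]]))) & !is.na(data[[ch]]))
      abort(glue::glue(
        "non-numeric score in channel '{ch}' at row(s) {paste(head(bad, 5), collapse = ', ')}"
      ), class = "screenaudit_parse_error")
    }
    if (any(!is.finite(data[[ch]]))) {
      abort(glue::glue("non-finite score in channel '{ch}'"),
        class = "screenaudit_parse_error")
    }
  }
  key <- paste(data$target, data$compound, data$receptor, data$pose_rank, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- which(duplicated(key))
    abort(glue::glue(
      "duplicate (target, compound, receptor, pose_rank) at row(s) ",
      "{paste(head(dup, 5), collapse = ', ')}"
    ), class = "screenaudit_integrity_error")
  }
  # label consistency: one label per (target, compound)
  lab <- unique(data[, c("target", "compound", "label")])
  if (anyDuplicated(lab[, c("target", "compound")])) {
    abort("conflicting labels for the same (target, compound)",
      class = "screenaudit_integrity_error")
  }
  if (!canonicalized) data <- canonicalize_scores(data, channels)
  front <- intersect(c("target", "compound", "label", "receptor", "pose_rank", "rmsd"),
                     names(data))
  data <- data[, c(front, setdiff(names(data), front))]
  structure(data,
    channels = channels,
    class = c("screen_tbl", class(data))
  )
}

#' @rdname as_screen_table
#' @param x A `screen_tbl`.
#' @export
screen_channels <- function(x) {
  ch <- attr(x, "channels", exact = TRUE)
  if (is.null(ch)) abort("not a screen table (no channels attribute)")
  ch
}

normalize_labels <- function(x) {
  raw <- tolower(trimws(as.character(x)))
  out <- dplyr::case_match(raw,
    c("1", "active", "true", "t") ~ "active",
    c("0", "inactive", "decoy", "false", "f") ~ "inactive",
    .default = NA_character_
  )
  if (anyNA(out)) {
    bad <- unique(raw[is.na(out)])
    abort(glue::glue(
      "unrecognized activity label(s): {paste(head(bad, 5), collapse = ', ')} ",
      "(expected active/inactive, 1/0, or true/false)"
    ), class = "screenaudit_schema_error")
  }
  out
}

# Binary 0/1 vector (1 = active) from a label column. Fast path for
# already-binary input keeps resampling loops cheap.
label_binary <- function(label) {
  if (is.logical(label)) return(as.integer(label))
  if (is.numeric(label) && all(label == 0 | label == 1)) {
    return(as.integer(label))
  }
  as.integer(normalize_labels(label) == "active")
}

assert_screen_classes <- function(labels) {
  if (length(unique(labels)) < 2) {
    abort("need at least one active and one inactive compound",
      class = "screenaudit_undefined_metric")
  }
}
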