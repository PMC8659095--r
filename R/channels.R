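#' Describe a score channel
#'
#' A score channel is one column of per-pose scores produced by a scoring
#' method: a pose probability (e.g. a CNN pose score in \[0, 1\]), a predicted
#' binding affinity in pK units, a docking energy (lower is better), or a
#' generic score. The direction declares which way "better" points; all
#' ingest routines canonicalize channels to higher-is-better (energies are
#' negated) so that every downstream ranking assumes descending scores.
#'
#' @param name Channel name; must match a score column in the table it
#'   describes.
#' @param direction `"higher_better"` or `"lower_better"`.
#' @param kind One of `"pose_prob"`, `"affinity_pK"`, `"energy"`,
#'   `"generic"`. `"energy"` defaults to lower-is-better.
#' @return A one-row tibble with columns `channel`, `direction`, `kind`.
#' @examples
#' score_channel("vina", kind = "energy")
#' score_channel("cnn_pose", kind = "pose_prob")
#' @export
score_channel <- function(name,
                          direction = NULL,
                          kind = c("generic", "pose_prob", "affinity_pK", "energy")) {
  kind <- match.arg(kind)
  if (is.null(direction)) {
    direction <- if (kind == "energy") "lower_better" else "higher_better"
  }
  direction <- match.arg(direction, c("higher_better", "lower_better"))
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  tibble(channel = name, direction = direction, kind = kind)
}

#' @rdname score_channel
#' @param ... One-row channel tibbles from [score_channel()], or bare
#'   character names (taken as generic higher-is-better channels).
#' @export
score_channels <- function(...) {
  dots <- list(...)
  rows <- purrr::map(dots, function(x) {
    if (is.character(x)) {
      purrr::map_dfr(x, score_channel)
    } else {
      x
    }
  })
  out <- dplyr::bind_rows(rows)
  if (anyDuplicated(out$channel)) {
    abort(glue::glue(
      "duplicate channel name(s): ",
      paste(unique(out$channel[duplicated(out$channel)]), collapse = ", ")
    ), class = "screenaudit_schema_error")
  }
  out
}

# Flip lower-is-better columns so every stored score is higher-is-better.
# Applied once at ingest; negating twice is the identity, so round-tripping
# a table through write/read is safe.
canonicalize_scores <- function(data, channels) {
  for (i in seq_len(nrow(channels))) {
    ch <- channels$channel[i]
    if (!ch %in% names(data)) {
      abort(glue::glue("channel column '{ch}' not found in table"),
        class = "screenaudit_schema_error")
    }
    if (channels$direction[i] == "lower_better") {
      data[[ch]] <- -data[[ch]]
    }
    if (channels$kind[i] == "pose_prob") {
      bad <- !is.na(data[[ch]]) & (data[[ch]] < 0 | data[[ch]] > 1)
      if (any(bad)) {
        abort(glue::glue(
          "pose_prob channel '{ch}' has {sum(bad)} value(s) outside [0, 1]"
        ), class = "screenaudit_domain_error")
      }
    }
  }
  data
}
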