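# Small in-code fixtures shared across tests.

# A minimal pose table: one target, two compounds, K poses each.
make_pose_df <- function(scores = list(a = c(0.2, 0.9, 0.4), b = c(0.1, 0.3)),
                         labels = c(a = "active", b = "inactive"),
                         target = "T1", receptor = "r1", channel = "s") {
  rows <- lapply(names(scores), function(cmp) {
    tibble::tibble(
      target = target, compound = cmp, label = labels[[cmp]],
      receptor = receptor, pose_rank = seq_along(scores[[cmp]]),
      s = scores[[cmp]]
    )
  })
  df <- dplyr::bind_rows(rows)
  names(df)[names(df) == "s"] <- channel
  df
}

make_screen <- function(...) {
  df <- make_pose_df(...)
  ch <- setdiff(names(df), c("target", "compound", "label", "receptor",
    "pose_rank", "rmsd"))
  as_screen_table(df, channels = score_channels(ch))
}

# Brute-force AUC: mean pairwise credit with half for ties.
brute_auc <- function(y, s) {
  act <- s[y == 1]
  inact <- s[y == 0]
  total <- 0
  for (a in act) for (i in inact) {
    total <- total + (a > i) + 0.5 * (a == i)
  }
  total / (length(act) * length(inact))
}

# Random binary fingerprint matrix.
random_fp <- function(n, bits, density = 0.1, seed = 1) {
  withr::with_seed(seed,
    matrix(as.integer(runif(n * bits) < density), n,
      dimnames = list(paste0("m", seq_len(n)), NULL)))
}

tmp_file <- function(lines, ext = ".csv") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}
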