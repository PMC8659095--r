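#' Tanimoto similarity of binary fingerprints
#'
#' `tanimoto()` is |a AND b| / |a OR b| for two equal-length binary
#' vectors, defined as 0 when both are empty. `tanimoto_matrix()` computes
#' the full cross-similarity matrix between the rows of two fingerprint
#' matrices in one linear-algebra pass.
#'
#' @param a,b Binary 0/1 vectors of equal length (or matrices with
#'   fingerprints in rows for `tanimoto_matrix()`).
#' @return A similarity in \[0, 1\], or an `nrow(a) x nrow(b)` matrix.
#' @examples
#' tanimoto(c(1, 1, 0, 0), c(1, 0, 1, 0)) # 1/3
#' @export
tanimoto <- function(a, b) {
  if (length(a) != length(b)) {
    abort("fingerprints must have equal length",
      class = "screenaudit_domain_error")
  }
  inter <- sum(a & b)
  uni <- sum(a | b)
  if (uni == 0) 0 else inter / uni
}

#' @rdname tanimoto
#' @export
tanimoto_matrix <- function(a, b) {
  if (ncol(a) != ncol(b)) {
    abort("fingerprints must have equal length",
      class = "screenaudit_domain_error")
  }
  am <- (a > 0) * 1
  bm <- (b > 0) * 1
  inter <- am %*% t(bm)
  na <- rowSums(am)
  nb <- rowSums(bm)
  uni <- outer(na, nb, "+") - inter
  out <- ifelse(uni == 0, 0, inter / uni)
  dimnames(out) <- list(rownames(a), rownames(b))
  out
}

#' Average maximum similarity of benchmark actives to a training pool
#'
#' For each active, the maximum Tanimoto similarity to any training-pool
#' compound; the mean of those maxima summarizes how close a target's
#' actives sit to the training set. Only actives are considered because
#' affinity training sets contain no inactive compounds.
#'
#' @param target_actives,training_pool Binary fingerprint matrices
#'   (fingerprints in rows), non-empty.
#' @return A single value in \[0, 1\].
#' @export
avg_max_similarity <- function(target_actives, training_pool) {
  if (nrow(target_actives) == 0 || nrow(training_pool) == 0) {
    abort("both fingerprint sets must be non-empty",
      class = "screenaudit_domain_error")
  }
  sims <- tanimoto_matrix(target_actives, training_pool)
  mean(apply(sims, 1, max))
}

#' Correlate training similarity with early enrichment across targets
#'
#' Spearman rank correlation (midranks, two-sided p) between each target's
#' average maximum training similarity and its early-enrichment metric
#' (conventionally NEF1%). A significant positive correlation indicates
#' that a method performs better where the benchmark chemistry resembles
#' its training data.
#'
#' @param similarity Tibble with columns `target`, `similarity` (or a named
#'   numeric vector).
#' @param performance Tibble with columns `target`, `value` (or a named
#'   numeric vector), paired by target.
#' @return One-row tibble: `rho`, `p_value`, `n_targets`.
#' @export
similarity_performance_correlation <- function(similarity, performance) {
  if (is.numeric(similarity)) {
    similarity <- tibble(target = names(similarity), similarity = unname(similarity))
  }
  if (is.numeric(performance)) {
    performance <- tibble(target = names(performance), value = unname(performance))
  }
  merged <- dplyr::inner_join(similarity, performance, by = "target")
  if (nrow(merged) < 3) {
    abort("need at least 3 paired targets", class = "screenaudit_domain_error")
  }
  ct <- spearman_correlation(merged$similarity, merged$value)
  tibble(rho = ct$rho, p_value = ct$p_value, n_targets = ct$n)
}
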