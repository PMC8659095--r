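#' Configure a synthetic screening benchmark
#'
#' The generator emulates the statistical structure of a docked
#' virtual-screening benchmark with known ground truth: per-target active
#' and inactive score distributions with controllable separation,
#' multi-pose score/RMSD ensembles, descriptor distributions with a
#' controllable active-vs-inactive shift, and fingerprint sets with
#' controllable similarity to a training pool. Every quantity the pipeline
#' estimates has a planted true value, so end-to-end parameter-recovery
#' tests need no external data.
#'
#' Scores follow the equal-variance binormal model: inactive compound
#' scores are Normal(0, 1) and active scores Normal(d, 1) for a per-method
#' separation `d >= 0`, giving the closed-form expected AUC
#' `pnorm(d / sqrt(2))`. Default separations (0.93 for the classical
#' channels, 1.17 for the CNN-affinity-like channel) are calibrated so the
#' expected AUCs sit at the median levels reported for empirical scoring
#' (~0.745) and CNN affinity scoring (~0.795) on DUD-E-scale benchmarks.
#' Per-pose scores are the compound-level draw minus ordered non-negative
#' offsets, so best-pose aggregation recovers the compound draw exactly and
#' the closed-form AUC applies to the whole pipeline.
#'
#' @param n_targets Number of targets (default 15, a LIT-PCBA-sized panel).
#' @param n_actives,n_inactives Compounds per target (defaults 100/4900).
#' @param methods Named numeric vector of binormal separations `d` per
#'   score channel.
#' @param poses_per_compound Poses per (compound, receptor) (default 9, the
#'   conventional `num_modes` docking default).
#' @param n_receptors Templates per target (default 1).
#' @param p_good_pose Probability a compound's ensemble contains a good
#'   (RMSD <= 2 A) pose.
#' @param score_rmsd_coupling In \[0, 1\]: 1 = the good pose is always the
#'   best-scored pose; 0 = its score rank is uniform.
#' @param descriptor_dim Number of synthetic descriptor features.
#' @param active_shift Mean shift of active descriptors along the training
#'   weight vector (0 = unbiased benchmark). Scalar or one value per target.
#' @param n_train Training-set size for the baseline models.
#' @param train_sigma Noise s.d. of the training affinities (pK units).
#' @param n_bits,bit_density Fingerprint length and expected on-bit density.
#' @param flip_rate Per-bit flip probability when deriving active
#'   fingerprints from training-pool members (0 = verbatim copies). Scalar
#'   or one value per target.
#' @param n_pool Training-pool fingerprint count.
#' @param seed Integer seed; generation is fully deterministic given the
#'   config.
#' @return A validated `synthetic_config` list.
#' @export
synthetic_config <- function(n_targets = 15,
                             n_actives = 100,
                             n_inactives = 4900,
                             methods = c(vina = 0.93, cnn_pose = 0.93,
                                         cnn_affinity = 1.17),
                             poses_per_compound = 9,
                             n_receptors = 1,
                             p_good_pose = 0.8,
                             score_rmsd_coupling = 0.5,
                             descriptor_dim = 6,
                             active_shift = 0,
                             n_train = 1000,
                             train_sigma = 1,
                             n_bits = 2048,
                             bit_density = 0.02,
                             flip_rate = 0.3,
                             n_pool = 500,
                             seed = 1) {
  cfg <- list(n_targets = n_targets, n_actives = n_actives,
    n_inactives = n_inactives, methods = methods,
    poses_per_compound = poses_per_compound, n_receptors = n_receptors,
    p_good_pose = p_good_pose, score_rmsd_coupling = score_rmsd_coupling,
    descriptor_dim = descriptor_dim, active_shift = active_shift,
    n_train = n_train, train_sigma = train_sigma, n_bits = n_bits,
    bit_density = bit_density, flip_rate = flip_rate, n_pool = n_pool,
    seed = seed)
  check_field <- function(ok, field, what) {
    if (!ok) {
      abort(glue::glue("invalid config field '{field}': {what}"),
        class = "screenaudit_config_error")
    }
  }
  check_field(n_targets >= 1, "n_targets", "must be >= 1")
  check_field(n_actives >= 1 && n_inactives >= 1, "n_actives", "must be >= 1")
  check_field(length(methods) >= 1 && !is.null(names(methods)) &&
    all(nzchar(names(methods))), "methods", "must be a named vector")
  check_field(all(methods >= 0), "methods", "separations must be >= 0")
  check_field(poses_per_compound >= 1, "poses_per_compound", "must be >= 1")
  check_field(n_receptors >= 1, "n_receptors", "must be >= 1")
  check_field(all(p_good_pose >= 0 & p_good_pose <= 1), "p_good_pose",
    "must lie in [0, 1]")
  check_field(all(score_rmsd_coupling >= 0 & score_rmsd_coupling <= 1),
    "score_rmsd_coupling", "must lie in [0, 1]")
  check_field(descriptor_dim >= 1, "descriptor_dim", "must be >= 1")
  check_field(length(active_shift) %in% c(1, n_targets), "active_shift",
    "must be scalar or one value per target")
  check_field(train_sigma > 0, "train_sigma", "must be > 0")
  check_field(n_bits >= 8, "n_bits", "must be >= 8")
  check_field(bit_density > 0 && bit_density < 1, "bit_density",
    "must lie in (0, 1)")
  check_field(all(flip_rate >= 0 & flip_rate <= 1), "flip_rate",
    "must lie in [0, 1]")
  check_field(length(flip_rate) %in% c(1, n_targets), "flip_rate",
    "must be scalar or one value per target")
  structure(cfg, class = "synthetic_config")
}

#' Generate a synthetic benchmark with ground truth
#'
#' Produces a [as_screen_table()] score table (with poses, receptors and
#' RMSDs), descriptor and fingerprint tables, a training table for the
#' baseline models, and a truth object holding the generating parameters
#' (expected AUC per method, planted shifts and weights, planted good-pose
#' ranks). Byte-identical for identical configs.
#'
#' @param config A [synthetic_config()].
#' @return List with elements `scores` (screen_tbl), `descriptors`,
#'   `train`, `fingerprints` (list: `pool` matrix, `actives` per-target
#'   matrix list), `truth`.
#' @export
generate_benchmark <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  cfg <- config
  shift <- rep(cfg$active_shift, length.out = cfg$n_targets)
  flip <- rep(cfg$flip_rate, length.out = cfg$n_targets)
  w <- rep(1, cfg$descriptor_dim) / sqrt(cfg$descriptor_dim)
  targets <- sprintf("T%02d", seq_len(cfg$n_targets))

  scores <- withr::with_seed(stable_seed(cfg$seed, "scores"), {
    purrr::map_dfr(seq_len(cfg$n_targets), function(t) {
      generate_target_scores(cfg, targets[t])
    })
  })
  scores <- as_screen_table(scores,
    channels = score_channels(names(cfg$methods)), canonicalized = TRUE)

  descriptors <- withr::with_seed(stable_seed(cfg$seed, "descriptors"), {
    purrr::map_dfr(seq_len(cfg$n_targets), function(t) {
      n <- cfg$n_actives + cfg$n_inactives
      x <- matrix(rnorm(n * cfg$descriptor_dim), n)
      x[seq_len(cfg$n_actives), ] <-
        x[seq_len(cfg$n_actives), ] + rep(shift[t] * w, each = cfg$n_actives)
      colnames(x) <- paste0("x", seq_len(cfg$descriptor_dim))
      dplyr::bind_cols(
        tibble(target = targets[t], compound = compound_ids(cfg, targets[t])),
        as_tibble(x))
    })
  })

  train <- withr::with_seed(stable_seed(cfg$seed, "train"), {
    x <- matrix(rnorm(cfg$n_train * cfg$descriptor_dim), cfg$n_train)
    colnames(x) <- paste0("x", seq_len(cfg$descriptor_dim))
    pk <- 6 + drop(x %*% w) + rnorm(cfg$n_train, sd = cfg$train_sigma)
    dplyr::bind_cols(
      tibble(compound = sprintf("train%05d", seq_len(cfg$n_train))),
      as_tibble(x), tibble(pk = pk))
  })

  fingerprints <- withr::with_seed(stable_seed(cfg$seed, "fingerprints"), {
    pool <- matrix(
      as.integer(runif(cfg$n_pool * cfg$n_bits) < cfg$bit_density),
      cfg$n_pool)
    rownames(pool) <- sprintf("pool%05d", seq_len(cfg$n_pool))
    actives <- lapply(seq_len(cfg$n_targets), function(t) {
      src <- sample(cfg$n_pool, cfg$n_actives, replace = TRUE)
      fp <- pool[src, , drop = FALSE]
      flips <- matrix(runif(length(fp)) < flip[t], nrow(fp))
      fp <- (fp + flips) %% 2L
      rownames(fp) <- head(compound_ids(cfg, targets[t]), cfg$n_actives)
      fp
    })
    names(actives) <- targets
    list(pool = pool, actives = actives)
  })

  truth <- list(
    methods = as.list(cfg$methods),
    expected_auc = as.list(setNames(
      pnorm(cfg$methods / sqrt(2)), names(cfg$methods))),
    active_shift = shift, train_weights = w, train_intercept = 6,
    train_sigma = cfg$train_sigma, flip_rate = flip,
    targets = targets, seed = cfg$seed
  )
  list(scores = scores, descriptors = descriptors, train = train,
    fingerprints = fingerprints, truth = truth, config = cfg)
}

compound_ids <- function(cfg, target) {
  n <- cfg$n_actives + cfg$n_inactives
  sprintf("%s_c%05d", target, seq_len(n))
}

generate_target_scores <- function(cfg, target) {
  n <- cfg$n_actives + cfg$n_inactives
  k <- cfg$poses_per_compound
  r <- cfg$n_receptors
  ids <- compound_ids(cfg, target)
  label <- rep(c("active", "inactive"), c(cfg$n_actives, cfg$n_inactives))
  base <- tidyr::expand_grid(
    compound = ids,
    receptor = sprintf("r%02d", seq_len(r)),
    pose_rank = seq_len(k))
  base$target <- target
  base$label <- label[match(base$compound, ids)]
  # ordered non-negative pose offsets; receptor 1 pose 1 carries offset 0 so
  # the best pose score equals the compound-level binormal draw
  n_slots <- nrow(base)
  rec_delta <- c(0, rexp(max(r - 1, 0)))[match(base$receptor,
    sprintf("r%02d", seq_len(r)))]
  first_pose <- base$pose_rank == 1
  offset <- rec_delta
  offset[!first_pose] <- rec_delta[!first_pose] +
    stats::ave(rexp(sum(!first_pose)),
      paste(base$compound, base$receptor)[!first_pose], FUN = cumsum)
  for (m in names(cfg$methods)) {
    d <- cfg$methods[[m]]
    v <- rnorm(n) + d * (label == "active")
    base[[m]] <- v[match(base$compound, ids)] - offset
  }
  # plant pose quality: good pose present with prob p_good_pose, its score
  # rank set by the coupling; remaining poses get decoy-like RMSDs
  good <- runif(n) < cfg$p_good_pose
  good_rank <- ifelse(runif(n) < cfg$score_rmsd_coupling, 1L,
    sample.int(k, n, replace = TRUE))
  good_rec <- rep(1L, n) # planted in the best-scored receptor
  base$rmsd <- runif(n_slots, 2, 10)
  comp_idx <- match(base$compound, ids)
  hit <- good[comp_idx] &
    base$pose_rank == good_rank[comp_idx] &
    base$receptor == sprintf("r%02d", good_rec[comp_idx])
  base$rmsd[hit] <- runif(sum(hit), 0, 2)
  base[, c("target", "compound", "label", "receptor", "pose_rank", "rmsd",
    names(cfg$methods))]
}

#' Generate cross-docking pose ensembles with planted good-pose ranks
#'
#' Builds a panel of cross-docking tasks (each ligand docked into every
#' non-cognate template of its target) where each task's good pose — if one
#' exists, with probability `p_good_pose` — is planted at a known score
#' rank: rank 1 with probability `score_rmsd_coupling`, otherwise uniform
#' over the ensemble. The returned truth records every planted rank, so
#' rank-success curves can be checked exactly.
#'
#' @param config A [synthetic_config()]; `n_receptors` should be >= 2 (one
#'   ligand per template, cognate pairs excluded).
#' @param n_ligands Ligands per target (default: one per receptor).
#' @return List: `poses` (tibble with `target`, `compound`, `receptor`,
#'   `pose_rank`, `score`, `rmsd`), `cognates` (ligand -> cognate receptor),
#'   `truth` (tibble with the planted rank per task, NA when no good pose).
#' @export
generate_pose_ensembles <- function(config, n_ligands = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  cfg <- config
  k <- cfg$poses_per_compound
  n_lig <- n_ligands %||% cfg$n_receptors
  targets <- sprintf("T%02d", seq_len(cfg$n_targets))
  withr::with_seed(stable_seed(cfg$seed, "pose_ensembles"), {
    out <- purrr::map(targets, function(t) {
      receptors <- paste0(t, "_r", seq_len(cfg$n_receptors))
      ligands <- paste0(t, "_l", seq_len(n_lig))
      cognates <- tibble(compound = ligands,
        receptor = receptors[((seq_len(n_lig) - 1) %% cfg$n_receptors) + 1])
      tasks <- tidyr::expand_grid(compound = ligands, receptor = receptors)
      tasks <- dplyr::anti_join(tasks, cognates,
        by = c("compound", "receptor"))
      n_task <- nrow(tasks)
      has_good <- runif(n_task) < cfg$p_good_pose
      rank_draw <- ifelse(runif(n_task) < cfg$score_rmsd_coupling, 1L,
        sample.int(k, n_task, replace = TRUE))
      planted <- ifelse(has_good, rank_draw, NA_integer_)
      poses <- tidyr::expand_grid(
        tasks |> dplyr::mutate(.task = dplyr::row_number()),
        pose_rank = seq_len(k))
      poses$score <- k - poses$pose_rank # strictly rank-ordered scores
      poses$rmsd <- runif(nrow(poses), 2, 10)
      hit <- !is.na(planted[poses$.task]) &
        poses$pose_rank == planted[poses$.task]
      poses$rmsd[hit] <- runif(sum(hit), 0, 2)
      poses$target <- t
      list(
        poses = poses[, c("target", "compound", "receptor", "pose_rank",
          "score", "rmsd")],
        cognates = cognates,
        truth = dplyr::bind_cols(tibble(target = t), tasks,
          tibble(planted_rank = planted))
      )
    })
    list(
      poses = purrr::map_dfr(out, "poses"),
      cognates = purrr::map_dfr(out, "cognates"),
      truth = purrr::map_dfr(out, "truth")
    )
  })
}

#' Write a generated benchmark to a directory
#'
#' Emits `scores.csv`, `descriptors.csv`, `train.csv`, `fingerprint_pool.csv`
#' and `fingerprint_actives.csv` (hex-encoded bitstrings), and a
#' `truth.json` sidecar with the generating parameters.
#'
#' @param benchmark Output of [generate_benchmark()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_benchmark <- function(benchmark, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(as_tibble(benchmark$scores), file.path(dir, "scores.csv"))
  readr::write_csv(benchmark$descriptors, file.path(dir, "descriptors.csv"))
  readr::write_csv(benchmark$train, file.path(dir, "train.csv"))
  readr::write_csv(fp_to_hex(benchmark$fingerprints$pool),
    file.path(dir, "fingerprint_pool.csv"))
  act <- purrr::imap_dfr(benchmark$fingerprints$actives, function(fp, t) {
    dplyr::mutate(fp_to_hex(fp), target = t, .before = 1)
  })
  readr::write_csv(act, file.path(dir, "fingerprint_actives.csv"))
  jsonlite::write_json(benchmark$truth, file.path(dir, "truth.json"),
    auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Hex encoding of fingerprint matrices
#'
#' `fp_to_hex()` packs each row of a binary matrix into a hex string
#' (4 bits per character, most significant bit first); `hex_to_fp()`
#' reverses it.
#'
#' @param fp Binary 0/1 matrix with rownames.
#' @param hex Tibble with columns `compound`, `n_bits`, `hex`.
#' @return A tibble (`fp_to_hex`) or binary matrix (`hex_to_fp`).
#' @export
fp_to_hex <- function(fp) {
  n_bits <- ncol(fp)
  pad <- (4 - n_bits %% 4) %% 4
  hex <- apply(fp, 1, function(bits) {
    bits <- c(bits, rep(0L, pad))
    nib <- matrix(bits, nrow = 4)
    paste(sprintf("%x", colSums(nib * c(8, 4, 2, 1))), collapse = "")
  })
  tibble(compound = rownames(fp) %||% as.character(seq_len(nrow(fp))),
    n_bits = n_bits, hex = unname(hex))
}

#' @rdname fp_to_hex
#' @export
hex_to_fp <- function(hex) {
  stopifnot(all(c("compound", "n_bits", "hex") %in% names(hex)))
  n_bits <- hex$n_bits[1]
  mat <- t(vapply(hex$hex, function(h) {
    nib <- strtoi(strsplit(h, "")[[1]], 16L)
    bits <- as.integer(t(outer(nib, c(8, 4, 2, 1), function(a, b) (a %/% b) %% 2)))
    bits[seq_len(n_bits)]
  }, integer(n_bits)))
  rownames(mat) <- hex$compound
  mat
}
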