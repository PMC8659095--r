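#' Compute ligand-only descriptor tables
#'
#' Computes the "simple descriptor" feature sets used to probe benchmarks
#' for ligand-only bias, via OpenBabel (ChemmineOB):
#'
#' * `dude6` — the six properties used to match decoys to actives in
#'   property-matched benchmarks: molecular weight, hydrogen-bond acceptor
#'   count, hydrogen-bond donor count, rotatable-bond count, logP, net
#'   formal charge.
#' * `muv17` — the seventeen features used in MUV-style construction:
#'   acceptors, donors, logP, all-atom and heavy-atom counts, counts of
#'   B/Br/C/Cl/F/I/N/O/P/S atoms, chiral-center count, ring-system count.
#' * `ecfp4` — folded ECFP4 circular fingerprint bits (see
#'   [compute_fingerprints()]).
#'
#' Conventions (the feature names alone do not pin these down): acceptors
#' are Lipinski-style N/O counts, donors are N/O bearing at least one
#' hydrogen, logP is the Crippen-type atomic-contribution estimate as
#' implemented in OpenBabel, net charge is the formal-charge sum, chiral
#' centers are the tetrahedral stereocenters carried by the canonical SMILES
#' (assigned stereo), and a ring system is a connected component of the
#' ring-bond subgraph (fused and spiro systems count once).
#'
#' Molecules whose descriptor computation fails are excluded with a warning.
#'
#' @param molecules Tibble with columns `compound`, `smiles` (from
#'   [read_molecules()]).
#' @param set `"dude6"`, `"muv17"` or `"ecfp4"`.
#' @param n_bits Folded fingerprint length for `set = "ecfp4"`.
#' @return Tibble: `compound` plus one numeric column per feature.
#' @export
compute_descriptors <- function(molecules, set = c("dude6", "muv17", "ecfp4"),
                                n_bits = 2048) {
  set <- match.arg(set)
  stopifnot(all(c("compound", "smiles") %in% names(molecules)))
  if (set == "ecfp4") {
    fp <- compute_fingerprints(molecules, n_bits = n_bits)
    colnames(fp) <- sprintf("bit_%04d", seq_len(ncol(fp)))
    return(dplyr::bind_cols(tibble(compound = rownames(fp)), as_tibble(fp)))
  }
  rows <- purrr::map(seq_len(nrow(molecules)), function(i) {
    tryCatch(
      molecule_descriptors(molecules$smiles[i], set),
      error = function(e) NULL
    )
  })
  failed <- vapply(rows, is.null, logical(1))
  if (any(failed)) {
    warn(glue::glue(
      "descriptor computation failed for {sum(failed)} molecule(s): ",
      "{paste(head(molecules$compound[failed], 5), collapse = ', ')}"
    ))
  }
  dplyr::bind_cols(
    tibble(compound = molecules$compound[!failed]),
    dplyr::bind_rows(rows[!failed])
  )
}

dude6_features <- c("mw", "hba", "hbd", "rotatable_bonds", "logp", "net_charge")
muv17_features <- c("hba", "hbd", "logp", "n_all_atoms", "n_heavy_atoms",
  "n_boron", "n_bromine", "n_carbon", "n_chlorine", "n_fluorine", "n_iodine",
  "n_nitrogen", "n_oxygen", "n_phosphorus", "n_sulfur",
  "n_chiral_centers", "n_ring_systems")

molecule_descriptors <- function(smi, set) {
  require_chemistry()
  res <- ChemmineOB::forEachMol("SMILES", smi, function(m) {
    p <- ChemmineOB::prop_OB(m)
    sm <- function(pat) ChemmineOB::smartsSearch_OB(list(m), pat)
    charge <- sum(vapply(1:8, function(q) {
      q * (sm(sprintf("[+%d]", q)) - sm(sprintf("[-%d]", q)))
    }, numeric(1)))
    list(p = p,
      hba = sm("[#7,#8]"),
      hbd = sm("[#7!H0,#8!H0]"),
      rot = sm("[!$(*#*)&!D1]-!@[!$(*#*)&!D1]"),
      charge = charge)
  })[[1]]
  counts <- parse_formula(res$p$formula)
  if (set == "dude6") {
    tibble(mw = res$p$MW, hba = res$hba, hbd = res$hbd,
      rotatable_bonds = res$rot, logp = res$p$logP, net_charge = res$charge)
  } else {
    tibble(
      hba = res$hba, hbd = res$hbd, logp = res$p$logP,
      n_all_atoms = sum(counts),
      n_heavy_atoms = sum(counts[names(counts) != "H"]),
      n_boron = counts["B"] %|0|% 0, n_bromine = counts["Br"] %|0|% 0,
      n_carbon = counts["C"] %|0|% 0, n_chlorine = counts["Cl"] %|0|% 0,
      n_fluorine = counts["F"] %|0|% 0, n_iodine = counts["I"] %|0|% 0,
      n_nitrogen = counts["N"] %|0|% 0, n_oxygen = counts["O"] %|0|% 0,
      n_phosphorus = counts["P"] %|0|% 0, n_sulfur = counts["S"] %|0|% 0,
      n_chiral_centers = count_stereocenters(res$p$cansmi),
      n_ring_systems = count_ring_systems(smi)
    )
  }
}

`%|0|%` <- function(x, default) {
  if (length(x) == 0 || is.na(x)) default else unname(x)
}

# Molecular formula like "C7H5O2-" -> named element counts (charge suffix
# ignored; counts include implicit hydrogens).
parse_formula <- function(formula) {
  body <- gsub("[+-]+\\d*$", "", formula)
  m <- gregexpr("([A-Z][a-z]?)(\\d*)", body)[[1]]
  parts <- regmatches(body, list(m))[[1]]
  el <- sub("^([A-Z][a-z]?).*$", "\\1", parts)
  n <- as.numeric(sub("^[A-Z][a-z]?", "", parts))
  n[is.na(n)] <- 1
  tapply(n, el, sum)
}

# Tetrahedral stereocenters written into the canonical SMILES: each run of
# "@" characters ("@" or "@@") marks one center.
count_stereocenters <- function(cansmi) {
  m <- gregexpr("@+", cansmi)[[1]]
  if (m[1] == -1) 0L else length(m)
}

# Ring systems = connected components of the subgraph of ring bonds
# (edges on a cycle, i.e. non-bridges). Fused/spiro systems merge.
count_ring_systems <- function(smi) {
  require_chemistry()
  sdf <- tryCatch(
    suppressWarnings(ChemmineR::smiles2sdf(smi)),
    error = function(e) NULL
  )
  if (is.null(sdf) || length(sdf) == 0) return(0L)
  bb <- tryCatch(ChemmineR::bondblock(sdf[[1]]), error = function(e) NULL)
  if (is.null(bb) || nrow(bb) == 0) return(0L)
  g <- igraph::graph_from_edgelist(
    cbind(as.character(bb[, 1]), as.character(bb[, 2])), directed = FALSE)
  bridges <- igraph::bridges(g)
  ring_edges <- setdiff(igraph::E(g), bridges)
  if (length(ring_edges) == 0) return(0L)
  sub <- igraph::subgraph_from_edges(g, ring_edges, delete.vertices = TRUE)
  igraph::components(sub)$no
}

require_chemistry <- function() {
  if (!requireNamespace("ChemmineOB", quietly = TRUE) ||
      !requireNamespace("ChemmineR", quietly = TRUE)) {
    abort("ChemmineOB and ChemmineR are required for descriptor computation")
  }
  invisible(TRUE)
}

#' Compute folded ECFP4 fingerprints
#'
#' Extended-connectivity circular fingerprints of diameter 4 as implemented
#' in OpenBabel, folded (by OR-ing halves) from the native 4096-bit vector
#' down to `n_bits`. Fingerprints feed the Tanimoto similarity statistics
#' ([tanimoto()], [avg_max_similarity()]) and the `ecfp4` descriptor set.
#'
#' @inheritParams compute_descriptors
#' @param n_bits Folded length; must divide the native length (4096).
#' @return Binary 0/1 matrix, one row per molecule (rownames = compound).
#' @export
compute_fingerprints <- function(molecules, n_bits = 2048) {
  require_chemistry()
  stopifnot(all(c("compound", "smiles") %in% names(molecules)))
  fps <- ChemmineOB::forEachMol("SMILES",
    paste(molecules$smiles, collapse = "\n"),
    function(m) ChemmineOB::fingerprint_OB(list(m), "ECFP4"))
  mat <- do.call(rbind, fps)
  mat <- (mat > 0) * 1L
  if (n_bits < ncol(mat)) {
    if (ncol(mat) %% n_bits != 0) {
      abort(glue::glue("n_bits must divide the native length {ncol(mat)}"),
        class = "screenaudit_domain_error")
    }
    folds <- ncol(mat) / n_bits
    folded <- matrix(0L, nrow(mat), n_bits)
    for (f in seq_len(folds)) {
      folded <- pmax(folded, mat[, ((f - 1) * n_bits + 1):(f * n_bits), drop = FALSE])
    }
    mat <- folded
  }
  rownames(mat) <- molecules$compound
  mat
}
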