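#' Decompose a molecule into a BRICS fragment-reaction graph
#'
#' Every bond matching a BRICS rule is cleaved; each resulting connected
#' component becomes one fragment node whose atom-membership set refers to
#' the parent graph's heavy atoms (attachment dummies are never members).
#' Each cleaved bond becomes one reaction edge labelled with the unordered
#' pair of its two BRICS link classes (L1..L16), encoded as two concatenated
#' one-hots sorted by label index. Molecules with no cleavable bond return a
#' single-fragment graph with no reaction edges.
#'
#' @param graph An [smiles_to_atom_graph()] result, or a SMILES string.
#' @param config A [feature_config()].
#' @return A `fragment_graph`: list with `fragments` (list of 1-based atom
#'   index vectors partitioning the parent's heavy atoms),
#'   `fragment_features` (n_fragments x 179 matrix of the seven fragment
#'   attribute groups), `reaction_edges` (tibble `u`, `v`, `label_a`,
#'   `label_b`; 1-based fragment indices, no self-loops),
#'   `reaction_features` (one 32-length row per edge) and `parent_smiles`.
#' @export
brics_decompose <- function(graph, config = feature_config()) {
  smiles <- if (inherits(graph, "atom_graph")) graph$smiles_canonical else graph
  stopifnot(is.character(smiles), length(smiles) == 1)
  info <- mol_info(smiles)
  require_parsed(info, smiles)
  fragment_graph_from_info(info[[1]], config)
}

fragment_graph_from_info <- function(rec, config) {
  nf <- length(rec$frags)
  feats <- do.call(rbind, lapply(rec$frag_desc, fragment_feature_vector, config = config))
  ne <- length(rec$frag_edges$u)
  rf <- if (ne > 0) {
    do.call(rbind, purrr::map2(rec$frag_edges$la, rec$frag_edges$lb, reaction_feature_vector))
  } else {
    matrix(0, 0, reaction_feature_length())
  }
  structure(list(
    fragments = rec$frags,
    fragment_features = feats,
    reaction_edges = tibble::tibble(
      u = rec$frag_edges$u + 1L, v = rec$frag_edges$v + 1L,
      label_a = rec$frag_edges$la, label_b = rec$frag_edges$lb
    ),
    reaction_features = rf,
    parent_smiles = rec$canonical
  ), class = "fragment_graph")
}

#' @export
print.fragment_graph <- function(x, ...) {
  cat(sprintf("<fragment_graph> %s: %d fragments, %d reaction edges\n",
              x$parent_smiles, length(x$fragments), nrow(x$reaction_edges)))
  invisible(x)
}

#' Featurize an atom subset of a molecule as a standalone fragment
#'
#' Computes the seven fragment attribute groups (MACCS keys, element counts,
#' TPSA, heavy-atom count, ring count, HBD, HBA) on the sub-molecule induced
#' by `atoms`, with cut bonds capped by implicit hydrogens.
#'
#' @param atoms Integer vector of 1-based atom indices into the parent.
#' @param parent_smiles The parent molecule's SMILES.
#' @param config A [feature_config()].
#' @return A numeric feature vector of length 179.
#' @export
featurize_fragment <- function(atoms, parent_smiles, config = feature_config()) {
  stopifnot(length(atoms) >= 1)
  res <- call_mol_helper("subfrag", list(items = list(
    list(smiles = parent_smiles, atoms = as.list(as.integer(atoms) - 1L))
  )))
  d <- res$desc[[1]]
  if (is.null(d)) abort("Could not build a valid sub-molecule from the given atom set.")
  fragment_feature_vector(
    list(maccs = unlist(d$maccs) %||% integer(0), elems = unlist(d$elems),
         tpsa = d$tpsa, heavy = d$heavy, rings = d$rings, hbd = d$hbd, hba = d$hba),
    config
  )
}

#' Build the positive dual-view pair for one molecule
#'
#' Returns the original atom-bond graph together with its BRICS
#' fragment-reaction view; the atom graph is untouched by fragmentation.
#'
#' @param smiles A single SMILES string.
#' @param config A [feature_config()].
#' @return A list with elements `original` (an `atom_graph`) and `augmented`
#'   (a `fragment_graph`).
#' @export
build_augmented_pair <- function(smiles, config = feature_config()) {
  info <- mol_info(smiles)
  require_parsed(info, smiles)
  list(original = atom_graph_from_info(info[[1]], config),
       augmented = fragment_graph_from_info(info[[1]], config))
}

# batched variant for training loops
augmented_pairs <- function(smiles, config = feature_config()) {
  info <- mol_info(smiles)
  require_parsed(info, smiles)
  list(original = lapply(info, atom_graph_from_info, config = config),
       augmented = lapply(info, fragment_graph_from_info, config = config))
}

#' Write a per-molecule fragment report
#'
#' Debug view of the BRICS decomposition: one row per fragment with member
#' atom indices (0-based, semicolon-joined) plus the reaction edges.
#'
#' @param smiles Character vector of SMILES.
#' @param path Optional CSV path; when given the report is also written there.
#' @return A tibble with columns `parent_smiles`, `fragment_index`,
#'   `member_atoms`, `reaction_edges`.
#' @export
fragment_report <- function(smiles, path = NULL) {
  info <- mol_info(smiles)
  require_parsed(info, smiles)
  rows <- purrr::map_dfr(info, function(rec) {
    edges <- sprintf("%d-%d:L%d/L%d", rec$frag_edges$u, rec$frag_edges$v,
                     rec$frag_edges$la, rec$frag_edges$lb)
    tibble::tibble(
      parent_smiles = rec$canonical,
      fragment_index = seq_along(rec$frags),
      member_atoms = vapply(rec$frags, function(a) paste(a - 1L, collapse = ";"), character(1)),
      reaction_edges = paste(edges, collapse = " ")
    )
  })
  if (!is.null(path)) utils::write.csv(rows, path, row.names = FALSE)
  rows
}
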