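#' Atom, bond and fragment featurization configuration
#'
#' Defines the vocabularies behind the fixed attribute-group encodings used
#' throughout the package: eight atom attribute groups (element, degree,
#' formal charge, chirality tag, attached hydrogens, hybridization,
#' aromaticity flag, scaled atomic mass), four bond attribute groups (bond
#' type, conjugation flag, ring flag, stereo tag) and seven fragment
#' attribute groups (MACCS keys, per-element heavy-atom counts, topological
#' polar surface area, heavy-atom count, ring count, hydrogen-bond donor and
#' acceptor counts). Feature lengths are constant for a fixed configuration,
#' so encoder weight shapes are reproducible.
#'
#' Out-of-vocabulary categories fall into a trailing "other" slot where one
#' is defined. Atomic mass is encoded as mass/100 (a single bounded scalar
#' channel); TPSA is scaled by 1/100 for the same reason.
#'
#' @return A `feature_config` object (a named list of vocabularies).
#' @examples
#' cfg <- feature_config()
#' names(atom_feature_groups(cfg))
#' @export
feature_config <- function() {
  structure(list(
    elements = c("C", "N", "O", "S", "F", "Cl", "Br", "I", "P", "B", "Si", "Se", "other"),
    degrees = 0:5,
    charges = -2:2,
    chiral_tags = c("CHI_UNSPECIFIED", "CHI_TETRAHEDRAL_CW", "CHI_TETRAHEDRAL_CCW", "other"),
    num_hs = 0:4,
    hybridizations = c("S", "SP", "SP2", "SP3", "SP3D", "SP3D2", "other"),
    bond_types = c("SINGLE", "DOUBLE", "TRIPLE", "AROMATIC"),
    bond_stereo = c("STEREONONE", "STEREOANY", "STEREOZ", "STEREOE", "STEREOCIS", "STEREOTRANS")
  ), class = "feature_config")
}

#' @rdname feature_config
#' @param config A [feature_config()] object.
#' @return For the group accessors, a named integer vector giving the length
#'   of each attribute-group encoding, one element per group.
#' @export
atom_feature_groups <- function(config = feature_config()) {
  c(element = length(config$elements),
    degree = length(config$degrees),
    formal_charge = length(config$charges),
    chirality = length(config$chiral_tags),
    num_hydrogens = length(config$num_hs),
    hybridization = length(config$hybridizations),
    aromaticity = 1L,
    atomic_mass = 1L)
}

#' @rdname feature_config
#' @export
bond_feature_groups <- function(config = feature_config()) {
  c(bond_type = length(config$bond_types),
    conjugation = 1L,
    in_ring = 1L,
    stereo = length(config$bond_stereo))
}

#' @rdname feature_config
#' @export
fragment_feature_groups <- function(config = feature_config()) {
  c(maccs = 167L,
    element_counts = 7L,
    tpsa = 1L,
    heavy_atoms = 1L,
    ring_count = 1L,
    hbd = 1L,
    hba = 1L)
}

atom_feature_length <- function(config = feature_config()) sum(atom_feature_groups(config))
bond_feature_length <- function(config = feature_config()) sum(bond_feature_groups(config))
fragment_feature_length <- function(config = feature_config()) sum(fragment_feature_groups(config))

# 16 BRICS link classes, encoded as the unordered label pair of a cleaved
# bond: two concatenated one-hots sorted by label index.
N_BRICS_LABELS <- 16L
reaction_feature_length <- function() 2L * N_BRICS_LABELS

config_hash <- function(config = feature_config()) rlang::hash(unclass(config))

onehot <- function(values, vocab, other = FALSE) {
  idx <- match(as.character(values), as.character(vocab))
  if (other) {
    idx[is.na(idx)] <- length(vocab)
  } else if (anyNA(idx)) {
    idx[is.na(idx)] <- 1L # unknown category maps to the first slot
  }
  out <- matrix(0, length(values), length(vocab))
  out[cbind(seq_along(values), idx)] <- 1
  out
}

atom_feature_matrix <- function(atoms, config) {
  cbind(
    onehot(atoms$symbol, config$elements, other = TRUE),
    onehot(atoms$degree, config$degrees),
    onehot(atoms$charge, config$charges),
    onehot(atoms$chiral, config$chiral_tags, other = TRUE),
    onehot(pmin(atoms$numh, max(config$num_hs)), config$num_hs),
    onehot(atoms$hybrid, config$hybridizations, other = TRUE),
    matrix(as.numeric(atoms$aromatic), ncol = 1),
    matrix(atoms$mass / 100, ncol = 1)
  )
}

# one row per *undirected* bond; callers duplicate rows for directed entries
bond_feature_matrix <- function(bonds, config) {
  n <- length(bonds$a)
  if (n == 0) {
    return(matrix(0, 0, bond_feature_length(config)))
  }
  cbind(
    onehot(bonds$type, config$bond_types),
    matrix(as.numeric(bonds$conj), ncol = 1),
    matrix(as.numeric(bonds$ring), ncol = 1),
    onehot(bonds$stereo, config$bond_stereo)
  )
}

fragment_feature_vector <- function(desc, config) {
  if (is.null(desc)) {
    return(rep(0, fragment_feature_length(config)))
  }
  maccs <- rep(0, 167)
  on <- desc$maccs[desc$maccs >= 1 & desc$maccs <= 167]
  maccs[on] <- 1
  c(maccs, desc$elems, desc$tpsa / 100, desc$heavy, desc$rings, desc$hbd, desc$hba)
}

reaction_feature_vector <- function(la, lb) {
  pair <- sort(c(la, lb))
  out <- rep(0, reaction_feature_length())
  out[pair[1]] <- 1
  out[N_BRICS_LABELS + pair[2]] <- 1
  out
}
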