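## Central S4 containers.

#' ProfileHMM: a profile hidden Markov model of a protein family
#'
#' A position-specific probabilistic model with match, insert and delete
#' states. Emission distributions are stored as probabilities over the
#' 20 canonical residues; transitions connect consecutive model nodes.
#' Scoring is local (uniform fragment entry/exit) in bits against an
#' i.i.d. background null model.
#'
#' @slot name Model name.
#' @slot L Number of match states.
#' @slot matchEmissions `L x 20` matrix; row k is the emission
#'   distribution of match state k.
#' @slot insertEmissions `L x 20` matrix; row k is the emission
#'   distribution of insert state k (defaults to the background).
#' @slot transitions `(L-1) x 7` matrix with columns
#'   `MM, MI, MD, IM, II, DM, DD`: probabilities of moving from node k
#'   states to node k+1 states.
#' @slot background Length-20 background residue distribution.
#' @slot map Integer vector of length `L`: source alignment column of
#'   each match state (strictly increasing).
#'
#' @seealso [buildProfile()], [forwardScore()], [searchProfile()]
#' @export
setClass("ProfileHMM",
  representation(
    name = "character",
    L = "integer",
    matchEmissions = "matrix",
    insertEmissions = "matrix",
    transitions = "matrix",
    background = "numeric",
    map = "integer"
  )
)

setValidity("ProfileHMM", function(object) {
  msg <- character()
  L <- object@L
  if (length(L) != 1L || is.na(L) || L < 1L)
    msg <- c(msg, "L must be a single integer >= 1")
  tol <- 1e-9
  checkRows <- function(m, what, n) {
    if (!is.numeric(m) || nrow(m) != n || ncol(m) != 20L)
      return(sprintf("%s must be a %d x 20 numeric matrix", what, n))
    if (any(m < -tol)) return(sprintf("%s has negative entries", what))
    if (n > 0L && any(abs(rowSums(m) - 1) > tol))
      return(sprintf("%s rows must sum to 1", what))
    NULL
  }
  msg <- c(msg, checkRows(object@matchEmissions, "matchEmissions", L))
  msg <- c(msg, checkRows(object@insertEmissions, "insertEmissions", L))
  tr <- object@transitions
  if (nrow(tr) != max(L - 1L, 0L) || ncol(tr) != 7L) {
    msg <- c(msg, "transitions must be (L-1) x 7")
  } else if (nrow(tr) > 0L) {
    if (any(abs(rowSums(tr[, c("MM", "MI", "MD"), drop = FALSE]) - 1) > tol))
      msg <- c(msg, "M-state transitions must sum to 1")
    if (any(abs(rowSums(tr[, c("IM", "II"), drop = FALSE]) - 1) > tol))
      msg <- c(msg, "I-state transitions must sum to 1")
    if (any(abs(rowSums(tr[, c("DM", "DD"), drop = FALSE]) - 1) > tol))
      msg <- c(msg, "D-state transitions must sum to 1")
  }
  if (length(object@background) != 20L ||
      abs(sum(object@background) - 1) > tol)
    msg <- c(msg, "background must be a length-20 distribution")
  if (length(object@map) != L || (L > 1L && any(diff(object@map) <= 0L)))
    msg <- c(msg, "map must be strictly increasing of length L")
  if (length(msg)) msg else TRUE
})

#' @describeIn ProfileHMM-class Compact display.
#' @param object A `ProfileHMM`.
#' @export
setMethod("show", "ProfileHMM", function(object) {
  cat("ProfileHMM '", object@name, "': ", object@L,
      " match states (alignment columns ", object@map[1L], "..",
      object@map[object@L], ")\n", sep = "")
  invisible(object)
})

#' DomainSplit: a profile pair from an anchor-split alignment
#'
#' Holds the N-terminal (cofactor-binding) and C-terminal (catalytic)
#' profiles obtained by splitting a family alignment at the alignment
#' column carrying a reference sequence's anchor residue. The anchor
#' column is assigned to the N-terminal block.
#'
#' @slot parent Name of the parent (full-length) profile.
#' @slot anchorResidue 1-based residue index in the reference sequence.
#' @slot nProfile,cProfile The two [ProfileHMM-class] objects.
#' @seealso [splitProfile()]
#' @export
setClass("DomainSplit",
  representation(
    parent = "character",
    anchorResidue = "integer",
    nProfile = "ProfileHMM",
    cProfile = "ProfileHMM"
  )
)

#' @describeIn DomainSplit-class Compact display.
#' @param object A `DomainSplit`.
#' @export
setMethod("show", "DomainSplit", function(object) {
  cat("DomainSplit of '", object@parent, "' at anchor residue ",
      object@anchorResidue, "\n  N-side: L = ", object@nProfile@L,
      "\n  C-side: L = ", object@cProfile@L, "\n", sep = "")
  invisible(object)
})

#' PocketDefinition: the named active-site positions of a reference
#'
#' Maps the 21 named pocket positions P1..P21 to residue numbers of a
#' reference structure, with optional per-family remaps (a family whose
#' pocket geometry shifts two positions to different reference residues,
#' as the G2 group does for P6/P7).
#'
#' @slot referenceStructure Label of the reference structure.
#' @slot positions Named integer vector (names `P1`..`P21`) of reference
#'   residue numbers.
#' @slot remaps Named list; each element is a named integer vector of
#'   position -> replacement residue number, keyed by family label.
#' @seealso [extractPocket()], [defaultPocketDefinition()]
#' @export
setClass("PocketDefinition",
  representation(
    referenceStructure = "character",
    positions = "integer",
    remaps = "list"
  )
)

setValidity("PocketDefinition", function(object) {
  msg <- character()
  p <- object@positions
  if (length(p) != 21L)
    msg <- c(msg, "exactly 21 pocket positions required")
  if (!identical(names(p), paste0("P", 1:21)))
    msg <- c(msg, "positions must be named P1..P21 in order")
  if (anyDuplicated(p))
    msg <- c(msg, "pocket residue numbers must be distinct")
  for (fam in names(object@remaps)) {
    r <- object@remaps[[fam]]
    if (!all(names(r) %in% names(p)))
      msg <- c(msg, sprintf("remap '%s' names unknown positions", fam))
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn PocketDefinition-class Compact display.
#' @param object A `PocketDefinition`.
#' @export
setMethod("show", "PocketDefinition", function(object) {
  cat("PocketDefinition on '", object@referenceStructure, "' (",
      length(object@positions), " positions",
      if (length(object@remaps))
        paste0("; remaps: ", paste(names(object@remaps), collapse = ", ")),
      ")\n", sep = "")
  invisible(object)
})

#' FamilyNetwork: a thresholded profile-similarity graph
#'
#' Nodes are family labels; undirected edges carry an alignment
#' probability, a coverage fraction and their product as weight. Only
#' edges meeting both admission thresholds are stored.
#'
#' @slot nodes Character vector of family labels.
#' @slot edges `data.frame` with columns `family_a`, `family_b`,
#'   `probability`, `coverage`, `weight` (`family_a < family_b`).
#' @slot thresholds Named numeric: minimum `probability` and `coverage`.
#' @seealso [buildFamilyNetwork()], [mclCluster()]
#' @export
setClass("FamilyNetwork",
  representation(
    nodes = "character",
    edges = "data.frame",
    thresholds = "numeric"
  )
)

setValidity("FamilyNetwork", function(object) {
  msg <- character()
  e <- object@edges
  need <- c("family_a", "family_b", "probability", "coverage", "weight")
  if (!all(need %in% names(e)))
    return("edges must have columns family_a, family_b, probability, coverage, weight")
  if (nrow(e)) {
    if (any(abs(e$weight - e$probability * e$coverage) > 1e-12))
      msg <- c(msg, "weight must equal probability * coverage")
    if (any(e$family_a >= e$family_b))
      msg <- c(msg, "edges must be stored with family_a < family_b")
    if (any(e$probability < object@thresholds[["probability"]]) ||
        any(e$coverage < object@thresholds[["coverage"]]))
      msg <- c(msg, "stored edges must meet the admission thresholds")
    if (!all(c(e$family_a, e$family_b) %in% object@nodes))
      msg <- c(msg, "edge endpoints must be nodes")
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn FamilyNetwork-class Compact display.
#' @param object A `FamilyNetwork`.
#' @export
setMethod("show", "FamilyNetwork", function(object) {
  cat("FamilyNetwork: ", length(object@nodes), " families, ",
      nrow(object@edges), " edges (probability >= ",
      object@thresholds[["probability"]], ", coverage >= ",
      object@thresholds[["coverage"]], ")\n", sep = "")
  invisible(object)
})

#' PocketTree: hierarchical classification of pocket fingerprints
#'
#' The result of agglomerative clustering of 21-position active-site
#' fingerprints: the dendrogram, the flat cluster assignment at the cut
#' threshold, per-cluster consensus fingerprints and the retention flag
#' (clusters smaller than `minClusterSize` are flagged not retained).
#'
#' @slot hclust The `stats::hclust` dendrogram (`NULL` for < 2
#'   fingerprints).
#' @slot assignments `data.frame` with columns `sequence_id`, `cluster`,
#'   `retained`.
#' @slot consensus Named character vector: consensus fingerprint string
#'   per cluster.
#' @slot minClusterSize Retention threshold (members per cluster).
#' @slot cutHeight Distance threshold used to cut the tree.
#' @seealso [clusterPockets()]
#' @export
setClass("PocketTree",
  representation(
    hclust = "ANY",
    assignments = "data.frame",
    consensus = "character",
    minClusterSize = "integer",
    cutHeight = "numeric"
  )
)

#' @describeIn PocketTree-class Compact display.
#' @param object A `PocketTree`.
#' @export
setMethod("show", "PocketTree", function(object) {
  k <- length(unique(object@assignments$cluster))
  nr <- sum(object@assignments$retained)
  cat("PocketTree: ", nrow(object@assignments), " fingerprints in ", k,
      " clusters (", nr, " fingerprints in retained clusters; ",
      "min cluster size ", object@minClusterSize, ")\n", sep = "")
  invisible(object)
})
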