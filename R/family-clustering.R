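## Family-level clustering: pairwise identity/coverage, greedy set-cover
## clustering, redundancy removal, profile-profile comparison with a
## calibrated hit probability, and Markov clustering of the resulting
## similarity network.

SUBMAT <- local({
  ab <- c(AA20, "X")
  m <- matrix(-1, 21, 21, dimnames = list(ab, ab))
  diag(m) <- 2
  m["X", ] <- 0
  m[, "X"] <- 0
  m
})

#' Pairwise identity and coverage of two sequences
#'
#' Globally aligns the two sequences (match-reward/mismatch-penalty
#' scoring with affine gaps), then computes identity as the fraction of
#' identical residue pairs over the alignment columns between the first
#' and last aligned residue pair (terminal gaps excluded) and coverage
#' as the number of aligned residue pairs divided by the shorter
#' sequence length.
#'
#' @param a,b Residue strings.
#' @return Named numeric: `identity`, `coverage`.
#' @export
#' @examples
#' pairwiseIdentity("ACDEFG", "ACDQFG")
pairwiseIdentity <- function(a, b) {
  stopifnot(nzchar(a), nzchar(b))
  pa <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::BString(a), subject = Biostrings::BString(b),
    type = "global", substitutionMatrix = SUBMAT,
    gapOpening = 10, gapExtension = 0.5)
  alignedPairStats(as.character(Biostrings::alignedPattern(pa)),
                   as.character(Biostrings::alignedSubject(pa)),
                   nchar(a), nchar(b))
}

## Identity/coverage from one pair of aligned strings (same definition
## as pairwiseIdentity()).
alignedPairStats <- function(ap, as_, na_, nb_) {
  ap <- splitResidues(ap)[[1L]]
  as_ <- splitResidues(as_)[[1L]]
  both <- ap != "-" & as_ != "-"
  if (!any(both)) return(c(identity = 0, coverage = 0))
  region <- seq(min(which(both)), max(which(both)))
  c(identity = sum(ap[region] == as_[region] & ap[region] != "-") /
      length(region),
    coverage = sum(both) / min(na_, nb_))
}

## All-vs-all identity/coverage tables for a record set. Alignments are
## batched one-subject-vs-many-patterns to avoid per-pair call overhead;
## the scoring parameters are identical to pairwiseIdentity().
pairwiseIdentityMatrix <- function(records) {
  n <- nrow(records)
  idm <- diag(1, n); cvm <- diag(1, n)
  dimnames(idm) <- dimnames(cvm) <- list(records$id, records$id)
  if (n > 1L) for (i in seq_len(n - 1L)) {
    js <- (i + 1L):n
    pa <- Biostrings::pairwiseAlignment(
      pattern = Biostrings::BStringSet(records$residues[js]),
      subject = Biostrings::BString(records$residues[i]),
      type = "global", substitutionMatrix = SUBMAT,
      gapOpening = 10, gapExtension = 0.5)
    aps <- as.character(Biostrings::alignedPattern(pa))
    ass <- as.character(Biostrings::alignedSubject(pa))
    for (k in seq_along(js)) {
      v <- alignedPairStats(aps[k], ass[k],
                            nchar(records$residues[js[k]]),
                            nchar(records$residues[i]))
      idm[i, js[k]] <- idm[js[k], i] <- v[["identity"]]
      cvm[i, js[k]] <- cvm[js[k], i] <- v[["coverage"]]
    }
  }
  list(identity = idm, coverage = cvm)
}

#' Greedy set-cover clustering of sequences
#'
#' Iteratively picks, among unclustered sequences, the one with the most
#' qualifying unclustered neighbours (identity and coverage at or above
#' the thresholds) as a representative, assigns all its qualifying
#' unclustered neighbours to it, and repeats. Ties are broken by longer
#' sequence, then lexicographic id. The output clusters partition the
#' input.
#'
#' @param records Record `data.frame`.
#' @param min_identity,min_coverage Admission thresholds in (0, 1].
#' @param precomputed Optional result of a previous all-vs-all
#'   identity/coverage computation over exactly these records (a list
#'   with `identity` and `coverage` matrices indexed by id), to avoid
#'   realigning.
#' @return `data.frame` with columns `representative`, `member`.
#' @export
greedySetCoverCluster <- function(records, min_identity = 0.8,
                                  min_coverage = 0.8, precomputed = NULL) {
  stopifnot(min_identity > 0, min_identity <= 1,
            min_coverage > 0, min_coverage <= 1)
  records <- assertRecords(records)
  n <- nrow(records)
  if (!n) return(data.frame(representative = character(),
                            member = character(), stringsAsFactors = FALSE))
  pm <- precomputed %||% pairwiseIdentityMatrix(records)
  stopifnot(identical(rownames(pm$identity), records$id))
  qualify <- pm$identity >= min_identity & pm$coverage >= min_coverage
  diag(qualify) <- TRUE
  len <- nchar(records$residues)
  ids <- records$id
  unclustered <- rep(TRUE, n)
  out <- list()
  while (any(unclustered)) {
    cand <- which(unclustered)
    nn <- vapply(cand, function(i) sum(qualify[i, ] & unclustered),
                 numeric(1L))
    ord <- order(-nn, -len[cand], ids[cand])
    rep_i <- cand[ord[1L]]
    members <- which(qualify[rep_i, ] & unclustered)
    unclustered[members] <- FALSE
    out[[length(out) + 1L]] <- data.frame(
      representative = ids[rep_i], member = ids[members],
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Remove redundant sequences
#'
#' At `identity = 1` exact duplicate residue strings are collapsed,
#' keeping the first-seen id. At lower thresholds the set is clustered
#' with [greedySetCoverCluster()] and the representatives are kept.
#'
#' @param records Record `data.frame`.
#' @param identity Identity threshold in (0, 1].
#' @param min_coverage Coverage threshold used when `identity < 1`.
#' @param precomputed Optional precomputed identity/coverage matrices
#'   (see [greedySetCoverCluster()]); ignored at `identity = 1`.
#' @return The non-redundant record `data.frame`.
#' @export
#' @examples
#' r <- sequenceRecords(c("a", "b", "c"), c("ACDE", "ACDE", "MKLV"))
#' removeRedundancy(r)$id
removeRedundancy <- function(records, identity = 1.0, min_coverage = 0.9,
                             precomputed = NULL) {
  stopifnot(identity > 0, identity <= 1)
  records <- assertRecords(records)
  if (identity == 1.0) {
    keep <- !duplicated(records$residues)
    out <- records[keep, , drop = FALSE]
    rownames(out) <- NULL
    return(out)
  }
  cl <- greedySetCoverCluster(records, identity, min_coverage, precomputed)
  reps <- unique(cl$representative)
  out <- records[match(reps, records$id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Compare two profile HMMs
#'
#' Local (Smith-Waterman) alignment of the two profiles' match-state
#' columns with per-column co-emission score
#' `log2 sum_a e1(a) e2(a) / bg(a)` and a linear gap penalty. The raw
#' score in bits per column (normalised by the shorter profile) is
#' mapped to an alignment probability by a logistic calibration whose
#' constants were fitted once on synthetic related/unrelated profile
#' pairs. Coverage is the number of aligned column pairs over the
#' shorter profile length.
#'
#' @param p1,p2 [ProfileHMM-class] objects.
#' @param gap_penalty Gap penalty per skipped column, in bits.
#' @param calibration Named numeric `slope` and `midpoint` of the
#'   logistic probability map.
#' @return One-row `data.frame`: `family_a`, `family_b`, `probability`,
#'   `coverage`, `weight` (`probability * coverage`), with
#'   `family_a < family_b`.
#' @export
profileProfileCompare <- function(p1, p2, gap_penalty = 1.0,
                                  calibration = c(slope = 5, midpoint = 1.5)) {
  bg <- p1@background
  S <- log2(p1@matchEmissions %*% t(p2@matchEmissions /
                                      matrix(bg, p2@L, 20, byrow = TRUE)))
  L1 <- p1@L; L2 <- p2@L
  H <- matrix(0, L1 + 1L, L2 + 1L)
  A <- matrix(0L, L1 + 1L, L2 + 1L)  # aligned-pair count along best path
  best <- 0; bi <- 0L; bj <- 0L
  for (i in seq_len(L1)) for (j in seq_len(L2)) {
    diag_ <- H[i, j] + S[i, j]
    up <- H[i, j + 1L] - gap_penalty
    left <- H[i + 1L, j] - gap_penalty
    m <- max(0, diag_, up, left)
    H[i + 1L, j + 1L] <- m
    A[i + 1L, j + 1L] <- if (m == 0) 0L else if (m == diag_)
      A[i, j] + 1L else if (m == up) A[i, j + 1L] else A[i + 1L, j]
    if (m > best) { best <- m; bi <- i + 1L; bj <- j + 1L }
  }
  aligned <- if (best > 0) A[bi, bj] else 0L
  z <- best / min(L1, L2)
  probability <- 1 / (1 + exp(-calibration[["slope"]] *
                                (z - calibration[["midpoint"]])))
  coverage <- aligned / min(L1, L2)
  fams <- sort(c(p1@name, p2@name))
  data.frame(family_a = fams[1L], family_b = fams[2L],
             probability = probability, coverage = coverage,
             weight = probability * coverage, stringsAsFactors = FALSE)
}

#' Build a thresholded profile-similarity network
#'
#' Compares all profile pairs with [profileProfileCompare()] and admits
#' an edge only when both the probability and the coverage meet their
#' thresholds (the distant-homolog hit rule: probability >= 0.95,
#' coverage >= 0.75). Edge weight is probability x coverage.
#'
#' @param profiles List of [ProfileHMM-class] objects with distinct
#'   names.
#' @param min_probability,min_coverage Edge-admission thresholds.
#' @param ... Passed to [profileProfileCompare()].
#' @return A [FamilyNetwork-class].
#' @export
buildFamilyNetwork <- function(profiles, min_probability = 0.95,
                               min_coverage = 0.75, ...) {
  nodes <- vapply(profiles, slot, character(1L), "name")
  if (anyDuplicated(nodes)) stop("profile names must be distinct")
  edges <- list()
  np <- length(profiles)
  if (np > 1L) for (i in seq_len(np - 1L)) for (j in (i + 1L):np) {
    e <- profileProfileCompare(profiles[[i]], profiles[[j]], ...)
    if (e$probability >= min_probability && e$coverage >= min_coverage)
      edges[[length(edges) + 1L]] <- e
  }
  edges <- if (length(edges)) do.call(rbind, edges) else
    data.frame(family_a = character(), family_b = character(),
               probability = numeric(), coverage = numeric(),
               weight = numeric(), stringsAsFactors = FALSE)
  new("FamilyNetwork", nodes = nodes, edges = edges,
      thresholds = c(probability = min_probability,
                     coverage = min_coverage))
}

#' Markov clustering of a family network
#'
#' Standard MCL: self-loops are added with weight equal to the largest
#' incident edge weight (1 for isolated nodes), columns are normalised
#' to a stochastic matrix, then expansion (matrix squaring) and
#' inflation (entrywise power and renormalisation) alternate until the
#' matrix changes by less than `tol` or `max_iter` is reached. Clusters
#' are read off the attractor rows of the limit matrix; overlapping
#' attractor systems are merged. Singletons are allowed.
#'
#' @param network A [FamilyNetwork-class].
#' @param inflation Inflation exponent (> 1; the distant-homolog screen
#'   uses 2).
#' @param tol Convergence tolerance on the max entry change.
#' @param max_iter Iteration cap; non-convergence returns the current
#'   interpretation with `converged = FALSE` and a warning.
#' @return List: `clusters` (`data.frame` with `family`, `cluster`),
#'   `converged`, `iterations`.
#' @export
mclCluster <- function(network, inflation = 2, tol = 1e-8,
                       max_iter = 100L) {
  stopifnot(inflation > 1)
  nodes <- network@nodes
  n <- length(nodes)
  M <- matrix(0, n, n, dimnames = list(nodes, nodes))
  e <- network@edges
  if (nrow(e)) {
    ia <- match(e$family_a, nodes); ib <- match(e$family_b, nodes)
    M[cbind(ia, ib)] <- e$weight
    M[cbind(ib, ia)] <- e$weight
  }
  loop <- apply(M, 2L, max)
  diag(M) <- ifelse(loop > 0, loop, 1)
  M <- sweep(M, 2L, colSums(M), "/")
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    M2 <- M %*% M
    M2 <- M2^inflation
    M2[M2 < 1e-14] <- 0
    M2 <- sweep(M2, 2L, colSums(M2), "/")
    delta <- max(abs(M2 - M))
    M <- M2
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged) warning("MCL did not converge in ", max_iter,
                          " iterations")
  ## attractors: rows with positive diagonal mass
  attr_rows <- which(diag(M) > 1e-6)
  cluster_of <- rep(NA_integer_, n)
  nextc <- 0L
  for (r in attr_rows) {
    members <- which(M[r, ] > 1e-6)
    hit <- unique(stats::na.omit(cluster_of[members]))
    if (length(hit)) {
      keep <- min(hit)
      cluster_of[members] <- keep
      cluster_of[cluster_of %in% hit] <- keep
    } else {
      nextc <- nextc + 1L
      cluster_of[members] <- nextc
    }
  }
  for (i in which(is.na(cluster_of))) {
    nextc <- nextc + 1L
    cluster_of[i] <- nextc
  }
  cluster_of <- match(cluster_of, sort(unique(cluster_of)))
  list(clusters = data.frame(family = nodes, cluster = cluster_of,
                             stringsAsFactors = FALSE),
       converged = converged, iterations = it)
}

#' Find singleton sequences against a known family
#'
#' Clusters the union of the new hits and the known family members at
#' the given thresholds and returns the new hits whose cluster contains
#' no known member (the distant-homolog singleton screen: 80% identity
#' on 80% coverage).
#'
#' @param new_hits,known_family Record `data.frame`s (disjoint ids).
#' @param identity,coverage Clustering thresholds in (0, 1].
#' @return Character vector of singleton ids.
#' @export
findSingletons <- function(new_hits, known_family, identity = 0.8,
                           coverage = 0.8) {
  new_hits <- assertRecords(new_hits)
  known_family <- assertRecords(known_family)
  if (length(intersect(new_hits$id, known_family$id)))
    stop("new_hits and known_family ids must be disjoint")
  cols <- intersect(names(new_hits), names(known_family))
  all <- rbind(new_hits[cols], known_family[cols])
  cl <- greedySetCoverCluster(all, identity, coverage)
  known_reps <- unique(cl$representative[cl$member %in% known_family$id])
  sort(cl$member[cl$member %in% new_hits$id &
                   !(cl$representative %in% known_reps)])
}
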