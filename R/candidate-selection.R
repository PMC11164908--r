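## Representative selection: neighbor-joining utility tree, catalytic
## P3-glutamate filter, pluggable solubility hook, and greedy maximin
## diversity coverage with per-group quotas.

#' Neighbor-joining tree from a distance matrix
#'
#' Thin wrapper around the standard neighbor-joining algorithm. Negative
#' branch lengths (possible on non-additive, identity-derived distances)
#' are clamped to zero and flagged in the `"clamped"` attribute.
#'
#' @param d Symmetric distance matrix with labelled rows/columns (>= 3
#'   labels) or a `dist`.
#' @return An `ape::phylo` tree (unrooted).
#' @export
#' @examples
#' d <- matrix(c(0, 2, 3, 2, 0, 3, 3, 3, 0), 3,
#'             dimnames = list(letters[1:3], letters[1:3]))
#' njTree(d)
njTree <- function(d) {
  m <- as.matrix(d)
  if (nrow(m) < 3L) stop("at least 3 labels required")
  if (max(abs(m - t(m))) > 1e-12) stop("distance matrix must be symmetric")
  tree <- ape::nj(m)
  clamped <- any(tree$edge.length < 0)
  tree$edge.length[tree$edge.length < 0] <- 0
  attr(tree, "clamped") <- clamped
  tree
}

#' Pairwise identity distance matrix
#'
#' `1 - identity` over global pairwise alignments; the input for
#' [njTree()].
#'
#' @param records Record `data.frame`.
#' @param precomputed Optional precomputed identity/coverage matrices
#'   over these records (see [greedySetCoverCluster()]).
#' @return Symmetric distance matrix.
#' @export
identityDistanceMatrix <- function(records, precomputed = NULL) {
  pm <- precomputed %||% pairwiseIdentityMatrix(records)
  stopifnot(all(records$id %in% rownames(pm$identity)))
  1 - pm$identity[records$id, records$id, drop = FALSE]
}

#' Select representative enzymes over a tree
#'
#' Operationalises "tree coverage" as greedy maximin patristic
#' diversity: the seed is the eligible leaf with the largest total
#' patristic distance to the other eligible leaves; each further pick
#' maximises the minimum distance to the current selection. Eligibility
#' requires the catalytic glutamate at pocket position P3 (when
#' `require_p3_glu`) and passing the solubility hook. Groups with unmet
#' per-group minimums are served first. All ties break lexicographically
#' by id, so selection is deterministic.
#'
#' @param tree An `ape::phylo` tree over the candidate ids.
#' @param group_labels Named character vector: leaf id -> group label
#'   (`NA` allowed).
#' @param criteria List: `require_p3_glu` (default `TRUE`),
#'   `n_representatives`, `per_group_minimum` (default 1),
#'   `solubility_hook` (function(ids) -> logical; default pass-all),
#'   `quota_groups` (groups the minimum applies to; default every group
#'   with at least one eligible leaf — an explicitly listed group with
#'   too few eligible members raises an error naming it).
#' @param fingerprints `data.frame` (`sequence_id`, `residues`) covering
#'   every leaf when `require_p3_glu`.
#' @return List: `selected` (character ids) and `report` (per-leaf
#'   `data.frame`: `sequence_id`, `group`, `p3`, `eligible`, `selected`,
#'   `reason`).
#' @export
selectRepresentatives <- function(tree, group_labels, criteria,
                                  fingerprints = NULL) {
  leaves <- tree$tip.label
  require_p3 <- isTRUE(criteria$require_p3_glu %||% TRUE)
  n_rep <- criteria$n_representatives
  per_group <- criteria$per_group_minimum %||% 1L
  hook <- criteria$solubility_hook %||% function(ids) rep(TRUE, length(ids))
  p3 <- rep(NA_character_, length(leaves))
  status <- rep("catalytic", length(leaves))
  if (require_p3) {
    if (is.null(fingerprints) || !all(leaves %in% fingerprints$sequence_id))
      stop("every leaf needs a fingerprint when require_p3_glu")
    fp <- fingerprints$residues[match(leaves, fingerprints$sequence_id)]
    p3 <- substr(fp, 3L, 3L)
    status <- catalyticStatus(fp)
  }
  soluble <- hook(leaves)
  eligible <- (status == "catalytic" | !require_p3) & soluble
  reason <- ifelse(!soluble, "solubility",
                   ifelse(require_p3 & status == "incomplete",
                          "incomplete active site",
                          ifelse(require_p3 & status == "non-catalytic",
                                 "P3 not glutamate", "")))
  groups <- group_labels[leaves]
  ## quota feasibility; quotas apply to criteria$quota_groups, or by
  ## default to every group with at least one eligible leaf
  real_groups <- criteria$quota_groups %||%
    unique(stats::na.omit(groups[eligible]))
  for (g in real_groups) {
    if (sum(eligible & !is.na(groups) & groups == g) < per_group)
      stop("infeasible per-group minimum for group ", g)
  }
  D <- ape::cophenetic.phylo(tree)
  elig_ids <- sort(leaves[eligible])
  if (length(elig_ids) <= n_rep) {
    sel <- elig_ids
  } else {
    tot <- rowSums(D[elig_ids, elig_ids, drop = FALSE])
    seed <- elig_ids[order(-tot, elig_ids)][1L]
    sel <- seed
    while (length(sel) < n_rep) {
      remaining <- setdiff(elig_ids, sel)
      deficit <- real_groups[vapply(real_groups, function(g)
        sum(!is.na(groups[match(sel, leaves)]) &
              groups[match(sel, leaves)] == g) < per_group, logical(1L))]
      pool <- remaining[!is.na(groups[match(remaining, leaves)]) &
                          groups[match(remaining, leaves)] %in% deficit]
      if (!length(pool)) pool <- remaining
      mind <- vapply(pool, function(c)
        min(D[c, sel, drop = TRUE]), numeric(1L))
      sel <- c(sel, pool[order(-mind, pool)][1L])
    }
    sel <- sort(sel)
  }
  report <- data.frame(
    sequence_id = leaves, group = unname(groups), p3 = p3,
    eligible = eligible, selected = leaves %in% sel,
    reason = ifelse(leaves %in% sel, "selected",
                    ifelse(nzchar(reason), reason, "diversity cutoff")),
    stringsAsFactors = FALSE)
  list(selected = sel, report = report)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Percent-identity matrix report
#'
#' Symmetric percent-identity matrix over all record pairs (100 on the
#' diagonal), optionally written as TSV.
#'
#' @param records Record `data.frame` (>= 2 records).
#' @param path Optional TSV output path.
#' @return The matrix, invisibly when written.
#' @export
identityMatrixReport <- function(records, path = NULL) {
  stopifnot(nrow(records) >= 2L)
  m <- 100 * pairwiseIdentityMatrix(records)$identity
  if (!is.null(path)) {
    writeTsv(data.frame(id = rownames(m), m, check.names = FALSE), path)
    return(invisible(m))
  }
  m
}
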