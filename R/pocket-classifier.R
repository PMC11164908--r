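## Structure-guided active-site fingerprinting: Kabsch superposition,
## pocket-residue extraction at the 21 named positions, hierarchical
## fingerprint classification and per-position conservation logos.

#' Default synthetic pocket definition
#'
#' Twenty-one named pocket positions on the package's ideal CA scaffold.
#' This is a synthetic stand-in configuration: the residue numbers place
#' the positions across the scaffold's catalytic region and include one
#' per-family remap (`G2`) in which P6 and P7 move to alternative
#' residues, mirroring families whose pocket geometry shifts those two
#' positions. Users analysing real structures should supply their own
#' definition.
#'
#' @param n_res Scaffold length the definition refers to.
#' @return A [PocketDefinition-class].
#' @export
defaultPocketDefinition <- function(n_res = 160L) {
  pos <- as.integer(round(seq(8L, n_res - 18L, length.out = 21L)))
  pos <- pos + seq(0L, 20L) %% 2L  # de-regularise spacing
  names(pos) <- paste0("P", 1:21)
  new("PocketDefinition",
      referenceStructure = "synthetic_reference_scaffold",
      positions = pos,
      remaps = list(G2 = c(P6 = pos[["P6"]] + 2L, P7 = pos[["P7"]] + 2L)))
}

#' Optimal rigid superposition (Kabsch)
#'
#' Least-squares optimal proper rotation and translation mapping the
#' mobile points onto the target points over a correspondence set,
#' solved in closed form by SVD with the determinant sign correction.
#'
#' @param mobile,target Numeric `n x 3` coordinate matrices.
#' @param correspondence Two-column integer matrix of row indices
#'   (mobile, target); defaults to 1:1 when the two sets have equal
#'   size.
#' @return List: `rotation` (3x3, det +1), `translation` (length 3; the
#'   fitted map is `x %*% t(rotation) + translation`), `rmsd` (angstroms
#'   over the correspondence set).
#' @export
#' @examples
#' pts <- matrix(rnorm(30), 10, 3)
#' kabschSuperpose(pts, pts)$rmsd
kabschSuperpose <- function(mobile, target, correspondence = NULL) {
  mobile <- as.matrix(mobile); target <- as.matrix(target)
  if (is.null(correspondence)) {
    if (nrow(mobile) != nrow(target))
      stop("correspondence required when point counts differ")
    correspondence <- cbind(seq_len(nrow(mobile)), seq_len(nrow(mobile)))
  }
  P <- mobile[correspondence[, 1L], , drop = FALSE]
  Q <- target[correspondence[, 2L], , drop = FALSE]
  n <- nrow(P)
  if (n < 3L) stop("at least 3 corresponding points required")
  cp <- colMeans(P); cq <- colMeans(Q)
  P0 <- sweep(P, 2L, cp); Q0 <- sweep(Q, 2L, cq)
  sv0 <- svd(P0)
  if (sv0$d[2L] < 1e-9 * max(sv0$d[1L], 1))
    stop("degenerate (collinear) point geometry")
  H <- crossprod(P0, Q0)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  tvec <- cq - as.numeric(R %*% cp)
  fitted <- P %*% t(R) + matrix(tvec, n, 3L, byrow = TRUE)
  rmsd <- sqrt(mean(rowSums((fitted - Q)^2)))
  list(rotation = R, translation = tvec, rmsd = rmsd)
}

structureXyz <- function(structure)
  as.matrix(structure[, c("x", "y", "z")])

## Residue-index correspondence from a global alignment of the two CA
## residue strings.
alignCorrespondence <- function(query, reference) {
  qs <- paste(query$residue, collapse = "")
  rs <- paste(reference$residue, collapse = "")
  pa <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::BString(qs), subject = Biostrings::BString(rs),
    type = "global", substitutionMatrix = SUBMAT,
    gapOpening = 10, gapExtension = 0.5)
  ap <- splitResidues(as.character(Biostrings::alignedPattern(pa)))[[1L]]
  as_ <- splitResidues(as.character(Biostrings::alignedSubject(pa)))[[1L]]
  qi <- cumsum(ap != "-"); ri <- cumsum(as_ != "-")
  both <- ap != "-" & as_ != "-"
  cbind(mobile = qi[both], target = ri[both])
}

#' Extract a pocket fingerprint from a structure
#'
#' Superposes the query CA structure onto the reference (alignment-
#' guided Kabsch: the correspondence comes from a global alignment of
#' the two residue strings), then reads, for each of the 21 reference
#' pocket residues, the residue type of the alignment-corresponding
#' query CA when it lies within `match_cutoff` of the reference
#' position; reference positions with no aligned partner fall back to
#' the spatially nearest query CA within the cutoff. Positions with no
#' CA in range yield a gap. When `family` names a remap of the
#' definition, the remapped residue numbers are used for the affected
#' positions.
#'
#' @param structure Query CA table (`resno`, `residue`, `x`, `y`, `z`).
#' @param reference Reference CA table carrying the pocket.
#' @param definition A [PocketDefinition-class].
#' @param match_cutoff Distance cutoff in angstroms.
#' @param family Optional family label selecting a remap.
#' @param sequence_id Id stored on the fingerprint.
#' @return One-row `data.frame`: `sequence_id`, `residues` (21
#'   characters), `rmsd`.
#' @export
extractPocket <- function(structure, reference, definition,
                          match_cutoff = 3, family = NULL,
                          sequence_id = "query") {
  pos <- definition@positions
  if (!is.null(family) && family %in% names(definition@remaps)) {
    r <- definition@remaps[[family]]
    pos[names(r)] <- r
  }
  corr <- alignCorrespondence(structure, reference)
  if (nrow(corr) < 3L) {
    warning("unresolvable correspondence for ", sequence_id,
            "; all-gap fingerprint")
    return(data.frame(sequence_id = sequence_id,
                      residues = paste(rep("-", length(pos)), collapse = ""),
                      rmsd = NA_real_, stringsAsFactors = FALSE))
  }
  fit <- kabschSuperpose(structureXyz(structure), structureXyz(reference),
                         corr)
  qxyz <- structureXyz(structure) %*% t(fit$rotation) +
    matrix(fit$translation, nrow(structure), 3L, byrow = TRUE)
  ## query row aligned to each reference row (NA where unaligned)
  q_of_r <- rep(NA_integer_, nrow(reference))
  q_of_r[corr[, 2L]] <- corr[, 1L]
  fp <- character(length(pos))
  for (p in seq_along(pos)) {
    ri <- match(pos[p], reference$resno)
    if (is.na(ri)) { fp[p] <- "-"; next }
    rxyz <- structureXyz(reference)[ri, ]
    j <- q_of_r[ri]
    if (is.na(j) ||
        sqrt(sum((qxyz[j, ] - rxyz)^2)) > match_cutoff) {
      d2 <- rowSums(sweep(qxyz, 2L, rxyz)^2)
      j <- which.min(d2)
      if (sqrt(d2[j]) > match_cutoff) { fp[p] <- "-"; next }
    }
    fp[p] <- structure$residue[j]
  }
  data.frame(sequence_id = sequence_id,
             residues = paste(fp, collapse = ""), rmsd = fit$rmsd,
             stringsAsFactors = FALSE)
}

#' Modeling eligibility gate
#'
#' A query is eligible for structure-based pocket extraction when its
#' best pairwise identity to any template sequence reaches
#' `min_identity` (default 0.23).
#'
#' @param query Residue string (or one-row record `data.frame`).
#' @param templates Record `data.frame` of template sequences.
#' @param min_identity Identity threshold in (0, 1].
#' @return Logical.
#' @export
modelingGate <- function(query, templates, min_identity = 0.23) {
  stopifnot(min_identity > 0, min_identity <= 1)
  if (is.data.frame(query)) query <- query$residues[1L]
  ids <- vapply(templates$residues, function(t)
    pairwiseIdentity(query, t)[["identity"]], numeric(1L))
  max(ids) >= min_identity
}

## Vectorised modelingGate over a record set: one alignment batch per
## template instead of one call per (query, template) pair.
batchModelingGate <- function(records, templates, min_identity = 0.23) {
  best <- rep(0, nrow(records))
  for (t in templates$residues) {
    pa <- Biostrings::pairwiseAlignment(
      pattern = Biostrings::BStringSet(records$residues),
      subject = Biostrings::BString(t),
      type = "global", substitutionMatrix = SUBMAT,
      gapOpening = 10, gapExtension = 0.5)
    aps <- as.character(Biostrings::alignedPattern(pa))
    ass <- as.character(Biostrings::alignedSubject(pa))
    ids <- vapply(seq_len(nrow(records)), function(k)
      alignedPairStats(aps[k], ass[k], nchar(records$residues[k]),
                       nchar(t))[["identity"]], numeric(1L))
    best <- pmax(best, ids)
  }
  best >= min_identity
}

fingerprintMatrix <- function(fingerprints) {
  m <- do.call(rbind, splitResidues(fingerprints$residues))
  rownames(m) <- fingerprints$sequence_id
  m
}

## Per-position identity distance between fingerprints; positions where
## either is a gap are excluded (all-gap overlap -> distance 1).
fingerprintDistance <- function(m) {
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  if (n > 1L) for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    ok <- m[i, ] != "-" & m[j, ] != "-"
    d[i, j] <- d[j, i] <- if (!any(ok)) 1 else mean(m[i, ok] != m[j, ok])
  }
  d
}

#' Hierarchically classify pocket fingerprints
#'
#' Agglomerative average-linkage clustering on a per-position identity
#' distance, cut at `cut_height`; clusters with fewer than
#' `min_cluster_size` members are flagged not retained. Per-cluster
#' consensus fingerprints take the most frequent non-gap residue at each
#' position (ties alphabetic).
#'
#' @param fingerprints `data.frame` with `sequence_id`, `residues`.
#' @param min_cluster_size Retention threshold (default 15).
#' @param cut_height Distance threshold cutting the dendrogram.
#' @return A [PocketTree-class].
#' @export
clusterPockets <- function(fingerprints, min_cluster_size = 15L,
                           cut_height = 0.5) {
  stopifnot(nrow(fingerprints) >= 1L)
  m <- fingerprintMatrix(fingerprints)
  if (nrow(m) == 1L) {
    cl <- 1L
    hc <- NULL
  } else {
    d <- fingerprintDistance(m)
    hc <- hclust(as.dist(d), method = "average")
    ## average linkage is monotone; tied merges can leave heights out of
    ## order by floating-point noise, which cutree rejects
    hc$height <- cummax(hc$height)
    cl <- cutree(hc, h = cut_height)
  }
  sizes <- table(cl)
  retained <- as.integer(names(sizes))[sizes >= min_cluster_size]
  consensus <- vapply(sort(unique(cl)), function(k) {
    sub <- m[cl == k, , drop = FALSE]
    paste(apply(sub, 2L, function(col) {
      col <- col[col != "-"]
      if (!length(col)) return("-")
      tt <- table(col)
      names(tt)[which.max(tt)]  # ties: first alphabetically
    }), collapse = "")
  }, character(1L))
  names(consensus) <- as.character(sort(unique(cl)))
  new("PocketTree", hclust = hc,
      assignments = data.frame(sequence_id = fingerprints$sequence_id,
                               cluster = as.integer(cl),
                               retained = as.integer(cl) %in% retained,
                               stringsAsFactors = FALSE),
      consensus = consensus,
      minClusterSize = as.integer(min_cluster_size),
      cutHeight = cut_height)
}

#' Export a pocket tree as Newick
#' @param tree A [PocketTree-class] built from >= 3 fingerprints.
#' @param path Optional output file.
#' @return The Newick string (invisibly when written to `path`).
#' @export
pocketTreeNewick <- function(tree, path = NULL) {
  if (is.null(tree@hclust)) stop("tree has no dendrogram (< 2 fingerprints)")
  phy <- ape::as.phylo(tree@hclust)
  nwk <- ape::write.tree(phy)
  if (!is.null(path)) { writeLines(nwk, path); return(invisible(nwk)) }
  nwk
}

#' Assign group labels to fingerprints via retained clusters
#'
#' Each cluster containing at least one labelled reference member takes
#' that label (majority vote on ties); members of unlabelled clusters
#' stay `NA`.
#'
#' @param tree A [PocketTree-class].
#' @param reference_labels Named character vector: sequence id -> group
#'   label (e.g. `G1`..`G5`).
#' @return Character vector of group labels parallel to the tree's
#'   assignments.
#' @export
assignGroups <- function(tree, reference_labels) {
  a <- tree@assignments
  out <- rep(NA_character_, nrow(a))
  for (k in unique(a$cluster)) {
    ids <- a$sequence_id[a$cluster == k]
    labs <- reference_labels[intersect(ids, names(reference_labels))]
    if (length(labs)) {
      tt <- table(labs)
      out[a$cluster == k] <- names(tt)[which.max(tt)]
    }
  }
  out
}

#' Per-position conservation logo of a fingerprint cluster
#'
#' For each position, residue frequencies are computed over the non-gap
#' symbols (the gap fraction is tracked separately) and the information
#' content is `log2(20)` minus the Shannon entropy of those frequencies.
#' All-gap positions have undefined (NA) information content.
#'
#' @param fingerprints `data.frame` with `sequence_id`, `residues` (all
#'   the same length; works for 21-position pockets and 6-position
#'   cofactor windows alike).
#' @return List: `frequencies` (positions x 20 matrix), `ic` (bits),
#'   `gap_fraction`.
#' @export
makeLogo <- function(fingerprints) {
  stopifnot(nrow(fingerprints) >= 1L)
  m <- fingerprintMatrix(fingerprints)
  P <- ncol(m)
  freq <- matrix(0, P, 20, dimnames = list(NULL, AA20))
  gapf <- numeric(P)
  ic <- numeric(P)
  for (p in seq_len(P)) {
    col <- m[, p]
    gapf[p] <- mean(col == "-")
    col <- col[col %in% AA20]
    if (!length(col)) { ic[p] <- NA_real_; next }
    f <- as.numeric(table(factor(col, levels = AA20))) / length(col)
    freq[p, ] <- f
    h <- -sum(ifelse(f > 0, f * log2(f), 0))
    ic[p] <- log2(20) - h
  }
  list(frequencies = freq, ic = ic, gap_fraction = gapf)
}

#' Catalytic-residue check at position P3
#'
#' The family's catalytic residue is the glutamate at pocket position
#' P3. `checkCatalytic()` returns `TRUE` only for fingerprints with `E`
#' at P3; `catalyticStatus()` distinguishes a non-glutamate residue
#' (`"non-catalytic"`) from a gap (`"incomplete"`, an incompletely
#' resolved active site).
#'
#' @param residues Character vector of fingerprint strings (>= 3
#'   positions).
#' @return `checkCatalytic()`: logical vector. `catalyticStatus()`:
#'   character vector in `{"catalytic", "non-catalytic", "incomplete"}`.
#' @export
#' @examples
#' checkCatalytic(c("AAEAA", "AAAAA", "AA-AA"))
#' catalyticStatus(c("AAEAA", "AAAAA", "AA-AA"))
checkCatalytic <- function(residues) {
  substr(residues, 3L, 3L) == "E"
}

#' @rdname checkCatalytic
#' @export
catalyticStatus <- function(residues) {
  p3 <- substr(residues, 3L, 3L)
  ifelse(p3 == "E", "catalytic",
         ifelse(p3 == "-", "incomplete", "non-catalytic"))
}
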