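## NAD/NADP cofactor-specificity prediction from the six-residue window
## R1..R6 (residues 36-41 in the reference numbering) by residue-class
## rules, plus window extraction, gap discard and R1-keyed clustering.

#' Residue class table for the cofactor rules
#'
#' The named residue sets the classification rules draw from: negative
#' (Asp, Glu), positive (His, Lys, Arg), polar (Ser, Asn), short-chain
#' (Ala, Ser), aliphatic (Val, Ile) and bulky (Arg, Tyr, Phe). The table
#' is configuration: classification is a pure function of it and users
#' may amend the sets.
#'
#' @return Named list of character vectors.
#' @export
defaultResidueClassTable <- function() {
  list(negative = c("D", "E"),
       positive = c("H", "K", "R"),
       polar = c("S", "N"),
       short = c("A", "S"),
       aliphatic = c("V", "I"),
       bulky = c("R", "Y", "F"))
}

#' Extract the R1..R6 cofactor window from an alignment
#'
#' The six alignment columns carrying the reference sequence's anchored
#' residues (`anchor_start` .. `anchor_start + 5`) define R1..R6; every
#' row contributes its symbols at those columns.
#'
#' @param alignment `data.frame` with columns `id`, `aligned`.
#' @param reference_id Id of the anchor reference row.
#' @param anchor_start,anchor_end 1-based first and last residue indices
#'   of the window in the ungapped reference (must span exactly six
#'   residues).
#' @return `data.frame`: `sequence_id`, `residues` (6 characters).
#' @export
extractCofactorWindow <- function(alignment, reference_id,
                                  anchor_start, anchor_end) {
  if (anchor_end - anchor_start != 5L)
    stop("anchor residues must be contiguous and six in number")
  i <- match(reference_id, alignment$id)
  if (is.na(i)) stop("reference id not in alignment: ", reference_id)
  refrow <- splitResidues(alignment$aligned[i])[[1L]]
  respos <- which(refrow != "-")
  if (anchor_end > length(respos))
    stop("anchor window beyond reference length")
  cols <- respos[anchor_start:anchor_end]
  rows <- splitResidues(alignment$aligned)
  data.frame(sequence_id = alignment$id,
             residues = vapply(rows, function(r)
               paste(r[cols], collapse = ""), character(1L)),
             stringsAsFactors = FALSE)
}

#' Discard gap-containing cofactor signatures
#'
#' @param signatures `data.frame` with `sequence_id`, `residues`.
#' @return List: `retained` (gap-free rows), `n_discarded`,
#'   `n_retained`.
#' @export
#' @examples
#' s <- data.frame(sequence_id = c("a", "b"),
#'                 residues = c("DVIGGY", "DV-GGY"))
#' discardGapped(s)$n_retained
discardGapped <- function(signatures) {
  gapped <- grepl("-", signatures$residues, fixed = TRUE)
  retained <- signatures[!gapped, , drop = FALSE]
  rownames(retained) <- NULL
  list(retained = retained, n_discarded = sum(gapped),
       n_retained = sum(!gapped))
}

#' Classify cofactor specificity from an R1..R6 signature
#'
#' Rule set (checked in order of specificity):
#' \itemize{
#'   \item dual (NAD and NADP): R1 negative, R2 and R6 positive, R3
#'     polar;
#'   \item NAD: R1 negative and R2, R3, R6 all aliphatic or bulky;
#'   \item NADP: R1 short-chain, R2 and R6 positive, R3 polar;
#'   \item otherwise unknown.
#' }
#' Signatures containing a gap are `unknown`. R4 and R5 are carried but
#' unused by the rules.
#'
#' @param residues Character vector of six-residue signature strings.
#' @param table Residue class table (see [defaultResidueClassTable()]).
#' @return Character vector in `{"NAD", "NADP", "dual", "unknown"}`.
#' @export
#' @examples
#' classifyCofactor(c("DVIGGY", "ARSGGK", "DHNGGR", "GGGGGG"))
classifyCofactor <- function(residues, table = defaultResidueClassTable()) {
  vapply(residues, function(s) {
    if (nchar(s) != 6L) stop("signature must have exactly 6 symbols")
    if (grepl("-", s, fixed = TRUE)) return("unknown")
    r <- splitResidues(s)[[1L]]
    r1 <- r[1L]; r2 <- r[2L]; r3 <- r[3L]; r6 <- r[6L]
    alibulk <- union(table$aliphatic, table$bulky)
    if (r1 %in% table$negative && r2 %in% table$positive &&
        r6 %in% table$positive && r3 %in% table$polar) return("dual")
    if (r1 %in% table$negative && all(c(r2, r3, r6) %in% alibulk))
      return("NAD")
    if (r1 %in% table$short && r2 %in% table$positive &&
        r6 %in% table$positive && r3 %in% table$polar) return("NADP")
    "unknown"
  }, character(1L), USE.NAMES = FALSE)
}

#' Cluster cofactor signatures under key position R1
#'
#' Signatures are grouped primarily by the R1 residue and subdivided by
#' exact window identity; cluster labels are `"<R1>.<k>"` with
#' sub-clusters numbered by decreasing size (ties lexicographic).
#'
#' @param signatures Gap-free signature `data.frame` (`sequence_id`,
#'   `residues`).
#' @return `data.frame`: `sequence_id`, `residues`, `r1`, `cluster`.
#' @export
clusterByR1 <- function(signatures) {
  if (any(grepl("-", signatures$residues, fixed = TRUE)))
    stop("signatures must be gap-free (run discardGapped first)")
  r1 <- substr(signatures$residues, 1L, 1L)
  cluster <- character(nrow(signatures))
  for (key in sort(unique(r1))) {
    sel <- r1 == key
    tt <- table(signatures$residues[sel])
    windows <- names(tt)[order(-as.numeric(tt), names(tt))]
    cluster[sel] <- paste0(key, ".",
                           match(signatures$residues[sel], windows))
  }
  out <- signatures
  out$r1 <- r1
  out$cluster <- cluster
  out
}
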