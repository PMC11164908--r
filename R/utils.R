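## Internal helpers shared across modules.

## Evaluate expr with a locally seeded RNG, restoring global state.
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    set.seed(as.integer(seed))
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
  }
  force(expr)
}

splitResidues <- function(x) strsplit(x, "", fixed = TRUE)

#' Assemble a sequence record table
#'
#' The package represents sequence sets as plain `data.frame`s with one
#' row per protein: `id`, `description`, `residues`, `obsolete`,
#' `source_db`. This constructor validates the invariants (unique
#' non-empty ids, non-empty residue strings over the amino-acid alphabet
#' plus `X`).
#'
#' @param id Character vector of unique identifiers.
#' @param residues Character vector of residue strings (uppercase
#'   canonical amino acids, optionally `X`).
#' @param description Free-text descriptions (default empty).
#' @param obsolete Logical curation flag (default `FALSE`).
#' @param source_db Source database label (default `"synthetic"`).
#' @return A `data.frame` with the five columns above.
#' @export
#' @examples
#' sequenceRecords(c("a", "b"), c("ACDE", "MKLV"))
sequenceRecords <- function(id, residues, description = "",
                            obsolete = FALSE, source_db = "synthetic") {
  id <- as.character(id)
  residues <- toupper(as.character(residues))
  if (anyDuplicated(id))
    stop("duplicate sequence ids: ",
         paste(unique(id[duplicated(id)]), collapse = ", "))
  if (any(!nzchar(id))) stop("empty sequence id")
  if (length(residues) && any(!nzchar(residues)))
    stop("empty residue string")
  bad <- grepl(sprintf("[^%sX]", paste(AA20, collapse = "")), residues)
  if (any(bad))
    stop("non-alphabet residues in: ", paste(id[bad], collapse = ", "))
  data.frame(id = id, description = rep_len(description, length(id)),
             residues = residues,
             obsolete = rep_len(obsolete, length(id)),
             source_db = rep_len(source_db, length(id)),
             stringsAsFactors = FALSE)
}

emptyRecords <- function() {
  data.frame(id = character(), description = character(),
             residues = character(), obsolete = logical(),
             source_db = character(), stringsAsFactors = FALSE)
}

assertRecords <- function(records) {
  need <- c("id", "residues")
  if (!is.data.frame(records) || !all(need %in% names(records)))
    stop("records must be a data.frame with columns id, residues")
  if (anyDuplicated(records$id))
    stop("duplicate sequence ids: ",
         paste(unique(records$id[duplicated(records$id)]), collapse = ", "))
  if (is.null(records$obsolete)) records$obsolete <- FALSE
  if (is.null(records$description)) records$description <- ""
  if (is.null(records$source_db)) records$source_db <- "unknown"
  records
}

## Sample one residue per column from a list of per-column distributions
## (each a named numeric over AA20).
sampleColumns <- function(profile) {
  vapply(profile, function(p) sample(AA20, 1L, prob = p), character(1L))
}

## A point-mass-with-noise column distribution: consensus residue with
## probability 1 - rate, the rest uniform over the other 19.
consensusColumn <- function(consensus, rate) {
  p <- rep(rate / 19, 20)
  names(p) <- AA20
  p[consensus] <- 1 - rate
  p
}

## Uniform random rotation (det +1) via QR of a Gaussian matrix.
randomRotation <- function() {
  qr. <- qr(matrix(rnorm(9), 3, 3))
  q <- qr.Q(qr.)
  d <- diag(sign(diag(qr.R(qr.))))
  q <- q %*% d
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

writeTsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
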