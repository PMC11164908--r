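## Profile-HMM construction, domain splitting at a reference anchor,
## local forward/Viterbi scoring in bits, database search and two-domain
## homolog confirmation.

TRANS_COLS <- c("MM", "MI", "MD", "IM", "II", "DM", "DD")

alignmentMatrix <- function(alignment) {
  if (!nrow(alignment)) stop("alignment is empty")
  w <- nchar(alignment$aligned[1])
  if (w == 0L) stop("alignment of width 0")
  m <- do.call(rbind, splitResidues(alignment$aligned))
  rownames(m) <- alignment$id
  m
}

#' Build a profile HMM from a multiple alignment
#'
#' Columns with gap fraction below 0.5 become match states. Match
#' emissions are background-mixture pseudocounted observed counts;
#' transitions are maximum-likelihood estimates of the row gap/insert
#' structure with +1 (Laplace) smoothing over each state's target set.
#' Insert emissions default to the background. Rows are weighted
#' uniformly.
#'
#' @param alignment `data.frame` with columns `id`, `aligned`.
#' @param pseudocount_weight Weight of the background mixed into match
#'   emission counts (> 0 recommended; 0 gives pure ML point masses).
#' @param background Residue background distribution (default uniform).
#' @param name Model name.
#' @return A [ProfileHMM-class].
#' @export
#' @examples
#' aln <- data.frame(id = c("a", "b"), aligned = c("ACD", "ACD"))
#' buildProfile(aln, name = "toy")
buildProfile <- function(alignment, pseudocount_weight = 1.0,
                         background = rep(1 / 20, 20), name = "profile") {
  m <- alignmentMatrix(alignment)
  allgap <- colMeans(m == "-") == 1
  if (any(allgap)) {
    warning(sum(allgap), " all-gap columns dropped")
  }
  gapfrac <- colMeans(m == "-")
  match_cols <- which(gapfrac < 0.5)
  if (!length(match_cols)) stop("no match-state columns (all too gapped)")
  L <- length(match_cols)
  bg <- background / sum(background)
  names(bg) <- AA20
  me <- matrix(0, L, 20, dimnames = list(NULL, AA20))
  for (k in seq_len(L)) {
    col <- m[, match_cols[k]]
    col <- col[col %in% AA20]
    cnt <- table(factor(col, levels = AA20))
    me[k, ] <- (as.numeric(cnt) + pseudocount_weight * bg) /
      (sum(cnt) + pseudocount_weight)
  }
  ie <- matrix(rep(bg, each = L), L, 20, dimnames = list(NULL, AA20))
  tr <- estimateTransitions(m, match_cols)
  new("ProfileHMM", name = name, L = L, matchEmissions = me,
      insertEmissions = ie, transitions = tr, background = unname(bg),
      map = as.integer(match_cols))
}

## Count M/I/D transition events per inter-node junction with +1
## smoothing. Insert events on rows deleted at the junction are
## projected onto the nearest representable plan7-lite path (no D->I).
estimateTransitions <- function(m, match_cols) {
  L <- length(match_cols)
  tr <- matrix(NA_real_, max(L - 1L, 0L), 7L,
               dimnames = list(NULL, TRANS_COLS))
  if (L < 2L) return(tr)
  for (k in seq_len(L - 1L)) {
    c1 <- match_cols[k]; c2 <- match_cols[k + 1L]
    between <- if (c2 > c1 + 1L) (c1 + 1L):(c2 - 1L) else integer()
    cnt <- setNames(numeric(7L), TRANS_COLS)
    for (r in seq_len(nrow(m))) {
      s1 <- if (m[r, c1] != "-") "M" else "D"
      s2 <- if (m[r, c2] != "-") "M" else "D"
      nins <- if (length(between)) sum(m[r, between] != "-") else 0L
      if (nins > 0L && s1 == "M" && s2 == "M") {
        cnt["MI"] <- cnt["MI"] + 1
        cnt["II"] <- cnt["II"] + (nins - 1L)
        cnt["IM"] <- cnt["IM"] + 1
      } else {
        key <- paste0(s1, s2)
        cnt[key] <- cnt[key] + 1
      }
    }
    mTot <- cnt["MM"] + cnt["MI"] + cnt["MD"] + 3
    iTot <- cnt["IM"] + cnt["II"] + 2
    dTot <- cnt["DM"] + cnt["DD"] + 2
    tr[k, ] <- c((cnt["MM"] + 1) / mTot, (cnt["MI"] + 1) / mTot,
                 (cnt["MD"] + 1) / mTot, (cnt["IM"] + 1) / iTot,
                 (cnt["II"] + 1) / iTot, (cnt["DM"] + 1) / dTot,
                 (cnt["DD"] + 1) / dTot)
  }
  tr
}

#' Split a family alignment at a reference anchor residue
#'
#' Finds the alignment column carrying the reference sequence's
#' `anchor_residue`-th residue and builds one profile from the columns
#' up to and including that column (the N-terminal, cofactor-binding
#' block) and one from the remaining columns (the C-terminal, catalytic
#' block).
#'
#' @param alignment `data.frame` with columns `id`, `aligned`.
#' @param reference_id Row id of the reference sequence.
#' @param anchor_residue 1-based residue index in the ungapped reference
#'   (must be strictly less than the reference length).
#' @param pseudocount_weight Passed to [buildProfile()].
#' @param name Parent profile name.
#' @return A [DomainSplit-class].
#' @export
splitProfile <- function(alignment, reference_id, anchor_residue,
                         pseudocount_weight = 1.0, name = "profile") {
  i <- match(reference_id, alignment$id)
  if (is.na(i)) stop("reference id not in alignment: ", reference_id)
  refrow <- splitResidues(alignment$aligned[i])[[1L]]
  respos <- which(refrow != "-")
  if (anchor_residue < 1L || anchor_residue >= length(respos))
    stop("anchor_residue must satisfy 1 <= anchor < reference length (",
         length(respos), ")")
  anchor_col <- respos[anchor_residue]
  w <- nchar(alignment$aligned[1])
  left <- data.frame(id = alignment$id,
                     aligned = substr(alignment$aligned, 1L, anchor_col),
                     stringsAsFactors = FALSE)
  right <- data.frame(id = alignment$id,
                      aligned = substr(alignment$aligned, anchor_col + 1L, w),
                      stringsAsFactors = FALSE)
  np <- buildProfile(left, pseudocount_weight,
                     name = paste0(name, "_Nbinding"))
  cp <- buildProfile(right, pseudocount_weight,
                     name = paste0(name, "_Ccatalytic"))
  cp@map <- cp@map + anchor_col
  new("DomainSplit", parent = name,
      anchorResidue = as.integer(anchor_residue),
      nProfile = np, cProfile = cp)
}

profileLogOdds <- function(profile) {
  bg <- profile@background
  list(lm = log(sweep(profile@matchEmissions, 2L, bg, "/")),
       li = log(sweep(profile@insertEmissions, 2L, bg, "/")),
       ltr = {
         tr <- profile@transitions
         if (nrow(tr)) log(tr) else matrix(0, 0L, 7L)
       })
}

encodeSeq <- function(seq) {
  r <- splitResidues(toupper(seq))[[1L]]
  idx <- match(r, AA20) - 1L
  idx[is.na(idx)] <- -1L
  idx
}

#' Score a sequence against a profile HMM
#'
#' `forwardScore()` returns the log2 ratio of the summed local-alignment
#' likelihood (all alignments, uniform fragment entry/exit, plus a
#' no-match path of odds 1) to the i.i.d. background null;
#' `viterbiScore()` maximises instead of summing and also returns the
#' best state path. The empty sequence scores 0 bits (the no-match
#' path). Unknown residues (`X`) score as background.
#'
#' @param profile A [ProfileHMM-class].
#' @param seq Residue string.
#' @return `forwardScore()`: a single bit score. `viterbiScore()`: a
#'   list with `bits` and `path` (state labels such as `"M3"`).
#' @export
#' @examples
#' p <- buildProfile(data.frame(id = "a", aligned = "ACDEF"))
#' forwardScore(p, "ACDEF") >= viterbiScore(p, "ACDEF")$bits
forwardScore <- function(profile, seq) {
  lo <- profileLogOdds(profile)
  .phmm_forward(lo$lm, lo$li, lo$ltr, encodeSeq(seq))
}

#' @rdname forwardScore
#' @export
viterbiScore <- function(profile, seq) {
  lo <- profileLogOdds(profile)
  .phmm_viterbi(lo$lm, lo$li, lo$ltr, encodeSeq(seq))
}

#' Search a sequence database with a profile HMM
#'
#' Scores every record with [forwardScore()] and marks those at or above
#' the bit-score threshold as passing. Results are sorted by descending
#' score with ties broken by id.
#'
#' @param profile A [ProfileHMM-class].
#' @param db Record `data.frame`.
#' @param score_threshold Bit-score acceptance threshold (default 50, the
#'   Rossmann-signature screen value).
#' @return `data.frame` with columns `sequence_id`, `bit_score`,
#'   `passed`, `profile`.
#' @export
searchProfile <- function(profile, db, score_threshold = 50) {
  stopifnot(is.finite(score_threshold))
  db <- assertRecords(db)
  if (!nrow(db))
    return(data.frame(sequence_id = character(), bit_score = numeric(),
                      passed = logical(), profile = character(),
                      stringsAsFactors = FALSE))
  lo <- profileLogOdds(profile)
  scores <- vapply(db$residues, function(s)
    .phmm_forward(lo$lm, lo$li, lo$ltr, encodeSeq(s)), numeric(1L),
    USE.NAMES = FALSE)
  out <- data.frame(sequence_id = db$id, bit_score = scores,
                    passed = scores >= score_threshold,
                    profile = profile@name, stringsAsFactors = FALSE)
  out <- out[order(-out$bit_score, out$sequence_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Confirm two-domain hits
#'
#' A sequence is a confirmed family member only if it passes both the
#' catalytic-domain and the NAD(P)-binding-domain profile screens.
#'
#' @param hits_catalytic,hits_binding Hit tables from [searchProfile()]
#'   over the same database.
#' @return Character vector of confirmed sequence ids (sorted).
#' @export
confirmTwoDomain <- function(hits_catalytic, hits_binding) {
  sort(intersect(hits_catalytic$sequence_id[hits_catalytic$passed],
                 hits_binding$sequence_id[hits_binding$passed]))
}

#' Serialize / read a profile HMM (flat text)
#'
#' A documented HMMER3-inspired flat layout (header; per-state emission,
#' insert and transition lines; map line) using full-precision (`%.17g`)
#' numbers, so profiles round-trip bit-exactly. Not byte-compatible with
#' HMMER.
#'
#' @param profile A [ProfileHMM-class].
#' @param path File path.
#' @return `writeProfile()`: `path` invisibly; `readProfile()`: a
#'   [ProfileHMM-class].
#' @export
writeProfile <- function(profile, path) {
  g <- function(x) sprintf("%.17g", x)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("POCKETFAM-HMM 1",
               paste("NAME", profile@name),
               paste("LENG", profile@L),
               paste("BG", paste(g(profile@background), collapse = " ")),
               paste("MAP", paste(profile@map, collapse = " "))), con)
  for (k in seq_len(profile@L)) {
    writeLines(paste("ME", k, paste(g(profile@matchEmissions[k, ]),
                                    collapse = " ")), con)
    writeLines(paste("IE", k, paste(g(profile@insertEmissions[k, ]),
                                    collapse = " ")), con)
    if (k < profile@L)
      writeLines(paste("TR", k, paste(g(profile@transitions[k, ]),
                                      collapse = " ")), con)
  }
  invisible(path)
}

#' @rdname writeProfile
#' @export
readProfile <- function(path) {
  lines <- readLines(path)
  if (!grepl("^POCKETFAM-HMM", lines[1])) stop("not a pocketfam profile file")
  fields <- strsplit(lines, " ", fixed = TRUE)
  tag <- vapply(fields, `[[`, character(1L), 1L)
  getnum <- function(f, from = 2L) as.numeric(f[-seq_len(from - 1L)])
  name <- fields[[which(tag == "NAME")[1]]][2]
  L <- as.integer(fields[[which(tag == "LENG")[1]]][2])
  bg <- getnum(fields[[which(tag == "BG")[1]]])
  map <- as.integer(getnum(fields[[which(tag == "MAP")[1]]]))
  me <- matrix(0, L, 20, dimnames = list(NULL, AA20))
  ie <- matrix(0, L, 20, dimnames = list(NULL, AA20))
  tr <- matrix(0, max(L - 1L, 0L), 7L, dimnames = list(NULL, TRANS_COLS))
  for (i in which(tag %in% c("ME", "IE", "TR"))) {
    f <- fields[[i]]
    k <- as.integer(f[2])
    v <- as.numeric(f[-(1:2)])
    switch(f[1], ME = (me[k, ] <- v), IE = (ie[k, ] <- v),
           TR = (tr[k, ] <- v))
  }
  new("ProfileHMM", name = name, L = L, matchEmissions = me,
      insertEmissions = ie, transitions = tr, background = bg, map = map)
}

#' ROC-based bit-score threshold selection
#'
#' Given scores for a labeled synthetic decoy set, picks the threshold
#' maximising Youden's J (sensitivity + specificity - 1) over the
#' midpoints between consecutive observed scores. This is the
#' alternative to the fixed 50-bit default when a labeled calibration
#' set is available.
#'
#' @param scores Numeric bit scores.
#' @param is_member Logical truth labels.
#' @return The selected threshold (bits).
#' @export
selectThreshold <- function(scores, is_member) {
  stopifnot(length(scores) == length(is_member), any(is_member),
            any(!is_member))
  s <- sort(unique(scores))
  cand <- if (length(s) > 1L) (head(s, -1L) + s[-1L]) / 2 else s
  j <- vapply(cand, function(t) {
    sens <- mean(scores[is_member] >= t)
    spec <- mean(scores[!is_member] < t)
    sens + spec - 1
  }, numeric(1L))
  cand[which.max(j)]
}
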