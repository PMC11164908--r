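## Standard-format I/O (FASTA, aligned FASTA, Stockholm, CA-only PDB
## subset) and the seed-set curation filter.

#' Read a FASTA file into a sequence record table
#'
#' The first whitespace-delimited token of each header is the id; the
#' remainder is the description. A record whose description contains the
#' token `OBSOLETE` is flagged obsolete. Lowercase residues are
#' uppercased with a warning.
#'
#' @param path FASTA file path.
#' @param source_db Source label stored on each record.
#' @return A record `data.frame` (see [sequenceRecords()]).
#' @export
readFastaRecords <- function(path, source_db = basename(path)) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (file.size(path) == 0L) {
    warning("empty FASTA file: ", path)
    return(emptyRecords())
  }
  ss <- Biostrings::readBStringSet(path)
  headers <- names(ss)
  id <- sub("\\s.*$", "", headers)
  if (anyDuplicated(id))
    stop("duplicate sequence ids: ",
         paste(unique(id[duplicated(id)]), collapse = ", "))
  description <- ifelse(grepl("\\s", headers),
                        sub("^\\S+\\s+", "", headers), "")
  residues <- as.character(ss)
  if (any(grepl("[a-z]", residues))) {
    warning("lowercase residues uppercased")
    residues <- toupper(residues)
  }
  sequenceRecords(id, residues, description = description,
                  obsolete = grepl("\\bOBSOLETE\\b", description),
                  source_db = source_db)
}

#' Write sequence records as FASTA
#'
#' Obsolete records get an `OBSOLETE` token appended to their header so
#' the flag round-trips through [readFastaRecords()].
#'
#' @param records A record `data.frame`.
#' @param path Output path.
#' @param width Line-wrapping width.
#' @return `path`, invisibly.
#' @export
writeFastaRecords <- function(records, path, width = 60L) {
  records <- assertRecords(records)
  desc <- records$description
  desc <- ifelse(records$obsolete & !grepl("\\bOBSOLETE\\b", desc),
                 trimws(paste(desc, "OBSOLETE")), desc)
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(records))) {
    hdr <- if (nzchar(desc[i])) paste(records$id[i], desc[i]) else records$id[i]
    writeLines(paste0(">", hdr), con)
    s <- records$residues[i]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read an aligned FASTA or Stockholm alignment
#'
#' @param path Alignment file; format detected from the first
#'   non-empty line (`# STOCKHOLM` vs `>`).
#' @return `data.frame` with columns `id`, `aligned` (equal widths).
#' @export
readAlignment <- function(path) {
  first <- readLines(path, n = 1L)
  aln <- if (grepl("^# STOCKHOLM", first)) {
    lines <- readLines(path)
    lines <- lines[!grepl("^(#|//|\\s*$)", lines)]
    parts <- strsplit(trimws(lines), "\\s+")
    ids <- vapply(parts, `[[`, character(1L), 1L)
    seqs <- vapply(parts, `[[`, character(1L), 2L)
    rows <- tapply(seqs, factor(ids, levels = unique(ids)),
                   paste, collapse = "")
    data.frame(id = names(rows), aligned = unname(unclass(rows)),
               stringsAsFactors = FALSE)
  } else {
    ss <- Biostrings::readBStringSet(path)
    data.frame(id = sub("\\s.*$", "", names(ss)),
               aligned = toupper(as.character(ss)),
               stringsAsFactors = FALSE)
  }
  aln$aligned <- gsub("\\.", "-", toupper(aln$aligned))
  if (length(unique(nchar(aln$aligned))) > 1L)
    stop("alignment rows have unequal widths")
  rownames(aln) <- NULL
  aln
}

#' Write an alignment as aligned FASTA
#' @param alignment `data.frame` with columns `id`, `aligned`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeAlignment <- function(alignment, path) {
  writeFastaRecords(
    data.frame(id = alignment$id, description = "",
               residues = alignment$aligned, obsolete = FALSE,
               source_db = "alignment", stringsAsFactors = FALSE),
    path, width = max(nchar(alignment$aligned[1]), 60L))
}

#' Curate a seed sequence set
#'
#' Removes obsolete records, records whose length falls outside
#' inclusive bounds, and records failing an optional positions predicate
#' (by default always true). Removal reasons are mutually exclusive and
#' applied in that order, so the per-reason counts plus the survivors
#' sum to the input count.
#'
#' @param records A record `data.frame`.
#' @param min_len,max_len Inclusive length bounds (a record survives iff
#'   `min_len <= nchar(residues) <= max_len`).
#' @param required_positions_check Optional predicate taking a residue
#'   string and returning `TRUE` to keep the record.
#' @return A list with `retained` (record `data.frame`) and `report`
#'   (named counts: `n_input`, `n_obsolete`, `n_length`,
#'   `n_predicate`, `n_retained`).
#' @export
#' @examples
#' cs <- generateCurationSet(50, 5, 3, c(250, 500), seed = 1)
#' curateSeedSet(cs$records, 250, 500)$report
curateSeedSet <- function(records, min_len, max_len,
                          required_positions_check = NULL) {
  stopifnot(min_len <= max_len)
  records <- assertRecords(records)
  n <- nrow(records)
  if (n == 0L) {
    warning("empty input set")
    return(list(retained = records,
                report = c(n_input = 0L, n_obsolete = 0L, n_length = 0L,
                           n_predicate = 0L, n_retained = 0L)))
  }
  obs <- records$obsolete
  len <- nchar(records$residues)
  lenbad <- !obs & (len < min_len | len > max_len)
  predbad <- rep(FALSE, n)
  if (!is.null(required_positions_check))
    predbad <- !obs & !lenbad &
      !vapply(records$residues, required_positions_check, logical(1L))
  keep <- !(obs | lenbad | predbad)
  retained <- records[keep, , drop = FALSE]
  rownames(retained) <- NULL
  if (!nrow(retained)) warning("curation removed all records")
  list(retained = retained,
       report = c(n_input = n, n_obsolete = sum(obs),
                  n_length = sum(lenbad), n_predicate = sum(predbad),
                  n_retained = sum(keep)))
}

AA3TO1 <- local({
  code <- Biostrings::AMINO_ACID_CODE[AA20]
  setNames(AA20, toupper(code))
})

#' Read a CA-only coordinate file (PDB subset)
#'
#' Parses fixed-width `ATOM` records, keeping one CA point per residue.
#' Residue numbering is preserved as written (1-based). Gaps in the
#' numbering are reported with a warning.
#'
#' @param path PDB-subset file.
#' @param chain Optional chain selector (single character).
#' @return `data.frame` with columns `resno`, `residue` (one-letter),
#'   `x`, `y`, `z`.
#' @export
readCaStructure <- function(path, chain = NULL) {
  lines <- readLines(path)
  idx <- grep("^ATOM ", lines)
  if (!length(idx)) stop("no ATOM records in ", path)
  out <- vector("list", length(idx))
  k <- 0L
  for (i in idx) {
    ln <- lines[i]
    atom <- trimws(substr(ln, 13, 16))
    if (atom != "CA") next
    ch <- substr(ln, 22, 22)
    if (!is.null(chain) && ch != chain) next
    xyz <- suppressWarnings(as.numeric(c(substr(ln, 31, 38),
                                         substr(ln, 39, 46),
                                         substr(ln, 47, 54))))
    resno <- suppressWarnings(as.integer(substr(ln, 23, 26)))
    if (anyNA(xyz) || is.na(resno))
      stop("malformed ATOM record at line ", i, " of ", path)
    res3 <- toupper(trimws(substr(ln, 18, 20)))
    res1 <- if (res3 %in% names(AA3TO1)) AA3TO1[[res3]] else "X"
    k <- k + 1L
    out[[k]] <- data.frame(resno = resno, residue = res1,
                           x = xyz[1], y = xyz[2], z = xyz[3],
                           stringsAsFactors = FALSE)
  }
  if (k == 0L) stop("no CA atoms", if (!is.null(chain))
    paste0(" in chain ", chain), " in ", path)
  st <- do.call(rbind, out[seq_len(k)])
  st <- st[order(st$resno), , drop = FALSE]
  rownames(st) <- NULL
  if (any(diff(st$resno) > 1L))
    warning("gaps in residue numbering (missing CA positions)")
  st
}

#' Write a CA-only coordinate table as a PDB subset
#' @param structure `data.frame` with `resno`, `residue`, `x`, `y`, `z`.
#' @param path Output path.
#' @param chain Chain identifier to write.
#' @return `path`, invisibly.
#' @export
writeCaStructure <- function(structure, path, chain = "A") {
  code3 <- setNames(names(AA3TO1), AA3TO1)
  res3 <- ifelse(structure$residue %in% names(code3),
                 code3[structure$residue], "UNK")
  lines <- sprintf(
    "ATOM  %5d  CA  %3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
    seq_len(nrow(structure)), res3, chain, structure$resno,
    structure$x, structure$y, structure$z)
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Write a generator truth table as TSV
#' @param truth Truth `data.frame` from a generator.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeTruthTable <- function(truth, path) writeTsv(truth, path)
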