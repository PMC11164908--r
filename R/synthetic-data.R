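## Seeded generators for every fixture the pipeline consumes: planted
## two-domain families, decoys, curation-flawed seed sets, gapped
## alignments, and toy CA-only scaffolds carrying pocket residues.

COFACTOR_CONSENSUS <- list(
  NAD  = c(R1 = "D", R2 = "V", R3 = "I", R4 = "G", R5 = "G", R6 = "Y"),
  NADP = c(R1 = "A", R2 = "R", R3 = "S", R4 = "G", R5 = "G", R6 = "K"),
  dual = c(R1 = "D", R2 = "H", R3 = "N", R4 = "G", R5 = "G", R6 = "R")
)

#' Specify a synthetic two-domain enzyme family
#'
#' Defines the generative model for one family: an N-terminal
#' Rossmann-like block, a linker, and a C-terminal catalytic block, each
#' emitted column-by-column from a consensus-plus-noise residue
#' distribution. Twenty-one named pocket positions (P1..P21) are planted
#' at distinct columns of the catalytic block and a contiguous
#' six-residue cofactor window (R1..R6) in the Rossmann block. Block
#' lengths and per-column consensus residues are drawn once per family
#' under `seed`, so all members of a family share one length and are
#' mutually aligned without indels.
#'
#' @param family_id Family label.
#' @param n_members Number of member sequences to emit.
#' @param length_range Total-length interval (inclusive) the family
#'   length is drawn from; must lie within \[50, 2000\].
#' @param block_fractions Approximate fractions of the total length given
#'   to the Rossmann block, linker, and catalytic block.
#' @param mutation_rate Per-residue probability of deviating from the
#'   column consensus.
#' @param cofactor_class Planted cofactor class: `"NAD"`, `"NADP"` or
#'   `"dual"`; fixes the consensus of the R1..R6 window.
#' @param pocket_consensus Optional named character vector (P1..P21) of
#'   pocket consensus residues; by default random with `P3 = "E"` (the
#'   catalytic glutamate).
#' @param seed Integer seed; identical specs with identical seeds yield
#'   byte-identical families.
#' @return A `familySpec` list with the resolved block lengths, planted
#'   columns, per-column distributions and consensus sequence.
#' @export
#' @examples
#' sp <- familySpec("fam1", n_members = 5, seed = 1)
#' sp$length
familySpec <- function(family_id, n_members,
                       length_range = c(250L, 500L),
                       block_fractions = c(rossmann = 0.45, linker = 0.05,
                                           catalytic = 0.5),
                       mutation_rate = 0.1,
                       cofactor_class = c("NAD", "NADP", "dual"),
                       pocket_consensus = NULL,
                       seed = 1L) {
  cofactor_class <- match.arg(cofactor_class)
  if (length(length_range) != 2L || length_range[1] > length_range[2])
    stop("length_range must be an increasing interval")
  if (length_range[1] < 50 || length_range[2] > 2000)
    stop("length_range must lie within [50, 2000]")
  if (mutation_rate < 0 || mutation_rate >= 1)
    stop("mutation_rate must be in [0, 1)")
  withSeed(seed, {
    total <- sample(seq(length_range[1], length_range[2]), 1L)
    n_ross <- max(20L, round(total * block_fractions[[1]]))
    n_link <- max(3L, round(total * block_fractions[[2]]))
    n_cat <- total - n_ross - n_link
    if (n_cat < 25L)
      stop("inconsistent block lengths vs length_range: catalytic block too short")
    consensus <- sample(AA20, total, replace = TRUE)
    ## plant the cofactor window: 6 contiguous Rossmann-block columns
    cof_start <- sample(seq_len(n_ross - 5L), 1L)
    cofactor_columns <- seq(cof_start, cof_start + 5L)
    names(cofactor_columns) <- paste0("R", 1:6)
    consensus[cofactor_columns] <- COFACTOR_CONSENSUS[[cofactor_class]]
    ## plant 21 distinct pocket columns in the catalytic block
    pocket_columns <- n_ross + n_link +
      sort(sample(seq_len(n_cat), 21L))
    names(pocket_columns) <- paste0("P", 1:21)
    if (is.null(pocket_consensus)) {
      pocket_consensus <- sample(AA20, 21L, replace = TRUE)
      names(pocket_consensus) <- paste0("P", 1:21)
      pocket_consensus[["P3"]] <- "E"
    }
    consensus[pocket_columns] <- pocket_consensus[names(pocket_columns)]
    structure(list(
      family_id = family_id,
      n_members = as.integer(n_members),
      length_range = as.integer(length_range),
      length = total,
      blocks = c(rossmann = n_ross, linker = n_link, catalytic = n_cat),
      consensus = consensus,
      pocket_columns = pocket_columns,
      cofactor_columns = cofactor_columns,
      cofactor_class = cofactor_class,
      mutation_rate = mutation_rate,
      seed = as.integer(seed)
    ), class = "familySpec")
  })
}

#' Generate a synthetic family with its truth table
#'
#' Emits `spec$n_members` sequences column-by-column from the family's
#' consensus-plus-noise distributions and records, for each sequence,
#' the residues actually emitted at the planted pocket and cofactor
#' columns.
#'
#' @param spec A [familySpec()].
#' @return A list with `records` (see [sequenceRecords()]) and `truth`
#'   (`data.frame`: `id`, `family`, `decoy`, `obsolete`,
#'   `pocket_residues`, `cofactor_window`, `cofactor_class`).
#' @export
#' @examples
#' fam <- generateFamily(familySpec("fam1", 3, seed = 7))
#' fam$truth$pocket_residues
generateFamily <- function(spec) {
  stopifnot(inherits(spec, "familySpec"))
  n <- spec$n_members
  if (n == 0L)
    return(list(records = emptyRecords(), truth = emptyTruth()))
  withSeed(spec$seed + 1L, {
    total <- spec$length
    seqs <- character(n)
    mu <- spec$mutation_rate
    for (i in seq_len(n)) {
      res <- spec$consensus
      if (mu > 0) {
        flip <- runif(total) < mu
        if (any(flip))
          res[flip] <- vapply(res[flip], function(cur)
            sample(setdiff(AA20, cur), 1L), character(1L))
      }
      seqs[i] <- paste(res, collapse = "")
    }
    ids <- sprintf("%s_m%03d", spec$family_id, seq_len(n))
    records <- sequenceRecords(ids, seqs, description = spec$family_id)
    chars <- splitResidues(seqs)
    truth <- data.frame(
      id = ids,
      family = spec$family_id,
      decoy = FALSE,
      obsolete = FALSE,
      pocket_residues = vapply(chars, function(r)
        paste(r[spec$pocket_columns], collapse = ""), character(1L)),
      cofactor_window = vapply(chars, function(r)
        paste(r[spec$cofactor_columns], collapse = ""), character(1L)),
      cofactor_class = spec$cofactor_class,
      stringsAsFactors = FALSE
    )
    list(records = records, truth = truth)
  })
}

emptyTruth <- function() {
  data.frame(id = character(), family = character(), decoy = logical(),
             obsolete = logical(), pocket_residues = character(),
             cofactor_window = character(), cofactor_class = character(),
             stringsAsFactors = FALSE)
}

#' Generate decoy sequences
#'
#' Decoys are i.i.d. draws from a background residue distribution
#' (uniform by default); a small fraction of positions may be the
#' unknown residue `X`.
#'
#' @param n Number of decoys.
#' @param length_range Length interval the decoy lengths are drawn from.
#' @param background Residue distribution over the 20 canonical amino
#'   acids.
#' @param x_rate Per-position probability of emitting `X`.
#' @param seed Integer seed.
#' @return A list with `records` and `truth` (decoy-flagged).
#' @export
generateDecoys <- function(n, length_range = c(250L, 500L),
                           background = rep(1 / 20, 20), x_rate = 0,
                           seed = 1L) {
  if (n == 0L)
    return(list(records = emptyRecords(), truth = emptyTruth()))
  withSeed(seed, {
    lens <- sample(seq(length_range[1], length_range[2]), n, replace = TRUE)
    seqs <- vapply(lens, function(L) {
      r <- sample(AA20, L, replace = TRUE, prob = background)
      if (x_rate > 0) r[runif(L) < x_rate] <- "X"
      paste(r, collapse = "")
    }, character(1L))
    ids <- sprintf("decoy_%04d", seq_len(n))
    records <- sequenceRecords(ids, seqs, description = "decoy")
    truth <- data.frame(id = ids, family = NA_character_, decoy = TRUE,
                        obsolete = FALSE, pocket_residues = NA_character_,
                        cofactor_window = NA_character_,
                        cofactor_class = NA_character_,
                        stringsAsFactors = FALSE)
    list(records = records, truth = truth)
  })
}

#' Generate a seed set with planted curation flaws
#'
#' Emulates a seed collection in which some entries are flagged obsolete
#' and some (disjoint from the obsolete ones) violate the length bounds;
#' the remainder are clean. Running [curateSeedSet()] on the output with
#' the same bounds retains exactly
#' `n_total - n_obsolete - n_length_violating` records.
#'
#' @param n_total Total number of records.
#' @param n_obsolete Number flagged obsolete (lengths within bounds).
#' @param n_length_violating Number of non-obsolete records with length
#'   outside `length_range` (half below, half above).
#' @param length_range Inclusive length bounds of the clean records.
#' @param seed Integer seed.
#' @return A list with `records` and `truth`.
#' @export
#' @examples
#' cs <- generateCurationSet(20, 3, 2, c(250, 500), seed = 1)
#' sum(cs$records$obsolete)
generateCurationSet <- function(n_total, n_obsolete, n_length_violating,
                                length_range = c(250L, 500L), seed = 1L) {
  if (n_obsolete + n_length_violating > n_total)
    stop("flawed subsets exceed n_total (overlap requested)")
  withSeed(seed, {
    n_clean <- n_total - n_obsolete - n_length_violating
    lo <- length_range[1]; hi <- length_range[2]
    inLens <- function(k) sample(seq(lo, hi), k, replace = TRUE)
    n_short <- n_length_violating %/% 2L
    n_long <- n_length_violating - n_short
    lens <- c(inLens(n_clean + n_obsolete),
              sample(seq(50L, lo - 1L), n_short, replace = TRUE),
              sample(seq(hi + 1L, hi + 200L), n_long, replace = TRUE))
    obsolete <- c(rep(FALSE, n_clean), rep(TRUE, n_obsolete),
                  rep(FALSE, n_length_violating))
    seqs <- vapply(lens, function(L)
      paste(sample(AA20, L, replace = TRUE), collapse = ""), character(1L))
    ids <- sprintf("seed_%05d", seq_len(n_total))
    records <- sequenceRecords(ids, seqs, obsolete = obsolete)
    truth <- data.frame(id = ids, family = NA_character_, decoy = FALSE,
                        obsolete = obsolete,
                        pocket_residues = NA_character_,
                        cofactor_window = NA_character_,
                        cofactor_class = NA_character_,
                        stringsAsFactors = FALSE)
    truth$length_violating <- c(rep(FALSE, n_clean + n_obsolete),
                                rep(TRUE, n_length_violating))
    list(records = records, truth = truth)
  })
}

#' Generate toy CA-only structures carrying pocket fingerprints
#'
#' Every structure shares one ideal helix-like CA template; the 21
#' pocket sites of `definition` hold the fingerprint's residues. Each
#' structure is then moved by a random rigid transform (recorded in the
#' truth) and perturbed with isotropic Gaussian coordinate noise.
#'
#' @param fingerprints `data.frame` with columns `sequence_id` and
#'   `residues` (21-character strings), as produced by [extractPocket()]
#'   or taken from a generator truth table.
#' @param definition A [PocketDefinition-class]; its residue numbers
#'   place the fingerprints on the scaffold.
#' @param noise_sd Coordinate noise standard deviation, in angstroms
#'   (>= 0).
#' @param n_res Scaffold length in residues.
#' @param identity_transform If `TRUE`, skip the random rigid move
#'   (useful for exactness checks).
#' @param seed Integer seed.
#' @return A list with `structures` (named list of CA tables: `resno`,
#'   `residue`, `x`, `y`, `z`), `template` (the unmoved scaffold
#'   geometry), and `truth` (per structure: rotation matrix and
#'   translation applied).
#' @export
generateStructures <- function(fingerprints, definition = defaultPocketDefinition(),
                               noise_sd = 0, n_res = 160L,
                               identity_transform = FALSE, seed = 1L) {
  stopifnot(noise_sd >= 0)
  pos <- definition@positions
  if (max(pos) > n_res) stop("scaffold too short for pocket definition")
  template <- scaffoldTrace(n_res)
  withSeed(seed, {
    structures <- list()
    truth <- list()
    base_res <- rep_len(AA20, n_res)
    for (i in seq_len(nrow(fingerprints))) {
      id <- fingerprints$sequence_id[i]
      fp <- splitResidues(fingerprints$residues[i])[[1L]]
      if (length(fp) != length(pos))
        stop("fingerprint length must match pocket definition")
      res <- base_res
      keep <- fp != "-"
      res[pos[keep]] <- fp[keep]
      xyz <- template
      if (!identity_transform) {
        R <- randomRotation()
        tvec <- runif(3, -20, 20)
      } else {
        R <- diag(3)
        tvec <- c(0, 0, 0)
      }
      xyz <- xyz %*% t(R) + matrix(tvec, n_res, 3, byrow = TRUE)
      if (noise_sd > 0)
        xyz <- xyz + matrix(rnorm(3L * n_res, sd = noise_sd), n_res, 3)
      structures[[id]] <- data.frame(resno = seq_len(n_res), residue = res,
                                     x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                                     stringsAsFactors = FALSE)
      truth[[id]] <- list(rotation = R, translation = tvec)
    }
    list(structures = structures,
         template = data.frame(resno = seq_len(n_res),
                               residue = base_res,
                               x = template[, 1], y = template[, 2],
                               z = template[, 3], stringsAsFactors = FALSE),
         truth = truth)
  })
}

## Ideal CA trace: a gently curved helix-like curve with ~3.8 A spacing.
scaffoldTrace <- function(n_res) {
  i <- seq_len(n_res)
  cbind(x = 2.3 * cos(i * 100 * pi / 180) + 0.05 * i,
        y = 2.3 * sin(i * 100 * pi / 180),
        z = 1.5 * i)
}

#' Generate an alignment with gapped rows planted in a window
#'
#' Builds an ungapped random alignment and inserts at least one gap
#' character inside `window` for exactly `n_gapped_in_window` rows; all
#' other rows are gap-free within the window.
#'
#' @param n_rows Number of alignment rows.
#' @param n_gapped_in_window Number of rows to receive in-window gaps.
#' @param window Integer length-2 column interval (inclusive).
#' @param width Alignment width in columns.
#' @param seed Integer seed.
#' @return A list with `alignment` (`data.frame`: `id`, `aligned`) and
#'   `truth` (`data.frame`: `id`, `gapped_in_window`).
#' @export
generateGappedAlignment <- function(n_rows, n_gapped_in_window, window,
                                    width = 60L, seed = 1L) {
  if (n_gapped_in_window > n_rows)
    stop("n_gapped_in_window exceeds n_rows")
  if (window[1] < 1L || window[2] > width || window[1] > window[2])
    stop("window outside alignment width")
  withSeed(seed, {
    mat <- matrix(sample(AA20, n_rows * width, replace = TRUE),
                  n_rows, width)
    gapped <- seq_len(n_gapped_in_window)
    wcols <- seq(window[1], window[2])
    for (r in gapped) {
      k <- sample(1:2, 1L)
      mat[r, sample(wcols, min(k, length(wcols)))] <- "-"
    }
    ids <- sprintf("row_%05d", seq_len(n_rows))
    aln <- data.frame(id = ids,
                      aligned = apply(mat, 1L, paste, collapse = ""),
                      stringsAsFactors = FALSE)
    truth <- data.frame(id = ids,
                        gapped_in_window = seq_len(n_rows) %in% gapped,
                        stringsAsFactors = FALSE)
    list(alignment = aln, truth = truth)
  })
}
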