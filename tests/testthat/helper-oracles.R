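## Independent oracles used to validate the package's algorithms on
## small instances. These deliberately share no code with the
## implementations they check.

## Brute-force local profile-HMM score by exhaustive path enumeration.
## Enumerates every (entry node, placement, state path, exit node)
## combination; paths are anchored on match states, inter-node moves go
## through M/I/D, the no-match path has odds 1, and each path carries
## the uniform fragment entry weight 2/(L(L+1)).
bruteForceScore <- function(profile, seq, mode = c("forward", "viterbi")) {
  mode <- match.arg(mode)
  aa <- pocketfam::aminoAcidAlphabet()
  x <- strsplit(toupper(seq), "")[[1]]
  xi <- match(x, aa)  # NA -> unknown, odds 1
  n <- length(xi)
  L <- profile@L
  me <- profile@matchEmissions
  ie <- profile@insertEmissions
  bg <- profile@background
  tr <- profile@transitions
  entry <- 2 / (L * (L + 1))
  modds <- function(k, i) if (is.na(xi[i])) 1 else me[k, xi[i]] / bg[xi[i]]
  iodds <- function(k, i) if (is.na(xi[i])) 1 else ie[k, xi[i]] / bg[xi[i]]
  total <- 1   # no-match path
  best <- 1
  recurse <- function(state, k, i, odds) {
    if (state == "M") {
      ## may exit here
      total <<- total + odds
      best <<- max(best, odds)
      if (k < L) {
        if (i < n)
          recurse("M", k + 1, i + 1, odds * tr[k, "MM"] * modds(k + 1, i + 1))
        if (i < n && k < L)
          recurse("I", k, i + 1, odds * tr[k, "MI"] * iodds(k, i + 1))
        recurse("D", k + 1, i, odds * tr[k, "MD"])
      }
    } else if (state == "I") {
      if (i < n)
        recurse("M", k + 1, i + 1, odds * tr[k, "IM"] * modds(k + 1, i + 1))
      if (i < n)
        recurse("I", k, i + 1, odds * tr[k, "II"] * iodds(k, i + 1))
    } else {  # D_k; no exit from deletes
      if (k < L) {
        if (i < n)
          recurse("M", k + 1, i + 1, odds * tr[k, "DM"] * modds(k + 1, i + 1))
        recurse("D", k + 1, i, odds * tr[k, "DD"])
      }
    }
  }
  if (n > 0)
    for (k0 in seq_len(L)) for (i0 in seq_len(n))
      recurse("M", k0, i0, entry * modds(k0, i0))
  log2(unname(if (mode == "forward") total else best))
}

## Independently coded greedy set-cover clustering over a precomputed
## qualification matrix (same tie rules: most neighbours, longer
## sequence, lexicographic id).
greedyCoverOracle <- function(records, min_identity, min_coverage) {
  n <- nrow(records)
  q <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) { q[i, j] <- TRUE; next }
    v <- pocketfam::pairwiseIdentity(records$residues[i],
                                     records$residues[j])
    q[i, j] <- v[["identity"]] >= min_identity &&
      v[["coverage"]] >= min_coverage
  }
  left <- rep(TRUE, n)
  out <- list()
  while (any(left)) {
    score <- sapply(seq_len(n), function(i)
      if (left[i]) sum(q[i, ] & left) else -1)
    best <- which(score == max(score))
    if (length(best) > 1) {
      lens <- nchar(records$residues[best])
      best <- best[lens == max(lens)]
      best <- best[order(records$id[best])]
    }
    r <- best[1]
    mem <- which(q[r, ] & left)
    left[mem] <- FALSE
    out[[length(out) + 1]] <- data.frame(representative = records$id[r],
                                         member = records$id[mem])
  }
  do.call(rbind, out)
}

## Truth-table oracle for the cofactor rules, written as one flat
## conditional per class over explicit residue sets.
cofactorOracle <- function(r1, r2, r3, r6) {
  neg <- c("D", "E"); pos <- c("H", "K", "R"); pol <- c("S", "N")
  sht <- c("A", "S"); ab <- c("V", "I", "R", "Y", "F")
  if (r1 %in% neg && r2 %in% pos && r6 %in% pos && r3 %in% pol) "dual"
  else if (r1 %in% neg && r2 %in% ab && r3 %in% ab && r6 %in% ab) "NAD"
  else if (r1 %in% sht && r2 %in% pos && r6 %in% pos && r3 %in% pol) "NADP"
  else "unknown"
}

## Independently coded greedy maximin selection mirroring the documented
## algorithm (quota-deficit groups first; ties by id).
maximinOracle <- function(D, eligible_ids, groups, n, per_group) {
  tot <- rowSums(D[eligible_ids, eligible_ids, drop = FALSE])
  seed <- eligible_ids[order(-tot, eligible_ids)][1]
  sel <- seed
  quota_groups <- unique(na.omit(groups[eligible_ids]))
  while (length(sel) < n && length(sel) < length(eligible_ids)) {
    remaining <- setdiff(eligible_ids, sel)
    deficit <- quota_groups[sapply(quota_groups, function(g)
      sum(!is.na(groups[sel]) & groups[sel] == g) < per_group)]
    pool <- remaining[!is.na(groups[remaining]) &
                        groups[remaining] %in% deficit]
    if (!length(pool)) pool <- remaining
    mind <- sapply(pool, function(c) min(D[c, sel]))
    sel <- c(sel, pool[order(-mind, pool)][1])
  }
  sort(sel)
}

## Random residue string helper.
randomSeq <- function(len) paste(sample(pocketfam::aminoAcidAlphabet(),
                                        len, replace = TRUE),
                                 collapse = "")
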