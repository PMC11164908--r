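## Helper: build a FamilyNetwork directly from an edge list (prob 0.96,
## coverage 0.8 satisfy the default thresholds).
makeNetwork <- function(nodes, pairs, probability = 0.96, coverage = 0.8) {
  edges <- if (nrow(pairs)) {
    a <- pmin(pairs[, 1], pairs[, 2]); b <- pmax(pairs[, 1], pairs[, 2])
    data.frame(family_a = a, family_b = b, probability = probability,
               coverage = coverage, weight = probability * coverage,
               stringsAsFactors = FALSE)
  } else data.frame(family_a = character(), family_b = character(),
                    probability = numeric(), coverage = numeric(),
                    weight = numeric(), stringsAsFactors = FALSE)
  new("FamilyNetwork", nodes = nodes, edges = edges,
      thresholds = c(probability = 0.95, coverage = 0.75))
}

## Helper: mutate a parent sequence at a given number of positions.
mutateSeq <- function(parent, k) {
  r <- strsplit(parent, "")[[1]]
  pos <- sample(length(r), k)
  for (p in pos) r[p] <- sample(setdiff(aminoAcidAlphabet(), r[p]), 1)
  paste(r, collapse = "")
}

test_that("pairwise identity and coverage match hand calculations", {
  v <- pairwiseIdentity("ACDEFG", "ACDQFG")
  expect_equal(unname(v["identity"]), 5 / 6)
  expect_equal(unname(v["coverage"]), 1)
  ## identical sequences
  v2 <- pairwiseIdentity("MKLVNP", "MKLVNP")
  expect_equal(unname(v2["identity"]), 1)
  expect_equal(unname(v2["coverage"]), 1)
  ## exact prefix: terminal gaps excluded from the identity region,
  ## coverage normalised by the shorter length
  v3 <- pairwiseIdentity("ACDEFGHI", "ACDE")
  expect_equal(unname(v3["identity"]), 1)
  expect_equal(unname(v3["coverage"]), 1)
  ## symmetry
  v4 <- pairwiseIdentity("ACDQFG", "ACDEFG")
  expect_equal(unname(v4["identity"]), unname(v["identity"]))
})

test_that("greedy set-cover clustering matches the oracle on small sets", {
  set.seed(101)
  for (rep in 1:6) {
    n <- sample(3:8, 1)
    parent <- randomSeq(60)
    recs <- sequenceRecords(
      sprintf("q%02d", seq_len(n)),
      vapply(seq_len(n), function(i)
        mutateSeq(parent, sample(c(2, 4, 30), 1)), character(1)))
    got <- greedySetCoverCluster(recs, 0.8, 0.8)
    want <- greedyCoverOracle(recs, 0.8, 0.8)
    got <- got[order(got$member), c("representative", "member")]
    want <- want[order(want$member), c("representative", "member")]
    expect_equal(got$member, want$member)
    expect_equal(got$representative, want$representative)
    ## output is a partition of the input
    expect_setequal(got$member, recs$id)
    expect_equal(anyDuplicated(got$member), 0L)
    ## every member meets the thresholds against its representative
    for (r in seq_len(nrow(got))) {
      if (got$representative[r] == got$member[r]) next
      v <- pairwiseIdentity(
        recs$residues[match(got$representative[r], recs$id)],
        recs$residues[match(got$member[r], recs$id)])
      expect_gte(v[["identity"]], 0.8)
      expect_gte(v[["coverage"]], 0.8)
    }
  }
})

test_that("redundancy removal: duplicates, idempotence, hash oracle", {
  r <- sequenceRecords(c("a", "b", "c"), c("ACDE", "ACDE", "MKLV"))
  nr <- removeRedundancy(r)
  expect_equal(nr$id, c("a", "c"))
  expect_equal(removeRedundancy(nr), nr)
  ## larger set: exact dedup equals an independent hash-set oracle
  set.seed(55)
  pool <- replicate(40, randomSeq(30))
  recs <- sequenceRecords(sprintf("s%04d", 1:1000),
                          sample(pool, 1000, replace = TRUE))
  nr2 <- removeRedundancy(recs, identity = 1.0)
  seen <- new.env(parent = emptyenv())
  keep <- logical(1000)
  for (i in 1:1000) {
    h <- recs$residues[i]
    if (!exists(h, envir = seen)) { assign(h, TRUE, envir = seen); keep[i] <- TRUE }
  }
  expect_identical(nr2$id, recs$id[keep])
  expect_equal(anyDuplicated(nr2$residues), 0L)
})

test_that("profile-profile comparison: self, unrelated, symmetric", {
  sp1 <- familySpec("famX", 8, length_range = c(250, 300), seed = 31)
  sp2 <- familySpec("famY", 8, length_range = c(250, 300), seed = 32)
  f1 <- generateFamily(sp1); f2 <- generateFamily(sp2)
  mk <- function(f, nm) buildProfile(
    data.frame(id = f$records$id, aligned = f$records$residues), name = nm)
  p1 <- mk(f1, "famX"); p2 <- mk(f2, "famY")
  self <- profileProfileCompare(p1, p1)
  expect_gte(self$probability, 0.99)
  expect_equal(self$coverage, 1)
  unrel <- profileProfileCompare(p1, p2)
  expect_lt(unrel$probability, 0.5)
  ## symmetry of probability/coverage/weight under argument swap
  sw <- profileProfileCompare(p2, p1)
  expect_equal(sw$probability, unrel$probability, tolerance = 1e-6)
  expect_equal(sw$coverage, unrel$coverage, tolerance = 1e-6)
  expect_equal(sw$family_a, unrel$family_a)
  expect_equal(unrel$weight, unrel$probability * unrel$coverage)
})

test_that("family network admits only above-threshold edges", {
  sp1 <- familySpec("famX", 6, length_range = c(250, 280), seed = 41)
  f1 <- generateFamily(sp1)
  ## two half-families of the same family -> related profiles
  mk <- function(rows, nm) buildProfile(
    data.frame(id = f1$records$id[rows],
               aligned = f1$records$residues[rows]), name = nm)
  pa <- mk(1:3, "half_a"); pb <- mk(4:6, "half_b")
  sp2 <- familySpec("famZ", 6, length_range = c(250, 280), seed = 42)
  f2 <- generateFamily(sp2)
  pc <- buildProfile(data.frame(id = f2$records$id,
                                aligned = f2$records$residues), name = "other")
  net <- buildFamilyNetwork(list(pa, pb, pc))
  expect_setequal(net@nodes, c("half_a", "half_b", "other"))
  expect_true(any(net@edges$family_a == "half_a" &
                    net@edges$family_b == "half_b"))
  expect_false(any(net@edges$family_a == "other" |
                     net@edges$family_b == "other"))
  expect_error(buildFamilyNetwork(list(pa, pa)), "distinct")
})

test_that("MCL separates two cliques joined by no edge", {
  nodes <- c(paste0("a", 1:4), paste0("b", 1:4))
  cl4 <- t(combn(1:4, 2))
  pairs <- rbind(
    cbind(nodes[cl4[, 1]], nodes[cl4[, 2]]),
    cbind(nodes[cl4[, 1] + 4], nodes[cl4[, 2] + 4]))
  res <- mclCluster(makeNetwork(nodes, pairs))
  expect_true(res$converged)
  cl <- res$clusters
  expect_equal(length(unique(cl$cluster)), 2L)
  expect_equal(length(unique(cl$cluster[grepl("^a", cl$family)])), 1L)
  expect_equal(length(unique(cl$cluster[grepl("^b", cl$family)])), 1L)
  expect_false(cl$cluster[cl$family == "a1"] == cl$cluster[cl$family == "b1"])
})

test_that("MCL refines the graph's connected components", {
  skip_if_not_installed("igraph")
  set.seed(77)
  for (rep in 1:5) {
    n <- sample(5:12, 1)
    nodes <- sprintf("n%02d", seq_len(n))
    all_pairs <- t(combn(seq_len(n), 2))
    m <- all_pairs[stats::runif(nrow(all_pairs)) < 0.25, , drop = FALSE]
    pairs <- cbind(nodes[m[, 1]], nodes[m[, 2]])
    res <- mclCluster(makeNetwork(nodes, pairs))
    g <- igraph::graph_from_data_frame(
      as.data.frame(pairs, stringsAsFactors = FALSE),
      directed = FALSE, vertices = nodes)
    comp <- igraph::components(g)$membership[res$clusters$family]
    ## every MCL cluster lies inside a single component
    split_comp <- split(unname(comp), res$clusters$cluster)
    expect_true(all(vapply(split_comp,
                           function(x) length(unique(x)) == 1L, logical(1))))
    ## isolated nodes are singleton clusters
    iso <- nodes[!(nodes %in% c(pairs))]
    if (length(iso)) {
      iso_cl <- res$clusters$cluster[res$clusters$family %in% iso]
      expect_false(any(iso_cl %in%
                         res$clusters$cluster[!(res$clusters$family %in% iso)]))
    }
  }
})

test_that("singleton screen flags hits with no known-family neighbour", {
  set.seed(91)
  parent <- randomSeq(80)
  known <- sequenceRecords(c("k1", "k2"),
                           c(mutateSeq(parent, 2), mutateSeq(parent, 3)))
  hits <- sequenceRecords(c("h_near", "h_far"),
                          c(mutateSeq(parent, 2), randomSeq(80)))
  s <- findSingletons(hits, known)
  expect_equal(s, "h_far")
  expect_error(findSingletons(known, known), "disjoint")
})

test_that("clustering is monotone in the identity threshold", {
  set.seed(13)
  parent <- randomSeq(60)
  recs <- sequenceRecords(sprintf("m%02d", 1:8),
                          replicate(8, mutateSeq(parent, sample(1:12, 1))))
  ## members are <= 12 substitutions from a common parent, so every
  ## pair is above 50% identity: the loose run collapses to one cluster
  loose <- greedySetCoverCluster(recs, 0.5, 0.5)
  tight <- greedySetCoverCluster(recs, 0.99, 0.99)
  expect_equal(length(unique(loose$representative)), 1L)
  expect_gte(length(unique(tight$representative)), 1L)
  expect_lte(length(unique(loose$representative)),
             length(unique(tight$representative)))
})
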