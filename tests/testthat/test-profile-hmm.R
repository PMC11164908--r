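test_that("profile construction: match states, limits, transitions", {
  ## single ungapped sequence of length 10
  s <- randomSeq(10)
  p <- buildProfile(data.frame(id = "a", aligned = s))
  expect_equal(p@L, 10L)
  expect_equal(p@map, 1:10)
  ## two identical rows with vanishing pseudocounts -> point masses
  aln <- data.frame(id = c("a", "b"), aligned = c("ACD", "ACD"))
  p0 <- buildProfile(aln, pseudocount_weight = 1e-12)
  expect_equal(unname(p0@matchEmissions[1, "A"]), 1, tolerance = 1e-9)
  expect_equal(unname(p0@matchEmissions[2, "C"]), 1, tolerance = 1e-9)
  expect_equal(unname(p0@matchEmissions[3, "D"]), 1, tolerance = 1e-9)
  ## hand-computed +1-smoothed transitions for a gapped toy alignment:
  ## rows ACD / A-D / ACD at junction 1->2: two M->M, one M->D, so
  ## MM = (2+1)/(3+3), MD = (1+1)/6, MI = 1/6; junction 2->3 has two
  ## M->M (gapped row contributes D->M): MM = 3/5, DM = 2/3.
  aln2 <- data.frame(id = c("a", "b", "c"),
                     aligned = c("ACD", "A-D", "ACD"))
  p2 <- buildProfile(aln2)
  expect_equal(unname(p2@transitions[1, "MM"]), 3 / 6)
  expect_equal(unname(p2@transitions[1, "MD"]), 2 / 6)
  expect_equal(unname(p2@transitions[1, "MI"]), 1 / 6)
  expect_equal(unname(p2@transitions[2, "MM"]), 3 / 5)
  expect_equal(unname(p2@transitions[2, "DM"]), 2 / 3)
  expect_true(validObject(p2))
  ## insert events: rows where the middle column is an insert column
  ## (gap fraction >= 0.5 drops it from match states)
  aln3 <- data.frame(id = c("a", "b"), aligned = c("AKD", "A-D"))
  p3 <- buildProfile(aln3)
  expect_equal(p3@L, 2L)
  expect_equal(p3@map, c(1L, 3L))
  ## junction events: one M->I->M (row a), one M->M (row b)
  expect_equal(unname(p3@transitions[1, "MI"]), 2 / 5)
  expect_equal(unname(p3@transitions[1, "MM"]), 2 / 5)
  expect_equal(unname(p3@transitions[1, "IM"]), 2 / 3)
})

test_that("degenerate alignments are rejected or repaired", {
  expect_error(buildProfile(data.frame(id = character(),
                                       aligned = character())), "empty")
  expect_warning(
    p <- buildProfile(data.frame(id = c("a", "b"),
                                 aligned = c("A-C", "A-C"))),
    "all-gap")
  expect_equal(p@L, 2L)
})

test_that("forward and viterbi equal exhaustive path enumeration", {
  set.seed(42)
  for (rep in 1:10) {
    L <- sample(1:3, 1)
    nr <- sample(2:4, 1)
    aln <- data.frame(id = paste0("r", seq_len(nr)),
                      aligned = replicate(nr, randomSeq(L)))
    ## sprinkle a gap sometimes to vary transitions
    if (L > 1 && rep %% 2 == 0)
      substr(aln$aligned[1], 1, 1) <- "-"
    p <- buildProfile(aln)
    for (len in 0:5) {
      s <- randomSeq(len)
      f <- forwardScore(p, s)
      v <- viterbiScore(p, s)$bits
      expect_equal(2^f, 2^bruteForceScore(p, s, "forward"),
                   tolerance = 1e-9)
      expect_equal(2^v, 2^bruteForceScore(p, s, "viterbi"),
                   tolerance = 1e-9)
      expect_lte(v, f + 1e-12)
    }
  }
})

test_that("viterbi returns a valid contiguous state path", {
  aln <- data.frame(id = c("a", "b"), aligned = c("ACDEF", "ACDEF"))
  p <- buildProfile(aln)
  v <- viterbiScore(p, "ACDEF")
  expect_equal(v$path, paste0("M", 1:5))
  ## empty sequence takes the no-match path
  v0 <- viterbiScore(p, "")
  expect_equal(v0$bits, 0)
  expect_equal(length(v0$path), 0L)
})

test_that("a profile's consensus outranks random sequences", {
  sp <- familySpec("fam", 8, length_range = c(250, 300), seed = 21)
  fam <- generateFamily(sp)
  p <- buildProfile(data.frame(id = fam$records$id,
                               aligned = fam$records$residues))
  cons <- paste(sp$consensus, collapse = "")
  sc <- forwardScore(p, cons)
  set.seed(33)
  rnd <- replicate(100, forwardScore(p, randomSeq(nchar(cons))))
  expect_true(all(sc > rnd))
})

test_that("search applies the threshold, sorts, and is db-order invariant", {
  sp <- familySpec("fam", 6, length_range = c(250, 300), seed = 5)
  fam <- generateFamily(sp)
  dec <- generateDecoys(6, length_range = c(250, 300), seed = 6)
  db <- rbind(fam$records, dec$records)
  p <- buildProfile(data.frame(id = fam$records$id,
                               aligned = fam$records$residues))
  hits <- searchProfile(p, db, 50)
  expect_equal(nrow(hits), nrow(db))
  expect_identical(hits$passed, hits$bit_score >= 50)
  expect_true(all(diff(hits$bit_score) <= 0))
  ## shuffling the db (and renaming a record) leaves scores unchanged
  db2 <- db[rev(seq_len(nrow(db))), ]
  db2$description <- "renamed"
  hits2 <- searchProfile(p, db2, 50)
  expect_equal(hits2[order(hits2$sequence_id), "bit_score"],
               hits[order(hits$sequence_id), "bit_score"])
  expect_equal(nrow(searchProfile(p, sequenceRecords(character(),
                                                     character()), 50)), 0L)
})

test_that("anchor split partitions the parent profile's columns", {
  sp <- familySpec("fam", 5, length_range = c(250, 300),
                   mutation_rate = 0.05, seed = 8)
  fam <- generateFamily(sp)
  aln <- data.frame(id = fam$records$id, aligned = fam$records$residues)
  anchor <- 145L
  ds <- splitProfile(aln, aln$id[1], anchor)
  parent <- buildProfile(aln)
  ## anchor column goes to the N-side block
  expect_equal(max(ds@nProfile@map), 145L)
  expect_equal(c(ds@nProfile@map, ds@cProfile@map), parent@map)
  expect_equal(ds@nProfile@L + ds@cProfile@L, parent@L)
  expect_error(splitProfile(aln, aln$id[1], nchar(aln$aligned[1])),
               "anchor")
  expect_error(splitProfile(aln, "missing", 10), "reference")
})

test_that("two-domain confirmation is the intersection of passed sets", {
  h1 <- data.frame(sequence_id = c("a", "b", "c"),
                   bit_score = c(80, 60, 10),
                   passed = c(TRUE, TRUE, FALSE), profile = "cat")
  h2 <- data.frame(sequence_id = c("a", "b", "c"),
                   bit_score = c(70, 20, 90),
                   passed = c(TRUE, FALSE, TRUE), profile = "bind")
  conf <- confirmTwoDomain(h1, h2)
  expect_equal(conf, "a")
  expect_true(all(conf %in% intersect(h1$sequence_id[h1$passed],
                                      h2$sequence_id[h2$passed])))
})

test_that("profile serialization round-trips bit-exactly", {
  sp <- familySpec("fam", 4, length_range = c(250, 280), seed = 13)
  fam <- generateFamily(sp)
  p <- buildProfile(data.frame(id = fam$records$id,
                               aligned = fam$records$residues),
                    name = "roundtrip")
  f <- tempfile(fileext = ".hmm")
  writeProfile(p, f)
  q <- readProfile(f)
  expect_true(all(q@matchEmissions == p@matchEmissions))
  expect_true(all(q@transitions == p@transitions))
  expect_identical(q@map, p@map)
  expect_identical(q@name, p@name)
  s <- randomSeq(40)
  expect_identical(forwardScore(p, s), forwardScore(q, s))
})

test_that("ROC threshold selection separates a labeled set", {
  scores <- c(90, 85, 80, 70, 12, 8, 5, 3)
  labels <- c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE)
  thr <- selectThreshold(scores, labels)
  expect_gt(thr, 12)
  expect_lt(thr, 70)
})
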