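## Proper rotation from Euler angles (test-local helper).
eulerRotation <- function(a, b, c) {
  rz <- function(t) matrix(c(cos(t), sin(t), 0, -sin(t), cos(t), 0,
                             0, 0, 1), 3, 3)
  ry <- function(t) matrix(c(cos(t), 0, -sin(t), 0, 1, 0,
                             sin(t), 0, cos(t)), 3, 3)
  rz(a) %*% ry(b) %*% rz(c)
}

test_that("Kabsch superposition: self, rigid copies, analytic case", {
  set.seed(3)
  pts <- matrix(rnorm(45), 15, 3)
  self <- kabschSuperpose(pts, pts)
  expect_equal(self$rmsd, 0, tolerance = 1e-12)
  expect_equal(self$rotation, diag(3), tolerance = 1e-9)
  ## rigid copy: rmsd < 1e-6 and the fit inverts the applied transform
  R <- eulerRotation(0.4, -1.1, 2.2)
  tv <- c(4, -7, 2)
  moved <- pts %*% t(R) + matrix(tv, 15, 3, byrow = TRUE)
  fit <- kabschSuperpose(moved, pts)
  expect_lt(fit$rmsd, 1e-6)
  expect_equal(fit$rotation, t(R), tolerance = 1e-9)
  back <- moved %*% t(fit$rotation) + matrix(fit$translation, 15, 3,
                                             byrow = TRUE)
  expect_equal(back, pts, tolerance = 1e-9)
  ## analytic value: unit octahedron vs doubled octahedron, optimal
  ## rotation is the identity and RMSD = mean displacement = 1
  oct <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
               c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  fit2 <- kabschSuperpose(oct, 2 * oct)
  expect_equal(fit2$rmsd, 1, tolerance = 1e-12)
  expect_equal(fit2$rotation, diag(3), tolerance = 1e-9)
  ## rmsd is invariant to a common rigid transform of both point sets
  R2 <- eulerRotation(-0.9, 0.3, 1.7)
  both <- function(m) m %*% t(R2) + matrix(c(1, 2, 3), nrow(m), 3,
                                           byrow = TRUE)
  fit3 <- kabschSuperpose(both(oct), both(2 * oct))
  expect_equal(fit3$rmsd, 1, tolerance = 1e-9)
})

test_that("Kabsch rejects degenerate inputs", {
  expect_error(kabschSuperpose(matrix(rnorm(6), 2, 3),
                               matrix(rnorm(6), 2, 3)), "3")
  line <- cbind(1:5, 2 * (1:5), 3 * (1:5))
  expect_error(kabschSuperpose(line, line), "collinear")
  expect_error(kabschSuperpose(matrix(rnorm(12), 4, 3),
                               matrix(rnorm(15), 5, 3)), "correspondence")
})

test_that("pocket extraction recovers planted fingerprints exactly", {
  pd <- defaultPocketDefinition()
  set.seed(8)
  fp_str <- paste(sample(aminoAcidAlphabet(), 21, replace = TRUE),
                  collapse = "")
  g <- generateStructures(data.frame(sequence_id = "q1", residues = fp_str),
                          pd, noise_sd = 0, seed = 9)
  out <- extractPocket(g$structures$q1, g$template, pd, sequence_id = "q1")
  expect_equal(out$residues, fp_str)
  expect_lt(out$rmsd, 1e-6)
  expect_equal(out$sequence_id, "q1")
})

test_that("family remap reads the shifted P6/P7 residues", {
  pd <- defaultPocketDefinition()
  g <- generateStructures(data.frame(sequence_id = "t", residues =
                                       strrep("E", 21)),
                          pd, noise_sd = 0, identity_transform = TRUE,
                          seed = 1)
  st <- g$template
  ## plant W at the remapped P6/P7 residue numbers only
  remap <- pd@remaps$G2
  st$residue[remap] <- "W"
  base <- extractPocket(st, g$template, pd)
  g2 <- extractPocket(st, g$template, pd, family = "G2")
  expect_equal(substr(g2$residues, 6, 7), "WW")
  expect_false(substr(base$residues, 6, 7) == "WW")
  ## positions other than P6/P7 are unaffected by the remap
  expect_equal(substr(g2$residues, 1, 5), substr(base$residues, 1, 5))
  expect_equal(substr(g2$residues, 8, 21), substr(base$residues, 8, 21))
})

test_that("extraction tolerates moderate coordinate noise", {
  pd <- defaultPocketDefinition()
  set.seed(10)
  fps <- data.frame(sequence_id = sprintf("n%02d", 1:20),
                    residues = replicate(20, paste(
                      sample(aminoAcidAlphabet(), 21, replace = TRUE),
                      collapse = "")))
  g <- generateStructures(fps, pd, noise_sd = 0.5, seed = 11)
  rec <- vapply(fps$sequence_id, function(id) {
    out <- extractPocket(g$structures[[id]], g$template, pd,
                         sequence_id = id)
    mean(strsplit(out$residues, "")[[1]] ==
           strsplit(fps$residues[fps$sequence_id == id], "")[[1]])
  }, numeric(1))
  expect_gte(mean(rec), 0.95)
})

test_that("modeling gate thresholds on best template identity", {
  set.seed(12)
  tmpl <- sequenceRecords("t1", randomSeq(80))
  near <- tmpl$residues[1]
  substr(near, 1, 10) <- strrep("A", 10)
  expect_true(modelingGate(near, tmpl, 0.23))
  expect_false(modelingGate(randomSeq(80), tmpl, 0.9))
})

test_that("pocket clustering recovers planted motifs and retention", {
  set.seed(14)
  motifA <- paste(sample(aminoAcidAlphabet(), 21, replace = TRUE),
                  collapse = "")
  motifB <- paste(rev(sample(aminoAcidAlphabet(), 21, replace = TRUE)),
                  collapse = "")
  jitter1 <- function(s) {  # flip one position
    r <- strsplit(s, "")[[1]]
    p <- sample(21, 1)
    r[p] <- sample(setdiff(aminoAcidAlphabet(), r[p]), 1)
    paste(r, collapse = "")
  }
  fps <- data.frame(
    sequence_id = sprintf("f%02d", 1:40),
    residues = c(replicate(20, jitter1(motifA)),
                 replicate(20, jitter1(motifB))),
    stringsAsFactors = FALSE)
  tree <- clusterPockets(fps, min_cluster_size = 15, cut_height = 0.5)
  a <- tree@assignments
  expect_equal(length(unique(a$cluster)), 2L)
  expect_equal(length(unique(a$cluster[1:20])), 1L)
  expect_equal(length(unique(a$cluster[21:40])), 1L)
  expect_true(all(a$retained))
  ## consensus equals the planted motifs (1 flip in 20 rows cannot
  ## displace the majority residue)
  expect_setequal(unname(tree@consensus), c(motifA, motifB))
  ## a small third group is not retained
  motifC <- paste(sample(aminoAcidAlphabet(), 21, replace = TRUE),
                  collapse = "")
  fps2 <- rbind(fps, data.frame(
    sequence_id = sprintf("g%02d", 1:5),
    residues = replicate(5, jitter1(motifC)), stringsAsFactors = FALSE))
  tree2 <- clusterPockets(fps2, min_cluster_size = 15, cut_height = 0.5)
  a2 <- tree2@assignments
  expect_false(any(a2$retained[41:45]))
  expect_true(all(a2$retained[1:40]))
  ## group labelling follows the labelled reference members
  labels <- c(f01 = "G1", f21 = "G2")
  gl <- assignGroups(tree, labels)
  expect_equal(gl[1:20], rep("G1", 20))
  expect_equal(gl[21:40], rep("G2", 20))
  ## Newick export covers all leaves
  nwk <- pocketTreeNewick(tree)
  expect_true(all(vapply(a$sequence_id, grepl, logical(1), x = nwk,
                         fixed = TRUE)))
})

test_that("logos: conserved, uniform, mixed and all-gap columns", {
  ## fully conserved column -> log2(20) bits
  fp <- data.frame(sequence_id = sprintf("s%02d", 1:20),
                   residues = paste0("E", aminoAcidAlphabet()))
  logo <- makeLogo(fp)
  expect_equal(logo$ic[1], log2(20))
  ## uniform column over all 20 residues -> 0 bits
  expect_equal(logo$ic[2], 0, tolerance = 1e-12)
  ## frequencies sum to 1 at informative positions
  expect_equal(unname(rowSums(logo$frequencies)), c(1, 1))
  ## hand value: 3/4 E + 1/4 D -> log2(20) - H(0.75, 0.25)
  fp2 <- data.frame(sequence_id = c("a", "b", "c", "d"),
                    residues = c("E", "E", "E", "D"))
  h <- -(0.75 * log2(0.75) + 0.25 * log2(0.25))
  expect_equal(makeLogo(fp2)$ic[1], log2(20) - h)
  ## all-gap -> NA ic, gap fraction tracked
  fp3 <- data.frame(sequence_id = c("a", "b"), residues = c("-A", "-A"))
  logo3 <- makeLogo(fp3)
  expect_true(is.na(logo3$ic[1]))
  expect_equal(logo3$gap_fraction, c(1, 0))
})

test_that("catalytic P3 check distinguishes E, substitution and gap", {
  x <- c("AAEAA", "AAAAA", "AA-AA")
  expect_identical(checkCatalytic(x), c(TRUE, FALSE, FALSE))
  expect_identical(catalyticStatus(x),
                   c("catalytic", "non-catalytic", "incomplete"))
})
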