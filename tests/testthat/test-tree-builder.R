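test_that("three-taxon NJ matches the closed form", {
  dm <- matrix(c(0, .2, .3, .2, 0, .4, .3, .4, 0), 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- neighbor_joining(dm)
  # pendant lengths (d_xy + d_xz - d_yz) / 2
  lens <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(lens[c("A", "B", "C")], c(A = 0.05, B = 0.15, C = 0.25))
})

test_that("NJ recovers planted additive trees exactly", {
  # the quartet ((A:1,B:2):1,(C:3,D:4)): distances read off the tree
  dm <- matrix(0, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  dm["A", "B"] <- dm["B", "A"] <- 3
  dm["A", "C"] <- dm["C", "A"] <- 5
  dm["A", "D"] <- dm["D", "A"] <- 6
  dm["B", "C"] <- dm["C", "B"] <- 6
  dm["B", "D"] <- dm["D", "B"] <- 7
  dm["C", "D"] <- dm["D", "C"] <- 7
  tr <- neighbor_joining(dm)
  planted <- parse_newick("((A:1,B:2):1,(C:3,D:4):0);")
  expect_equal(rf_distance(tr, planted), 0)
  expect_equal(ape::cophenetic.phylo(tr)[LETTERS[1:4], LETTERS[1:4]],
               dm, tolerance = 1e-12)

  set.seed(55)
  for (r in 1:10) {
    n <- sample(5:12, 1)
    planted <- ape::rtree(n, rooted = FALSE)
    planted$edge.length <- runif(nrow(planted$edge), 0.05, 2)
    dm <- ape::cophenetic.phylo(planted)
    rec <- neighbor_joining(dm)
    expect_equal(rf_distance(rec, planted), 0)
    expect_lt(max(abs(ape::cophenetic.phylo(rec)[rownames(dm), colnames(dm)] -
                        dm)), 1e-9)
  }
})

test_that("NJ validates input and handles two taxa", {
  dm <- matrix(c(0, .5, .5, 0), 2, dimnames = list(c("A", "B"), c("A", "B")))
  tr <- neighbor_joining(dm)
  expect_equal(sum(tr$edge.length), 0.5)
  bad <- matrix(c(0, 1, 2, 0), 2)
  expect_error(neighbor_joining(bad), "symmetric")
  nan <- matrix(c(0, NA, NA, 0), 2)
  expect_error(neighbor_joining(nan), "missing")
})

test_that("leaf-order permutation leaves the unrooted NJ tree unchanged", {
  set.seed(56)
  msets <- lapply(1:6, function(i) random_manual_mset(paste0("s", i)))
  D <- build_distance_matrix(msets)
  tr1 <- neighbor_joining(D)
  p <- sample(6)
  tr2 <- neighbor_joining(D[p, p])
  expect_equal(rf_distance(tr1, tr2), 0)
})

test_that("p-distances honour pairwise and complete deletion", {
  aln <- c(s1 = "ACGT", s2 = "ACGA")
  P <- pairwise_p_distance(aln)
  expect_equal(P["s1", "s2"], 0.25)
  expect_equal(attr(P, "sites")["s1", "s2"], 4)

  aln2 <- c(s1 = "AC-T", s2 = "ACGT")
  P2 <- pairwise_p_distance(aln2, "pairwise")
  expect_equal(P2["s1", "s2"], 0)
  expect_equal(attr(P2, "sites")["s1", "s2"], 3)

  aln3 <- c(s1 = "AC-TT", s2 = "ACGTA", s3 = "ACGTT")
  Pc <- pairwise_p_distance(aln3, "complete")
  expect_equal(attr(Pc, "sites")["s1", "s2"], 4)   # gap column dropped for all
  expect_equal(Pc["s2", "s3"], 0.25)

  # U reads as T; N and ? are missing
  aln4 <- c(s1 = "ACGU", s2 = "ACGT")
  expect_equal(pairwise_p_distance(aln4)["s1", "s2"], 0)
  aln5 <- c(s1 = "NNNN", s2 = "ACGT")
  expect_error(pairwise_p_distance(aln5), "no comparable sites")
  expect_error(pairwise_p_distance(c(a = "ACG", b = "AC")), "same length")
})

test_that("Jukes-Cantor transform and its domain edge", {
  aln <- c(s1 = "AAAA", s2 = "AAAC")          # p = 0.25
  D <- jukes_cantor_distance(aln)
  expect_equal(D["s1", "s2"], -0.75 * log(1 - 1 / 3))
  expect_equal(jukes_cantor_distance(c(a = "ACGT", b = "ACGT"))["a", "b"], 0)
  sat <- c(s1 = "AAAAA", s2 = "CCCCG")        # p = 1 >= 0.75
  expect_error(jukes_cantor_distance(sat), "saturated")
  # JC >= p on non-trivial distances
  P <- pairwise_p_distance(aln)
  expect_gte(D["s1", "s2"], P["s1", "s2"])
})

test_that("Newick parsing round-trips and rejects malformed input", {
  tr <- parse_newick("(A:1,B:2);")
  expect_equal(sort(tr$tip.label), c("A", "B"))
  expect_equal(sort(tr$edge.length), c(1, 2))

  set.seed(57)
  t0 <- ape::rtree(6)
  txt <- write_newick(t0)
  t1 <- parse_newick(txt)
  expect_equal(rf_distance(t0, t1), 0)
  expect_equal(sort(t1$edge.length), sort(t0$edge.length), tolerance = 1e-9)

  expect_error(parse_newick("((A,B),C;"), "parse error")
  expect_error(parse_newick("(A:1,A:2);"), "duplicate leaf")

  f <- tempfile()
  write_newick(t0, f)
  expect_equal(rf_distance(parse_newick(file = f), t0), 0)
})

test_that("FASTA alignments load as named equal-length sequences", {
  f <- tempfile(fileext = ".fa")
  writeLines(c(">sp1", "ACGT-CGT", ">sp2", "ACGTTCGA"), f)
  aln <- read_fasta_alignment(f)
  expect_equal(names(aln), c("sp1", "sp2"))
  expect_equal(nchar(aln[["sp1"]]), 8)
  P <- pairwise_p_distance(aln)
  expect_equal(P["sp1", "sp2"], 1 / 7)
})
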