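test_that("bipartitions enumerate one split per branch, canonically sided", {
  two <- parse_newick("(A:1,B:1);")
  b <- bipartitions(two)
  expect_length(b, 1)
  expect_equal(b[[1]]$side1, "A")
  expect_equal(b[[1]]$side2, "B")

  quartet <- parse_newick("((A:1,B:1):1,(C:1,D:1):1);")
  bq <- bipartitions(quartet)
  expect_length(bq, 5)                      # 4 pendant + 1 internal
  internal <- Filter(function(x) length(x$side2) == 2, bq)
  expect_length(internal, 1)
  expect_setequal(internal[[1]]$side2, c("C", "D"))

  star <- parse_newick("(A:1,B:1,C:1);")
  expect_length(bipartitions(star), 3)
  expect_error(bipartitions(parse_newick("(A:1,B:1);")[c("edge")]),
               class = "error")
})

test_that("branch scores take the better pairing's worse Jaccard side", {
  q1 <- bipartitions(parse_newick("((A,B),(C,D));"))
  q2 <- bipartitions(parse_newick("((A,C),(B,D));"))
  int1 <- Filter(function(x) length(x$side2) == 2, q1)[[1]]
  int2 <- Filter(function(x) length(x$side2) == 2, q2)[[1]]
  expect_equal(branch_score(int1, int2), 1 / 3)
  expect_equal(branch_score(int1, int1), 1)
  # identical pendant splits always score 1
  pa1 <- Filter(function(x) identical(x$side2, "D"), q1)[[1]]
  pa2 <- Filter(function(x) identical(x$side2, "D"), q2)[[1]]
  expect_equal(branch_score(pa1, pa2), 1)

  other <- bipartitions(parse_newick("((A,B),(C,E));"))[[1]]
  expect_error(branch_score(int1, other), "different leaf sets")
})

test_that("optimal branch map is exact against factorial enumeration", {
  set.seed(601)
  for (r in 1:20) {
    n <- sample(4:5, 1)
    t1 <- ape::rtree(n, tip.label = LETTERS[1:n])
    t2 <- ape::rtree(n, tip.label = LETTERS[1:n])
    m <- optimal_branch_map(t1, t2)
    expect_equal(m$total, oracle_matching_total(t1, t2), tolerance = 1e-12)
    expect_true(all(m$pairs$score >= 0 & m$pairs$score <= 1))
    b1 <- m$pairs$branch1[!is.na(m$pairs$branch1)]
    expect_false(anyDuplicated(b1) > 0)
  }
})

test_that("identical trees score 100 percent; quartet case as derived", {
  set.seed(602)
  for (r in 1:5) {
    tr <- ape::rtree(sample(4:8, 1))
    m <- optimal_branch_map(tr, tr)
    expect_equal(m$percent, 100)
    expect_equal(m$total, length(bipartitions(tr)))
  }
  t1 <- parse_newick("((A,B),(C,D));")
  t2 <- parse_newick("((A,C),(B,D));")
  m <- optimal_branch_map(t1, t2)
  expect_equal(m$total, 4 + 1 / 3)
  expect_equal(m$percent, 100 * (4 + 1 / 3) / 5)
  expect_equal(similarity_percent(m), m$percent)
  expect_equal(similarity_percent(m, t1, t2, internal_only = TRUE), 100 / 3)
})

test_that("unequal branch counts are padded; label permutation is neutral", {
  bin <- parse_newick("((A,B),(C,D),E);")
  multi <- parse_newick("(A,B,C,D,E);")          # star: pendants only
  m <- optimal_branch_map(bin, multi)
  expect_equal(m$n_branches, c(7L, 5L))
  expect_equal(nrow(m$pairs), 7)
  expect_equal(sum(is.na(m$pairs$branch2)), 2)
  expect_equal(m$total, oracle_matching_total(bin, multi), tolerance = 1e-12)
  expect_error(optimal_branch_map(bin, parse_newick("(A,B,C);")),
               "same leaf set")

  # consistent leaf relabelling leaves the percentage unchanged
  t1 <- ape::rtree(6); t2 <- ape::rtree(6)
  p1 <- optimal_branch_map(t1, t2)$percent
  perm <- setNames(sample(t1$tip.label), t1$tip.label)
  t1b <- t1; t1b$tip.label <- unname(perm[t1$tip.label])
  t2b <- t2; t2b$tip.label <- unname(perm[t2$tip.label])
  expect_equal(optimal_branch_map(t1b, t2b)$percent, p1)
})

test_that("RF distance agrees with phangorn on random tree pairs", {
  skip_if_not_installed("phangorn")
  set.seed(603)
  for (r in 1:20) {
    n <- sample(4:10, 1)
    t1 <- ape::rtree(n); t2 <- ape::rtree(n)
    t2$tip.label <- sample(t1$tip.label)
    expect_equal(rf_distance(t1, t2),
                 as.integer(phangorn::RF.dist(t1, t2)))
  }
  tr <- ape::rtree(7)
  expect_equal(rf_distance(tr, tr), 0)
  # identical split sets imply 100 % similarity
  expect_equal(optimal_branch_map(tr, tr)$percent, 100)
})
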