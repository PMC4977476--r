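#' Bipartitions (splits) of a tree
#'
#' Deleting a branch of an unrooted leaf-labelled tree splits the leaf set
#' in two; this returns one such bipartition per branch, pendant branches
#' included.  Sides are canonically ordered: the side containing the
#' lexicographically smallest leaf comes first.  Rooted input is unrooted
#' first (the two branches meeting at a binary root describe the same
#' split).
#'
#' @param tree a `phylo` object with at least 2 leaves.
#' @return list of `bipartition` objects: lists with sorted character
#'   vectors `side1`, `side2` and the originating `branch` index.
#' @export
bipartitions <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (length(tree$tip.label) < 2L) {
    stop("tree must have at least 2 leaves", call. = FALSE)
  }
  if (length(tree$tip.label) == 2L) {
    l <- sort(tree$tip.label)
    return(list(structure(list(side1 = l[1], side2 = l[2], branch = 1L),
                          class = "bipartition")))
  }
  tree <- ape::unroot(tree)
  labels <- tree$tip.label
  ntip <- length(labels)
  smallest <- min(labels)
  nedge <- nrow(tree$edge)
  # tips below each edge via one post-order sweep
  below <- vector("list", ntip + tree$Nnode)
  for (i in seq_len(ntip)) below[[i]] <- i
  ord <- ape::reorder.phylo(tree, "postorder")
  for (k in seq_len(nrow(ord$edge))) {
    p <- ord$edge[k, 1]; ch <- ord$edge[k, 2]
    below[[p]] <- c(below[[p]], below[[ch]])
  }
  out <- vector("list", nedge)
  for (e in seq_len(nedge)) {
    tips_in <- sort(labels[below[[tree$edge[e, 2]]]])
    tips_out <- sort(setdiff(labels, tips_in))
    if (smallest %in% tips_in) {
      sides <- list(side1 = tips_in, side2 = tips_out)
    } else {
      sides <- list(side1 = tips_out, side2 = tips_in)
    }
    out[[e]] <- structure(c(sides, list(branch = e)), class = "bipartition")
  }
  out
}

jaccard <- function(a, b) {
  u <- length(union(a, b))
  if (u == 0L) return(1)
  length(intersect(a, b)) / u
}

#' Topological score between two bipartitions
#'
#' The score of branches i and j pairs the sides of their bipartitions in
#' the two possible ways and takes, over the better pairing, the worse of
#' the two side-wise Jaccard indices:
#' \eqn{s = \max(\min(J(p_1,q_1), J(p_2,q_2)), \min(J(p_1,q_2), J(p_2,q_1)))}.
#' Identical splits score 1; the score is symmetric and lies in \[0, 1\].
#'
#' @param p,q `bipartition` objects over the same leaf set.
#' @return a number in \[0, 1\].
#' @export
branch_score <- function(p, q) {
  lp <- c(p$side1, p$side2); lq <- c(q$side1, q$side2)
  if (!setequal(lp, lq)) {
    stop("bipartitions are over different leaf sets; symmetric difference: ",
         paste(union(setdiff(lp, lq), setdiff(lq, lp)), collapse = ", "),
         call. = FALSE)
  }
  max(min(jaccard(p$side1, q$side1), jaccard(p$side2, q$side2)),
      min(jaccard(p$side1, q$side2), jaccard(p$side2, q$side1)))
}

# exact minimum-cost assignment (Jonker-Volgenant style shortest augmenting
# paths, O(n^3)); returns for each row the assigned column
solve_assignment <- function(cost) {
  n <- nrow(cost)
  stopifnot(ncol(cost) == n)
  u <- numeric(n + 1L)
  v <- numeric(n + 1L)
  p <- integer(n + 1L)       # p[j+1]: row assigned to column j (0 = none)
  way <- integer(n + 1L)
  for (i in seq_len(n)) {
    p[1L] <- i
    j0 <- 0L
    minv <- rep(Inf, n + 1L)
    used <- rep(FALSE, n + 1L)
    repeat {
      used[j0 + 1L] <- TRUE
      i0 <- p[j0 + 1L]
      delta <- Inf
      j1 <- 0L
      for (j in seq_len(n)) {
        if (!used[j + 1L]) {
          cur <- cost[i0, j] - u[i0 + 1L] - v[j + 1L]
          if (cur < minv[j + 1L]) {
            minv[j + 1L] <- cur
            way[j + 1L] <- j0
          }
          if (minv[j + 1L] < delta) {
            delta <- minv[j + 1L]
            j1 <- j
          }
        }
      }
      for (j in 0:n) {
        if (used[j + 1L]) {
          u[p[j + 1L] + 1L] <- u[p[j + 1L] + 1L] + delta
          v[j + 1L] <- v[j + 1L] - delta
        } else {
          minv[j + 1L] <- minv[j + 1L] - delta
        }
      }
      j0 <- j1
      if (p[j0 + 1L] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1L]
      p[j0 + 1L] <- p[j1 + 1L]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  assignment <- integer(n)
  for (j in seq_len(n)) {
    if (p[j + 1L] > 0L) assignment[p[j + 1L]] <- j
  }
  assignment
}

#' Optimal one-to-one branch matching between two trees
#'
#' Scores every pair of branches of two trees on the same leaf set with
#' [branch_score()] and finds the bijection between the branch sets
#' maximizing the total score, by an exact optimal-assignment solve on the
#' full score grid.  When the trees have different branch counts
#' (non-binary references such as taxonomies) the smaller set is padded
#' with null partners scoring 0.
#'
#' @param T1,T2 `phylo` trees sharing the same leaf set.
#' @return object of class `branch_matching`: `pairs` (data frame with
#'   `branch1`, `branch2`, `score`; `NA` branch = padded null partner),
#'   `total` score, `percent` similarity (see [similarity_percent()]),
#'   `n_branches` per tree.
#' @export
optimal_branch_map <- function(T1, T2) {
  l1 <- sort(T1$tip.label); l2 <- sort(T2$tip.label)
  if (!identical(l1, l2)) {
    stop("trees must share the same leaf set; symmetric difference: ",
         paste(union(setdiff(l1, l2), setdiff(l2, l1)), collapse = ", "),
         call. = FALSE)
  }
  b1 <- bipartitions(T1)
  b2 <- bipartitions(T2)
  n1 <- length(b1); n2 <- length(b2)
  S <- matrix(0, n1, n2)
  for (i in seq_len(n1)) {
    for (j in seq_len(n2)) S[i, j] <- branch_score(b1[[i]], b2[[j]])
  }
  n <- max(n1, n2)
  Spad <- matrix(0, n, n)
  Spad[seq_len(n1), seq_len(n2)] <- S
  assignment <- solve_assignment(max(Spad) - Spad)
  pairs <- data.frame(branch1 = ifelse(seq_len(n) <= n1, seq_len(n), NA),
                      branch2 = ifelse(assignment <= n2, assignment, NA),
                      score = Spad[cbind(seq_len(n), assignment)])
  pairs <- pairs[!(is.na(pairs$branch1) & is.na(pairs$branch2)), , drop = FALSE]
  rownames(pairs) <- NULL
  total <- sum(pairs$score)
  structure(list(pairs = pairs, total = total,
                 percent = 100 * total / max(n1, n2),
                 n_branches = c(n1, n2),
                 score_grid = S),
            class = "branch_matching")
}

#' @export
print.branch_matching <- function(x, ...) {
  cat(sprintf("<branch_matching> %d vs %d branches: total score %.4f, %.2f%% similar\n",
              x$n_branches[1], x$n_branches[2], x$total, x$percent))
  invisible(x)
}

#' Percentage similarity of a branch matching
#'
#' `100 * total score / max(branch counts)`, over all branches (pendant
#' and internal); identical trees score 100.  With `internal_only = TRUE`
#' the quantity is recomputed over internal branches alone (pendant
#' branches of a shared leaf set always match perfectly, so the default
#' includes them).
#'
#' @param match a `branch_matching` from [optimal_branch_map()].
#' @param T1,T2 the trees (only needed for `internal_only`).
#' @param internal_only restrict to internal branches?
#' @return percentage in \[0, 100\].
#' @export
similarity_percent <- function(match, T1 = NULL, T2 = NULL,
                               internal_only = FALSE) {
  stopifnot(inherits(match, "branch_matching"))
  if (!internal_only) return(match$percent)
  if (is.null(T1) || is.null(T2)) {
    stop("internal_only needs the two trees", call. = FALSE)
  }
  b1 <- bipartitions(T1); b2 <- bipartitions(T2)
  int1 <- which(vapply(b1, function(b) min(length(b$side1), length(b$side2)), 1L) >= 2L)
  int2 <- which(vapply(b2, function(b) min(length(b$side1), length(b$side2)), 1L) >= 2L)
  if (!length(int1) && !length(int2)) return(100)
  keep <- match$pairs$branch1 %in% int1 & match$pairs$branch2 %in% int2
  100 * sum(match$pairs$score[keep]) / max(length(int1), length(int2))
}

#' Robinson-Foulds distance between two unrooted trees
#'
#' Number of internal (non-trivial) splits present in one tree but not the
#' other; 0 means identical topologies.
#'
#' @param T1,T2 `phylo` trees on the same leaf set.
#' @return non-negative integer.
#' @export
rf_distance <- function(T1, T2) {
  key <- function(tree) {
    b <- bipartitions(tree)
    b <- b[vapply(b, function(x) min(length(x$side1), length(x$side2)), 1L) >= 2L]
    unique(vapply(b, function(x) paste(x$side2, collapse = "|"), ""))
  }
  k1 <- key(T1); k2 <- key(T2)
  length(setdiff(k1, k2)) + length(setdiff(k2, k1))
}
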