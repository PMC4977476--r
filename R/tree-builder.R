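#' Neighbor-joining tree from a species distance matrix
#'
#' Classic agglomerative neighbor joining (Q-matrix pair selection,
#' standard branch-length and distance-update formulas), delegated to
#' [ape::nj()]; consistent on additive matrices, so a distance matrix read
#' off a tree returns exactly that tree.  Two taxa yield a single branch
#' carrying the given distance.  Negative branch lengths are kept as
#' computed unless `clamp_negative = TRUE`, which moves each negative
#' pendant length to zero and transfers the difference to its sister
#' branch (the common viewer-friendly adjustment).
#'
#' @param dm symmetric numeric matrix with zero diagonal, species codes as
#'   dimnames, no NA/NaN.
#' @param clamp_negative zero out negative branch lengths (compensating on
#'   the adjacent branch)?
#' @return an unrooted `phylo` tree (see [ape::read.tree()]).
#' @export
neighbor_joining <- function(dm, clamp_negative = FALSE) {
  dm <- as.matrix(dm)
  if (is.null(rownames(dm))) rownames(dm) <- colnames(dm) <- paste0("t", seq_len(nrow(dm)))
  if (nrow(dm) != ncol(dm) || anyNA(dm)) {
    stop("distance matrix must be square with no missing values", call. = FALSE)
  }
  if (max(abs(dm - t(dm))) > 1e-8) {
    stop("distance matrix must be symmetric", call. = FALSE)
  }
  if (any(abs(diag(dm)) > 1e-12)) {
    stop("distance matrix must have a zero diagonal", call. = FALSE)
  }
  n <- nrow(dm)
  if (n < 2L) stop("need at least 2 taxa", call. = FALSE)
  if (n == 2L) {
    tree <- ape::read.tree(text = sprintf("(%s:%s,%s:%s);",
                                          rownames(dm)[1], format_num(dm[1, 2] / 2),
                                          rownames(dm)[2], format_num(dm[1, 2] / 2)))
    return(tree)
  }
  tree <- ape::nj(stats::as.dist(dm))
  if (clamp_negative) {
    neg <- which(tree$edge.length < 0)
    for (e in neg) {
      child <- tree$edge[e, 2]
      parent <- tree$edge[e, 1]
      sisters <- which(tree$edge[, 1] == parent & seq_along(tree$edge[, 2]) != e)
      tree$edge.length[sisters] <- tree$edge.length[sisters] + tree$edge.length[e]
      tree$edge.length[e] <- 0
    }
  }
  tree
}

# normalize one sequence: uppercase, U->T, N/?/- and anything odd -> NA
clean_sequence <- function(s) {
  x <- strsplit(toupper(s), "")[[1]]
  x[x == "U"] <- "T"
  x[!x %in% c("A", "C", "G", "T")] <- NA
  x
}

as_alignment_matrix <- function(aln) {
  if (is.matrix(aln)) {
    mat <- toupper(aln)
    mat[mat == "U"] <- "T"
    mat[!mat %in% c("A", "C", "G", "T")] <- NA
    return(mat)
  }
  if (!is.character(aln) || is.null(names(aln))) {
    stop("alignment must be a named character vector or character matrix",
         call. = FALSE)
  }
  lens <- nchar(aln)
  if (length(unique(lens)) != 1L) {
    stop("aligned sequences must all have the same length", call. = FALSE)
  }
  if (length(aln) < 2L) stop("need at least 2 sequences", call. = FALSE)
  mat <- t(vapply(aln, clean_sequence, character(lens[1])))
  rownames(mat) <- names(aln)
  mat
}

#' Pairwise p-distances from an alignment
#'
#' Proportion of differing sites per sequence pair.  Gaps, `N` and `?` are
#' missing data; `U` is read as `T`.  Under `deletion = "pairwise"` a site
#' is compared whenever *neither* sequence of the pair is missing there;
#' under `"complete"` only columns clean in every sequence are used.
#'
#' @param aln named character vector of equal-length aligned sequences (or
#'   a character matrix, one row per species).
#' @param deletion `"pairwise"` (default) or `"complete"`.
#' @return symmetric matrix of p-distances with attribute `sites`: the
#'   matrix of per-pair compared-position counts.
#' @export
pairwise_p_distance <- function(aln, deletion = c("pairwise", "complete")) {
  deletion <- match.arg(deletion)
  mat <- as_alignment_matrix(aln)
  if (deletion == "complete") {
    mat <- mat[, colSums(is.na(mat)) == 0L, drop = FALSE]
  }
  n <- nrow(mat)
  D <- matrix(0, n, n, dimnames = list(rownames(mat), rownames(mat)))
  sites <- matrix(ncol(mat), n, n, dimnames = dimnames(D))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      ok <- !is.na(mat[i, ]) & !is.na(mat[j, ])
      ns <- sum(ok)
      if (ns == 0L) {
        stop(sprintf("no comparable sites for pair (%s, %s)",
                     rownames(mat)[i], rownames(mat)[j]), call. = FALSE)
      }
      D[i, j] <- D[j, i] <- sum(mat[i, ok] != mat[j, ok]) / ns
      sites[i, j] <- sites[j, i] <- ns
    }
  }
  attr(D, "sites") <- sites
  attr(D, "provenance") <- "sequence"
  D
}

#' Jukes-Cantor distances from an alignment
#'
#' \eqn{d = -\frac{3}{4} \ln(1 - \frac{4}{3} p)} applied to the pairwise
#' p-distances; undefined (an error) when any pair is saturated
#' (\eqn{p \ge 0.75}).
#'
#' @inheritParams pairwise_p_distance
#' @return symmetric distance matrix.
#' @export
jukes_cantor_distance <- function(aln, deletion = c("pairwise", "complete")) {
  P <- pairwise_p_distance(aln, deletion)
  if (any(P >= 0.75)) {
    bad <- which(P >= 0.75, arr.ind = TRUE)[1, ]
    stop(sprintf("Jukes-Cantor distance undefined for saturated pair (%s, %s): p = %.3f",
                 rownames(P)[bad[1]], colnames(P)[bad[2]],
                 P[bad[1], bad[2]]), call. = FALSE)
  }
  D <- -0.75 * log(1 - 4 * P / 3)
  diag(D) <- 0
  attr(D, "sites") <- attr(P, "sites")
  attr(D, "provenance") <- "sequence"
  D
}

#' Read an aligned FASTA file
#'
#' @param file FASTA path (aligned, equal-length sequences).
#' @return named character vector of sequences.
#' @export
read_fasta_alignment <- function(file) {
  seqs <- ape::read.FASTA(file)
  out <- vapply(as.character(seqs), paste, "", collapse = "")
  names(out) <- names(seqs)
  out
}

#' Newick reading and writing
#'
#' Thin validated wrappers around [ape::read.tree()] /
#' [ape::write.tree()]: parse errors (unbalanced parentheses and the
#' like) and duplicate leaf labels are reported as errors rather than
#' warnings or `NULL` returns.
#'
#' @param text Newick string (alternatively give `file`).
#' @param file path to a Newick file.
#' @return `parse_newick()`: a `phylo` tree; `write_newick()`: the Newick
#'   string (written to `file` when given).
#' @export
parse_newick <- function(text = NULL, file = NULL) {
  tree <- withCallingHandlers(
    tryCatch({
      if (!is.null(file)) ape::read.tree(file = file)
      else ape::read.tree(text = text)
    }, error = function(e) stop("Newick parse error: ", conditionMessage(e),
                                call. = FALSE)),
    warning = function(w) {
      stop("Newick parse error: ", conditionMessage(w), call. = FALSE)
    })
  if (is.null(tree)) stop("Newick parse error: invalid tree text", call. = FALSE)
  if (anyDuplicated(tree$tip.label)) {
    stop("duplicate leaf labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "), call. = FALSE)
  }
  tree
}

#' @rdname parse_newick
#' @param tree a `phylo` object.
#' @export
write_newick <- function(tree, file = NULL) {
  stopifnot(inherits(tree, "phylo"))
  txt <- ape::write.tree(tree, digits = 10)
  if (!is.null(file)) writeLines(txt, file)
  invisible(txt)
}
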