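#' Module-overlap similarity and distance between species
#'
#' The module tree rests on three set-based quantities.  For two modules
#' \eqn{M_1} (from species x) and \eqn{M_2} (from species y), viewed as sets
#' of cross-species member identifiers,
#' \deqn{Sim(M_1, M_2) = |M_1 \cap M_2| / |M_1 \cup M_2|}
#' (the Jaccard index: common members normalized by the non-redundant
#' members of both modules).  Species similarity averages `Sim` over the
#' full \eqn{m_1 \times m_2} grid of module pairs,
#' \deqn{S_M(x, y) = \sum_{i,j} Sim(M_i, M_j) / (m_1 m_2),}
#' and the distance is \eqn{D_M(x, y) = 1 - S_M(x, y)}.
#'
#' Note that \eqn{S_M(x, x) < 1} whenever a species has more than one
#' distinct module, so [build_distance_matrix()] forces the diagonal of the
#' assembled matrix to 0 (a requirement of distance-based tree building)
#' and keeps the off-diagonal entries exactly as defined.
#'
#' @param m1,m2 non-empty character vectors of member identifiers.
#' @return `module_similarity()`: a number in \[0, 1\].
#' @examples
#' module_similarity(c("a", "b", "c"), c("b", "c", "d"))  # 0.5
#' @export
module_similarity <- function(m1, m2) {
  m1 <- unique(as.character(m1)); m2 <- unique(as.character(m2))
  if (!length(m1) || !length(m2)) {
    stop("modules must be non-empty member sets", call. = FALSE)
  }
  length(intersect(m1, m2)) / length(union(m1, m2))
}

# m1 x m2 grid of Sim values for two module sets
module_similarity_grid <- function(msetX, msetY) {
  stopifnot(inherits(msetX, "module_set"), inherits(msetY, "module_set"))
  mx <- msetX$member_view; my <- msetY$member_view
  if (!length(mx)) stop("species '", msetX$species, "' has no modules", call. = FALSE)
  if (!length(my)) stop("species '", msetY$species, "' has no modules", call. = FALSE)
  universe <- sort(unique(c(unlist(mx), unlist(my))))
  A <- vapply(mx, function(m) universe %in% m, logical(length(universe)))
  B <- vapply(my, function(m) universe %in% m, logical(length(universe)))
  A <- matrix(A, nrow = length(universe)); B <- matrix(B, nrow = length(universe))
  inter <- crossprod(A, B)                       # |Mi n Mj|
  sizesX <- colSums(A); sizesY <- colSums(B)
  uni <- outer(sizesX, sizesY, "+") - inter      # |Mi u Mj|
  inter / uni
}

#' @rdname module_similarity
#' @param msetX,msetY `module_set` objects from [modularize()].
#' @return `species_similarity()`: \eqn{S_M(x,y)} in \[0, 1\].
#' @export
species_similarity <- function(msetX, msetY) {
  grid <- module_similarity_grid(msetX, msetY)
  sum(grid) / (nrow(grid) * ncol(grid))
}

#' @rdname module_similarity
#' @return `species_distance()`: \eqn{D_M(x,y) = 1 - S_M(x,y)}.
#' @export
species_distance <- function(msetX, msetY) {
  1 - species_similarity(msetX, msetY)
}

#' Assemble the all-pairs species distance matrix
#'
#' @param msets list of `module_set` objects with distinct species codes.
#' @param provenance tag recording which distance fills the matrix.
#' @return symmetric numeric matrix with zero diagonal, dimnames set to the
#'   species codes, and attribute `provenance`.
#' @export
build_distance_matrix <- function(msets, provenance = "module") {
  stopifnot(is.list(msets), length(msets) >= 1L)
  species <- vapply(msets, function(m) m$species, "")
  if (anyDuplicated(species)) {
    stop("duplicate species codes: ",
         paste(unique(species[duplicated(species)]), collapse = ", "),
         call. = FALSE)
  }
  n <- length(msets)
  D <- matrix(0, n, n, dimnames = list(species, species))
  if (n > 1L) {
    for (i in 1:(n - 1L)) {
      for (j in (i + 1L):n) {
        d <- species_distance(msets[[i]], msets[[j]])
        D[i, j] <- d
        D[j, i] <- d
      }
    }
  }
  diag(D) <- 0   # explicit contract: self-distance is 0 by definition
  attr(D, "provenance") <- provenance
  D
}

#' Write / read a species distance matrix
#'
#' `write_distance_tsv()` emits a square tab-separated matrix with species
#' codes as header row and first column; `write_phylip_distances()` emits
#' the lower-triangular PHYLIP format for interoperability.
#'
#' @param D symmetric matrix with species dimnames.
#' @param file output path.
#' @export
write_distance_tsv <- function(D, file) {
  m <- matrix(format_num(D), nrow(D), dimnames = dimnames(D))
  df <- data.frame(species = rownames(D), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname write_distance_tsv
#' @export
read_distance_tsv <- function(file) {
  df <- utils::read.table(file, sep = "\t", header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  D <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(D) <- "double"
  rownames(D) <- df[[1]]
  D
}

#' @rdname write_distance_tsv
#' @export
write_phylip_distances <- function(D, file) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(sprintf("%5d", nrow(D)), con)
  for (i in seq_len(nrow(D))) {
    vals <- if (i > 1L) paste(format_num(D[i, 1:(i - 1L)]), collapse = " ") else ""
    writeLines(trimws(paste(sprintf("%-10s", rownames(D)[i]), vals), "right"), con)
  }
  invisible(file)
}
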