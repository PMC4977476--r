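#' Read every KGML file in a directory
#'
#' @param dir directory containing `.xml`/`.kgml` files.
#' @param ... passed to [parse_kgml()].
#' @return named list of [pathway_graph()] objects (names = species codes).
#' @export
read_kgml_dir <- function(dir, ...) {
  files <- sort(list.files(dir, pattern = "\\.(xml|kgml)$", full.names = TRUE))
  if (!length(files)) stop("no KGML files found in ", dir, call. = FALSE)
  graphs <- lapply(files, parse_kgml, ...)
  names(graphs) <- vapply(graphs, function(g) g$species, "")
  graphs
}

#' The module-tree pipeline
#'
#' Modularizes every pathway with factor `c`, assembles the module-overlap
#' distance matrix and runs neighbor joining: the end-to-end route from a
#' set of species-specific pathway graphs to their module tree.
#'
#' @param graphs named list of [pathway_graph()] objects.
#' @param c modularization factor; `c` is capped per graph at its own
#'   maximum total degree (a single shared factor must stay legal for
#'   every species).
#' @return list with `tree` (`phylo`), `distances`, `module_sets`.
#' @export
module_tree <- function(graphs, c = 3L) {
  msets <- lapply(graphs, function(g) {
    cc <- max(1L, min(as.integer(c), max_total_degree(g)))
    modularize(g, cc)
  })
  D <- build_distance_matrix(unname(msets))
  list(tree = neighbor_joining(D), distances = D, module_sets = msets)
}

#' The pathway-tree pipeline
#'
#' Whole-topology counterpart of [module_tree()]: all-pairs graphlet
#' alignment distances (1 - edge correctness) followed by neighbor
#' joining.
#'
#' @param graphs named list of [pathway_graph()] objects.
#' @param alpha alignment balance parameter, see [align_graphs()].
#' @return list with `tree` and `distances`.
#' @export
pathway_tree <- function(graphs, alpha = 0.8) {
  D <- pathway_distance_matrix(unname(graphs), alpha)
  list(tree = neighbor_joining(D), distances = D)
}
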