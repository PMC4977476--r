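#' Decompose a pathway graph into modules
#'
#' Splits a pathway graph into modules — connected, disjoint subsets that
#' tend to be self-sufficient, keeping most of their edges internal — using
#' a degree-seeded synchronous label-propagation algorithm governed by a
#' single user factor `c`:
#'
#' 1. every node whose total degree is at least `c` *seeds* its own module;
#' 2. repeatedly, every still-unassigned node adjacent to at least one
#'    module joins (synchronously) the module to which it has the most
#'    edges — ties broken by the module containing its highest-degree
#'    neighbour, then by the module with the smallest member identifier;
#' 3. a connected component containing no seed becomes one whole module;
#' 4. isolated nodes become singleton modules.
#'
#' Legal values of `c` run from 1 to the highest total degree of a node in
#' the graph.  Small `c` produces many fine modules, large `c` few coarse
#' ones; the number of modules is non-increasing in `c`.  For an edge-free
#' graph the range check is vacuous and every node is a singleton module.
#'
#' @param graph a [pathway_graph()].
#' @param c integer modularization factor.
#' @return an object of class `module_set`: list with `species`, `modules`
#'   (list of sorted integer node-id vectors, ordered by smallest member
#'   identifier) and `member_view` (per module, the sorted union of member
#'   identifiers of its nodes).
#' @examples
#' g <- pathway_graph(data.frame(node_id = 1:3, node_class = "gene"),
#'                    data.frame(from = c(1, 2), to = c(2, 3)))
#' modularize(g, c = 2)
#' @export
modularize <- function(graph, c = 3L) {
  stopifnot(inherits(graph, "pathway_graph"))
  c <- as.integer(c)
  maxdeg <- max_total_degree(graph)
  if (nrow(graph$edges) > 0L && (is.na(c) || c < 1L || c > maxdeg)) {
    stop(sprintf("factor c = %s outside the legal interval [1, %d]", c, maxdeg),
         call. = FALSE)
  }
  ids <- graph$nodes$node_id
  n <- length(ids)
  if (n == 0L) {
    return(new_module_set(graph$species, list(), graph))
  }
  deg <- degree_vector(graph)
  adj <- adjacency_list(graph)

  # assignment: module index per node, NA while unassigned
  assign_vec <- rep(NA_integer_, n)
  names(assign_vec) <- as.character(ids)

  seeds <- ids[deg[as.character(ids)] >= c & deg[as.character(ids)] > 0L]
  if (nrow(graph$edges) == 0L) seeds <- integer(0)
  for (i in seq_along(seeds)) assign_vec[as.character(seeds[i])] <- i
  next_mod <- length(seeds) + 1L

  # smallest member identifier per node, for the final tie rule
  min_member <- vapply(graph$nodes$member_ids, function(m) {
    if (length(m)) min(m) else "￿"
  }, "")
  names(min_member) <- as.character(ids)

  # synchronous label propagation until no unassigned node touches a module
  repeat {
    un <- ids[is.na(assign_vec[as.character(ids)])]
    if (!length(un)) break
    # smallest member identifier currently in each module (for ties)
    mod_min_member <- tapply(min_member[!is.na(assign_vec)],
                             assign_vec[!is.na(assign_vec)], min)
    updates <- list()
    for (u in un) {
      nb <- adj[[as.character(u)]]
      if (is.null(nb)) next
      lab <- assign_vec[as.character(nb)]
      keep <- !is.na(lab)
      if (!any(keep)) next
      nb <- nb[keep]; lab <- lab[keep]
      cnt <- tapply(rep(1L, length(lab)), lab, sum)
      best <- as.integer(names(cnt)[cnt == max(cnt)])
      if (length(best) > 1L) {
        # module containing the highest-degree neighbour among the tied ones
        sel <- lab %in% best
        nbdeg <- deg[as.character(nb[sel])]
        top <- lab[sel][nbdeg == max(nbdeg)]
        best <- unique(as.integer(top))
        if (length(best) > 1L) {
          mm <- mod_min_member[as.character(best)]
          best <- best[order(mm, best)][1L]
        } else {
          best <- best[1L]
        }
      }
      updates[[as.character(u)]] <- best
    }
    if (!length(updates)) break
    for (u in names(updates)) assign_vec[u] <- updates[[u]]
  }

  # seedless components (incl. isolated nodes) become whole modules
  comps <- connected_components(graph)
  for (cp in comps) {
    a <- assign_vec[as.character(cp)]
    if (all(is.na(a))) {
      assign_vec[as.character(cp)] <- next_mod
      next_mod <- next_mod + 1L
    }
  }
  modules <- split(ids, assign_vec[as.character(ids)])
  modules <- lapply(modules, function(v) sort(as.integer(v)))
  new_module_set(graph$species, unname(modules), graph)
}

# order modules by smallest member identifier (then smallest node id) and
# attach the member view
new_module_set <- function(species, modules, graph) {
  member_of <- graph$nodes$member_ids
  names(member_of) <- as.character(graph$nodes$node_id)
  member_view <- lapply(modules, function(m) {
    sort(unique(unlist(member_of[as.character(m)], use.names = FALSE)))
  })
  if (length(modules)) {
    key1 <- vapply(member_view, function(m) if (length(m)) m[1L] else "￿", "")
    key2 <- vapply(modules, min, 1L)
    o <- order(key1, key2)
    modules <- modules[o]
    member_view <- member_view[o]
  }
  structure(list(species = species, modules = modules,
                 member_view = member_view),
            class = "module_set")
}

#' @export
print.module_set <- function(x, ...) {
  cat(sprintf("<module_set> species '%s': %d modules (sizes %s)\n",
              x$species, length(x$modules),
              paste(vapply(x$modules, length, 1L), collapse = ", ")))
  invisible(x)
}

#' Degenerate one-module decomposition
#'
#' Places the whole pathway in a single module — the natural control for
#' the module tree: distances reduce to one minus the Jaccard index of
#' the full member sets, discarding all modular structure.
#'
#' @param graph a [pathway_graph()].
#' @return a `module_set` with exactly one module (empty for an empty
#'   graph).
#' @export
single_module_set <- function(graph) {
  stopifnot(inherits(graph, "pathway_graph"))
  mods <- if (nrow(graph$nodes)) list(sort(graph$nodes$node_id)) else list()
  new_module_set(graph$species, mods, graph)
}

#' Number of modules in a module set
#' @param mset a `module_set` as returned by [modularize()].
#' @return non-negative integer.
#' @export
module_count <- function(mset) {
  stopifnot(inherits(mset, "module_set"))
  length(mset$modules)
}

#' Write a module set as a TSV table
#'
#' One row per (module, member identifier): columns `species`,
#' `module_index`, `member_id`.
#' @param mset a `module_set`.
#' @param file output path.
#' @export
write_modules_tsv <- function(mset, file) {
  stopifnot(inherits(mset, "module_set"))
  rows <- do.call(rbind, lapply(seq_along(mset$member_view), function(i) {
    mem <- mset$member_view[[i]]
    if (!length(mem)) mem <- NA_character_
    data.frame(species = mset$species, module_index = i, member_id = mem,
               stringsAsFactors = FALSE)
  }))
  if (is.null(rows)) {
    rows <- data.frame(species = character(0), module_index = integer(0),
                       member_id = character(0))
  }
  utils::write.table(rows, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
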