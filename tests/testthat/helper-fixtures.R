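# Shared fixtures and independent oracles.  Oracles are deliberately naive
# (explicit loops, exhaustive enumeration) and never call the code paths
# they check.

toy_graph <- function(edges, n = NULL, species = "toy", members = NULL) {
  ids <- if (is.null(n)) sort(unique(c(edges$from, edges$to))) else seq_len(n)
  nodes <- data.frame(node_id = ids, node_class = "gene")
  if (!is.null(members)) nodes$member_ids <- members
  pathway_graph(nodes, edges, species)
}

path_graph <- function(n, species = "path") {
  toy_graph(data.frame(from = seq_len(n - 1), to = 2:n), n = n,
            species = species)
}

# a module_set built directly from member sets (bypasses modularize so the
# distance stage can be exercised on arbitrary set systems)
manual_module_set <- function(species, member_sets) {
  structure(list(species = species,
                 modules = lapply(seq_along(member_sets), function(i) i),
                 member_view = lapply(member_sets, function(m) sort(unique(m)))),
            class = "module_set")
}

random_manual_mset <- function(species, universe = sprintf("K%03d", 1:30)) {
  k <- sample(1:5, 1)
  manual_module_set(species, lapply(seq_len(k), function(i) {
    sample(universe, sample(1:8, 1))
  }))
}

# --- brute-force module-distance oracle: explicit double loop over the grid
oracle_distance_matrix <- function(msets) {
  n <- length(msets)
  D <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      tot <- 0
      for (a in msets[[i]]$member_view) {
        for (b in msets[[j]]$member_view) {
          tot <- tot + length(intersect(a, b)) / length(union(a, b))
        }
      }
      D[i, j] <- 1 - tot / (length(msets[[i]]$member_view) *
                              length(msets[[j]]$member_view))
    }
  }
  D
}

# --- naive edge-correctness oracle: per-edge loop
oracle_edge_correctness <- function(G, H, mapping) {
  if (nrow(G$edges) == 0) return(1)
  hkeys <- character(0)
  for (k in seq_len(nrow(H$edges))) {
    a <- H$edges$from[k]; b <- H$edges$to[k]
    hkeys <- c(hkeys, paste(min(a, b), max(a, b)))
  }
  hit <- 0
  for (k in seq_len(nrow(G$edges))) {
    u <- mapping[as.character(G$edges$from[k])]
    v <- mapping[as.character(G$edges$to[k])]
    if (paste(min(u, v), max(u, v)) %in% hkeys) hit <- hit + 1
  }
  hit / nrow(G$edges)
}

# --- exhaustive orbit-count oracle: every node subset of size 2..5, VF2
# classification against the catalog (independent of the ESU/canonical-code
# implementation path)
oracle_orbit_counts <- function(graph) {
  cat <- graphlet_catalog()
  glets <- lapply(cat$graphlets, function(g) {
    igraph::graph_from_adjacency_matrix(g$A, mode = "undirected")
  })
  ids <- graph$nodes$node_id
  n <- length(ids)
  counts <- matrix(0L, n, cat$n_orbits,
                   dimnames = list(as.character(ids), NULL))
  if (n < 2) return(counts)
  A <- matrix(0L, n, n)
  for (k in seq_len(nrow(graph$edges))) {
    i <- match(graph$edges$from[k], ids); j <- match(graph$edges$to[k], ids)
    A[i, j] <- A[j, i] <- 1L
  }
  for (k in 2:min(5L, n)) {
    subs <- utils::combn(n, k)
    for (ci in seq_len(ncol(subs))) {
      S <- subs[, ci]
      AS <- A[S, S]
      gi <- igraph::graph_from_adjacency_matrix(AS, mode = "undirected")
      if (!igraph::is_connected(gi)) next
      m <- sum(AS) / 2
      for (t in seq_along(glets)) {
        g <- cat$graphlets[[t]]
        if (g$k != k || g$n_edges != m) next
        maps <- igraph::subgraph_isomorphisms(glets[[t]], gi, method = "vf2")
        if (!length(maps)) next
        mp <- as.integer(maps[[1]])      # pattern vertex v -> subgraph vertex
        for (v in seq_len(k)) {
          node <- S[mp[v]]
          orb <- g$orbit[v] + 1L
          counts[node, orb] <- counts[node, orb] + 1L
        }
        break
      }
    }
  }
  counts
}

# --- factorial branch-matching oracle: maximum over all padded bijections
oracle_matching_total <- function(T1, T2) {
  b1 <- bipartitions(T1); b2 <- bipartitions(T2)
  n1 <- length(b1); n2 <- length(b2)
  S <- matrix(0, n1, n2)
  for (i in seq_len(n1)) for (j in seq_len(n2)) {
    S[i, j] <- branch_score(b1[[i]], b2[[j]])
  }
  n <- max(n1, n2)
  Spad <- matrix(0, n, n)
  Spad[seq_len(n1), seq_len(n2)] <- S
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    }
    out
  }
  best <- -Inf
  for (p in perms(seq_len(n))) {
    best <- max(best, sum(Spad[cbind(seq_len(n), p)]))
  }
  best
}

# random connected pathway graph (retry over seeds)
random_connected_graph <- function(n, p, seed, species = "rnd") {
  repeat {
    g <- random_graph(n, p, seed, species = species)
    if (length(connected_components(g)) == 1) return(g)
    seed <- seed + 997
  }
}

# checks that a module_set is a partition of the graph into connected parts
expect_valid_partition <- function(mset, graph) {
  all_nodes <- sort(unlist(mset$modules))
  expect_identical(all_nodes, sort(graph$nodes$node_id))
  expect_false(anyDuplicated(all_nodes) > 0)
  ig <- as_igraph(graph)
  for (m in mset$modules) {
    sub <- igraph::induced_subgraph(ig, as.character(m))
    expect_true(igraph::is_connected(sub) || length(m) == 1)
  }
}
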