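#' Random pathway graph
#'
#' Erdős–Rényi-style simple graph with `n` gene nodes (members
#' `"K0001"`-style drawn from a global namespace) and each of the
#' \eqn{\binom{n}{2}} edges present independently with probability `p`;
#' fully reproducible from `seed`.
#'
#' @param n number of nodes.
#' @param p edge probability in \[0, 1\].
#' @param seed integer seed.
#' @param species species code.
#' @param member_offset members are named from `member_offset + 1`
#'   onwards, letting callers draw several graphs from one namespace.
#' @return a [pathway_graph()].
#' @export
random_graph <- function(n, p, seed, species = "sim", member_offset = 0L) {
  stopifnot(n >= 0, p >= 0, p <= 1)
  with_seed(seed, {
    nodes <- data.frame(node_id = seq_len(n), node_class = rep("gene", n))
    nodes$member_ids <- lapply(seq_len(n) + member_offset,
                               function(i) sprintf("K%04d", i))
    edges <- NULL
    if (n >= 2L) {
      prs <- utils::combn(n, 2L)
      keep <- stats::runif(ncol(prs)) < p
      edges <- data.frame(from = prs[1, keep], to = prs[2, keep])
    }
    pathway_graph(nodes, edges, species)
  })
}

#' Random planted phylogeny
#'
#' A random binary tree whose branch lengths are drawn uniformly from
#' `[min_len, max_len]`.  The defaults are sized against the default
#' gain/loss rates of [simulate_family()] (0.08 each per unit length) so
#' that every branch expects at least \eqn{30 \times 0.16 \approx 5}
#' events: the probability that a branch carries no event at all — in
#' which case no distance-based method could recover the corresponding
#' split — stays below about 1% per branch.
#'
#' @param n_leaves number of leaves (>= 3).
#' @param seed integer seed.
#' @param min_len,max_len branch-length range (units: evolutionary time
#'   such that `rate * length` is the expected event count per branch).
#' @return a rooted `phylo` tree with leaf labels `sp01, sp02, ...`.
#' @export
random_planted_tree <- function(n_leaves, seed, min_len = 30, max_len = 60) {
  stopifnot(n_leaves >= 3)
  with_seed(seed, {
    tree <- ape::rtree(n_leaves, rooted = TRUE,
                       tip.label = sprintf("sp%02d", seq_len(n_leaves)))
    tree$edge.length <- stats::runif(nrow(tree$edge), min_len, max_len)
    tree
  })
}

#' Simulate a pathway family along a known phylogeny
#'
#' Starts from a random connected ancestor pathway (regenerated until
#' connected) and evolves it down the planted tree.  On each branch of
#' length L, three Poisson event counts are drawn: node losses
#' (`Pois(loss_rate * L)`; the node and its incident edges are removed),
#' node gains (`Pois(gain_rate * L)`; a brand-new member from the shared
#' namespace is attached to 1–3 existing nodes chosen preferentially in
#' proportion to degree + 1, keeping hubs hub-like) and edge rewires
#' (`Pois(rewire_rate * L)`; one endpoint of a random edge is moved).
#' Member identifiers are global, so module overlap between leaves is
#' exact set intersection by construction.
#'
#' @param planted_tree rooted `phylo` with branch lengths (e.g. from
#'   [random_planted_tree()]).
#' @param ancestor_size nodes in the ancestor graph.
#' @param ancestor_density edge probability of the ancestor graph.
#' @param loss_rate,gain_rate,rewire_rate expected events per unit branch
#'   length.
#' @param seed integer seed; the whole family is reproducible from it.
#' @return object of class `pathway_family`: list with `planted_tree`,
#'   `graphs` (one [pathway_graph()] per leaf, species = leaf label),
#'   `ancestor`, and `events` (per-branch event log).
#' @export
simulate_family <- function(planted_tree, ancestor_size = 40,
                            ancestor_density = 0.15,
                            loss_rate = 0.08, gain_rate = 0.08,
                            rewire_rate = 0, seed = 1L) {
  stopifnot(inherits(planted_tree, "phylo"),
            !is.null(planted_tree$edge.length),
            length(planted_tree$tip.label) >= 3L,
            loss_rate >= 0, gain_rate >= 0, rewire_rate >= 0)
  with_seed(seed, {
    ancestor <- NULL
    for (try in 1:50) {
      g <- random_graph(ancestor_size, ancestor_density,
                        seed = stats::runif(1, 1, 2^30), species = "ancestor")
      if (length(connected_components(g)) == 1L) { ancestor <- g; break }
    }
    if (is.null(ancestor)) {
      stop("could not generate a connected ancestor; raise ancestor_density",
           call. = FALSE)
    }
    next_member <- ancestor_size + 1L
    next_node <- ancestor_size + 1L

    evolve_branch <- function(graph, len, branch_label) {
      log <- list(branch = branch_label, lost = character(0),
                  gained = character(0), rewired = 0L)
      n_loss <- stats::rpois(1, loss_rate * len)
      n_gain <- stats::rpois(1, gain_rate * len)
      n_rew <- stats::rpois(1, rewire_rate * len)
      for (k in seq_len(n_loss)) {
        if (nrow(graph$nodes) <= 1L) {
          stop("pathway emptied by losses; lower loss_rate or branch lengths",
               call. = FALSE)
        }
        victim <- sample(graph$nodes$node_id, 1L)
        log$lost <- c(log$lost, unlist(
          graph$nodes$member_ids[graph$nodes$node_id == victim]))
        keep <- graph$nodes$node_id != victim
        edges <- graph$edges[graph$edges$from != victim &
                               graph$edges$to != victim, , drop = FALSE]
        graph <- pathway_graph(graph$nodes[keep, , drop = FALSE], edges,
                               graph$species)
      }
      for (k in seq_len(n_gain)) {
        member <- sprintf("K%04d", next_member)
        next_member <<- next_member + 1L
        node_id <- next_node
        next_node <<- next_node + 1L
        deg <- degree_vector(graph)
        n_att <- min(sample(1:3, 1L), nrow(graph$nodes))
        targets <- if (nrow(graph$nodes) == 1L) graph$nodes$node_id else
          sample(graph$nodes$node_id, n_att,
                 prob = deg[as.character(graph$nodes$node_id)] + 1)
        nodes <- rbind(graph$nodes,
                       data.frame(node_id = node_id, node_class = "gene",
                                  member_ids = I(list(member))))
        edges <- rbind(graph$edges,
                       data.frame(from = targets, to = node_id,
                                  subtype = NA_character_))
        graph <- pathway_graph(nodes, edges, graph$species)
        log$gained <- c(log$gained, member)
      }
      for (k in seq_len(n_rew)) {
        if (nrow(graph$edges) < 1L || nrow(graph$nodes) < 3L) break
        e <- sample(nrow(graph$edges), 1L)
        keepend <- sample(c(graph$edges$from[e], graph$edges$to[e]), 1L)
        candidates <- setdiff(graph$nodes$node_id,
                              c(graph$edges$from[e], graph$edges$to[e]))
        newend <- if (length(candidates) == 1L) candidates else
          sample(candidates, 1L)
        edges <- graph$edges
        edges$from[e] <- keepend
        edges$to[e] <- newend
        graph <- pathway_graph(graph$nodes, edges, graph$species)
        log$rewired <- log$rewired + 1L
      }
      list(graph = graph, log = log)
    }

    tree <- planted_tree
    ntip <- length(tree$tip.label)
    root <- ntip + 1L
    state <- vector("list", ntip + tree$Nnode)
    state[[root]] <- ancestor
    events <- list()
    ord <- ape::reorder.phylo(tree, "cladewise")
    for (k in seq_len(nrow(ord$edge))) {
      parent <- ord$edge[k, 1]; child <- ord$edge[k, 2]
      lab <- if (child <= ntip) tree$tip.label[child] else paste0("node", child)
      res <- evolve_branch(state[[parent]], ord$edge.length[k], lab)
      state[[child]] <- res$graph
      events[[lab]] <- res$log
    }
    graphs <- lapply(seq_len(ntip), function(i) {
      g <- state[[i]]
      g$species <- tree$tip.label[i]
      g
    })
    names(graphs) <- tree$tip.label
    structure(list(planted_tree = tree, graphs = graphs,
                   ancestor = ancestor, events = events),
              class = "pathway_family")
  })
}

#' @export
print.pathway_family <- function(x, ...) {
  cat(sprintf("<pathway_family> %d leaves; ancestor %d nodes / %d edges\n",
              length(x$graphs), nrow(x$ancestor$nodes), nrow(x$ancestor$edges)))
  invisible(x)
}

#' Write a simulated family to disk
#'
#' One KGML file per leaf, the planted tree as Newick and the event log as
#' JSON — a self-contained, fully synthetic input set for the module-tree
#' pipeline.
#'
#' @param family a `pathway_family` from [simulate_family()].
#' @param dir output directory (created if missing).
#' @return invisibly, the vector of files written.
#' @export
write_family <- function(family, dir) {
  stopifnot(inherits(family, "pathway_family"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  for (sp in names(family$graphs)) {
    f <- file.path(dir, paste0(sp, ".xml"))
    emit_kgml(family$graphs[[sp]], pathway_name = paste0("synthetic:", sp),
              file = f)
    files <- c(files, f)
  }
  tf <- file.path(dir, "planted_tree.nwk")
  write_newick(family$planted_tree, tf)
  ef <- file.path(dir, "events.json")
  jsonlite::write_json(family$events, ef, auto_unbox = TRUE, pretty = TRUE)
  invisible(c(files, tf, ef))
}
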