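#' Seed-and-extend global network alignment
#'
#' Embeds the smaller pathway graph `G` into the larger `H` with a greedy
#' seed-and-extend strategy driven by graphlet degree signatures.  The
#' cost of aligning nodes u of G and v of H blends degrees and signature
#' similarity,
#' \deqn{cost(u, v) = 2 - [(1 - \alpha)(deg(u) + deg(v)) /
#'   (maxdeg(G) + maxdeg(H)) + \alpha \, sim(u, v)],}
#' so that high-degree, topologically similar pairs are cheap.  The
#' alignment seeds at the cheapest pair, then walks both graphs breadth
#' first: nodes at equal distance r from the two seeds are paired greedily
#' in order of cost (ties: smaller degree gap, then smallest node-id
#' pair).  When spheres are exhausted and unaligned nodes remain (other
#' components, or H too small locally), a new seed is chosen among the
#' unaligned pairs and the extension repeats; components of G are
#' processed in decreasing size, and any leftover nodes are matched
#' greedily by cost alone.  Every node of G ends up aligned to exactly one
#' node of H; the procedure is deterministic.
#'
#' @param G,H [pathway_graph()] objects with `n_nodes(G) <= n_nodes(H)`
#'   (see [pathway_distance()] for the symmetric wrapper).
#' @param alpha balance between degree term and signature term, in
#'   \[0, 1\]; default 0.8 (mostly signature-driven).
#' @return list of class `pathway_alignment`: `mapping` (named integer
#'   vector, names = G node ids, values = H node ids), `edge_correctness`,
#'   `alpha`.
#' @export
align_graphs <- function(G, H, alpha = 0.8) {
  stopifnot(inherits(G, "pathway_graph"), inherits(H, "pathway_graph"))
  if (n_nodes(G) == 0L) stop("cannot align an empty graph", call. = FALSE)
  if (n_nodes(G) > n_nodes(H)) {
    stop("G must not have more nodes than H; use pathway_distance() for the ",
         "symmetric wrapper", call. = FALSE)
  }
  idsG <- G$nodes$node_id
  idsH <- H$nodes$node_id
  degG <- degree_vector(G)
  degH <- degree_vector(H)
  sigG <- orbit_counts(G)
  sigH <- orbit_counts(H)
  sim <- signature_similarity_matrix(sigG, sigH)
  maxsum <- max(degG, 1L) + max(degH, 1L)
  degterm <- outer(degG, degH, "+") / maxsum
  cost <- 2 - ((1 - alpha) * degterm + alpha * sim)
  dimnames(cost) <- list(as.character(idsG), as.character(idsH))
  gapmat <- abs(outer(degG, degH, "-"))

  igG <- as_igraph(G)
  igH <- as_igraph(H)
  distG <- igraph::distances(igG)
  distH <- igraph::distances(igH)
  dimnames(distG) <- list(as.character(idsG), as.character(idsG))
  dimnames(distH) <- list(as.character(idsH), as.character(idsH))

  mapping <- stats::setNames(rep(NA_integer_, length(idsG)),
                             as.character(idsG))
  freeH <- as.character(idsH)

  # deterministic pick of the cheapest pair from a cost submatrix
  pick_pair <- function(rows, cols) {
    cm <- cost[rows, cols, drop = FALSE]
    m <- min(cm)
    hits <- which(cm <= m + 1e-12, arr.ind = TRUE)
    if (nrow(hits) > 1L) {
      gaps <- gapmat[cbind(match(rows[hits[, 1]], as.character(idsG)),
                           match(cols[hits[, 2]], as.character(idsH)))]
      hits <- hits[gaps == min(gaps), , drop = FALSE]
      o <- order(as.integer(rows[hits[, 1]]), as.integer(cols[hits[, 2]]))
      hits <- hits[o, , drop = FALSE]
    }
    c(rows[hits[1, 1]], cols[hits[1, 2]])
  }

  comps <- connected_components(G)
  comps <- comps[order(-vapply(comps, length, 1L), vapply(comps, min, 1L))]

  for (comp in comps) {
    compch <- as.character(comp)
    while (any(is.na(mapping[compch]))) {
      un <- compch[is.na(mapping[compch])]
      if (!length(freeH)) break
      seed <- pick_pair(un, freeH)
      mapping[seed[1]] <- as.integer(seed[2])
      freeH <- setdiff(freeH, seed[2])
      r <- 1
      repeat {
        sg <- un[distG[seed[1], un] == r & is.na(mapping[un])]
        sh <- freeH[is.finite(distH[seed[2], freeH]) &
                      distH[seed[2], freeH] == r]
        if (!length(sg)) {
          if (all(!is.finite(distG[seed[1], un]) | distG[seed[1], un] <= r) ||
              !length(freeH)) break
          r <- r + 1
          next
        }
        while (length(sg) && length(sh)) {
          pr <- pick_pair(sg, sh)
          mapping[pr[1]] <- as.integer(pr[2])
          freeH <- setdiff(freeH, pr[2])
          sg <- setdiff(sg, pr[1])
          sh <- setdiff(sh, pr[2])
        }
        r <- r + 1
        if (r > max(distG[seed[1], un][is.finite(distG[seed[1], un])], 0)) break
      }
    }
  }
  # safety net: greedy by cost for anything still unaligned
  while (anyNA(mapping) && length(freeH)) {
    un <- names(mapping)[is.na(mapping)]
    pr <- pick_pair(un, freeH)
    mapping[pr[1]] <- as.integer(pr[2])
    freeH <- setdiff(freeH, pr[2])
  }
  ec <- edge_correctness(G, H, mapping)
  structure(list(mapping = mapping, edge_correctness = ec, alpha = alpha),
            class = "pathway_alignment")
}

#' @export
print.pathway_alignment <- function(x, ...) {
  cat(sprintf("<pathway_alignment> %d nodes aligned, EC = %.4f (alpha = %g)\n",
              length(x$mapping), x$edge_correctness, x$alpha))
  invisible(x)
}

#' Edge correctness of an alignment
#'
#' The fraction of edges of G whose images under the mapping are edges of
#' H.  Graphs with zero edges score 1 by convention (with a warning): the
#' condition is vacuously satisfied.
#'
#' @param G,H [pathway_graph()] objects.
#' @param mapping named integer vector (names = all node ids of G, values
#'   = distinct node ids of H).
#' @return a number in \[0, 1\].
#' @export
edge_correctness <- function(G, H, mapping) {
  stopifnot(inherits(G, "pathway_graph"), inherits(H, "pathway_graph"))
  idsG <- as.character(G$nodes$node_id)
  if (anyNA(mapping) || !setequal(names(mapping), idsG)) {
    stop("mapping must be total on the nodes of G", call. = FALSE)
  }
  if (anyDuplicated(mapping)) {
    stop("mapping must be injective", call. = FALSE)
  }
  if (!all(mapping %in% H$nodes$node_id)) {
    stop("mapping targets unknown nodes of H", call. = FALSE)
  }
  if (nrow(G$edges) == 0L) {
    warning("edge-free graph: edge correctness is 1 by convention",
            call. = FALSE)
    return(1)
  }
  ekey <- paste(pmin(H$edges$from, H$edges$to),
                pmax(H$edges$from, H$edges$to))
  fu <- mapping[as.character(G$edges$from)]
  fv <- mapping[as.character(G$edges$to)]
  mean(paste(pmin(fu, fv), pmax(fu, fv)) %in% ekey)
}

#' Topological pathway distance
#'
#' \eqn{D_P(x, y) = 1 - S_P(x, y)} where the topological similarity
#' \eqn{S_P} is the edge correctness of the seed-and-extend alignment of
#' the smaller graph into the larger.  Symmetric by construction: the
#' smaller graph is always the one embedded.
#'
#' @inheritParams align_graphs
#' @return a number in \[0, 1\].
#' @export
pathway_distance <- function(G, H, alpha = 0.8) {
  if (n_nodes(G) > n_nodes(H)) {
    tmp <- G; G <- H; H <- tmp
  }
  1 - align_graphs(G, H, alpha)$edge_correctness
}

#' All-pairs pathway (topology) distance matrix
#'
#' @param graphs list of [pathway_graph()] objects with distinct species.
#' @param alpha see [align_graphs()].
#' @return symmetric matrix with zero diagonal, provenance
#'   `"pathway-topology"`.
#' @export
pathway_distance_matrix <- function(graphs, alpha = 0.8) {
  species <- vapply(graphs, function(g) g$species, "")
  if (anyDuplicated(species)) {
    stop("duplicate species codes: ",
         paste(unique(species[duplicated(species)]), collapse = ", "),
         call. = FALSE)
  }
  n <- length(graphs)
  D <- matrix(0, n, n, dimnames = list(species, species))
  if (n > 1L) {
    for (i in 1:(n - 1L)) {
      for (j in (i + 1L):n) {
        d <- pathway_distance(graphs[[i]], graphs[[j]], alpha)
        D[i, j] <- d; D[j, i] <- d
      }
    }
  }
  attr(D, "provenance") <- "pathway-topology"
  D
}
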