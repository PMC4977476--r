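# Graphlet machinery.
#
# Graphlets are the 30 connected non-isomorphic graphs on 2-5 nodes; their
# nodes fall into 73 automorphism orbits.  The catalog (graphlets, orbits,
# canonical forms, orbit weights) is generated in code at first use and
# cached for the session: graphlets are enumerated exhaustively per size,
# canonicalized by the minimum adjacency bit-code over all vertex
# permutations, and ordered by (node count, edge count, descending degree
# sequence, canonical code); orbits within a graphlet are ordered by
# (degree, sorted neighbour degrees, triangle count, canonical position).
# This deterministic numbering reproduces the conventional indices for
# orbits 0-14 (edge, path, triangle, the six 4-node graphlets); in
# particular orbit 0 counts edge endpoints, so every node's orbit-0 count
# equals its degree.

.pmt_cache <- new.env(parent = emptyenv())

# pair indexing: columns of combn(k, 2) in order (1,2),(1,3),...,(2,3),...
pair_index <- function(k) {
  prs <- utils::combn(k, 2L)
  POS <- matrix(0L, k, k)
  for (t in seq_len(ncol(prs))) {
    POS[prs[1, t], prs[2, t]] <- t
    POS[prs[2, t], prs[1, t]] <- t
  }
  list(pairs = prs, POS = POS, npair = ncol(prs))
}

all_perms <- function(k) {
  if (k == 1L) return(matrix(1L, 1, 1))
  sub <- all_perms(k - 1L)
  out <- matrix(0L, 0, k)
  for (i in seq_len(k)) {
    block <- cbind(i, sub + (sub >= i))
    out <- rbind(out, block)
  }
  out
}

adj_from_bits <- function(bits, k, pi) {
  A <- matrix(0L, k, k)
  on <- which(bits)
  for (t in on) {
    i <- pi$pairs[1, t]; j <- pi$pairs[2, t]
    A[i, j] <- 1L; A[j, i] <- 1L
  }
  A
}

is_connected_adj <- function(A) {
  k <- nrow(A)
  seen <- logical(k)
  seen[1] <- TRUE
  frontier <- 1L
  while (length(frontier)) {
    nb <- which(colSums(A[frontier, , drop = FALSE]) > 0L & !seen)
    seen[nb] <- TRUE
    frontier <- nb
  }
  all(seen)
}

# per-size machinery: permutations, pair remap weights for canonical codes
size_tables <- function(k) {
  key <- paste0("size", k)
  if (!is.null(.pmt_cache[[key]])) return(.pmt_cache[[key]])
  pi <- pair_index(k)
  P <- all_perms(k)
  PM <- matrix(0L, nrow(P), pi$npair)
  for (p in seq_len(nrow(P))) {
    for (t in seq_len(pi$npair)) {
      PM[p, t] <- pi$POS[P[p, pi$pairs[1, t]], P[p, pi$pairs[2, t]]]
    }
  }
  W <- matrix(2 ^ (PM - 1L), nrow(P), pi$npair)
  res <- list(pi = pi, perms = P, PM = PM, W = W)
  .pmt_cache[[key]] <- res
  res
}

canonical_code <- function(bits, st) {
  codes <- as.vector(st$W %*% bits)
  list(code = min(codes), perm = st$perms[which.min(codes), ])
}

#' The graphlet/orbit catalog
#'
#' Builds (once per session) the catalog of all connected 2-5-node
#' graphlets and their automorphism orbits, together with the per-orbit
#' weights used by [signature_similarity()].
#'
#' @return list with elements `graphlets` (list of 30 records: `k`,
#'   `n_edges`, adjacency `A`, canonical `code`, `orbit` giving the global
#'   orbit id of each canonical vertex), `n_orbits` (73), `orbit_degree`,
#'   `orbit_weight` and `orbit_affect_counts`.
#' @export
graphlet_catalog <- function() {
  if (!is.null(.pmt_cache$catalog)) return(.pmt_cache$catalog)

  graphlets <- list()
  for (k in 2:5) {
    st <- size_tables(k)
    seen <- new.env(parent = emptyenv())
    for (code in seq_len(2 ^ st$pi$npair) - 1L) {
      bits <- as.integer(intToBits(code)[seq_len(st$pi$npair)]) > 0L
      if (sum(bits) < k - 1L) next
      A <- adj_from_bits(bits, k, st$pi)
      if (!is_connected_adj(A)) next
      canon <- canonical_code(bits, st)
      ckey <- paste0(k, ":", canon$code)
      if (is.null(seen[[ckey]])) {
        # representative = the graph realizing the minimum code
        cbits <- as.integer(intToBits(canon$code)[seq_len(st$pi$npair)]) > 0L
        CA <- adj_from_bits(cbits, k, st$pi)
        seen[[ckey]] <- TRUE
        graphlets[[length(graphlets) + 1L]] <-
          list(k = k, n_edges = sum(cbits), A = CA, bits = cbits,
               code = canon$code)
      }
    }
  }
  # deterministic graphlet order
  ord_key <- lapply(graphlets, function(g) {
    degs <- sort(rowSums(g$A), decreasing = TRUE)
    c(g$k, g$n_edges, degs, rep(0, 5 - g$k), g$code)
  })
  ord <- do.call(order, as.data.frame(do.call(rbind, ord_key)))
  graphlets <- graphlets[ord]
  stopifnot(length(graphlets) == 30L)

  # orbits: automorphism classes per graphlet, globally numbered
  next_orbit <- 0L
  orbit_degree <- integer(0)
  for (gi in seq_along(graphlets)) {
    g <- graphlets[[gi]]
    st <- size_tables(g$k)
    parent <- seq_len(g$k)
    find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
    for (p in seq_len(nrow(st$perms))) {
      # automorphism iff permuting the bit vector leaves it unchanged
      if (all(g$bits[st$PM[p, ]] == g$bits)) {
        for (v in seq_len(g$k)) {
          a <- find(v); b <- find(st$perms[p, v])
          if (a != b) parent[a] <- b
        }
      }
    }
    cls <- vapply(seq_len(g$k), find, 1L)
    degs <- rowSums(g$A)
    A2 <- g$A %*% g$A
    tri <- diag(A2 %*% g$A) / 2
    nbr_key <- vapply(seq_len(g$k), function(v) {
      paste(sprintf("%02d", sort(degs[g$A[v, ] > 0])), collapse = "")
    }, "")
    reps <- sort(unique(cls))
    okey <- lapply(reps, function(r) {
      v <- which(cls == r)[1]
      c(degs[v], tri[v], min(which(cls == r)))
    })
    # order orbits by degree, neighbour degrees, triangles, position
    okey_str <- vapply(reps, function(r) {
      v <- which(cls == r)[1]
      paste(sprintf("%02d", degs[v]), nbr_key[v],
            sprintf("%02d", tri[v]), sprintf("%02d", min(which(cls == r))))
    }, "")
    reps <- reps[order(okey_str)]
    orbit_of_vertex <- integer(g$k)
    for (r in reps) {
      orbit_of_vertex[cls == r] <- next_orbit
      orbit_degree <- c(orbit_degree, degs[which(cls == r)[1]])
      next_orbit <- next_orbit + 1L
    }
    graphlets[[gi]]$orbit <- orbit_of_vertex
  }
  n_orbits <- next_orbit
  stopifnot(n_orbits == 73L)

  # "affects" relation: orbit j affects orbit i when the graphlet of j
  # embeds as a (partial) subgraph of the graphlet of i with a node of
  # orbit j landing on a node of orbit i
  affects <- matrix(FALSE, n_orbits, n_orbits)   # [j, i]
  for (ga in seq_along(graphlets)) {     # small graphlet (source, orbit j)
    for (gb in seq_along(graphlets)) {   # large graphlet (target, orbit i)
      gj <- graphlets[[ga]]; gi <- graphlets[[gb]]
      if (gj$k > gi$k) next
      ste <- size_tables(gj$k)
      edge_pairs <- which(gj$bits)
      e1 <- ste$pi$pairs[1, edge_pairs]; e2 <- ste$pi$pairs[2, edge_pairs]
      subsets <- utils::combn(gi$k, gj$k)
      permsj <- all_perms(gj$k)
      for (s in seq_len(ncol(subsets))) {
        for (p in seq_len(nrow(permsj))) {
          map <- subsets[permsj[p, ], s]
          if (all(gi$A[cbind(map[e1], map[e2])] == 1L)) {
            affects[cbind(gj$orbit + 1L, gi$orbit[map] + 1L)] <- TRUE
          }
        }
      }
    }
  }
  o <- colSums(affects)
  weight <- 1 - log(o) / log(n_orbits)

  codemap <- new.env(parent = emptyenv())
  for (gi in seq_along(graphlets)) {
    g <- graphlets[[gi]]
    codemap[[paste0(g$k, ":", g$code)]] <- gi
  }

  .pmt_cache$catalog <- list(graphlets = graphlets, n_orbits = n_orbits,
                             orbit_degree = orbit_degree,
                             orbit_affect_counts = o,
                             orbit_weight = weight, codemap = codemap)
  .pmt_cache$catalog
}

# ESU (exclusive-neighbourhood) enumeration of all connected induced
# subgraphs on 2..5 nodes; calls visit(subset_sorted, bits) per subgraph.
esu_enumerate <- function(adjmat, visit) {
  n <- nrow(adjmat)
  if (n < 2L) return(invisible(NULL))
  nbrs <- lapply(seq_len(n), function(v) which(adjmat[v, ] > 0L))
  sts <- lapply(2:5, size_tables)
  recurse <- function(sub, ext, v) {
    s <- length(sub)
    if (s >= 2L) {
      S <- sort(sub)
      st <- sts[[s - 1L]]
      bits <- adjmat[cbind(S[st$pi$pairs[1, ]], S[st$pi$pairs[2, ]])] > 0L
      visit(S, bits, st)
    }
    if (s == 5L || !length(ext)) return(invisible(NULL))
    closed <- c(sub, unlist(nbrs[sub], use.names = FALSE))
    while (length(ext)) {
      w <- ext[1L]
      ext <- ext[-1L]
      excl <- setdiff(nbrs[[w]], closed)
      recurse(c(sub, w), c(ext, excl[excl > v]), v)
    }
  }
  for (v in seq_len(n)) {
    recurse(v, nbrs[[v]][nbrs[[v]] > v], v)
  }
  invisible(NULL)
}

#' Graphlet degree signatures of every node
#'
#' Counts, for every node, the number of times it appears in each of the 73
#' automorphism orbits of the connected 2-5-node graphlets (induced
#' subgraphs).  Orbit 0 counts edge endpoints, so the first column equals
#' the degree vector.
#'
#' @param graph a [pathway_graph()].
#' @return integer matrix (nodes x 73) with rownames the node ids.
#' @export
orbit_counts <- function(graph) {
  stopifnot(inherits(graph, "pathway_graph"))
  cat <- graphlet_catalog()
  ids <- graph$nodes$node_id
  n <- length(ids)
  counts <- matrix(0L, n, cat$n_orbits,
                   dimnames = list(as.character(ids), NULL))
  if (n == 0L) return(counts)
  A <- matrix(0L, n, n)
  if (nrow(graph$edges)) {
    ii <- match(graph$edges$from, ids)
    jj <- match(graph$edges$to, ids)
    A[cbind(ii, jj)] <- 1L
    A[cbind(jj, ii)] <- 1L
  }
  visit <- function(S, bits, st) {
    codes <- as.vector(st$W %*% bits)
    best <- which.min(codes)
    gi <- cat$codemap[[paste0(length(S), ":", codes[best])]]
    orb <- cat$graphlets[[gi]]$orbit[st$perms[best, ]] + 1L
    counts[cbind(S, orb)] <<- counts[cbind(S, orb)] + 1L
  }
  esu_enumerate(A, visit)
  counts
}

#' Graphlet signature similarity between two nodes
#'
#' Compares two 73-orbit graphlet degree vectors with the weighted
#' logarithmic distance scheme of graphlet-based network alignment: the
#' per-orbit distance is
#' \deqn{d_i = w_i |log(u_i + 1) - log(v_i + 1)| / log(max(u_i, v_i) + 2)}
#' with orbit weights \eqn{w_i = 1 - log(o_i)/log(73)}, where \eqn{o_i} is
#' the number of orbits that affect orbit i (computed from the subgraph
#' relation between graphlets); the similarity is
#' \eqn{1 - \sum d_i / \sum w_i}, in \[0, 1\], equal to 1 for identical
#' signatures.
#'
#' @param sig_u,sig_v numeric vectors of length 73 (rows of
#'   [orbit_counts()]).
#' @return a number in \[0, 1\].
#' @export
signature_similarity <- function(sig_u, sig_v) {
  cat <- graphlet_catalog()
  if (length(sig_u) != cat$n_orbits || length(sig_v) != cat$n_orbits) {
    stop("signatures must have length ", cat$n_orbits, call. = FALSE)
  }
  w <- cat$orbit_weight
  d <- w * abs(log(sig_u + 1) - log(sig_v + 1)) / log(pmax(sig_u, sig_v) + 2)
  1 - sum(d) / sum(w)
}

# all-pairs signature similarity: rows of su vs rows of sv
signature_similarity_matrix <- function(su, sv) {
  cat <- graphlet_catalog()
  w <- cat$orbit_weight
  sw <- sum(w)
  lu <- log(su + 1); lv <- log(sv + 1)
  out <- matrix(0, nrow(su), nrow(sv),
                dimnames = list(rownames(su), rownames(sv)))
  for (i in seq_len(nrow(su))) {
    num <- abs(sweep(lv, 2, lu[i, ], "-"))
    den <- log(pmax(matrix(su[i, ], nrow(sv), ncol(sv), byrow = TRUE), sv) + 2)
    out[i, ] <- 1 - as.vector((num / den) %*% w) / sw
  }
  out
}
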