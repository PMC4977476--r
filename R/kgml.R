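#' Parse a KGML pathway document into a pathway graph
#'
#' Reads a KEGG Markup Language file (`<pathway>` with `<entry>` and
#' `<relation>` elements) and returns the species-specific pathway as an
#' undirected simple [pathway_graph()]:
#'
#' * `gene` and `ortholog` entries always become nodes; `compound` entries
#'   only when `include_compounds = TRUE`; `map` and `enzyme` entries are
#'   dropped (pathway links and legacy annotations carry no member
#'   identity);
#' * `group` entries (complexes) are expanded: the group is replaced by its
#'   component entries connected as a clique, and every relation touching
#'   the group is re-attached to all components;
#' * relations are collapsed to undirected simple edges (duplicates merged,
#'   self-relations dropped); the first relation subtype is kept as an edge
#'   tag but ignored by all computations; `maplink` relations are dropped;
#' * each entry's whitespace-separated name tokens become the node's
#'   member identifiers.  Without a namespace map the species prefix
#'   (`"hsa:"`-style) is stripped so that identical accession tokens match
#'   across species; with a namespace map (e.g. an orthology table) tokens
#'   are translated through it.
#'
#' @param file path to a KGML file, or an `xml2` document.
#' @param include_compounds keep compound entries as nodes?
#' @param namespace optional namespace map from [read_namespace_map()] (a
#'   named character vector `local id -> member id`), applied to gene-class
#'   member identifiers.
#' @param strict if `TRUE`, relations referencing unknown entries and (with
#'   a namespace) unmapped gene identifiers are errors; otherwise they are
#'   skipped with a warning.
#' @return a [pathway_graph()]; the species code is taken from the pathway
#'   `org` attribute (falling back to `name`).
#' @export
parse_kgml <- function(file, include_compounds = FALSE, namespace = NULL,
                       strict = TRUE) {
  doc <- if (inherits(file, "xml_document")) file else {
    tryCatch(xml2::read_xml(file),
             error = function(e) stop("malformed KGML document: ",
                                      conditionMessage(e), call. = FALSE))
  }
  root <- xml2::xml_find_first(doc, "//pathway")
  if (is.na(xml2::xml_name(root)) || xml2::xml_name(root) != "pathway") {
    stop("malformed KGML: no <pathway> element", call. = FALSE)
  }
  species <- xml2::xml_attr(root, "org")
  if (is.na(species)) species <- xml2::xml_attr(root, "name")
  if (is.na(species)) species <- "unknown"

  entries <- xml2::xml_find_all(root, "entry")
  ent_id <- as.integer(xml2::xml_attr(entries, "id"))
  ent_type <- xml2::xml_attr(entries, "type")
  ent_name <- xml2::xml_attr(entries, "name")
  if (anyDuplicated(ent_id)) {
    stop("malformed KGML: duplicate entry id ",
         paste(unique(ent_id[duplicated(ent_id)]), collapse = ", "),
         call. = FALSE)
  }

  keep_class <- function(type) {
    switch(type,
           gene = "gene", ortholog = "gene",
           compound = if (include_compounds) "compound" else NA_character_,
           group = "group",
           NA_character_)           # map, enzyme, brite, other -> dropped
  }
  cls <- vapply(ent_type, keep_class, "", USE.NAMES = FALSE)

  # group expansion: group id -> component entry ids (recursively flattened)
  comp_of <- list()
  for (k in seq_along(entries)) {
    if (identical(cls[k], "group")) {
      comp <- xml2::xml_find_all(entries[[k]], "component")
      comp_of[[as.character(ent_id[k])]] <-
        as.integer(xml2::xml_attr(comp, "id"))
      if (!length(comp_of[[as.character(ent_id[k])]])) {
        stop("malformed KGML: group entry ", ent_id[k], " has no components",
             call. = FALSE)
      }
    }
  }
  flatten_group <- function(id, seen = integer(0)) {
    key <- as.character(id)
    if (!key %in% names(comp_of)) return(id)
    if (id %in% seen) stop("malformed KGML: cyclic group nesting at entry ",
                           id, call. = FALSE)
    unlist(lapply(comp_of[[key]], flatten_group, seen = c(seen, id)))
  }

  retained <- ent_id[!is.na(cls) & cls != "group"]
  class_of <- cls[!is.na(cls) & cls != "group"]
  names(class_of) <- as.character(retained)

  # member identifiers from name tokens
  member_of <- list()
  for (k in seq_along(entries)) {
    if (ent_id[k] %in% retained) {
      toks <- strsplit(trimws(ent_name[k] %||% ""), "\\s+")[[1]]
      toks <- toks[nzchar(toks) & toks != "undefined"]
      if (is.null(namespace)) {
        toks <- sub("^[A-Za-z0-9]{2,4}:", "", toks)
      } else if (class_of[as.character(ent_id[k])] == "gene") {
        hit <- namespace[toks]
        if (anyNA(hit)) {
          missing_ids <- toks[is.na(hit)]
          if (strict) {
            stop("namespace map does not cover: ",
                 paste(missing_ids, collapse = ", "), call. = FALSE)
          }
          warning("unmapped identifiers kept verbatim: ",
                  paste(missing_ids, collapse = ", "), call. = FALSE)
          hit[is.na(hit)] <- missing_ids
        }
        toks <- unname(hit)
      }
      if (!length(toks)) {
        if (class_of[as.character(ent_id[k])] == "gene") {
          stop("malformed KGML: gene entry ", ent_id[k], " has no name tokens",
               call. = FALSE)
        }
        toks <- paste0("cpd_", ent_id[k])
      }
      member_of[[as.character(ent_id[k])]] <- unique(toks)
    }
  }

  edges_from <- integer(0); edges_to <- integer(0); edges_sub <- character(0)
  add_edge <- function(a, b, subtype) {
    edges_from <<- c(edges_from, a)
    edges_to <<- c(edges_to, b)
    edges_sub <<- c(edges_sub, subtype)
  }

  # clique among members of each group
  group_derived <- integer(0)
  for (gid in names(comp_of)) {
    mem <- intersect(flatten_group(as.integer(gid)), retained)
    group_derived <- c(group_derived, mem)
    if (length(mem) >= 2L) {
      prs <- utils::combn(sort(mem), 2L)
      for (k in seq_len(ncol(prs))) add_edge(prs[1, k], prs[2, k], "group")
    }
  }

  relations <- xml2::xml_find_all(root, "relation")
  expand_end <- function(id) intersect(flatten_group(id), retained)
  for (rel in relations) {
    rtype <- xml2::xml_attr(rel, "type")
    if (identical(rtype, "maplink")) next
    e1 <- as.integer(xml2::xml_attr(rel, "entry1"))
    e2 <- as.integer(xml2::xml_attr(rel, "entry2"))
    if (is.na(e1) || is.na(e2) ||
        !(e1 %in% c(ent_id)) || !(e2 %in% ent_id)) {
      msg <- sprintf("relation references unknown entry (%s, %s)",
                     xml2::xml_attr(rel, "entry1"), xml2::xml_attr(rel, "entry2"))
      if (strict) stop("malformed KGML: ", msg, call. = FALSE)
      warning(msg, call. = FALSE)
      next
    }
    sub <- xml2::xml_attr(xml2::xml_find_first(rel, "subtype"), "name")
    if (is.na(sub)) sub <- rtype %||% NA_character_
    for (a in expand_end(e1)) for (b in expand_end(e2)) {
      if (a != b) add_edge(a, b, sub)
    }
  }

  nodes <- data.frame(node_id = retained,
                      node_class = unname(class_of[as.character(retained)]),
                      stringsAsFactors = FALSE)
  nodes$node_class[nodes$node_id %in% group_derived &
                     nodes$node_class == "gene"] <- "group-derived"
  nodes$member_ids <- member_of[as.character(retained)]
  pathway_graph(nodes = nodes,
                edges = data.frame(from = edges_from, to = edges_to,
                                   subtype = edges_sub,
                                   stringsAsFactors = FALSE),
                species = species)
}

#' Read a namespace map
#'
#' Two-column TSV (`local_id<TAB>member_id`), `#` comments allowed.
#' @param file path.
#' @return named character vector mapping local to cross-species ids.
#' @export
read_namespace_map <- function(file) {
  df <- utils::read.table(file, sep = "\t", header = FALSE, comment.char = "#",
                          col.names = c("local_id", "member_id"),
                          colClasses = "character")
  if (anyDuplicated(df$local_id)) {
    stop("namespace map has duplicate local ids: ",
         paste(unique(df$local_id[duplicated(df$local_id)]), collapse = ", "),
         call. = FALSE)
  }
  stats::setNames(df$member_id, df$local_id)
}

#' Relabel member identifiers through a namespace map
#'
#' Topology is untouched; two nodes mapping to the same member identifier
#' are both relabelled but never merged.
#'
#' @param graph a [pathway_graph()].
#' @param namespace named character vector (`local -> member id`).
#' @param strict error on uncovered gene identifiers (otherwise kept
#'   verbatim).
#' @return a [pathway_graph()].
#' @export
relabel_members <- function(graph, namespace, strict = TRUE) {
  stopifnot(inherits(graph, "pathway_graph"))
  nodes <- graph$nodes
  offenders <- character(0)
  nodes$member_ids <- lapply(seq_len(nrow(nodes)), function(i) {
    ids <- nodes$member_ids[[i]]
    if (nodes$node_class[i] == "compound") return(ids)
    out <- namespace[ids]
    if (anyNA(out)) {
      offenders <<- c(offenders, ids[is.na(out)])
      out[is.na(out)] <- ids[is.na(out)]
    }
    unique(unname(out))
  })
  if (length(offenders) && strict) {
    stop("namespace map does not cover: ",
         paste(unique(offenders), collapse = ", "), call. = FALSE)
  }
  pathway_graph(nodes, graph$edges, graph$species)
}

#' Emit a pathway graph as a KGML document
#'
#' The counterpart of [parse_kgml()], used by the synthetic generator to
#' produce fixture files: round-tripping a graph through
#' `emit_kgml()` + [parse_kgml()] reproduces it exactly (node ids, edge
#' set, member identifiers).
#'
#' @param graph a [pathway_graph()].
#' @param pathway_name name recorded in the `<pathway>` element.
#' @param file optional path; when given the document is written there.
#' @return an `xml2` document (invisibly, when `file` is given).
#' @export
emit_kgml <- function(graph, pathway_name = "synthetic pathway", file = NULL) {
  stopifnot(inherits(graph, "pathway_graph"))
  doc <- xml2::xml_new_root("pathway",
                            name = pathway_name,
                            org = graph$species,
                            title = pathway_name)
  for (i in seq_len(nrow(graph$nodes))) {
    type <- switch(graph$nodes$node_class[i],
                   compound = "compound",
                   "gene")   # group-derived nodes re-emitted as plain genes
    xml2::xml_add_child(doc, "entry",
                        id = as.character(graph$nodes$node_id[i]),
                        name = paste(graph$nodes$member_ids[[i]], collapse = " "),
                        type = type)
  }
  for (k in seq_len(nrow(graph$edges))) {
    rel <- xml2::xml_add_child(doc, "relation",
                               entry1 = as.character(graph$edges$from[k]),
                               entry2 = as.character(graph$edges$to[k]),
                               type = "PPrel")
    sub <- graph$edges$subtype[k]
    if (!is.na(sub)) xml2::xml_add_child(rel, "subtype", name = sub, value = "")
  }
  if (!is.null(file)) {
    xml2::write_xml(doc, file)
    return(invisible(doc))
  }
  doc
}
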