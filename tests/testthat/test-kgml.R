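kgml_fixture <- function(entries, relations = "") {
  xml2::read_xml(paste0('<pathway name="path:test" org="tst">',
                        entries, relations, "</pathway>"))
}

gene_entry <- function(id, name) {
  sprintf('<entry id="%d" name="%s" type="gene"/>', id, name)
}

test_that("plain gene entries and relations parse into nodes and edges", {
  doc <- kgml_fixture(
    paste0(gene_entry(1, "tst:g1"), gene_entry(2, "tst:g2"),
           gene_entry(3, "tst:g3")),
    paste0('<relation entry1="1" entry2="2" type="PPrel">',
           '<subtype name="activation" value="--&gt;"/></relation>',
           '<relation entry1="2" entry2="3" type="GErel"/>'))
  g <- parse_kgml(doc)
  expect_equal(g$species, "tst")
  expect_equal(nrow(g$nodes), 3)
  expect_equal(nrow(g$edges), 2)
  # species prefix stripped without a namespace map
  expect_equal(sort(unlist(g$nodes$member_ids)), c("g1", "g2", "g3"))
})

test_that("repeated relations collapse to one undirected edge", {
  doc <- kgml_fixture(
    paste0(gene_entry(1, "tst:a"), gene_entry(2, "tst:b")),
    paste0('<relation entry1="1" entry2="2" type="PPrel"/>',
           '<relation entry1="2" entry2="1" type="GErel"/>'))
  g <- parse_kgml(doc)
  expect_equal(nrow(g$edges), 1)
})

test_that("group entries expand to cliques with re-attached relations", {
  doc <- kgml_fixture(
    paste0(gene_entry(1, "tst:e1"), gene_entry(2, "tst:e2"),
           gene_entry(3, "tst:e3"),
           '<entry id="4" name="undefined" type="group">',
           '<component id="1"/><component id="2"/></entry>'),
    '<relation entry1="4" entry2="3" type="PPrel"/>')
  g <- parse_kgml(doc)
  expect_equal(nrow(g$nodes), 3)
  got <- paste(g$edges$from, g$edges$to)
  expect_setequal(got, c("1 2", "1 3", "2 3"))
  expect_true(all(g$nodes$node_class[g$nodes$node_id %in% 1:2] ==
                    "group-derived"))
})

test_that("map entries, maplinks and compounds follow the retention rules", {
  doc <- kgml_fixture(
    paste0(gene_entry(1, "tst:a"),
           '<entry id="2" name="path:map04310" type="map"/>',
           '<entry id="3" name="cpd:C00575" type="compound"/>'),
    paste0('<relation entry1="1" entry2="2" type="maplink"/>',
           '<relation entry1="1" entry2="3" type="PCrel"/>'))
  g <- parse_kgml(doc)
  expect_equal(nrow(g$nodes), 1)          # gene only by default
  expect_equal(nrow(g$edges), 0)
  g2 <- parse_kgml(doc, include_compounds = TRUE)
  expect_equal(nrow(g2$nodes), 2)
  expect_equal(nrow(g2$edges), 1)
})

test_that("strictness controls unknown-entry relations and parse errors", {
  doc <- kgml_fixture(gene_entry(1, "tst:a"),
                      '<relation entry1="1" entry2="77" type="PPrel"/>')
  expect_error(parse_kgml(doc), "unknown entry")
  expect_warning(g <- parse_kgml(doc, strict = FALSE), "unknown entry")
  expect_equal(nrow(g$edges), 0)
  expect_error(parse_kgml(textConnection("<pathway><entry></pathway>")),
               "malformed")
  dup <- kgml_fixture(paste0(gene_entry(1, "tst:a"), gene_entry(1, "tst:b")))
  expect_error(parse_kgml(dup), "duplicate entry id")
})

test_that("namespace maps translate members; relabelling keeps topology", {
  doc <- kgml_fixture(
    paste0(gene_entry(1, "hsa:1"), gene_entry(2, "hsa:2")),
    '<relation entry1="1" entry2="2" type="PPrel"/>')
  ns <- c("hsa:1" = "K001", "hsa:2" = "K002")
  g <- parse_kgml(doc, namespace = ns)
  expect_setequal(unlist(g$nodes$member_ids), c("K001", "K002"))
  expect_error(parse_kgml(doc, namespace = ns[1]), "does not cover")

  g0 <- parse_kgml(doc)
  g1 <- relabel_members(g0, c("1" = "K001", "2" = "K001"))
  expect_equal(nrow(g1$nodes), 2)                 # no merging
  expect_equal(unlist(g1$nodes$member_ids), c("K001", "K001"))
  expect_equal(g1$edges, g0$edges)
  expect_error(relabel_members(g0, c("1" = "K001")), "does not cover")
  # identity namespace leaves the graph unchanged
  idns <- c("1" = "1", "2" = "2")
  expect_equal(relabel_members(g0, idns)$nodes, g0$nodes)

  tf <- tempfile()
  writeLines(c("# orthology", "hsa:1\tK001", "hsa:2\tK002"), tf)
  expect_equal(read_namespace_map(tf), ns)
})

test_that("parsing is order-independent and emit/parse round-trips", {
  ents <- c(gene_entry(1, "tst:a"), gene_entry(2, "tst:b"),
            gene_entry(3, "tst:c"))
  rels <- c('<relation entry1="1" entry2="2" type="PPrel"/>',
            '<relation entry1="2" entry2="3" type="PPrel"/>')
  g1 <- parse_kgml(kgml_fixture(paste(ents, collapse = ""),
                                paste(rels, collapse = "")))
  g2 <- parse_kgml(kgml_fixture(paste(rev(ents), collapse = ""),
                                paste(rev(rels), collapse = "")))
  expect_equal(g1$nodes, g2$nodes)
  expect_equal(g1$edges, g2$edges)

  for (s in c(3, 8, 21)) {
    g <- random_graph(10, 0.3, seed = s, species = "sim")
    f <- tempfile(fileext = ".xml")
    emit_kgml(g, file = f)
    back <- parse_kgml(f)
    expect_equal(back$nodes$node_id, g$nodes$node_id)
    expect_equal(back$nodes$member_ids, g$nodes$member_ids)
    expect_equal(back$edges[c("from", "to")], g$edges[c("from", "to")])
  }
})
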