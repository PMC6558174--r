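test_that("parse_obo builds terms and typed edges from stanzas", {
  txt <- c(
    "format-version: 1.2",
    "ontology: po-test",
    "",
    "[Term]",
    "id: PO:0007631",
    "name: plant embryo development stage",
    "namespace: plant_structure_development_stage",
    "synonym: \"embryo stage\" EXACT []",
    "is_a: PO:0007134 ! sporophyte vegetative stage",
    "",
    "[Term]",
    "id: PO:0007134",
    "name: sporophyte vegetative stage"
  )
  g <- parse_obo(text = txt)
  expect_equal(n_terms(g), 2L)
  expect_equal(nrow(g$edges), 1L)
  expect_equal(g$edges$subject, "PO:0007631")
  expect_equal(g$edges$predicate, "is_a")
  expect_equal(g$edges$object, "PO:0007134")
  expect_equal(g$terms$synonyms[[1L]], "embryo stage")
  expect_equal(g$header[1:2], txt[1:2])

  empty <- parse_obo(text = character())
  expect_equal(n_terms(empty), 0L)
  expect_equal(nrow(empty$edges), 0L)
})

test_that("parse_obo rejects stanzas without id and duplicate ids", {
  no_id <- c("[Term]", "name: orphan stanza")
  expect_error(parse_obo(text = no_id), "line 1")
  dup <- c("[Term]", "id: PO:0000001", "", "[Term]", "id: PO:0000001")
  expect_error(parse_obo(text = dup), "PO:0000001")
})

test_that("precedes/preceded_by inverses are materialised at parse time", {
  txt <- c("[Term]", "id: PO:0000001", "name: a",
           "relationship: precedes PO:0000002",
           "", "[Term]", "id: PO:0000002", "name: b")
  g <- parse_obo(text = txt)
  expect_equal(nrow(g$edges), 2L)
  inv <- g$edges[g$edges$predicate == "preceded_by", ]
  expect_equal(inv$subject, "PO:0000002")
  expect_equal(inv$object, "PO:0000001")
})

test_that("unknown relationship predicates are stored but excluded from reasoning", {
  txt <- c("[Term]", "id: PO:0000001", "name: a",
           "relationship: regulates PO:0000002",
           "", "[Term]", "id: PO:0000002", "name: b")
  g <- parse_obo(text = txt)
  expect_true("regulates" %in% g$edges$predicate)
  expect_error(stage_ancestors(g, "PO:0000001", "regulates"), "unsupported")
  expect_length(stage_ancestors(g, "PO:0000001", "is_a"), 0L)
})

test_that("write/parse round trip preserves a 50-term random graph", {
  set.seed(42)
  n <- 50
  ids <- sprintf("RT:%07d", seq_len(n))
  terms <- data.frame(
    id = ids, name = paste("term", seq_len(n)),
    namespace = sample(c("ns1", "ns2"), n, replace = TRUE),
    is_obsolete = runif(n) < 0.1, stringsAsFactors = FALSE)
  terms$synonyms <- lapply(seq_len(n), function(i) {
    if (runif(1) < 0.3) paste("syn", i, seq_len(sample(2, 1))) else character()
  })
  pairs <- which(upper.tri(matrix(TRUE, n, n)), arr.ind = TRUE)
  keep <- sample(nrow(pairs), 80)
  edges <- data.frame(
    subject = ids[pairs[keep, 1L]],
    predicate = sample(c("is_a", "part_of", "precedes", "has_participant"),
                       80, replace = TRUE),
    object = ids[pairs[keep, 2L]], stringsAsFactors = FALSE)
  g <- stage_graph(terms, edges, header = "format-version: 1.2")

  g2 <- parse_obo(text = write_obo(g))
  expect_equal(g2$terms$id, g$terms$id)
  expect_equal(g2$terms$name, g$terms$name)
  expect_equal(g2$terms$namespace, g$terms$namespace)
  expect_equal(g2$terms$is_obsolete, g$terms$is_obsolete)
  expect_equal(g2$terms$synonyms, g$terms$synonyms)
  expect_setequal(
    paste(g2$edges$subject, g2$edges$predicate, g2$edges$object),
    paste(g$edges$subject, g$edges$predicate, g$edges$object))
  expect_equal(nrow(g2$edges), nrow(g$edges))
})

test_that("subclass closure climbs the stage hierarchy", {
  # flower development stage is a reproductive shoot system development
  # stage, which is a shoot system development stage
  txt <- c(
    "[Term]", "id: PO:0007615", "name: flower development stage",
    "is_a: PO:0025530",
    "", "[Term]", "id: PO:0025530",
    "name: reproductive shoot system development stage",
    "is_a: PO:0025527",
    "", "[Term]", "id: PO:0025527", "name: shoot system development stage")
  g <- parse_obo(text = txt)
  anc <- stage_ancestors(g, "PO:0007615", "is_a")
  expect_true(all(c("PO:0025530", "PO:0025527") %in% anc))
  expect_length(stage_ancestors(g, "PO:0025527", "is_a"), 0L)
  expect_error(stage_ancestors(g, "PO:9999999", "is_a"), "unknown term")
})

test_that("closures match igraph reachability on random DAGs", {
  for (seed in 1:10) {
    g <- random_dag_graph(30, p = 0.12, seed = seed)
    for (v in sample(g$terms$id, 5)) {
      expect_setequal(stage_ancestors(g, v, "is_a"),
                      igraph_reachable(g, v, "is_a"))
      expect_setequal(stage_descendants(g, v, "is_a"),
                      setdiff(g$terms$id[vapply(
                        g$terms$id,
                        function(u) v %in% igraph_reachable(g, u, "is_a"),
                        TRUE)], v))
    }
  }
})

test_that("obsolete terms are excluded from closures", {
  txt <- c("[Term]", "id: PO:0000001", "name: a", "is_a: PO:0000002",
           "", "[Term]", "id: PO:0000002", "name: b", "is_a: PO:0000003",
           "is_obsolete: true",
           "", "[Term]", "id: PO:0000003", "name: c")
  g <- parse_obo(text = txt)
  expect_length(stage_ancestors(g, "PO:0000001", "is_a"), 0L)
})

test_that("preceded_by closure walks the embryo chain transitively", {
  g <- embryo_chain_graph()
  ids <- embryo_chain_ids
  closure <- preceded_by_closure(g, ids[["bilateral"]])
  expect_true(all(ids[c("globular", "proembryo", "zygote")] %in% closure))
  expect_length(preceded_by_closure(g, ids[["zygote"]]), 0L)
})

test_that("preceded_by closure matches reachability on random chains with shortcuts", {
  for (seed in 1:5) {
    g <- random_dag_graph(25, p = 0.1, predicate = "preceded_by", seed = seed)
    for (v in sample(g$terms$id, 4)) {
      expect_setequal(preceded_by_closure(g, v),
                      igraph_reachable(g, v, "preceded_by"))
    }
  }
})

test_that("closure duality: b preceded_by a iff a precedes b after completion", {
  g <- embryo_chain_graph()
  for (a in g$terms$id) {
    for (b in g$terms$id) {
      expect_equal(b %in% preceded_by_closure(g, a),
                   a %in% stage_ancestors(g, b, "precedes"))
    }
  }
})

test_that("temporal_sort orders the embryo chain and is stable", {
  g <- embryo_chain_graph()
  ids <- embryo_chain_ids
  out <- temporal_sort(g, unname(ids[c("bilateral", "proembryo", "globular")]))
  expect_equal(out, unname(ids[c("proembryo", "globular", "bilateral")]))

  expect_equal(temporal_sort(g, ids[["mature"]]), ids[["mature"]])

  # cotyledonary and coleoptilar are temporally unrelated: input order kept
  out2 <- temporal_sort(g, unname(ids[c("coleoptilar", "cotyledonary", "zygote")]))
  expect_equal(out2, unname(ids[c("zygote", "coleoptilar", "cotyledonary")]))

  # idempotence
  expect_equal(temporal_sort(g, out), out)
})

test_that("temporal_sort output satisfies all pairwise precedes constraints", {
  for (seed in 1:8) {
    g <- random_dag_graph(20, p = 0.15, predicate = "precedes", seed = seed)
    terms <- sample(g$terms$id, 12)
    out <- temporal_sort(g, terms)
    expect_setequal(out, terms)
    pos <- setNames(seq_along(out), out)
    for (a in terms) {
      after_a <- intersect(stage_ancestors(g, a, "precedes"), terms)
      for (b in after_a) expect_lt(pos[[a]], pos[[b]])
    }
    expect_equal(temporal_sort(g, out), out)
  }
})

test_that("temporal_sort reports cycles among input terms", {
  edges <- data.frame(subject = c("CY:0000001", "CY:0000002"),
                      predicate = "precedes",
                      object = c("CY:0000002", "CY:0000001"),
                      stringsAsFactors = FALSE)
  terms <- data.frame(id = c("CY:0000001", "CY:0000002"), name = c("a", "b"),
                      namespace = NA, is_obsolete = FALSE,
                      stringsAsFactors = FALSE)
  g <- stage_graph(terms, edges)
  expect_error(temporal_sort(g, c("CY:0000001", "CY:0000002")),
               "cycle.*CY:0000001")
})

test_that("participation inference is one-hop and direction-asymmetric", {
  # protonema participates_in gametophyte development stage: an entity
  # annotated to the structure is inferred to the stage, never conversely
  terms <- data.frame(
    id = c("PO:0025279", "PO:0028003"),
    name = c("protonema", "gametophyte development stage"),
    namespace = NA, is_obsolete = FALSE, stringsAsFactors = FALSE)
  edges <- data.frame(subject = "PO:0025279", predicate = "participates_in",
                      object = "PO:0028003", stringsAsFactors = FALSE)
  g <- stage_graph(terms, edges)

  to_stage <- infer_stage_structure_links(
    g, data.frame(entity = "gene1", term = "PO:0028003"))
  expect_equal(nrow(to_stage), 0L)

  to_structure <- infer_stage_structure_links(
    g, data.frame(entity = "gene1", term = "PO:0025279"))
  expect_equal(to_structure$term, "PO:0028003")
  expect_match(to_structure$provenance, "participates_in")

  # has_participant infers stage -> structure
  g2 <- stage_graph(terms, data.frame(
    subject = "PO:0028003", predicate = "has_participant",
    object = "PO:0025279", stringsAsFactors = FALSE))
  inf <- infer_stage_structure_links(
    g2, data.frame(entity = "gene1", term = "PO:0028003"))
  expect_equal(inf$term, "PO:0025279")
})

test_that("participation inference equals an exhaustive edge scan", {
  set.seed(7)
  for (rep in 1:5) {
    n <- 15
    ids <- sprintf("PI:%07d", seq_len(n))
    terms <- data.frame(id = ids, name = ids, namespace = NA,
                        is_obsolete = FALSE, stringsAsFactors = FALSE)
    e_idx <- matrix(sample(n, 20, replace = TRUE), ncol = 2)
    e_idx <- e_idx[e_idx[, 1] != e_idx[, 2], , drop = FALSE]
    edges <- data.frame(
      subject = ids[e_idx[, 1]],
      predicate = sample(c("has_participant", "participates_in", "is_a"),
                         nrow(e_idx), replace = TRUE),
      object = ids[e_idx[, 2]], stringsAsFactors = FALSE)
    g <- stage_graph(terms, edges)
    assoc <- data.frame(entity = sprintf("e%d", 1:10),
                        term = sample(ids, 10, replace = TRUE))
    got <- infer_stage_structure_links(g, assoc)
    # oracle: scan every (association, participation edge) combination
    want <- unique(do.call(rbind, lapply(seq_len(nrow(assoc)), function(i) {
      hits <- edges[edges$subject == assoc$term[i] &
                      edges$predicate %in% c("has_participant", "participates_in"), ]
      if (nrow(hits) == 0L) return(NULL)
      data.frame(entity = assoc$entity[i], term = hits$object,
                 stringsAsFactors = FALSE)
    })))
    if (is.null(want)) {
      expect_equal(nrow(got), 0L)
    } else {
      expect_setequal(paste(got$entity, got$term), paste(want$entity, want$term))
    }
  }
})

test_that("inference returns no rows for graphs without participation edges", {
  g <- embryo_chain_graph()
  out <- infer_stage_structure_links(
    g, data.frame(entity = "gene1", term = embryo_chain_ids[["globular"]]))
  expect_equal(nrow(out), 0L)
})

test_that("ancestor sets are monotone under edge addition", {
  g <- random_dag_graph(20, p = 0.1, seed = 3)
  before <- lapply(g$terms$id, function(v) stage_ancestors(g, v, "is_a"))
  # add an edge between two previously unrelated nodes (keep acyclic: i < j)
  g2 <- g
  g2$edges <- rbind(g2$edges, data.frame(
    subject = g$terms$id[2], predicate = "is_a", object = g$terms$id[19],
    stringsAsFactors = FALSE))
  after <- lapply(g2$terms$id, function(v) stage_ancestors(g2, v, "is_a"))
  for (i in seq_along(before)) expect_true(all(before[[i]] %in% after[[i]]))
})

test_that("validate reports cycles, self-edges, dangling edges and missing inverses", {
  g <- embryo_chain_graph()
  expect_equal(nrow(validate_stage_graph(g)), 0L)

  terms <- data.frame(id = c("VA:0000001", "VA:0000002"), name = c("a", "b"),
                      namespace = NA, is_obsolete = FALSE,
                      stringsAsFactors = FALSE)
  edges <- data.frame(
    subject = c("VA:0000001", "VA:0000002", "VA:0000001", "VA:0000001"),
    predicate = c("precedes", "precedes", "is_a", "is_a"),
    object = c("VA:0000002", "VA:0000001", "VA:0000001", "VA:0000009"),
    stringsAsFactors = FALSE)
  g_bad <- stage_graph(terms, edges, complete_inverses = FALSE)
  report <- validate_stage_graph(g_bad)
  expect_true(all(c("precedes_cycle", "self_edge", "dangling_edge",
                    "missing_inverse") %in% report$issue_type))
  expect_equal(sum(report$issue_type == "precedes_cycle"), 2L)
})

test_that("cycle counts agree with igraph strong components on random graphs", {
  set.seed(11)
  for (rep in 1:8) {
    n <- 30
    ids <- sprintf("CG:%07d", seq_len(n))
    terms <- data.frame(id = ids, name = ids, namespace = NA,
                        is_obsolete = FALSE, stringsAsFactors = FALSE)
    e_idx <- matrix(sample(n, 2 * 45, replace = TRUE), ncol = 2)
    e_idx <- e_idx[e_idx[, 1] != e_idx[, 2], , drop = FALSE]
    edges <- data.frame(subject = ids[e_idx[, 1]], predicate = "is_a",
                        object = ids[e_idx[, 2]], stringsAsFactors = FALSE)
    g <- stage_graph(terms, edges, complete_inverses = FALSE)
    report <- validate_stage_graph(g)
    got <- sum(report$issue_type == "is_a_cycle")
    ig <- igraph::graph_from_data_frame(edges[, c("subject", "object")],
                                        vertices = ids)
    comp <- igraph::components(ig, mode = "strong")
    want <- sum(comp$csize[comp$membership] > 1)
    expect_equal(got, want)
  }
})
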