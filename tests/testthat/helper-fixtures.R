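# Shared fixtures built in code: the embryo-stage temporal chain, random
# graphs for closure oracles, and small OBO/GAF text snippets.

# Embryo development chain: zygote -> proembryo -> globular -> bilateral,
# then branching into cotyledonary (dicot) and coleoptilar (monocot), each
# followed by a later stage. Ids for the named embryo stages are the real
# ontology identifiers; the zygote id is a synthetic placeholder.
embryo_chain_ids <- c(
  zygote = "PO:0000999",       # synthetic placeholder id
  proembryo = "PO:0001180",
  globular = "PO:0001185",
  bilateral = "PO:0004507",
  cotyledonary = "PO:0001078",
  coleoptilar = "PO:0001094",
  mature = "PO:0001081",
  true_leaf = "PO:0001095"
)

embryo_chain_graph <- function() {
  ids <- embryo_chain_ids
  terms <- data.frame(
    id = unname(ids),
    name = c("plant zygote stage", "plant proembryo stage",
             "plant embryo globular stage", "plant embryo bilateral stage",
             "plant embryo cotyledonary stage", "plant embryo coleoptilar stage",
             "mature plant embryo stage", "plant embryo true leaf formation stage"),
    namespace = "plant_structure_development_stage",
    is_obsolete = FALSE,
    stringsAsFactors = FALSE
  )
  terms$synonyms <- rep(list(character()), nrow(terms))
  later <- c(ids[["proembryo"]], ids[["globular"]], ids[["bilateral"]],
             ids[["cotyledonary"]], ids[["coleoptilar"]],
             ids[["mature"]], ids[["true_leaf"]])
  earlier <- c(ids[["zygote"]], ids[["proembryo"]], ids[["globular"]],
               ids[["bilateral"]], ids[["bilateral"]],
               ids[["cotyledonary"]], ids[["coleoptilar"]])
  edges <- data.frame(subject = later, predicate = "preceded_by",
                      object = earlier, stringsAsFactors = FALSE)
  stage_graph(terms, edges)
}

# Random DAG over n nodes: edge i -> j allowed only for i < j, so the graph
# is acyclic by construction.
random_dag_graph <- function(n, p = 0.15, predicate = "is_a", seed = 1) {
  set.seed(seed)
  ids <- sprintf("RD:%07d", seq_len(n))
  pairs <- which(upper.tri(matrix(TRUE, n, n)), arr.ind = TRUE)
  keep <- runif(nrow(pairs)) < p
  edges <- data.frame(subject = ids[pairs[keep, 1L]],
                      predicate = predicate,
                      object = ids[pairs[keep, 2L]],
                      stringsAsFactors = FALSE)
  terms <- data.frame(id = ids, name = paste("node", seq_len(n)),
                      namespace = "random", is_obsolete = FALSE,
                      stringsAsFactors = FALSE)
  terms$synonyms <- rep(list(character()), n)
  stage_graph(terms, edges, complete_inverses = FALSE)
}

# Independent reachability oracle via igraph.
igraph_reachable <- function(graph, from, predicates) {
  e <- graph$edges[graph$edges$predicate %in% predicates, , drop = FALSE]
  ids <- graph$terms$id
  g <- igraph::graph_from_data_frame(e[, c("subject", "object")],
                                     vertices = ids, directed = TRUE)
  out <- names(igraph::subcomponent(g, from, mode = "out"))
  setdiff(out, from)
}

# GAF 2.1 line with the given fields in the standard columns.
gaf_line <- function(object_id, term_id, evidence = "IEP", db = "TAIR",
                     taxon = "taxon:3702", date = "20181201") {
  paste(db, object_id, object_id, "", term_id, "PMID:1", evidence, "", "T",
        "", "", "gene", taxon, date, db, sep = "\t")
}

random_annotation_table <- function(n, seed = 1) {
  set.seed(seed)
  annotation_table(data.frame(
    source_db = sample(c("TAIR", "MaizeGDB"), n, replace = TRUE),
    object_id = sprintf("G%03d", sample(50, n, replace = TRUE)),
    term_id = sprintf("PO:%07d", sample(5, n, replace = TRUE)),
    evidence_code = sample(c("IEP", "IDA", "IEA", "ISS"), n, replace = TRUE),
    taxon = sample(c("taxon:3702", "taxon:4577"), n, replace = TRUE),
    stringsAsFactors = FALSE
  ))
}
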