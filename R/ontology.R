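# Stage-ontology graph: typed-relation storage and reasoning.

#' Relation predicates used for reasoning
#'
#' The six typed relations recognised by the reasoning operations. Any other
#' predicate found in an OBO file is preserved on the graph but ignored by
#' closures, ordering and inference.
#'
#' @format Character vector of predicate names.
#' @export
REASONING_PREDICATES <- c(
  "is_a", "part_of", "precedes", "preceded_by",
  "has_participant", "participates_in"
)

CURIE_PATTERN <- "^[A-Za-z][A-Za-z0-9_]*:[0-9]{7}$"

#' Construct a stage graph
#'
#' A `stage_graph` holds development-stage ontology terms and typed relation
#' edges. Terms live in a data frame (one row per term, synonyms as a list
#' column); edges in a data frame with columns `subject`, `predicate`,
#' `object`. `precedes`/`preceded_by` edges are materialised as mutual
#' inverses so both temporal directions can be traversed.
#'
#' @param terms data frame with columns `id`, `name`, `namespace`,
#'   `is_obsolete` and a list column `synonyms`.
#' @param edges data frame with columns `subject`, `predicate`, `object`.
#' @param header character vector of OBO header lines, preserved verbatim on
#'   write.
#' @param other_stanzas character vector of non-Term stanza lines preserved
#'   verbatim on write.
#' @param complete_inverses logical; materialise missing
#'   `precedes`/`preceded_by` inverse edges.
#' @return An object of class `stage_graph`.
#' @export
stage_graph <- function(terms = empty_terms(), edges = empty_edges(),
                        header = character(), other_stanzas = character(),
                        complete_inverses = TRUE) {
  stopifnot(is.data.frame(terms), is.data.frame(edges))
  if (anyDuplicated(terms$id)) {
    dup <- terms$id[duplicated(terms$id)][1L]
    stop("duplicate term id: ", dup, call. = FALSE)
  }
  if (!"synonyms" %in% names(terms)) terms$synonyms <- rep(list(character()), nrow(terms))
  if (!"namespace" %in% names(terms)) terms$namespace <- NA_character_
  if (!"is_obsolete" %in% names(terms)) terms$is_obsolete <- FALSE
  edges$subject <- as.character(edges$subject)
  edges$predicate <- as.character(edges$predicate)
  edges$object <- as.character(edges$object)
  if (complete_inverses) edges <- complete_temporal_inverses(edges)
  structure(
    list(terms = terms, edges = edges, header = header,
         other_stanzas = other_stanzas),
    class = "stage_graph"
  )
}

empty_terms <- function() {
  data.frame(id = character(), name = character(), namespace = character(),
             is_obsolete = logical(), stringsAsFactors = FALSE)
}

empty_edges <- function() {
  data.frame(subject = character(), predicate = character(),
             object = character(), stringsAsFactors = FALSE)
}

edge_keys <- function(edges) {
  paste(edges$subject, edges$predicate, edges$object, sep = "\r")
}

# Add the missing member of every precedes/preceded_by pair.
complete_temporal_inverses <- function(edges) {
  inv <- c(precedes = "preceded_by", preceded_by = "precedes")
  tmp <- edges[edges$predicate %in% names(inv), , drop = FALSE]
  if (nrow(tmp) == 0L) return(edges)
  mirrored <- data.frame(
    subject = tmp$object,
    predicate = unname(inv[tmp$predicate]),
    object = tmp$subject,
    stringsAsFactors = FALSE
  )
  missing <- !(edge_keys(mirrored) %in% edge_keys(edges))
  rbind(edges, mirrored[missing, , drop = FALSE])
}

#' @export
print.stage_graph <- function(x, ...) {
  cat(sprintf("<stage_graph> %d terms, %d edges\n", nrow(x$terms), nrow(x$edges)))
  tab <- table(x$edges$predicate)
  if (length(tab)) {
    cat("  edges by predicate:",
        paste(sprintf("%s=%d", names(tab), as.integer(tab)), collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' Number of terms in a stage graph
#' @param graph a `stage_graph`.
#' @return integer count of terms.
#' @export
n_terms <- function(graph) nrow(graph$terms)

has_term <- function(graph, id) id %in% graph$terms$id

assert_terms_exist <- function(graph, ids) {
  missing <- setdiff(ids, graph$terms$id)
  if (length(missing)) {
    stop("unknown term id(s): ", paste(missing, collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

obsolete_ids <- function(graph) graph$terms$id[isTRUE_vec(graph$terms$is_obsolete)]

isTRUE_vec <- function(x) !is.na(x) & as.logical(x)

#' Parse an OBO flat file into a stage graph
#'
#' Reads OBO 1.2/1.4 flat text. Every `[Term]` stanza becomes a term; `is_a:`
#' and `relationship:` lines become typed edges. Unknown relationship
#' predicates are stored but excluded from reasoning. Missing
#' `precedes`/`preceded_by` inverse edges are materialised. The header and
#' any non-Term stanzas are preserved verbatim for [write_obo()].
#'
#' @param file path to an OBO file, or a connection.
#' @param text optional character vector of OBO lines (used instead of
#'   `file`).
#' @return A [stage_graph()].
#' @examples
#' g <- parse_obo(text = c(
#'   "format-version: 1.2", "",
#'   "[Term]", "id: PO:0000001", "name: example stage"))
#' n_terms(g)
#' @export
parse_obo <- function(file = NULL, text = NULL) {
  lines <- if (!is.null(text)) text else readLines(file, warn = FALSE)
  stanza_starts <- grep("^\\[", lines)
  header <- if (length(stanza_starts)) lines[seq_len(stanza_starts[1L] - 1L)] else lines

  ids <- character(); names_ <- character(); namespaces <- character()
  obsolete <- logical(); synonyms <- list()
  subj <- character(); pred <- character(); obj <- character()
  other <- character()

  n_st <- length(stanza_starts)
  bounds <- c(stanza_starts, length(lines) + 1L)
  for (i in seq_len(n_st)) {
    start <- stanza_starts[i]
    block <- lines[start:(bounds[i + 1L] - 1L)]
    if (!identical(block[1L], "[Term]")) {
      other <- c(other, block)
      next
    }
    body <- block[-1L]
    body <- body[nzchar(trimws(body))]
    kv <- regmatches(body, regexec("^([A-Za-z_]+):\\s*(.*)$", body))
    keys <- vapply(kv, function(m) if (length(m) == 3L) m[2L] else "", "")
    vals <- vapply(kv, function(m) if (length(m) == 3L) m[3L] else "", "")

    id_idx <- which(keys == "id")
    if (!length(id_idx)) {
      stop("OBO parse error: [Term] stanza starting at line ", start,
           " has no id: line", call. = FALSE)
    }
    id <- strip_obo_comment(vals[id_idx[1L]])
    if (id %in% ids) stop("duplicate term id: ", id, call. = FALSE)

    ids <- c(ids, id)
    names_ <- c(names_, first_or_na(vals[keys == "name"]))
    namespaces <- c(namespaces, first_or_na(vals[keys == "namespace"]))
    obsolete <- c(obsolete, any(grepl("^true", vals[keys == "is_obsolete"])))
    syn_raw <- vals[keys == "synonym"]
    synonyms <- c(synonyms, list(extract_quoted(syn_raw)))

    for (v in vals[keys == "is_a"]) {
      subj <- c(subj, id); pred <- c(pred, "is_a")
      obj <- c(obj, strip_obo_comment(v))
    }
    for (v in vals[keys == "relationship"]) {
      v <- strip_obo_comment(v)
      parts <- strsplit(trimws(v), "\\s+")[[1L]]
      if (length(parts) >= 2L) {
        subj <- c(subj, id); pred <- c(pred, parts[1L]); obj <- c(obj, parts[2L])
      }
    }
  }

  terms <- data.frame(id = ids, name = names_, namespace = namespaces,
                      is_obsolete = obsolete, stringsAsFactors = FALSE)
  terms$synonyms <- synonyms
  edges <- data.frame(subject = subj, predicate = pred, object = obj,
                      stringsAsFactors = FALSE)
  stage_graph(terms, edges, header = header, other_stanzas = other)
}

strip_obo_comment <- function(x) trimws(sub("\\s*!.*$", "", x))

first_or_na <- function(x) if (length(x)) x[1L] else NA_character_

extract_quoted <- function(x) {
  if (!length(x)) return(character())
  m <- regmatches(x, regexec("\"([^\"]*)\"", x))
  out <- vapply(m, function(mm) if (length(mm) == 2L) mm[2L] else NA_character_, "")
  out[!is.na(out)]
}

#' Write a stage graph to an OBO flat file
#'
#' Emits the preserved header verbatim, one `[Term]` stanza per term (in
#' graph order), and any preserved non-Term stanzas. `parse_obo(write_obo(g))`
#' reproduces the term set and edge multiset of `g`.
#'
#' @param graph a [stage_graph()].
#' @param file path or connection to write to; if `NULL`, the lines are
#'   returned invisibly without writing.
#' @return The character vector of lines, invisibly.
#' @export
write_obo <- function(graph, file = NULL) {
  out <- graph$header
  edges <- graph$edges
  for (i in seq_len(nrow(graph$terms))) {
    t <- graph$terms[i, ]
    stanza <- c("", "[Term]", paste0("id: ", t$id))
    if (!is.na(t$name)) stanza <- c(stanza, paste0("name: ", t$name))
    if (!is.na(t$namespace)) stanza <- c(stanza, paste0("namespace: ", t$namespace))
    for (s in t$synonyms[[1L]]) {
      stanza <- c(stanza, sprintf("synonym: \"%s\" RELATED []", s))
    }
    e <- edges[edges$subject == t$id, , drop = FALSE]
    for (j in seq_len(nrow(e))) {
      stanza <- c(stanza,
                  if (e$predicate[j] == "is_a") paste0("is_a: ", e$object[j])
                  else sprintf("relationship: %s %s", e$predicate[j], e$object[j]))
    }
    if (isTRUE(t$is_obsolete)) stanza <- c(stanza, "is_obsolete: true")
    out <- c(out, stanza)
  }
  if (length(graph$other_stanzas)) out <- c(out, "", graph$other_stanzas)
  if (!is.null(file)) writeLines(out, file)
  invisible(out)
}

# Forward adjacency restricted to the given predicates; named list
# subject -> character vector of objects. reverse=TRUE swaps direction.
adjacency <- function(graph, predicates, reverse = FALSE) {
  e <- graph$edges[graph$edges$predicate %in% predicates, , drop = FALSE]
  from <- if (reverse) e$object else e$subject
  to <- if (reverse) e$subject else e$object
  split(to, from)
}

# BFS transitive closure from `start` over a precomputed adjacency list,
# excluding the start term and any obsolete terms.
bfs_closure <- function(adj, start, exclude = character()) {
  seen <- new.env(parent = emptyenv())
  queue <- start
  out <- character()
  while (length(queue)) {
    node <- queue[[1L]]; queue <- queue[-1L]
    nexts <- adj[[node]]
    for (nx in nexts) {
      if (nx %in% exclude) next
      if (is.null(seen[[nx]])) {
        seen[[nx]] <- TRUE
        out <- c(out, nx)
        queue <- c(queue, nx)
      }
    }
  }
  setdiff(out, start)
}

#' Transitive ancestors over chosen predicates
#'
#' Returns every term reachable from `term` by repeatedly following edges
#' whose predicate is in `predicates`, excluding `term` itself and any
#' obsolete terms. With `predicates = "is_a"` this is the subclass closure;
#' with `"preceded_by"` it walks backward in developmental time.
#'
#' @param graph a [stage_graph()].
#' @param term a term id present in the graph.
#' @param predicates subset of `is_a`, `part_of`, `precedes`, `preceded_by`.
#' @return Character vector of term ids (order of discovery).
#' @export
stage_ancestors <- function(graph, term, predicates = "is_a") {
  assert_terms_exist(graph, term)
  allowed <- c("is_a", "part_of", "precedes", "preceded_by")
  bad <- setdiff(predicates, allowed)
  if (length(bad)) {
    stop("unsupported closure predicate(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  bfs_closure(adjacency(graph, predicates), term, exclude = obsolete_ids(graph))
}

#' Transitive descendants over chosen predicates
#'
#' Reverse of [stage_ancestors()]: all terms from which `term` is reachable.
#' Used for true-path annotation propagation (a gene annotated to a subclass
#' counts for every ancestor stage).
#'
#' @inheritParams stage_ancestors
#' @return Character vector of term ids.
#' @export
stage_descendants <- function(graph, term, predicates = "is_a") {
  assert_terms_exist(graph, term)
  bfs_closure(adjacency(graph, predicates, reverse = TRUE), term,
              exclude = obsolete_ids(graph))
}

#' Temporal predecessors of a stage
#'
#' All stages reachable from `term` via `preceded_by` edges, i.e. every stage
#' known to end at or before the start of `term`. `preceded_by` is
#' transitive, so the closure provides a temporal order even when only
#' adjacent stages are linked.
#'
#' @inheritParams stage_ancestors
#' @return Character vector of term ids.
#' @export
preceded_by_closure <- function(graph, term) {
  assert_terms_exist(graph, term)
  bfs_closure(adjacency(graph, "preceded_by"), term,
              exclude = obsolete_ids(graph))
}

#' Sort stage terms into temporal order
#'
#' Orders the input terms so that whenever one transitively precedes another
#' it appears first. Terms with no ordering relation between them keep their
#' input order (the sort is stable); a `precedes` cycle among the inputs is
#' an error naming the terms involved.
#'
#' @param graph a [stage_graph()].
#' @param terms character vector of term ids to order.
#' @return The input ids, permuted into temporal order.
#' @export
temporal_sort <- function(graph, terms) {
  assert_terms_exist(graph, terms)
  n <- length(terms)
  if (n <= 1L) return(terms)
  adj <- adjacency(graph, "precedes")
  closure <- lapply(terms, function(t) intersect(bfs_closure(adj, t), terms))
  names(closure) <- terms
  # preds[[b]]: input terms that must appear before b
  preds <- lapply(terms, function(b) {
    terms[vapply(terms, function(a) a != b && b %in% closure[[a]], TRUE)]
  })
  names(preds) <- terms
  placed <- character()
  remaining <- terms
  while (length(remaining)) {
    ok <- vapply(remaining, function(t) all(preds[[t]] %in% placed), TRUE)
    if (!any(ok)) {
      stop("temporal ordering cycle among terms: ",
           paste(remaining, collapse = ", "), call. = FALSE)
    }
    nxt <- remaining[which(ok)[1L]]
    placed <- c(placed, nxt)
    remaining <- setdiff(remaining, nxt)
  }
  placed
}

#' Infer stage/structure associations from participation edges
#'
#' One-hop inference over `has_participant` and `participates_in` edges,
#' following the every/some reading of the relations: an entity associated
#' with a stage that `has_participant` some structure is inferred to be
#' associated with that structure, and an entity associated with a structure
#' that `participates_in` some stage is inferred to be associated with that
#' stage. The converse directions are never inferred (a stage does not imply
#' every participating structure type, nor a structure every stage).
#'
#' @param graph a [stage_graph()].
#' @param assoc data frame with columns `entity` and `term`.
#' @return Data frame with columns `entity`, `term` (the inferred term) and
#'   `provenance` (the edge used), deduplicated. Zero rows when the graph has
#'   no participation edges.
#' @export
infer_stage_structure_links <- function(graph, assoc) {
  stopifnot(all(c("entity", "term") %in% names(assoc)))
  e <- graph$edges[graph$edges$predicate %in%
                     c("has_participant", "participates_in"), , drop = FALSE]
  out <- data.frame(entity = character(), term = character(),
                    provenance = character(), stringsAsFactors = FALSE)
  if (nrow(e) == 0L || nrow(assoc) == 0L) return(out)
  hit <- merge(assoc, e, by.x = "term", by.y = "subject")
  if (nrow(hit) == 0L) return(out)
  out <- data.frame(
    entity = hit$entity,
    term = hit$object,
    provenance = sprintf("%s %s %s", hit$term, hit$predicate, hit$object),
    stringsAsFactors = FALSE
  )
  unique(out)
}

#' Validate a stage graph
#'
#' Reports structural problems without modifying the graph: cycles in the
#' `is_a` and `precedes` subgraphs, edges whose endpoints are not terms,
#' `precedes`/`preceded_by` edges missing their inverse, self-edges,
#' malformed term ids, and obsolete terms that still carry outgoing edges.
#'
#' @param graph a [stage_graph()].
#' @return Data frame with columns `issue_type`, `subject`, `object`,
#'   `detail`; zero rows for a clean graph.
#' @export
validate_stage_graph <- function(graph) {
  issues <- list()
  add <- function(type, subject, object = NA_character_, detail = "") {
    issues[[length(issues) + 1L]] <<- data.frame(
      issue_type = type, subject = subject, object = object, detail = detail,
      stringsAsFactors = FALSE)
  }
  edges <- graph$edges
  ids <- graph$terms$id

  self <- edges$subject == edges$object
  for (i in which(self)) {
    add("self_edge", edges$subject[i], edges$object[i], edges$predicate[i])
  }
  dangle <- !(edges$subject %in% ids) | !(edges$object %in% ids)
  for (i in which(dangle)) {
    add("dangling_edge", edges$subject[i], edges$object[i], edges$predicate[i])
  }
  for (pred in c("is_a", "precedes")) {
    cyc <- cycle_members(edges[edges$predicate == pred & !self, , drop = FALSE])
    for (node in cyc) {
      add(paste0(pred, "_cycle"), node, detail = "term lies on a directed cycle")
    }
  }
  for (pred in c("precedes", "preceded_by")) {
    inv <- if (pred == "precedes") "preceded_by" else "precedes"
    fwd <- edges[edges$predicate == pred, , drop = FALSE]
    if (nrow(fwd) == 0L) next
    rev_keys <- edge_keys(edges[edges$predicate == inv, , drop = FALSE])
    want <- data.frame(subject = fwd$object, predicate = inv,
                       object = fwd$subject, stringsAsFactors = FALSE)
    miss <- which(!(edge_keys(want) %in% rev_keys))
    for (i in miss) {
      add("missing_inverse", fwd$subject[i], fwd$object[i],
          sprintf("no %s inverse", inv))
    }
  }
  bad_id <- ids[!grepl(CURIE_PATTERN, ids)]
  for (id in bad_id) add("bad_curie", id, detail = "id does not match prefix:0000000")
  obs <- obsolete_ids(graph)
  obs_out <- intersect(obs, edges$subject)
  for (id in obs_out) add("obsolete_edge", id, detail = "obsolete term has outgoing edges")

  if (!length(issues)) {
    return(data.frame(issue_type = character(), subject = character(),
                      object = character(), detail = character(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, issues)
}

# Terms lying on a directed cycle (self-edges excluded by the caller):
# node is on a cycle iff it can reach itself through >= 1 edge.
cycle_members <- function(edges) {
  nodes <- unique(c(edges$subject, edges$object))
  if (!length(nodes)) return(character())
  adj <- split(edges$object, edges$subject)
  on_cycle <- vapply(nodes, function(n) {
    reach <- bfs_closure(adj, n)
    # bfs_closure drops the start; re-check direct and indirect return paths
    n %in% unlist(adj[c(n, reach)], use.names = FALSE)
  }, TRUE)
  nodes[on_cycle]
}

#' Write a validation report as TSV
#'
#' @param report data frame from [validate_stage_graph()].
#' @param file path to write to.
#' @return The file path, invisibly.
#' @export
write_validation_report <- function(report, file) {
  utils::write.table(report, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
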