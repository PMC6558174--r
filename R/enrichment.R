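# Slim-mapped one-sided Fisher term enrichment with Benjamini-Yekutieli
# adjustment, and cross-set comparison of enrichment results.

#' Enrichment parameters
#'
#' @param min_mapped minimum number of study genes mapped to a term for the
#'   term to be tested (terms below this are pruned as untestable).
#' @param alpha significance level applied to the adjusted p-values.
#' @param adjustment multiple-test adjustment; Benjamini-Yekutieli (`"BY"`,
#'   valid under arbitrary dependence between term tests) or
#'   Benjamini-Hochberg (`"BH"`).
#' @param slim_terms optional character vector of slim term ids; when given,
#'   annotations are mapped to their minimal slim ancestors before testing.
#' @return List of class `enrichment_params`.
#' @export
enrichment_params <- function(min_mapped = 5, alpha = 0.05,
                              adjustment = c("BY", "BH"),
                              slim_terms = NULL) {
  stopifnot(min_mapped >= 1, alpha > 0, alpha < 1)
  structure(list(min_mapped = min_mapped, alpha = alpha,
                 adjustment = match.arg(adjustment),
                 slim_terms = slim_terms),
            class = "enrichment_params")
}

as_gene_terms <- function(gene_terms) {
  stopifnot(is.data.frame(gene_terms),
            all(c("gene_id", "term_id") %in% names(gene_terms)))
  unique(data.frame(gene_id = as.character(gene_terms$gene_id),
                    term_id = as.character(gene_terms$term_id),
                    stringsAsFactors = FALSE))
}

#' Map gene annotations onto a slim term set
#'
#' Replaces each annotated term by its minimal slim ancestors: the slim
#' terms reachable from the annotated term (including itself) that have no
#' other reachable slim term as a descendant. A term already in the slim
#' maps to itself. Genes none of whose terms reach any slim term are dropped
#' and counted in attribute `"n_dropped"` (`"dropped_genes"` holds the ids).
#' A gene is counted at most once per slim term.
#'
#' @param graph a [stage_graph()] (or any term DAG in that representation).
#' @param gene_terms data frame with columns `gene_id`, `term_id`.
#' @param slim_terms character vector of slim term ids, all present in
#'   `graph`.
#' @param predicates relations followed when walking to ancestors
#'   (default `is_a` and `part_of`, the usual slimming semantics).
#' @return Data frame `gene_id`, `term_id` in slim space.
#' @export
map_to_slim <- function(graph, gene_terms, slim_terms,
                        predicates = c("is_a", "part_of")) {
  gene_terms <- as_gene_terms(gene_terms)
  missing <- setdiff(slim_terms, graph$terms$id)
  if (length(missing)) {
    stop("slim term(s) absent from graph: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  terms <- unique(gene_terms$term_id)
  anc_cache <- lapply(terms, function(t) {
    if (!has_term(graph, t)) character()
    else c(t, stage_ancestors(graph, t, predicates))
  })
  names(anc_cache) <- terms
  slim_of <- lapply(terms, function(t) {
    s <- intersect(anc_cache[[t]], slim_terms)
    if (length(s) <= 1L) return(s)
    # minimal elements: drop any slim ancestor that is an ancestor of
    # another reachable slim term
    keep <- vapply(s, function(si) {
      !any(vapply(setdiff(s, si), function(sj) {
        si %in% stage_ancestors(graph, sj, predicates)
      }, TRUE))
    }, TRUE)
    s[keep]
  })
  names(slim_of) <- terms
  mapped <- lapply(seq_len(nrow(gene_terms)), function(i) {
    st <- slim_of[[gene_terms$term_id[i]]]
    if (!length(st)) return(NULL)
    data.frame(gene_id = gene_terms$gene_id[i], term_id = st,
               stringsAsFactors = FALSE)
  })
  out <- unique(do.call(rbind, c(mapped, list(
    data.frame(gene_id = character(), term_id = character(),
               stringsAsFactors = FALSE)))))
  rownames(out) <- NULL
  dropped <- setdiff(unique(gene_terms$gene_id), unique(out$gene_id))
  attr(out, "n_dropped") <- length(dropped)
  attr(out, "dropped_genes") <- dropped
  out
}

#' One-sided hypergeometric over-representation p-value
#'
#' `P[X >= k]` for `X ~ Hypergeometric` with population size `N`, `K`
#' population successes and a sample (study set) of size `n`: the
#' probability of seeing at least the observed number of study genes
#' carrying the term if study membership were independent of the term.
#' Identical to the one-sided Fisher exact test on the corresponding 2x2
#' table.
#'
#' @param k study genes carrying the term.
#' @param n study size.
#' @param K population genes carrying the term.
#' @param N population size.
#' @return p-value in `(0, 1]`.
#' @export
hypergeom_pvalue <- function(k, n, K, N) {
  ok <- k >= 0 & n >= 0 & K >= 0 & N >= 1 & k <= pmin(n, K) & n <= N & K <= N &
    k >= pmax(0, n + K - N)
  if (!all(ok)) {
    stop("invalid hypergeometric counts: need 0 <= k <= min(n, K), ",
         "k >= n + K - N, n <= N, K <= N", call. = FALSE)
  }
  pmin(1, stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE))
}

#' Benjamini-Yekutieli adjusted p-values
#'
#' Step-up FDR adjustment with the harmonic-sum correction
#' `c(m) = sum(1/i, i = 1..m)`, valid under arbitrary dependence among the
#' tests: for the r-th smallest p-value the adjusted value is
#' `min over j >= r of (m * c(m) * p_(j) / j)`, capped at 1, returned in the
#' input order.
#'
#' @param pvals numeric vector of p-values in `(0, 1]`.
#' @return Adjusted p-values, same length and order.
#' @export
adjust_by <- function(pvals) {
  if (length(pvals) == 0L) return(numeric())
  if (any(is.na(pvals)) || any(pvals <= 0 | pvals > 1)) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  stats::p.adjust(pvals, method = "BY")
}

#' Fisher term enrichment of a study set against a population
#'
#' For every term mapped to at least `min_mapped` study genes, tests
#' over-representation of the term in the study set with the one-sided
#' hypergeometric test, then adjusts the family of p-values
#' (Benjamini-Yekutieli by default) and flags terms with adjusted FDR at or
#' below `alpha`. Population genes with no term mapping are excluded from
#' the population size `N` (their count is attached as attribute
#' `"n_unmapped_population"`). When `params$slim_terms` is set, annotations
#' are first collapsed with [map_to_slim()] (requires `graph`).
#'
#' @param study character vector of study gene ids (must be a subset of
#'   `population`, nonempty).
#' @param population character vector of background gene ids.
#' @param gene_terms data frame with columns `gene_id`, `term_id`.
#' @param params an [enrichment_params()].
#' @param graph optional [stage_graph()], needed for slim mapping.
#' @return Data frame of class `enrichment_result` with columns `term_id`,
#'   `k`, `n`, `K`, `N`, `p_value`, `fdr`, `significant`, ordered by
#'   p-value.
#' @export
fisher_enrichment <- function(study, population, gene_terms,
                              params = enrichment_params(), graph = NULL) {
  study <- unique(study); population <- unique(population)
  if (length(study) == 0L) stop("empty study set", call. = FALSE)
  extra <- setdiff(study, population)
  if (length(extra)) {
    stop("study set is not a subset of the population (e.g. ",
         extra[1L], ")", call. = FALSE)
  }
  gene_terms <- as_gene_terms(gene_terms)
  if (!is.null(params$slim_terms)) {
    if (is.null(graph)) {
      stop("slim mapping requested but no graph supplied", call. = FALSE)
    }
    gene_terms <- map_to_slim(graph, gene_terms, params$slim_terms)
  }
  gene_terms <- gene_terms[gene_terms$gene_id %in% population, , drop = FALSE]
  mapped_genes <- unique(gene_terms$gene_id)
  n_unmapped <- length(setdiff(population, mapped_genes))
  pop <- intersect(population, mapped_genes)
  stu <- intersect(study, pop)
  N <- length(pop)
  n <- length(stu)
  if (n == 0L) stop("no study gene has a term mapping", call. = FALSE)

  K_tab <- table(gene_terms$term_id)
  in_study <- gene_terms$gene_id %in% stu
  k_tab <- table(gene_terms$term_id[in_study])
  test_terms <- names(k_tab)[k_tab >= params$min_mapped]
  res <- data.frame(
    term_id = test_terms,
    k = as.integer(k_tab[test_terms]),
    n = n,
    K = as.integer(K_tab[test_terms]),
    N = N,
    stringsAsFactors = FALSE
  )
  res$p_value <- if (nrow(res)) hypergeom_pvalue(res$k, res$n, res$K, res$N) else numeric()
  res$fdr <- if (nrow(res)) {
    if (params$adjustment == "BY") adjust_by(res$p_value)
    else stats::p.adjust(res$p_value, method = "BH")
  } else numeric()
  res$significant <- res$fdr <= params$alpha
  res <- res[order(res$p_value, res$term_id), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "n_unmapped_population") <- n_unmapped
  class(res) <- c("enrichment_result", "data.frame")
  res
}

#' Cross-tabulate enrichment results across gene sets
#'
#' Builds a term-by-set grid of adjusted FDR values and significance flags
#' over the union of tested terms, with per-set significant counts and the
#' union/intersection of the significant term lists — the cross-comparison
#' view used to contrast enrichment profiles of several gene sets.
#'
#' @param results_per_set named list (length >= 2) of `enrichment_result`
#'   data frames from [fisher_enrichment()].
#' @param alpha significance level applied to the stored `fdr` columns.
#' @return List of class `compare_table`: `grid` (data frame `term_id` plus
#'   `fdr.<set>` and `significant.<set>` columns), `n_significant` (named
#'   vector), `union` and `intersection` (counts over the significant term
#'   lists), `union_terms`, `intersection_terms`.
#' @export
seacompare <- function(results_per_set, alpha = 0.05) {
  stopifnot(is.list(results_per_set), length(results_per_set) >= 2L,
            !is.null(names(results_per_set)))
  all_terms <- sort(unique(unlist(lapply(results_per_set, `[[`, "term_id"),
                                  use.names = FALSE)))
  grid <- data.frame(term_id = all_terms, stringsAsFactors = FALSE)
  sig_sets <- list()
  for (label in names(results_per_set)) {
    r <- results_per_set[[label]]
    fdr <- setNames(r$fdr, r$term_id)[all_terms]
    sig <- !is.na(fdr) & fdr <= alpha
    grid[[paste0("fdr.", label)]] <- unname(fdr)
    grid[[paste0("significant.", label)]] <- sig
    sig_sets[[label]] <- all_terms[sig]
  }
  structure(list(
    grid = grid,
    n_significant = vapply(sig_sets, length, 0L),
    union = length(Reduce(union, sig_sets)),
    intersection = length(Reduce(intersect, sig_sets)),
    union_terms = Reduce(union, sig_sets),
    intersection_terms = Reduce(intersect, sig_sets)
  ), class = "compare_table")
}

#' @export
print.compare_table <- function(x, ...) {
  cat("<compare_table>\n  significant per set:",
      paste(sprintf("%s=%d", names(x$n_significant), x$n_significant),
            collapse = ", "),
      sprintf("\n  union=%d, intersection=%d\n", x$union, x$intersection))
  invisible(x)
}

#' Write an enrichment result (or compare table grid) as TSV
#'
#' @param x an `enrichment_result` data frame or a `compare_table`.
#' @param file path to write to.
#' @return The file path, invisibly.
#' @export
write_enrichment <- function(x, file) {
  df <- if (inherits(x, "compare_table")) x$grid else as.data.frame(x)
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Read a gene-to-term mapping TSV
#'
#' Two tab-separated columns, `gene_id` and `term_id`, with or without a
#' header line.
#'
#' @param file path to the TSV.
#' @return Data frame `gene_id`, `term_id`.
#' @export
read_gene_terms <- function(file) {
  first <- readLines(file, n = 1L)
  has_header <- grepl("gene_id", first, fixed = TRUE)
  df <- utils::read.delim(file, header = has_header, stringsAsFactors = FALSE)
  if (!has_header) names(df)[1:2] <- c("gene_id", "term_id")
  as_gene_terms(df[, c("gene_id", "term_id")])
}

#' Read a one-id-per-line gene list
#'
#' @param file path to the list file.
#' @return Character vector of distinct ids.
#' @export
read_gene_list <- function(file) {
  x <- trimws(readLines(file, warn = FALSE))
  unique(x[nzchar(x)])
}
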