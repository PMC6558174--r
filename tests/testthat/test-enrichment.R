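# Independent enumeration oracle: P[X >= k] from the hypergeometric mass
# written out with binomial coefficients.
enum_tail <- function(k, n, K, N) {
  x <- k:min(n, K)
  sum(exp(lchoose(K, x) + lchoose(N - K, n - x) - lchoose(N, n)))
}

test_that("hypergeometric p-value handles the boundary cases", {
  expect_equal(hypergeom_pvalue(0, 3, 2, 5), 1.0)
  expect_equal(hypergeom_pvalue(2, 5, 2, 5), 1.0)   # study = population
  expect_equal(hypergeom_pvalue(2, 3, 2, 5), 0.3)   # enumeration: 3/10
  expect_error(hypergeom_pvalue(3, 2, 2, 5), "invalid")
  expect_error(hypergeom_pvalue(0, 3, 6, 5), "invalid")
})

test_that("hypergeometric p-value matches enumeration on random counts", {
  set.seed(19)
  for (rep in 1:200) {
    N <- sample(2:60, 1)
    n <- sample(0:N, 1)
    K <- sample(0:N, 1)
    ks <- max(0, n + K - N):min(n, K)
    k <- ks[sample.int(length(ks), 1)]
    expect_equal(hypergeom_pvalue(k, n, K, N), enum_tail(k, n, K, N),
                 tolerance = 1e-12)
  }
})

test_that("BY adjustment reproduces the hand-evaluated step-up formula", {
  expect_equal(adjust_by(0.5), 0.5)          # c(1) = 1
  expect_equal(adjust_by(c(0.01, 0.02, 0.03)), c(0.055, 0.055, 0.055))
  expect_equal(adjust_by(rep(1, 5)), rep(1, 5))
  expect_error(adjust_by(c(0.5, 0)), "\\(0, 1\\]")
  expect_error(adjust_by(c(0.5, 1.2)), "\\(0, 1\\]")
})

test_that("BY is monotone, never below raw p, and never below BH", {
  set.seed(4)
  for (rep in 1:50) {
    p <- runif(sample(2:30, 1))
    by <- adjust_by(p)
    bh <- p.adjust(p, "BH")
    expect_true(all(by >= p))
    expect_true(all(by >= bh))
    ord <- order(p)
    expect_true(all(diff(by[ord]) >= -1e-12))
  }
})

test_that("map_to_slim keeps slim terms fixed and finds minimal slim ancestors", {
  # chain t -> s1 -> s2 with both s1 and s2 in the slim: only the closer
  # slim term s1 survives
  txt <- c("[Term]", "id: SL:0000001", "name: t", "is_a: SL:0000002",
           "", "[Term]", "id: SL:0000002", "name: s1", "is_a: SL:0000003",
           "", "[Term]", "id: SL:0000003", "name: s2",
           "", "[Term]", "id: SL:0000004", "name: orphan")
  g <- parse_obo(text = txt)
  slim <- c("SL:0000002", "SL:0000003")

  gt <- data.frame(gene_id = c("g1", "g2", "g3"),
                   term_id = c("SL:0000001", "SL:0000002", "SL:0000004"))
  out <- map_to_slim(g, gt, slim)
  expect_equal(out$term_id[out$gene_id == "g1"], "SL:0000002")
  expect_equal(out$term_id[out$gene_id == "g2"], "SL:0000002")  # maps to itself
  expect_false("g3" %in% out$gene_id)                           # no slim ancestor
  expect_equal(attr(out, "n_dropped"), 1L)
  expect_equal(attr(out, "dropped_genes"), "g3")

  expect_error(map_to_slim(g, gt, "SL:9999999"), "SL:9999999")
})

test_that("minimal slim ancestors match a path-search oracle on random DAGs", {
  for (seed in 1:5) {
    g <- random_dag_graph(40, p = 0.08, seed = seed)
    set.seed(seed + 50)
    slim <- sample(g$terms$id, 8)
    genes <- sprintf("g%02d", 1:15)
    gt <- data.frame(gene_id = genes,
                     term_id = sample(g$terms$id, 15, replace = TRUE))
    out <- map_to_slim(g, gt, slim, predicates = "is_a")
    for (i in seq_along(genes)) {
      t <- gt$term_id[i]
      reach <- c(t, igraph_reachable(g, t, "is_a"))
      s <- intersect(reach, slim)
      minimal <- s[vapply(s, function(si) {
        !any(vapply(setdiff(s, si),
                    function(sj) si %in% igraph_reachable(g, sj, "is_a"), TRUE))
      }, TRUE)]
      expect_setequal(out$term_id[out$gene_id == genes[i]], minimal)
    }
    mapped <- length(unique(out$gene_id))
    expect_equal(mapped + attr(out, "n_dropped"), length(unique(gt$gene_id)))
  }
})

test_that("fisher_enrichment tests only terms meeting the study minimum", {
  gt <- data.frame(
    gene_id = c(sprintf("s%d", 1:4), sprintf("s%d", 1:6), sprintf("p%d", 1:30)),
    term_id = c(rep("T:0000001", 4), rep("T:0000002", 6), rep("T:0000003", 30)))
  study <- sprintf("s%d", 1:6)
  population <- unique(gt$gene_id)
  res <- fisher_enrichment(study, population, gt,
                           enrichment_params(min_mapped = 5))
  expect_false("T:0000001" %in% res$term_id)  # only 4 study genes mapped
  expect_true("T:0000002" %in% res$term_id)
})

test_that("fisher_enrichment validates its inputs", {
  gt <- data.frame(gene_id = c("g1", "g2"), term_id = "T:0000001")
  expect_error(fisher_enrichment(character(), c("g1", "g2"), gt), "empty study")
  expect_error(fisher_enrichment("zz", c("g1", "g2"), gt), "subset")
})

test_that("study equal to population yields nothing significant", {
  set.seed(8)
  genes <- sprintf("g%03d", 1:200)
  gt <- data.frame(gene_id = sample(genes, 400, replace = TRUE),
                   term_id = sample(sprintf("T:%07d", 1:5), 400, replace = TRUE))
  res <- fisher_enrichment(genes, genes, gt, enrichment_params())
  expect_true(all(res$p_value == 1))
  expect_false(any(res$significant))
})

test_that("a planted five-fold term gets the smallest FDR", {
  fx <- make_enrichment_fixture(n_genes = 3000, n_terms = 10, fold = 5,
                                study_size = 150, seed = 42)
  res <- fisher_enrichment(fx$study, fx$population, fx$gene_terms,
                           enrichment_params())
  expect_equal(res$term_id[1L], fx$truth$enriched_term)
  expect_equal(res$fdr[1L], min(res$fdr))
  expect_true(res$significant[1L])
  expect_true(all(res$fdr >= res$p_value))
})

test_that("unmapped population genes are excluded from N and counted", {
  gt <- data.frame(gene_id = sprintf("g%d", 1:10),
                   term_id = rep("T:0000001", 10))
  population <- sprintf("g%d", 1:15)     # 5 genes without any mapping
  res <- fisher_enrichment(sprintf("g%d", 1:6), population, gt,
                           enrichment_params(min_mapped = 3))
  expect_equal(unique(res$N), 10L)
  expect_equal(attr(res, "n_unmapped_population"), 5L)
})

test_that("seacompare cross-tabulates significance across sets", {
  mk <- function(terms, fdrs) {
    structure(data.frame(term_id = terms, k = 1, n = 1, K = 1, N = 1,
                         p_value = fdrs, fdr = fdrs,
                         significant = fdrs <= 0.05,
                         stringsAsFactors = FALSE),
              class = c("enrichment_result", "data.frame"))
  }
  r1 <- mk(c("T:0000001", "T:0000002", "T:0000003"), c(0.01, 0.20, 0.04))
  r2 <- mk(c("T:0000002", "T:0000003", "T:0000004"), c(0.30, 0.02, 0.01))
  cmp <- seacompare(list(one = r1, two = r2), alpha = 0.05)
  expect_equal(unname(cmp$n_significant), c(2L, 2L))
  expect_equal(cmp$union, 3L)
  expect_equal(cmp$intersection, 1L)
  expect_setequal(cmp$intersection_terms, "T:0000003")
  expect_equal(nrow(cmp$grid), 4L)

  same <- seacompare(list(a = r1, b = r1))
  expect_equal(same$union, same$intersection)
  expect_equal(same$union, unname(same$n_significant[1L]))
})

test_that("seacompare counts equal brute-force set algebra on random grids", {
  set.seed(13)
  for (rep in 1:10) {
    terms <- sprintf("T:%07d", 1:20)
    mk_rand <- function() {
      ts <- sample(terms, sample(8:15, 1))
      structure(data.frame(term_id = ts, k = 1, n = 1, K = 1, N = 1,
                           p_value = runif(length(ts)), fdr = runif(length(ts)),
                           significant = NA, stringsAsFactors = FALSE),
                class = c("enrichment_result", "data.frame"))
    }
    sets <- list(a = mk_rand(), b = mk_rand(), c = mk_rand())
    cmp <- seacompare(sets, alpha = 0.3)
    sig <- lapply(sets, function(r) r$term_id[r$fdr <= 0.3])
    expect_equal(unname(cmp$n_significant), unname(vapply(sig, length, 0L)))
    expect_equal(cmp$union, length(unique(unlist(sig))))
    expect_equal(cmp$intersection, length(Reduce(intersect, sig)))
  }
})
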