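# Stage overlap and uniqueness statistics, within and between species.

#' Construct a per-stage identifier map
#'
#' Holds, for one species, the distinct identifiers (gene ids or homolog
#' cluster ids) associated with each development stage. All set statistics
#' in this package operate on these deduplicated sets.
#'
#' @param species species label.
#' @param stages named list; each element a character vector of identifiers
#'   for one stage (names are stage term ids or labels).
#' @param id_space `"gene"` or `"cluster"`.
#' @param min_genes stages with fewer identifiers than this trigger a
#'   warning (sparsely annotated species/stage combinations give unstable
#'   percentages and are normally excluded from analysis).
#' @return An object of class `stage_gene_map`.
#' @export
stage_gene_map <- function(species, stages, id_space = c("gene", "cluster"),
                           min_genes = 50) {
  id_space <- match.arg(id_space)
  stopifnot(is.list(stages), length(names(stages)) == length(stages))
  stages <- lapply(stages, function(x) unique(as.character(x)))
  small <- names(stages)[lengths(stages) < min_genes]
  if (length(small)) {
    warning(sprintf("species %s: stage(s) with fewer than %d identifiers: %s",
                    species, min_genes, paste(small, collapse = ", ")),
            call. = FALSE)
  }
  structure(list(species = species, id_space = id_space, stages = stages),
            class = "stage_gene_map")
}

#' @export
print.stage_gene_map <- function(x, ...) {
  cat(sprintf("<stage_gene_map> %s (%s space), %d stages\n",
              x$species, x$id_space, length(x$stages)))
  for (s in names(x$stages)) cat(sprintf("  %s: %d ids\n", s, length(x$stages[[s]])))
  invisible(x)
}

#' Build a stage map from an annotation table
#'
#' Convenience wrapper collecting [genes_for_stage()] for several stages.
#'
#' @inheritParams genes_for_stage
#' @param species species label for the map.
#' @param stages character vector of stage term ids.
#' @param ... passed to [stage_gene_map()] (e.g. `min_genes`).
#' @return A [stage_gene_map()] in gene space.
#' @export
stage_map_from_annotations <- function(table, graph, species, stages,
                                       propagate = FALSE, ...) {
  sets <- lapply(stages, function(s) genes_for_stage(table, graph, s, propagate))
  names(sets) <- stages
  stage_gene_map(species, sets, id_space = "gene", ...)
}

#' Convert a gene-space stage map to cluster space
#'
#' @param map a [stage_gene_map()] in gene space.
#' @param clusters a `homolog_clusters` object.
#' @param ... passed to [stage_gene_map()].
#' @return A [stage_gene_map()] in cluster space; per-stage unmapped gene
#'   counts are attached as attribute `"unmapped"`.
#' @export
stage_map_to_clusters <- function(map, clusters, ...) {
  mapped <- lapply(map$stages, genes_to_clusters, clusters = clusters)
  sets <- lapply(mapped, `[[`, "cluster_ids")
  out <- stage_gene_map(map$species, sets, id_space = "cluster", ...)
  attr(out, "unmapped") <- vapply(mapped, `[[`, 0L, "unmapped")
  out
}

#' Percent overlap between two identifier sets
#'
#' The stage-comparison statistic: shared identifiers divided by the average
#' of the two set sizes, times 100:
#' `|A intersect B| / ((|A| + |B|) / 2) * 100`.
#' Equals 100 iff the sets are equal (and nonempty), 0 iff disjoint.
#'
#' @param a,b character vectors (deduplicated internally).
#' @return Percent in `[0, 100]`.
#' @export
percent_overlap <- function(a, b) {
  a <- unique(a); b <- unique(b)
  if (length(a) + length(b) == 0L) {
    stop("percent_overlap is undefined for two empty sets", call. = FALSE)
  }
  length(intersect(a, b)) / ((length(a) + length(b)) / 2) * 100
}

#' Round half away from zero
#'
#' Fixed-precision rounding matching how the overlap tables are printed
#' (2.5 -> 3 at digits 0), unlike base `round()`'s round-half-even.
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Identifiers unique to each stage
#'
#' For each stage, the identifiers not occurring in any other stage of the
#' same map, with the percent unique relative to the stage total (reported
#' to 2 decimals, half-up).
#'
#' @param map a [stage_gene_map()] with at least one stage.
#' @return Data frame with columns `stage`, `total`, `n_unique`,
#'   `percent_unique`; the unique identifier sets are attached as attribute
#'   `"unique_sets"` (named list).
#' @export
unique_genes <- function(map) {
  stages <- map$stages
  stopifnot(length(stages) >= 1L)
  uniq <- lapply(names(stages), function(s) {
    others <- unlist(stages[setdiff(names(stages), s)], use.names = FALSE)
    setdiff(stages[[s]], others)
  })
  names(uniq) <- names(stages)
  out <- data.frame(
    stage = names(stages),
    total = lengths(stages),
    n_unique = lengths(uniq),
    stringsAsFactors = FALSE
  )
  out$percent_unique <- ifelse(out$total > 0,
                               round_half_up(out$n_unique / out$total * 100, 2),
                               NA_real_)
  rownames(out) <- NULL
  attr(out, "unique_sets") <- uniq
  out
}

#' Pairwise stage overlap matrix within a species
#'
#' Off-diagonal entries are [percent_overlap()] between the two stages'
#' identifier sets; the diagonal carries the percent-unique value from
#' [unique_genes()] (with unique counts as attribute `"unique_counts"`).
#'
#' @param map a [stage_gene_map()] with at least two stages.
#' @return Symmetric numeric matrix with stage names on both dimensions.
#' @export
pairwise_overlap <- function(map) {
  stages <- map$stages
  stopifnot(length(stages) >= 2L)
  n <- length(stages)
  m <- matrix(NA_real_, n, n, dimnames = list(names(stages), names(stages)))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i < j) {
        m[i, j] <- m[j, i] <- percent_overlap(stages[[i]], stages[[j]])
      }
    }
  }
  uq <- unique_genes(map)
  diag(m) <- uq$percent_unique
  attr(m, "unique_counts") <- setNames(uq$n_unique, uq$stage)
  m
}

#' Cross-species stage overlap matrix
#'
#' Percent overlap between every stage of one species and every stage of
#' another, computed on homolog cluster identifiers so that the comparison
#' is meaningful across gene namespaces. Both maps must be in cluster space.
#'
#' @param map_a,map_b [stage_gene_map()]s in cluster id space.
#' @return Numeric matrix, rows = stages of `map_a`, cols = stages of
#'   `map_b`.
#' @export
cross_species_overlap <- function(map_a, map_b) {
  if (map_a$id_space != "cluster" || map_b$id_space != "cluster") {
    stop("cross-species overlap requires both maps in cluster id space",
         call. = FALSE)
  }
  m <- matrix(NA_real_, length(map_a$stages), length(map_b$stages),
              dimnames = list(names(map_a$stages), names(map_b$stages)))
  for (i in names(map_a$stages)) {
    for (j in names(map_b$stages)) {
      m[i, j] <- percent_overlap(map_a$stages[[i]], map_b$stages[[j]])
    }
  }
  m
}

#' Pooled cluster sets and their difference
#'
#' Pools the cluster identifiers across all stages within each species and
#' reports the pooled sizes and how many clusters are present in the first
#' species but not the second (`|A \\ B| = |A| - |A intersect B|`).
#'
#' @param map_a,map_b [stage_gene_map()]s in cluster id space.
#' @return Named numeric vector `c(pooled_a, pooled_b, a_not_b)`.
#' @export
pooled_cluster_difference <- function(map_a, map_b) {
  if (map_a$id_space != "cluster" || map_b$id_space != "cluster") {
    stop("pooled cluster difference requires both maps in cluster id space",
         call. = FALSE)
  }
  a <- unique(unlist(map_a$stages, use.names = FALSE))
  b <- unique(unlist(map_b$stages, use.names = FALSE))
  c(pooled_a = length(a), pooled_b = length(b),
    a_not_b = length(setdiff(a, b)))
}

#' Construct the enrichment contrast sets
#'
#' Builds the four gene sets used for enrichment comparison between an early
#' and a late stage within species A, and between a species-B-specific stage
#' and a species-A-specific stage across species:
#' \itemize{
#'   \item Set1: genes of `early_stage` not in `late_stage` (species A, gene
#'     space);
#'   \item Set2: genes of `late_stage` not in `early_stage`;
#'   \item Set3: clusters of species B's `stage_b` not among species A's
#'     `stage_a` clusters, back-converted to gene ids — `set3a` in species-B
#'     gene ids, `set3b` in species-A gene ids;
#'   \item Set4: all species-A genes of `stage_a`.
#' }
#'
#' @param gene_map_a [stage_gene_map()] for species A in gene space.
#' @param cluster_map_a,cluster_map_b cluster-space maps for the two species.
#' @param clusters the `homolog_clusters` object used for back-conversion.
#' @param early_stage,late_stage stage names in `gene_map_a` (Set1/Set2).
#' @param stage_a stage name in `gene_map_a`/`cluster_map_a` (Set3/Set4).
#' @param stage_b stage name in `cluster_map_b`.
#' @return List of class `contrast_sets` with elements `set1`, `set2`,
#'   `set3a`, `set3b`, `set4` (character vectors) and `recipes` (named
#'   character vector describing each construction).
#' @export
contrast_sets <- function(gene_map_a, cluster_map_a, cluster_map_b, clusters,
                          early_stage, late_stage, stage_a, stage_b) {
  need <- function(map, stage) {
    if (!stage %in% names(map$stages)) {
      stop("stage not present in map for species ", map$species, ": ", stage,
           call. = FALSE)
    }
    map$stages[[stage]]
  }
  early <- need(gene_map_a, early_stage)
  late <- need(gene_map_a, late_stage)
  cl_a <- need(cluster_map_a, stage_a)
  cl_b <- need(cluster_map_b, stage_b)

  set3_clusters <- setdiff(cl_b, cl_a)
  m <- clusters$clusters
  in3 <- m[m$cluster_id %in% set3_clusters, , drop = FALSE]
  species_a <- gene_map_a$species
  set3a <- sort(unique(in3$gene_id[in3$species != species_a]))
  set3b <- sort(unique(in3$gene_id[in3$species == species_a]))

  structure(list(
    set1 = setdiff(early, late),
    set2 = setdiff(late, early),
    set3a = set3a,
    set3b = set3b,
    set4 = need(gene_map_a, stage_a),
    set3_clusters = set3_clusters,
    recipes = c(
      set1 = sprintf("%s genes in %s but not %s", species_a, early_stage, late_stage),
      set2 = sprintf("%s genes in %s but not %s", species_a, late_stage, early_stage),
      set3a = sprintf("clusters of %s:%s not in %s:%s, as %s gene ids",
                      cluster_map_b$species, stage_b, species_a, stage_a,
                      cluster_map_b$species),
      set3b = sprintf("clusters of %s:%s not in %s:%s, as %s gene ids",
                      cluster_map_b$species, stage_b, species_a, stage_a,
                      species_a),
      set4 = sprintf("all %s genes in %s", species_a, stage_a)
    )
  ), class = "contrast_sets")
}

#' Write an overlap matrix as TSV
#'
#' Percent entries are formatted to 2 decimals (half-up).
#'
#' @param m numeric matrix from [pairwise_overlap()] or
#'   [cross_species_overlap()].
#' @param file path to write to.
#' @return The file path, invisibly.
#' @export
write_overlap_matrix <- function(m, file) {
  fm <- format(round_half_up(m, 2), nsmall = 2, trim = TRUE)
  df <- data.frame(stage = rownames(m), fm, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Write gene-list files for contrast sets
#'
#' One id per line, one file per set, suitable as enrichment input.
#'
#' @param sets a `contrast_sets` object.
#' @param dir output directory (created if absent).
#' @return Named character vector of the files written, invisibly.
#' @export
write_contrast_sets <- function(sets, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  nm <- c("set1", "set2", "set3a", "set3b", "set4")
  files <- file.path(dir, paste0(nm, ".txt"))
  for (i in seq_along(nm)) writeLines(sets[[nm[i]]], files[i])
  invisible(setNames(files, nm))
}
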