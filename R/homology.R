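# Reciprocal-best-hit homolog clustering with in-paralog assignment.

#' Construct a similarity hit table
#'
#' Pairwise BLAST-like hits between genes of two species. Scores are bit
#' scores; `query_aln_frac` and `subject_aln_frac` are the fractions of the
#' query and subject sequence lengths covered by the alignment, used by the
#' mutual-overlap filter.
#'
#' @param query_id,subject_id gene identifiers.
#' @param query_species,subject_species species labels.
#' @param score numeric, non-negative.
#' @param query_aln_frac,subject_aln_frac fractions in `[0, 1]`.
#' @return Data frame of class `similarity_hits`.
#' @export
similarity_hits <- function(query_id, subject_id, query_species,
                            subject_species, score,
                            query_aln_frac = 1, subject_aln_frac = 1) {
  n <- length(query_id)
  recycle <- function(x) if (length(x) == 1L && n != 1L) rep(x, n) else x
  query_aln_frac <- recycle(query_aln_frac)
  subject_aln_frac <- recycle(subject_aln_frac)
  out <- data.frame(
    query_id = as.character(query_id),
    subject_id = as.character(subject_id),
    query_species = as.character(query_species),
    subject_species = as.character(subject_species),
    score = as.numeric(score),
    query_aln_frac = as.numeric(query_aln_frac),
    subject_aln_frac = as.numeric(subject_aln_frac),
    stringsAsFactors = FALSE
  )
  if (any(out$score < 0)) stop("scores must be >= 0", call. = FALSE)
  if (any(out$query_aln_frac < 0 | out$query_aln_frac > 1 |
          out$subject_aln_frac < 0 | out$subject_aln_frac > 1)) {
    stop("alignment fractions must lie in [0, 1]", call. = FALSE)
  }
  class(out) <- c("similarity_hits", "data.frame")
  out
}

#' Read a BLAST-like tabular similarity file
#'
#' Tab-separated with a header row. Expected columns: `qseqid`, `sseqid`,
#' `qspecies`, `sspecies`, `bitscore`, and either fraction columns
#' (`qcovfrac`, `scovfrac`) or length columns (`qlen`, `slen`, `qalnlen`,
#' `salnlen`) from which fractions are computed (aligned length capped at
#' sequence length). `col_map` renames nonstandard headers, e.g.
#' `c(qseqid = "query")`.
#'
#' @param file path to a TSV file.
#' @param col_map named character vector mapping standard names to the
#'   file's column names.
#' @return A [similarity_hits()] table.
#' @export
read_similarity_table <- function(file, col_map = character()) {
  raw <- utils::read.delim(file, stringsAsFactors = FALSE, check.names = FALSE)
  pick <- function(std) {
    nm <- if (std %in% names(col_map)) col_map[[std]] else std
    if (!nm %in% names(raw)) return(NULL)
    raw[[nm]]
  }
  qf <- pick("qcovfrac"); sf <- pick("scovfrac")
  if (is.null(qf) || is.null(sf)) {
    qlen <- pick("qlen"); slen <- pick("slen")
    qaln <- pick("qalnlen"); saln <- pick("salnlen")
    if (is.null(qlen) || is.null(slen) || is.null(qaln) || is.null(saln)) {
      stop("similarity table needs qcovfrac/scovfrac or qlen/slen/qalnlen/salnlen",
           call. = FALSE)
    }
    qf <- pmin(qaln, qlen) / qlen
    sf <- pmin(saln, slen) / slen
  }
  similarity_hits(pick("qseqid"), pick("sseqid"), pick("qspecies"),
                  pick("sspecies"), pick("bitscore"), qf, sf)
}

#' Filter hits by mutual alignment overlap
#'
#' Retains hits where at least `min_overlap_frac` of *both* sequences is
#' covered by the alignment (inclusive boundary). The default 0.50 keeps
#' only homolog candidates in which at least half of the two sequences
#' overlap each other.
#'
#' @param hits a [similarity_hits()] table.
#' @param min_overlap_frac threshold in `(0, 1]`.
#' @return Filtered [similarity_hits()].
#' @export
filter_hits <- function(hits, min_overlap_frac = 0.5) {
  stopifnot(min_overlap_frac > 0, min_overlap_frac <= 1)
  out <- hits[hits$query_aln_frac >= min_overlap_frac &
                hits$subject_aln_frac >= min_overlap_frac, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("similarity_hits", "data.frame")
  out
}

# Cross-species hits in both orientations, multiple hits per ordered pair
# collapsed to the maximum score. If only one direction is present for a
# pair, the score is mirrored (symmetric-score assumption).
symmetrized_cross_hits <- function(hits, species_a, species_b) {
  cross <- hits[(hits$query_species == species_a & hits$subject_species == species_b) |
                  (hits$query_species == species_b & hits$subject_species == species_a),
                , drop = FALSE]
  if (nrow(cross) == 0L) {
    return(data.frame(from = character(), to = character(), score = numeric(),
                      stringsAsFactors = FALSE))
  }
  both <- rbind(
    data.frame(from = cross$query_id, to = cross$subject_id,
               score = cross$score, stringsAsFactors = FALSE),
    data.frame(from = cross$subject_id, to = cross$query_id,
               score = cross$score, stringsAsFactors = FALSE)
  )
  key <- paste(both$from, both$to, sep = "\r")
  best <- tapply(both$score, key, max)
  ft <- do.call(rbind, strsplit(names(best), "\r", fixed = TRUE))
  data.frame(from = ft[, 1L], to = ft[, 2L], score = as.numeric(best),
             stringsAsFactors = FALSE)
}

# Best hit of each `from` gene under the deterministic tie-break
# (highest score, then lexicographically smallest target id).
best_hits <- function(pairs_df) {
  if (nrow(pairs_df) == 0L) return(character())
  ord <- order(pairs_df$from, -pairs_df$score, pairs_df$to)
  sorted <- pairs_df[ord, , drop = FALSE]
  first <- !duplicated(sorted$from)
  setNames(sorted$to[first], sorted$from[first])
}

#' Reciprocal best hit pairs between two species
#'
#' A pair `(a, b)` is returned iff `b` is `a`'s highest-scoring
#' cross-species hit and `a` is `b`'s, with score ties broken
#' deterministically toward the lexicographically smaller target id. When
#' hits exist in only one orientation the score is mirrored, so the result
#' does not depend on which species was queried.
#'
#' @param hits a [similarity_hits()] table (typically after [filter_hits()]).
#' @param species_a,species_b the two species labels; pairs are oriented
#'   `(gene of species_a, gene of species_b)`.
#' @return Data frame with columns `gene_a`, `gene_b`, `score`, ordered by
#'   `gene_a`.
#' @export
reciprocal_best_pairs <- function(hits, species_a, species_b) {
  sym <- symmetrized_cross_hits(hits, species_a, species_b)
  empty <- data.frame(gene_a = character(), gene_b = character(),
                      score = numeric(), stringsAsFactors = FALSE)
  if (nrow(sym) == 0L) return(empty)
  species_of <- species_lookup(hits)
  a_genes <- names(species_of)[species_of == species_a]
  sym_ab <- sym[sym$from %in% a_genes, , drop = FALSE]
  sym_ba <- sym[!(sym$from %in% a_genes), , drop = FALSE]
  best_ab <- best_hits(sym_ab)
  best_ba <- best_hits(sym_ba)
  a <- names(best_ab)
  b <- unname(best_ab)
  recip <- !is.na(best_ba[b]) & best_ba[b] == a
  if (!any(recip)) return(empty)
  score_key <- paste(sym_ab$from, sym_ab$to, sep = "\r")
  scores <- setNames(sym_ab$score, score_key)
  out <- data.frame(gene_a = a[recip], gene_b = b[recip],
                    score = unname(scores[paste(a[recip], b[recip], sep = "\r")]),
                    stringsAsFactors = FALSE)
  out <- out[order(out$gene_a), , drop = FALSE]
  rownames(out) <- NULL
  out
}

species_lookup <- function(hits) {
  ids <- c(hits$query_id, hits$subject_id)
  sp <- c(hits$query_species, hits$subject_species)
  first <- !duplicated(ids)
  setNames(sp[first], ids[first])
}

#' Build homolog clusters from reciprocal best pairs
#'
#' Each reciprocal best pair seeds one cluster. An unseeded gene `g` of one
#' species joins the cluster seeded by `(a, b)` (with `b` in the other
#' species) iff `g`'s best cross-species hit is `b` and
#' `score(g, b) >= score(a, b)` (the in-paralog rule). A gene qualifying for
#' several clusters joins the one where its qualifying score is highest;
#' every gene belongs to at most one cluster. Cluster ids are deterministic
#' (`HC` + index after sorting seeds by gene id).
#'
#' @param pairs data frame from [reciprocal_best_pairs()].
#' @param hits the [similarity_hits()] table the pairs were derived from.
#' @param species_a,species_b the two species labels.
#' @return An object of class `homolog_clusters`: list with `clusters` (data
#'   frame `cluster_id`, `gene_id`, `species`, `is_inparalog`) and `seeds`
#'   (data frame `cluster_id`, `gene_a`, `gene_b`, `score`).
#' @export
build_clusters <- function(pairs, hits, species_a, species_b) {
  if (nrow(pairs) == 0L) {
    return(structure(list(
      clusters = data.frame(cluster_id = character(), gene_id = character(),
                            species = character(), is_inparalog = logical(),
                            stringsAsFactors = FALSE),
      seeds = cbind(data.frame(cluster_id = character(),
                               stringsAsFactors = FALSE), pairs)),
      class = "homolog_clusters"))
  }
  pairs <- pairs[order(pairs$gene_a, pairs$gene_b), , drop = FALSE]
  pairs$cluster_id <- sprintf("HC%05d", seq_len(nrow(pairs)))
  sym <- symmetrized_cross_hits(hits, species_a, species_b)
  species_of <- species_lookup(hits)
  seed_genes <- c(pairs$gene_a, pairs$gene_b)

  members <- data.frame(
    cluster_id = rep(pairs$cluster_id, 2L),
    gene_id = seed_genes,
    species = c(rep(species_a, nrow(pairs)), rep(species_b, nrow(pairs))),
    is_inparalog = FALSE,
    stringsAsFactors = FALSE
  )

  # candidate in-paralogs: unseeded genes whose best cross hit is a seed's
  # partner and whose score reaches the seed score
  free <- setdiff(unique(c(sym$from, sym$to)), seed_genes)
  if (length(free)) {
    best <- best_hits(sym[sym$from %in% free, , drop = FALSE])
    seed_of_partner <- c(setNames(seq_len(nrow(pairs)), pairs$gene_a),
                         setNames(seq_len(nrow(pairs)), pairs$gene_b))
    score_key <- paste(sym$from, sym$to, sep = "\r")
    score_of <- setNames(sym$score, score_key)
    cand <- lapply(names(best), function(g) {
      partner <- best[[g]]
      idx <- seed_of_partner[partner]
      if (is.na(idx)) return(NULL)
      # partner must belong to the opposite species' side of the seed
      seed_mate <- if (pairs$gene_a[idx] == partner) pairs$gene_b[idx] else pairs$gene_a[idx]
      g_score <- score_of[[paste(g, partner, sep = "\r")]]
      if (g_score >= pairs$score[idx]) {
        data.frame(gene_id = g, cluster_idx = idx, qual_score = g_score,
                   stringsAsFactors = FALSE)
      } else NULL
    })
    cand <- do.call(rbind, cand)
    if (!is.null(cand) && nrow(cand)) {
      # conflicts: keep highest qualifying score per gene (ties: lowest idx)
      cand <- cand[order(cand$gene_id, -cand$qual_score, cand$cluster_idx), ,
                   drop = FALSE]
      cand <- cand[!duplicated(cand$gene_id), , drop = FALSE]
      members <- rbind(members, data.frame(
        cluster_id = pairs$cluster_id[cand$cluster_idx],
        gene_id = cand$gene_id,
        species = unname(species_of[cand$gene_id]),
        is_inparalog = TRUE,
        stringsAsFactors = FALSE
      ))
    }
  }
  members <- members[order(members$cluster_id, members$is_inparalog,
                           members$gene_id), , drop = FALSE]
  rownames(members) <- NULL
  structure(list(clusters = members,
                 seeds = pairs[, c("cluster_id", "gene_a", "gene_b", "score")]),
            class = "homolog_clusters")
}

#' @export
print.homolog_clusters <- function(x, ...) {
  cat(sprintf("<homolog_clusters> %d clusters, %d genes (%d in-paralogs)\n",
              nrow(x$seeds), nrow(x$clusters), sum(x$clusters$is_inparalog)))
  invisible(x)
}

#' Map genes to homolog cluster ids
#'
#' @param genes character vector of gene ids.
#' @param clusters a `homolog_clusters` object from [build_clusters()].
#' @return List with `cluster_ids` (sorted distinct ids of clusters
#'   containing any input gene), `unmapped` (count of input genes in no
#'   cluster) and `unmapped_ids`.
#' @export
genes_to_clusters <- function(genes, clusters) {
  genes <- unique(genes)
  m <- clusters$clusters
  hit <- m[m$gene_id %in% genes, , drop = FALSE]
  unmapped_ids <- setdiff(genes, m$gene_id)
  list(cluster_ids = sort(unique(hit$cluster_id)),
       unmapped = length(unmapped_ids),
       unmapped_ids = unmapped_ids)
}

#' Write homolog clusters as TSV
#'
#' @param clusters a `homolog_clusters` object.
#' @param file path to write to.
#' @return The file path, invisibly.
#' @export
write_clusters <- function(clusters, file) {
  utils::write.table(clusters$clusters, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}
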