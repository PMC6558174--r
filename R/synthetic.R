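# Seeded synthetic fixtures with the statistical structure the comparison
# workflow assumes: a stage ontology with a temporal chain, annotation
# tables with a controlled shared fraction, similarity tables with planted
# ortholog pairs, and enrichment inputs with a planted over-represented
# term.

# Run `code` under `set.seed(seed)`, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

synthetic_stage_ids <- function(n_stages) sprintf("SD:%07d", 1000 + seq_len(n_stages))

#' Generate a synthetic stage ontology
#'
#' A linear temporal chain of `n_stages` leaf stages (consecutive stages
#' linked by `precedes`, with inverses materialised), grouped under
#' `n_groups` `is_a` parents below a single root — the shape of a real
#' development-stage branch: an `is_a` hierarchy crossed with a
#' `precedes` chain. The generated graph always passes
#' [validate_stage_graph()] with an empty report.
#'
#' @param n_stages number of leaf stages (>= 1).
#' @param n_groups number of intermediate grouping terms
#'   (1 <= n_groups <= n_stages).
#' @param seed unused (the construction is deterministic); accepted for API
#'   symmetry with the other generators.
#' @return A [stage_graph()].
#' @export
make_stage_ontology <- function(n_stages, n_groups = 1, seed = NULL) {
  if (n_stages < 1 || n_groups < 1 || n_groups > n_stages) {
    stop("need n_stages >= 1 and 1 <= n_groups <= n_stages", call. = FALSE)
  }
  root <- "SD:0000001"
  groups <- sprintf("SD:%07d", 100 + seq_len(n_groups))
  leaves <- synthetic_stage_ids(n_stages)
  group_of <- groups[ceiling(seq_len(n_stages) * n_groups / n_stages)]

  terms <- data.frame(
    id = c(root, groups, leaves),
    name = c("synthetic whole plant development stage",
             sprintf("synthetic stage group %d", seq_len(n_groups)),
             sprintf("synthetic development stage %d", seq_len(n_stages))),
    namespace = "synthetic_development_stage",
    is_obsolete = FALSE,
    stringsAsFactors = FALSE
  )
  terms$synonyms <- rep(list(character()), nrow(terms))

  edges <- rbind(
    data.frame(subject = groups, predicate = "is_a", object = root,
               stringsAsFactors = FALSE),
    data.frame(subject = leaves, predicate = "is_a", object = group_of,
               stringsAsFactors = FALSE),
    if (n_stages > 1) {
      data.frame(subject = leaves[-n_stages], predicate = "precedes",
                 object = leaves[-1L], stringsAsFactors = FALSE)
    }
  )
  g <- stage_graph(terms, edges, header = c("format-version: 1.2",
                                            "ontology: synthetic-stages"))
  attr(g, "leaf_stages") <- leaves
  g
}

#' Generate a synthetic stage annotation table
#'
#' Emulates the empirical structure of stage-annotation data: a large core
#' of genes annotated to every stage (high between-stage overlap) and a
#' small stage-unique remainder. A core pool of
#' `round(shared_frac * genes_per_stage)` genes is annotated to all stages;
#' the remaining genes of each stage are specific to it. Evidence codes are
#' sampled with fixed proportions (IEP 0.60, IDA 0.25, IEA 0.15), so
#' evidence filtering removes roughly 15% of records.
#'
#' @param genes_per_stage identifiers per stage.
#' @param shared_frac fraction of each stage's genes drawn from the shared
#'   core, in `[0, 1]`.
#' @param n_stages number of stages.
#' @param seed integer seed (drives evidence-code sampling).
#' @param stages optional stage term ids (default the leaf ids of
#'   [make_stage_ontology()]).
#' @return List with `table` (an [annotation_table()]) and `truth` (planted
#'   structure: core and per-stage unique gene ids, parameters, seed).
#' @export
make_annotation_table <- function(genes_per_stage, shared_frac,
                                  n_stages = 4, seed = 1, stages = NULL) {
  stopifnot(shared_frac >= 0, shared_frac <= 1, genes_per_stage >= 1,
            n_stages >= 1)
  if (is.null(stages)) stages <- synthetic_stage_ids(n_stages)
  stopifnot(length(stages) == n_stages)
  n_core <- round(shared_frac * genes_per_stage)
  n_uniq <- genes_per_stage - n_core
  core <- sprintf("GCORE%05d", seq_len(n_core))
  uniq <- lapply(seq_len(n_stages), function(i) {
    if (n_uniq == 0L) character() else sprintf("GS%02dU%05d", i, seq_len(n_uniq))
  })
  names(uniq) <- stages

  gene_col <- unlist(lapply(seq_len(n_stages), function(i) c(core, uniq[[i]])),
                     use.names = FALSE)
  stage_col <- rep(stages, each = genes_per_stage)
  n_rec <- length(gene_col)
  evid <- with_seed(seed, sample(c("IEP", "IDA", "IEA"), n_rec, replace = TRUE,
                                 prob = c(0.60, 0.25, 0.15)))
  tab <- annotation_table(data.frame(
    source_db = "SYNTH",
    object_id = gene_col,
    object_symbol = gene_col,
    term_id = stage_col,
    reference = "SYNTH:0000001",
    evidence_code = evid,
    aspect = "T",
    object_type = "gene",
    taxon = "taxon:0000001",
    date = "20181201",
    assigned_by = "SYNTH",
    stringsAsFactors = FALSE
  ))
  list(table = tab,
       truth = list(core_genes = core, unique_genes = uniq,
                    genes_per_stage = genes_per_stage,
                    shared_frac = shared_frac, stages = stages, seed = seed))
}

#' Generate a synthetic cross-species similarity table
#'
#' Plants `n_pairs` one-to-one ortholog pairs (scores in `[200, 400]`, high
#' mutual overlap), `n_inparalogs` in-paralogs and `n_noise` noise hits.
#' Each in-paralog gene carries a within-species hit to its seed gene
#' scoring up to 10% above the seed pair's score (the in-paralog evidence)
#' and a cross-species hit to the seed's partner tied exactly at the seed
#' score; in-paralog ids sort after their seed's id, so the deterministic
#' tie-break keeps the planted pair as the reciprocal best hit while the
#' in-paralog still satisfies the join rule. Noise hits always involve at
#' least one planted gene, score in `[40, 120]` (strictly below every
#' planted score) and half of them additionally fail the 0.50 overlap rule.
#' Under this margin guarantee, clustering recovers exactly the planted
#' pairs.
#'
#' @param n_pairs planted ortholog pairs.
#' @param n_inparalogs in-paralog genes (attached to random pairs; requires
#'   `n_pairs >= 1` when positive).
#' @param n_noise noise hits.
#' @param seed integer seed.
#' @param species_a,species_b species labels.
#' @return List with `hits` (a [similarity_hits()] table) and `truth`
#'   (planted pairs, in-paralogs, noise count, seed).
#' @export
make_similarity_fixture <- function(n_pairs, n_inparalogs = 0, n_noise = 0,
                                    seed = 1, species_a = "speciesA",
                                    species_b = "speciesB") {
  stopifnot(n_pairs >= 0, n_inparalogs >= 0, n_noise >= 0)
  if (n_pairs == 0L && (n_inparalogs > 0L || n_noise > 0L)) {
    stop("in-paralogs and noise hits require at least one planted pair",
         call. = FALSE)
  }
  empty <- similarity_hits(character(), character(), character(), character(),
                           numeric())
  if (n_pairs == 0L) {
    return(list(hits = empty,
                truth = list(pairs = data.frame(gene_a = character(),
                                                gene_b = character(),
                                                score = numeric()),
                             inparalogs = data.frame(gene = character(),
                                                     seed_gene = character(),
                                                     species = character()),
                             n_noise = 0L, seed = seed)))
  }
  with_seed(seed, {
    gene_a <- sprintf("A%04d", seq_len(n_pairs))
    gene_b <- sprintf("B%04d", seq_len(n_pairs))
    score <- stats::runif(n_pairs, 200, 400)
    hits <- list(similarity_hits(
      gene_a, gene_b, species_a, species_b, score,
      stats::runif(n_pairs, 0.6, 1), stats::runif(n_pairs, 0.6, 1)))

    ip_truth <- data.frame(gene = character(), seed_gene = character(),
                           species = character(), stringsAsFactors = FALSE)
    if (n_inparalogs > 0L) {
      pair_idx <- sample.int(n_pairs, n_inparalogs, replace = TRUE)
      side_a <- stats::runif(n_inparalogs) < 0.5
      seed_gene <- ifelse(side_a, gene_a[pair_idx], gene_b[pair_idx])
      partner <- ifelse(side_a, gene_b[pair_idx], gene_a[pair_idx])
      ip_gene <- sprintf("%s_ip%02d", seed_gene, seq_len(n_inparalogs))
      ip_species <- ifelse(side_a, species_a, species_b)
      partner_species <- ifelse(side_a, species_b, species_a)
      # within-species in-paralog evidence: up to 10% above the seed score
      hits <- c(hits, list(similarity_hits(
        ip_gene, seed_gene, ip_species, ip_species,
        score[pair_idx] * stats::runif(n_inparalogs, 1.0, 1.1),
        stats::runif(n_inparalogs, 0.6, 1), stats::runif(n_inparalogs, 0.6, 1))))
      # cross-species hit tied at the seed score
      hits <- c(hits, list(similarity_hits(
        ip_gene, partner, ip_species, partner_species, score[pair_idx],
        stats::runif(n_inparalogs, 0.6, 1), stats::runif(n_inparalogs, 0.6, 1))))
      ip_truth <- data.frame(gene = ip_gene, seed_gene = seed_gene,
                             species = ip_species, stringsAsFactors = FALSE)
    }
    if (n_noise > 0L) {
      # one end a planted species-A gene; the other a planted species-B gene
      # of a different pair, or an extra unclustered gene
      i <- sample.int(n_pairs, n_noise, replace = TRUE)
      use_extra <- stats::runif(n_noise) < 0.5
      j <- vapply(i, function(ii) {
        if (n_pairs == 1L) 1L else sample(setdiff(seq_len(n_pairs), ii), 1L)
      }, 1L)
      other <- ifelse(use_extra, sprintf("BX%04d", seq_len(n_noise)), gene_b[j])
      low_overlap <- seq_len(n_noise) %% 2L == 0L
      qf <- ifelse(low_overlap, stats::runif(n_noise, 0.1, 0.45),
                   stats::runif(n_noise, 0.6, 1))
      hits <- c(hits, list(similarity_hits(
        gene_a[i], other, species_a, species_b,
        stats::runif(n_noise, 40, 120), qf, stats::runif(n_noise, 0.6, 1))))
    }
    all_hits <- do.call(rbind, lapply(hits, as.data.frame))
    class(all_hits) <- c("similarity_hits", "data.frame")
    list(hits = all_hits,
         truth = list(pairs = data.frame(gene_a = gene_a, gene_b = gene_b,
                                         score = score,
                                         stringsAsFactors = FALSE),
                      inparalogs = ip_truth, n_noise = as.integer(n_noise),
                      seed = seed))
  })
}

#' Generate a synthetic enrichment input with a planted signal
#'
#' Background term frequencies are uniform: each of `n_terms` terms is
#' carried by each population gene independently with probability
#' `background_freq`. The study set is drawn so that carriers of
#' `enriched` (the first term) appear at `fold` times the background
#' frequency; with `fold = 1` the study set is a uniform sample and carries
#' no signal.
#'
#' @param n_genes population size.
#' @param n_terms number of terms.
#' @param fold planted fold enrichment of the first term (>= 1).
#' @param study_size study-set size.
#' @param background_freq per-term background carrier probability.
#' @param seed integer seed.
#' @return List with `gene_terms` (data frame `gene_id`, `term_id`),
#'   `population`, `study` (character vectors) and `truth` (enriched term
#'   id, fold, parameters, seed).
#' @export
make_enrichment_fixture <- function(n_genes, n_terms, fold, study_size,
                                    background_freq = 0.05, seed = 1) {
  if (fold < 1) stop("fold must be >= 1", call. = FALSE)
  stopifnot(n_genes >= study_size, n_terms >= 1,
            background_freq > 0, background_freq < 1)
  with_seed(seed, {
    genes <- sprintf("G%05d", seq_len(n_genes))
    terms <- sprintf("GT:%07d", seq_len(n_terms))
    carry <- matrix(stats::runif(n_genes * n_terms) < background_freq,
                    n_genes, n_terms)
    idx <- which(carry, arr.ind = TRUE)
    gene_terms <- data.frame(gene_id = genes[idx[, 1L]],
                             term_id = terms[idx[, 2L]],
                             stringsAsFactors = FALSE)
    carriers <- genes[carry[, 1L]]
    if (fold == 1) {
      study <- sample(genes, study_size)
    } else {
      p_study <- min(1, fold * background_freq)
      n_carrier <- stats::rbinom(1L, study_size, p_study)
      n_carrier <- min(n_carrier, length(carriers))
      study <- c(sample(carriers, n_carrier),
                 sample(setdiff(genes, carriers), study_size - n_carrier))
    }
    list(gene_terms = gene_terms, population = genes, study = study,
         truth = list(enriched_term = terms[1L], fold = fold,
                      n_genes = n_genes, n_terms = n_terms,
                      study_size = study_size,
                      background_freq = background_freq, seed = seed))
  })
}

#' Write a similarity hit table as TSV
#'
#' Columns `qseqid`, `sseqid`, `qspecies`, `sspecies`, `bitscore`,
#' `qcovfrac`, `scovfrac` — readable back with [read_similarity_table()].
#'
#' @param hits a [similarity_hits()] table.
#' @param file path to write to.
#' @return The file path, invisibly.
#' @export
write_similarity_table <- function(hits, file) {
  df <- data.frame(qseqid = hits$query_id, sseqid = hits$subject_id,
                   qspecies = hits$query_species, sspecies = hits$subject_species,
                   bitscore = hits$score, qcovfrac = hits$query_aln_frac,
                   scovfrac = hits$subject_aln_frac, stringsAsFactors = FALSE)
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Write a fixture truth sidecar as JSON
#'
#' @param truth the `truth` element returned by a fixture generator.
#' @param file path to write to.
#' @return The file path, invisibly.
#' @export
write_fixture_truth <- function(truth, file) {
  jsonlite::write_json(truth, file, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(file)
}
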