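# End-to-end workflow: within-species stage comparison and between-species
# comparison via homolog clusters, driven by a config file and emitting a
# reproducible report directory.

#' Read a workflow configuration
#'
#' YAML with keys: `ontology` (OBO path), `species` (named list; each entry
#' has `assoc` and `stages`), optional `similarity` (TSV path),
#' `background_map` and `slim_terms` (enrichment inputs), `params`
#' (`evidence_codes`, `min_overlap_frac`, `min_mapped`, `alpha`,
#' `min_genes`), optional `contrasts` (`early_stage`, `late_stage`,
#' `stage_a`, `stage_b`), `out_dir` and `seed`. Relative paths are resolved
#' against the config file's directory.
#'
#' @param file path to the YAML config.
#' @return List of class `workflow_config`.
#' @export
read_workflow_config <- function(file) {
  cfg <- yaml::read_yaml(file)
  base <- dirname(normalizePath(file))
  resolve <- function(p) {
    if (is.null(p)) NULL
    else ifelse(grepl("^(/|[A-Za-z]:)", p), p, file.path(base, p))
  }
  cfg$ontology <- resolve(cfg$ontology)
  for (sp in names(cfg$species)) {
    cfg$species[[sp]]$assoc <- resolve(cfg$species[[sp]]$assoc)
  }
  cfg$similarity <- resolve(cfg$similarity)
  cfg$background_map <- resolve(cfg$background_map)
  cfg$slim_terms <- resolve(cfg$slim_terms)
  defaults <- list(evidence_codes = c("IEP", "IDA"), min_overlap_frac = 0.5,
                   min_mapped = 5, alpha = 0.05, min_genes = 50)
  cfg$params <- utils::modifyList(defaults, cfg$params %||% list())
  cfg$seed <- cfg$seed %||% 1L
  existing <- c(cfg$ontology,
                unlist(lapply(cfg$species, `[[`, "assoc")),
                cfg$similarity, cfg$background_map, cfg$slim_terms)
  missing <- existing[!file.exists(existing)]
  if (length(missing)) {
    stop("config references missing file(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  class(cfg) <- "workflow_config"
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

log_msg <- function(log_file, level, ...) {
  line <- sprintf("%s [%s] %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                  level, paste0(...))
  message(line)
  if (!is.null(log_file)) cat(line, "\n", file = log_file, append = TRUE)
  invisible(line)
}

start_report <- function(out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  structure(list(out_dir = out_dir, counts = list(), warnings = character(),
                 files = character(),
                 log_file = file.path(out_dir, "run.log")),
            class = "run_report")
}

report_count <- function(report, name, value) {
  report$counts[[name]] <- value
  report
}

report_file <- function(report, path) {
  report$files <- c(report$files, path)
  report
}

finish_report <- function(report) {
  report$manifest <- data.frame(
    file = basename(report$files),
    md5 = unname(tools::md5sum(report$files)),
    stringsAsFactors = FALSE
  )
  out <- list(counts = report$counts, warnings = report$warnings,
              manifest = report$manifest)
  jsonlite::write_json(out, file.path(report$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  report
}

load_species_map <- function(cfg, species, graph, log_file) {
  sp <- cfg$species[[species]]
  if (is.null(sp)) stop("species not in config: ", species, call. = FALSE)
  tab <- read_assoc(sp$assoc)
  n_raw <- nrow(tab)
  tab <- filter_evidence(tab, cfg$params$evidence_codes)
  log_msg(log_file, "INFO", species, ": ", n_raw, " records read, ",
          nrow(tab), " retained after evidence filter (",
          paste(cfg$params$evidence_codes, collapse = ","), ")")
  missing <- setdiff(sp$stages, unique(tab$term_id))
  if (length(missing)) {
    stop("no annotations for stage(s) of ", species, ": ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  map <- withCallingHandlers(
    stage_map_from_annotations(tab, graph, species, sp$stages,
                               min_genes = cfg$params$min_genes),
    warning = function(w) {
      log_msg(log_file, "WARN", conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  list(table = tab, map = map, n_raw = n_raw)
}

#' Run the within-species stage comparison
#'
#' Reads the ontology and one species' annotations, filters by evidence
#' code, builds the per-stage gene sets, and writes the gene-space overlap
#' matrix (percent-unique diagonal), per-stage unique-gene lists and — when
#' `contrasts` and `background_map` are configured — the Set1/Set2 contrast
#' gene lists with their enrichment tables and cross-set comparison.
#' Deterministic given fixed inputs and seed.
#'
#' @param config a `workflow_config` from [read_workflow_config()].
#' @param species which configured species to analyse (default the first).
#' @return A `run_report` (counts, warnings, file manifest with checksums),
#'   invisibly; `report.json` and all tables are written under
#'   `config$out_dir`.
#' @export
run_within_species <- function(config, species = names(config$species)[1L]) {
  out_dir <- file.path(config$out_dir %||% "stagecomp-out",
                       paste0("within-", species))
  report <- start_report(out_dir)
  lf <- report$log_file
  set.seed(config$seed)
  graph <- parse_obo(config$ontology)
  log_msg(lf, "INFO", "ontology: ", n_terms(graph), " terms")
  loaded <- load_species_map(config, species, graph, lf)
  map <- loaded$map
  report <- report_count(report, "records_read", loaded$n_raw)
  report <- report_count(report, "records_filtered", nrow(loaded$table))
  report <- report_count(report, "genes_per_stage", lengths(map$stages))
  if (length(map$stages) < 2L) {
    stop("within-species comparison needs >= 2 stages", call. = FALSE)
  }

  m <- pairwise_overlap(map)
  f_matrix <- file.path(out_dir, "overlap_matrix.tsv")
  write_overlap_matrix(m, f_matrix)
  report <- report_file(report, f_matrix)

  uq <- unique_genes(map)
  f_uq <- file.path(out_dir, "unique_genes.tsv")
  utils::write.table(uq, f_uq, sep = "\t", quote = FALSE, row.names = FALSE)
  report <- report_file(report, f_uq)
  sets <- attr(uq, "unique_sets")
  for (s in names(sets)) {
    f <- file.path(out_dir, sprintf("unique_%s.txt", gsub("[^A-Za-z0-9]", "_", s)))
    writeLines(sets[[s]], f)
    report <- report_file(report, f)
  }

  ctr <- config$contrasts
  if (!is.null(ctr) && !is.null(config$background_map)) {
    early <- map$stages[[ctr$early_stage]]
    late <- map$stages[[ctr$late_stage]]
    if (is.null(early) || is.null(late)) {
      stop("contrast stages not found in species map", call. = FALSE)
    }
    set1 <- setdiff(early, late)
    set2 <- setdiff(late, early)
    gene_terms <- read_gene_terms(config$background_map)
    population <- unique(gene_terms$gene_id)
    slim <- if (!is.null(config$slim_terms)) read_gene_list(config$slim_terms)
    params <- enrichment_params(min_mapped = config$params$min_mapped,
                                alpha = config$params$alpha,
                                slim_terms = slim)
    results <- list()
    for (nm in c("set1", "set2")) {
      genes <- intersect(get(nm), population)
      f_list <- file.path(out_dir, paste0(nm, ".txt"))
      writeLines(genes, f_list)
      report <- report_file(report, f_list)
      res <- fisher_enrichment(genes, population, gene_terms, params, graph)
      f_enr <- file.path(out_dir, paste0("enrichment_", nm, ".tsv"))
      write_enrichment(res, f_enr)
      report <- report_file(report, f_enr)
      results[[nm]] <- res
      report <- report_count(report, paste0("terms_tested_", nm), nrow(res))
    }
    cmp <- seacompare(results, alpha = config$params$alpha)
    f_cmp <- file.path(out_dir, "seacompare.tsv")
    write_enrichment(cmp, f_cmp)
    report <- report_file(report, f_cmp)
    report <- report_count(report, "significant_union", cmp$union)
    report <- report_count(report, "significant_intersection", cmp$intersection)
  }
  report <- finish_report(report)
  log_msg(lf, "INFO", "within-species run complete: ", out_dir)
  invisible(report)
}

#' Run the between-species comparison
#'
#' Builds homolog clusters from the configured similarity table (mutual
#' overlap filter, reciprocal best hits, in-paralog assignment), converts
#' both species' stage maps to cluster space, and writes the cross-species
#' overlap matrix, pooled cluster difference and — when `contrasts` is
#' configured — the Set3-style contrast gene lists in both species' id
#' conventions.
#'
#' @param config a `workflow_config` from [read_workflow_config()]; must
#'   name a `similarity` table and exactly two species.
#' @return A `run_report`, invisibly; outputs written under
#'   `config$out_dir`.
#' @export
run_between_species <- function(config) {
  if (is.null(config$similarity)) {
    stop("between-species comparison requires a similarity table",
         call. = FALSE)
  }
  if (length(config$species) != 2L) {
    stop("between-species comparison requires exactly two configured species",
         call. = FALSE)
  }
  out_dir <- file.path(config$out_dir %||% "stagecomp-out", "between")
  report <- start_report(out_dir)
  lf <- report$log_file
  set.seed(config$seed)
  graph <- parse_obo(config$ontology)
  sp_names <- names(config$species)

  hits <- read_similarity_table(config$similarity)
  n_hits <- nrow(hits)
  hits <- filter_hits(hits, config$params$min_overlap_frac)
  log_msg(lf, "INFO", n_hits, " similarity hits, ", nrow(hits),
          " pass the mutual-overlap filter (>=", config$params$min_overlap_frac, ")")
  pairs <- reciprocal_best_pairs(hits, sp_names[1L], sp_names[2L])
  clusters <- build_clusters(pairs, hits, sp_names[1L], sp_names[2L])
  log_msg(lf, "INFO", nrow(clusters$seeds), " clusters from ",
          nrow(pairs), " reciprocal best pairs; ",
          sum(clusters$clusters$is_inparalog), " in-paralogs")
  f_cl <- file.path(out_dir, "clusters.tsv")
  write_clusters(clusters, f_cl)
  report <- report_file(report, f_cl)
  report <- report_count(report, "hits_read", n_hits)
  report <- report_count(report, "hits_filtered", nrow(hits))
  report <- report_count(report, "clusters_built", nrow(clusters$seeds))

  maps <- lapply(sp_names, function(sp) {
    loaded <- load_species_map(config, sp, graph, lf)
    cl_map <- stage_map_to_clusters(loaded$map, clusters,
                                    min_genes = config$params$min_genes)
    for (s in names(cl_map$stages)) {
      log_msg(lf, "INFO", sp, " ", s, ": ", length(loaded$map$stages[[s]]),
              " genes -> ", length(cl_map$stages[[s]]), " clusters (",
              attr(cl_map, "unmapped")[[s]], " unmapped)")
    }
    list(gene = loaded$map, cluster = cl_map)
  })
  names(maps) <- sp_names
  report <- report_count(report, "genes_unmapped",
                         lapply(maps, function(m) as.list(attr(m$cluster, "unmapped"))))

  m <- cross_species_overlap(maps[[1L]]$cluster, maps[[2L]]$cluster)
  f_matrix <- file.path(out_dir, "cross_species_overlap.tsv")
  write_overlap_matrix(m, f_matrix)
  report <- report_file(report, f_matrix)

  pooled <- pooled_cluster_difference(maps[[1L]]$cluster, maps[[2L]]$cluster)
  report <- report_count(report, "pooled_clusters", as.list(pooled))
  log_msg(lf, "INFO", "pooled clusters: ", pooled[["pooled_a"]], " vs ",
          pooled[["pooled_b"]], "; in ", sp_names[1L], " only: ",
          pooled[["a_not_b"]])

  ctr <- config$contrasts
  if (!is.null(ctr)) {
    sets <- contrast_sets(maps[[1L]]$gene, maps[[1L]]$cluster,
                          maps[[2L]]$cluster, clusters,
                          early_stage = ctr$early_stage,
                          late_stage = ctr$late_stage,
                          stage_a = ctr$stage_a, stage_b = ctr$stage_b)
    files <- write_contrast_sets(sets, out_dir)
    for (f in files) report <- report_file(report, f)
    report <- report_count(report, "contrast_set_sizes",
                           lapply(sets[c("set1", "set2", "set3a", "set3b", "set4")],
                                  length))
  }
  report <- finish_report(report)
  log_msg(lf, "INFO", "between-species run complete: ", out_dir)
  invisible(report)
}
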