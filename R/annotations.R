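# GAF-style annotation tables: reading, evidence filtering, per-stage gene
# sets and summary statistics.

GAF_COLUMNS <- c(
  "source_db", "object_id", "object_symbol", "qualifier", "term_id",
  "reference", "evidence_code", "with_from", "aspect", "object_name",
  "object_synonym", "object_type", "taxon", "date", "assigned_by",
  "annotation_extension", "gene_product_form_id"
)

#' Construct an annotation table
#'
#' An `annotation_table` is a data frame of GAF 2.x records (one row per
#' annotation) with the 17 standard columns named
#' `source_db, object_id, object_symbol, qualifier, term_id, reference,
#' evidence_code, with_from, aspect, object_name, object_synonym,
#' object_type, taxon, date, assigned_by, annotation_extension,
#' gene_product_form_id`. Missing trailing columns are filled with `""`.
#'
#' @param records data frame holding at least `object_id`, `term_id` and
#'   `evidence_code`; remaining GAF columns are filled with `""`.
#' @return A data frame of class `annotation_table`.
#' @export
annotation_table <- function(records = NULL) {
  if (is.null(records)) {
    records <- as.data.frame(
      setNames(replicate(length(GAF_COLUMNS), character(), simplify = FALSE),
               GAF_COLUMNS),
      stringsAsFactors = FALSE)
  }
  stopifnot(all(c("object_id", "term_id", "evidence_code") %in% names(records)))
  for (col in GAF_COLUMNS) {
    if (!col %in% names(records)) records[[col]] <- rep("", nrow(records))
  }
  records <- records[, GAF_COLUMNS, drop = FALSE]
  records$evidence_code <- toupper(records$evidence_code)
  class(records) <- c("annotation_table", "data.frame")
  records
}

#' Read a GAF-style `.assoc` annotation file
#'
#' Tab-delimited GAF 2.x dialect: comment lines start with `!`; data lines
#' carry 15 to 17 tab-separated columns (extras beyond 17 are ignored).
#' Malformed lines (fewer than 15 columns) are not silently dropped: they are
#' collected in a rejects report attached as attribute `"rejects"` (columns
#' `line`, `reason`, `text`).
#'
#' @param file path or connection.
#' @param text optional character vector of lines used instead of `file`.
#' @return An [annotation_table()]; `attr(, "rejects")` holds the rejects
#'   report (zero rows when every line parsed).
#' @export
read_assoc <- function(file = NULL, text = NULL) {
  lines <- if (!is.null(text)) text else readLines(file, warn = FALSE)
  keep <- !grepl("^!", lines) & nzchar(lines)
  data_lines <- lines[keep]
  line_no <- which(keep)
  parts <- strsplit(data_lines, "\t", fixed = TRUE)
  nfield <- lengths(parts)
  bad <- nfield < 15L
  rejects <- data.frame(
    line = line_no[bad],
    reason = sprintf("expected >=15 tab-separated fields, got %d", nfield[bad]),
    text = data_lines[bad],
    stringsAsFactors = FALSE
  )
  parts <- parts[!bad]
  pad <- function(p) c(p, rep("", 17L))[1:17]
  mat <- if (length(parts)) t(vapply(parts, pad, character(17L))) else
    matrix(character(), ncol = 17L)
  records <- as.data.frame(mat, stringsAsFactors = FALSE)
  names(records) <- GAF_COLUMNS
  tab <- annotation_table(records)
  attr(tab, "rejects") <- rejects
  tab
}

#' Write an annotation table as a GAF file
#'
#' @param table an [annotation_table()].
#' @param file path or connection to write to.
#' @param header character vector of comment lines to emit first (each
#'   prefixed with `!` if not already).
#' @return The lines written, invisibly.
#' @export
write_assoc <- function(table, file = NULL, header = "!gaf-version: 2.1") {
  header <- ifelse(grepl("^!", header), header, paste0("!", header))
  body <- do.call(paste, c(unclass(table)[GAF_COLUMNS], sep = "\t"))
  out <- c(header, body)
  if (!is.null(file)) writeLines(out, file)
  invisible(out)
}

#' Filter annotations by evidence code
#'
#' Retains exactly the records whose evidence code is in `evidence_codes`,
#' preserving record order. The default keeps the two experimental codes that
#' dominate stage-annotation data: Inferred from Expression Pattern (IEP) and
#' Inferred from Direct Assay (IDA).
#'
#' @param table an [annotation_table()].
#' @param evidence_codes non-empty character vector of codes to retain.
#' @return A filtered [annotation_table()].
#' @export
filter_evidence <- function(table, evidence_codes = c("IEP", "IDA")) {
  if (length(evidence_codes) == 0L) {
    stop("evidence_codes must be non-empty; an empty filter is ambiguous",
         call. = FALSE)
  }
  out <- table[table$evidence_code %in% toupper(evidence_codes), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("annotation_table", "data.frame")
  out
}

#' Genes annotated to a stage
#'
#' Distinct bioentity identifiers (GAF column 2) annotated to `stage`. With
#' `propagate = TRUE` the true-path rule is applied over the `is_a`
#' hierarchy: genes annotated to any subclass of `stage` are included, so a
#' grouping stage such as a reproductive whole-plant stage collects the
#' annotations of all its sub-stages.
#'
#' @param table an [annotation_table()].
#' @param graph a [stage_graph()] supplying the `is_a` hierarchy.
#' @param stage term id present in `graph`.
#' @param propagate logical; include annotations to `is_a` descendants.
#' @return Character vector of distinct object ids.
#' @export
genes_for_stage <- function(table, graph, stage, propagate = FALSE) {
  assert_terms_exist(graph, stage)
  terms <- stage
  if (propagate) terms <- c(stage, stage_descendants(graph, stage, "is_a"))
  unique(table$object_id[table$term_id %in% terms])
}

#' Per-source annotation statistics
#'
#' Groups records by taxon and source database and reports direct annotation
#' counts and distinct bioentity counts, plus a totals row. The total
#' annotation count is the exact column sum; the total bioentity count is the
#' number of distinct bioentities across the whole table, which can differ
#' from the column sum when a bioentity is annotated by several sources.
#'
#' @param table an [annotation_table()].
#' @return Data frame with columns `taxon`, `source_db`, `n_annotations`,
#'   `n_bioentities`; the final row (`taxon == "total"`) carries the totals.
#' @export
annotation_stats <- function(table) {
  if (nrow(table) == 0L) {
    return(data.frame(taxon = character(), source_db = character(),
                      n_annotations = integer(), n_bioentities = integer(),
                      stringsAsFactors = FALSE))
  }
  key <- paste(table$taxon, table$source_db, sep = "\r")
  groups <- split(seq_len(nrow(table)), key)
  rows <- lapply(groups, function(idx) {
    data.frame(taxon = table$taxon[idx[1L]],
               source_db = table$source_db[idx[1L]],
               n_annotations = length(idx),
               n_bioentities = length(unique(table$object_id[idx])),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$n_annotations), , drop = FALSE]
  rownames(out) <- NULL
  rbind(out, data.frame(
    taxon = "total", source_db = "",
    n_annotations = nrow(table),
    n_bioentities = length(unique(table$object_id)),
    stringsAsFactors = FALSE))
}

#' Write the rejects report of [read_assoc()] as TSV
#'
#' @param table an [annotation_table()] carrying a `"rejects"` attribute.
#' @param file path to write to.
#' @return The file path, invisibly.
#' @export
write_rejects_report <- function(table, file) {
  rejects <- attr(table, "rejects")
  if (is.null(rejects)) rejects <- data.frame(line = integer(),
                                              reason = character(),
                                              text = character())
  utils::write.table(rejects, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
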