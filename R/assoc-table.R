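#' Long-form gene-association tables
#'
#' An association table is the common long-form container for the four
#' kinds of input the workflow consumes: GWAS gene--disease associations
#' (`kind = "gwas"`), disease differential-expression signatures
#' (`"disease_deg"`), drug perturbation signatures (`"drug_deg"`), and
#' drug--disease indication / clinical-trial links (`"indication"`).
#' Each row associates an entity (a disease or a drug) with a gene; DEG
#' kinds additionally carry a signed, nonzero effect (log-fold-change
#' scale). For the indication kind the `gene_id` column holds the
#' associated *disease* identifier -- the same two-column long form is
#' reused for entity--entity links.
#'
#' Duplicate `(entity_id, gene_id)` rows are collapsed on construction:
#' DEG kinds keep the row with the largest absolute effect (ties broken
#' by the larger signed effect, then input order), other kinds keep the
#' first occurrence.
#'
#' @param entity_id character vector of disease or drug identifiers.
#' @param gene_id character vector of gene identifiers (disease
#'   identifiers for `kind = "indication"`).
#' @param effect numeric vector of signed effects, required (finite and
#'   nonzero) for DEG kinds and disallowed otherwise.
#' @param source optional character vector naming the data source.
#' @param kind one of `"gwas"`, `"disease_deg"`, `"drug_deg"`,
#'   `"indication"`.
#' @return A `data.frame` of class `"assoc_table"` with columns
#'   `entity_id`, `gene_id`, `effect`, `source` and a `kind` attribute.
#' @examples
#' association_table(c("d1", "d1"), c("gA", "gB"), c(1.2, -0.8),
#'                   kind = "disease_deg")
#' @export
association_table <- function(entity_id, gene_id, effect = NULL,
                              source = "", kind) {
  kind <- match.arg(kind, assoc_kinds())
  n <- length(entity_id)
  stopifnot(length(gene_id) == n)
  is_deg <- kind %in% c("disease_deg", "drug_deg")
  if (is_deg) {
    if (is.null(effect)) {
      stop("kind '", kind, "' requires an 'effect' column", call. = FALSE)
    }
    effect <- as.numeric(effect)
    bad <- which(!is.finite(effect) | effect == 0)
    if (length(bad)) {
      stop("zero or non-finite effect in ", kind, " rows: ",
           paste(utils::head(bad, 10L), collapse = ", "), call. = FALSE)
    }
  } else {
    if (!is.null(effect) && any(!is.na(effect))) {
      stop("kind '", kind, "' must not carry effects", call. = FALSE)
    }
    effect <- rep(NA_real_, n)
  }
  df <- data.frame(entity_id = as.character(entity_id),
                   gene_id = as.character(gene_id),
                   effect = effect,
                   source = rep_len(as.character(source), n),
                   stringsAsFactors = FALSE)
  df <- collapse_duplicates(df, is_deg)
  structure(df, kind = kind, class = c("assoc_table", "data.frame"))
}

assoc_kinds <- function() c("gwas", "disease_deg", "drug_deg", "indication")

#' @export
print.assoc_table <- function(x, ...) {
  cat("<assoc_table> kind =", attr(x, "kind"), "/", nrow(x), "rows,",
      length(unique(x$entity_id)), "entities,",
      length(unique(x$gene_id)), "genes\n")
  print.data.frame(utils::head(as.data.frame(x), 6L), ...)
  invisible(x)
}

# keep-max-|effect| collapse; non-deg tables keep the first occurrence
collapse_duplicates <- function(df, is_deg) {
  if (!nrow(df)) return(df)
  if (is_deg) {
    ord <- order(df$entity_id, df$gene_id,
                 -abs(df$effect), -df$effect, seq_len(nrow(df)))
    df <- df[ord, , drop = FALSE]
  }
  keep <- !duplicated(df[, c("entity_id", "gene_id")])
  out <- df[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Kind of an association table
#' @param table an [association_table()].
#' @return The kind string.
#' @export
assoc_kind <- function(table) attr(table, "kind")

#' Read an association table from a TSV file
#'
#' Expects a UTF-8, tab-separated file with a header containing
#' `entity_id` and `gene_id` columns, plus an `effect` column for DEG
#' kinds. Duplicate rows are collapsed by the rule documented in
#' [association_table()]; the number of rows read is reported via
#' `message()`.
#'
#' @param path path to a TSV file.
#' @param kind one of `"gwas"`, `"disease_deg"`, `"drug_deg"`,
#'   `"indication"`.
#' @return An [association_table()].
#' @export
read_association_table <- function(path, kind) {
  kind <- match.arg(kind, assoc_kinds())
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = NA, check.names = TRUE)
  for (col in c("entity_id", "gene_id")) {
    if (!col %in% names(df)) {
      stop("file '", path, "' lacks required column '", col, "'",
           call. = FALSE)
    }
  }
  is_deg <- kind %in% c("disease_deg", "drug_deg")
  if (is_deg && !"effect" %in% names(df)) {
    stop("kind '", kind, "' requires an 'effect' column in '", path, "'",
         call. = FALSE)
  }
  message("read ", nrow(df), " rows from ", path)
  association_table(df$entity_id, df$gene_id,
                    effect = if (is_deg) df$effect else NULL,
                    source = if ("source" %in% names(df)) df$source else "",
                    kind = kind)
}

#' Write a tabular result to TSV
#'
#' Writes any data frame (score records, overlap results, enrichment
#' records, association tables) as a UTF-8 tab-separated file with a
#' header row. Real-valued columns are rendered with 6 significant
#' digits; list columns (e.g. gene intersections) are flattened to
#' comma-separated strings. An empty input yields a header-only file.
#'
#' @param records a data frame.
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
write_table <- function(records, path) {
  df <- as.data.frame(records)
  for (j in seq_along(df)) {
    if (is.list(df[[j]])) {
      df[[j]] <- vapply(df[[j]], function(v) paste(v, collapse = ","), "")
    } else if (is.double(df[[j]])) {
      df[[j]] <- signif(df[[j]], 6L)
    }
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, na = "NA")
  invisible(path)
}

#' Static identifier mapping tables
#'
#' A mapping table translates one identifier namespace (gene, compound
#' or disease) into a canonical one. It replaces the web-service
#' lookups a production run would use with a static, reproducible
#' two-column contract: each source identifier maps to exactly one
#' canonical identifier, and identifiers without a mapping are dropped
#' during [harmonize()].
#'
#' @param source_id character vector of source identifiers (unique).
#' @param canonical_id character vector of canonical identifiers.
#' @return A named character vector of class `"mapping_table"` (names =
#'   source ids).
#' @export
mapping_table <- function(source_id, canonical_id) {
  source_id <- as.character(source_id)
  canonical_id <- as.character(canonical_id)
  stopifnot(length(source_id) == length(canonical_id))
  if (anyDuplicated(source_id)) {
    stop("mapping table has duplicated source ids", call. = FALSE)
  }
  structure(stats::setNames(canonical_id, source_id),
            class = "mapping_table")
}

#' Read a two-column mapping table from TSV
#' @param path TSV file with columns `source_id`, `canonical_id`.
#' @return A [mapping_table()].
#' @export
read_mapping_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  for (col in c("source_id", "canonical_id")) {
    if (!col %in% names(df)) {
      stop("mapping file lacks required column '", col, "'", call. = FALSE)
    }
  }
  mapping_table(df$source_id, df$canonical_id)
}

#' Harmonize a table's gene identifiers through a mapping table
#'
#' Replaces every `gene_id` by its canonical identifier. Identifiers
#' that are already canonical (appear among the mapping's targets) are
#' kept as they are; rows whose identifier is neither mappable nor
#' canonical are dropped (the count is reported via `message()`),
#' never silently kept. After mapping, duplicates created by
#' many-to-one mappings are re-collapsed by the table's collapse rule.
#' Together these make harmonization idempotent.
#'
#' @param table an [association_table()].
#' @param mapping a [mapping_table()].
#' @return A harmonized [association_table()] of the same kind.
#' @export
harmonize <- function(table, mapping) {
  stopifnot(inherits(table, "assoc_table"), inherits(mapping, "mapping_table"))
  kind <- assoc_kind(table)
  mapped <- unclass(mapping)[table$gene_id]
  already <- is.na(mapped) & table$gene_id %in% unclass(mapping)
  mapped[already] <- table$gene_id[already]
  drop <- is.na(mapped)
  if (any(drop)) message("harmonize: dropped ", sum(drop), " unmappable rows")
  keep <- which(!drop)
  is_deg <- kind %in% c("disease_deg", "drug_deg")
  association_table(table$entity_id[keep], mapped[keep],
                    effect = if (is_deg) table$effect[keep] else NULL,
                    source = table$source[keep], kind = kind)
}

#' Gene signature of one entity
#'
#' The signed expression signature of a single disease or drug: its set
#' of genes plus a signed effect (delta-E, log-fold-change scale) per
#' gene. This is the object handed to the pathway perturbation model.
#'
#' @param entity_id entity identifier.
#' @param delta_e named numeric vector of finite signed effects; names
#'   are gene identifiers.
#' @param genes optional character vector of member genes; defaults to
#'   `names(delta_e)` and must be a superset of it.
#' @param ... further fields stored on the object (e.g. `drug`,
#'   `disease` context for filtered drug-in-disease sets).
#' @return A list of class `"gene_signature"`.
#' @export
gene_signature <- function(entity_id, delta_e, genes = names(delta_e), ...) {
  stopifnot(is.numeric(delta_e), !is.null(names(delta_e)),
            all(is.finite(delta_e)))
  if (!all(names(delta_e) %in% genes)) {
    stop("delta_e names must be a subset of genes", call. = FALSE)
  }
  structure(list(entity_id = entity_id, genes = unique(as.character(genes)),
                 delta_e = delta_e, ...),
            class = "gene_signature")
}

#' @export
print.gene_signature <- function(x, ...) {
  cat("<gene_signature>", x$entity_id, "/", length(x$genes), "genes\n")
  invisible(x)
}

#' Split an association table into per-entity gene signatures
#'
#' @param table a DEG-kind [association_table()].
#' @return A named list of [gene_signature()] objects, one per entity,
#'   sorted by entity id.
#' @export
signatures_from_table <- function(table) {
  stopifnot(inherits(table, "assoc_table"))
  if (!assoc_kind(table) %in% c("disease_deg", "drug_deg")) {
    stop("gene signatures require a DEG-kind table", call. = FALSE)
  }
  ids <- sort(unique(table$entity_id))
  out <- lapply(ids, function(id) {
    rows <- table[table$entity_id == id, , drop = FALSE]
    gene_signature(id, stats::setNames(rows$effect, rows$gene_id))
  })
  stats::setNames(out, ids)
}

#' Container for a stage's filtered gene sets
#'
#' @param stage one of `"disease_specific"`, `"drug_in_disease"`,
#'   `"triple"`.
#' @param sets named list of [gene_signature()] objects.
#' @return A list of class `"filtered_gene_sets"`.
#' @export
filtered_gene_sets <- function(stage, sets) {
  stage <- match.arg(stage, c("disease_specific", "drug_in_disease", "triple"))
  stopifnot(is.list(sets))
  structure(list(stage = stage, sets = sets), class = "filtered_gene_sets")
}

#' @export
print.filtered_gene_sets <- function(x, ...) {
  cat("<filtered_gene_sets> stage =", x$stage, "/", length(x$sets), "sets\n")
  invisible(x)
}
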