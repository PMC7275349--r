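#' Run the full repositioning workflow on a set of tables
#'
#' Orchestrates the whole pipeline: the (optional) three-stage GWAS
#' overlap filtering cascade, topology-based pathway enrichment of the
#' resulting disease- and drug-specific gene signatures, signed
#' signature-vector construction, and correlation scoring of every
#' applicable (drug, disease) pair.
#'
#' The cascade is optional end to end: with `filter_stages = FALSE`
#' (or an empty stage vector) the enrichment runs directly on the full
#' DEG signatures, so every drug is scored against every disease --
#' the mode used for ROC validation, where unlabeled drugs must
#' receive scores too. With filtering on, drug signatures are computed
#' per (drug, disease) context from the stage-3 sets and scored only
#' against that disease.
#'
#' @param tables named list with `gwas`, `disease_deg`, `drug_deg` and
#'   (for indication-restricted stage 2) `indications`
#'   [association_table()]s.
#' @param pathways named list of [pathway_graph()] objects.
#' @param cfg a [run_config()].
#' @param filter_stages `TRUE` for the full cascade, `FALSE` for none,
#'   or an integer subset of `c(1, 2, 3)` naming the stages to apply.
#' @param universe optional explicit gene universe for enrichment;
#'   defaults to the union of all genes in the tables and pathways.
#' @return A list of class `"pipeline_result"`: `stage1`, `stage2`,
#'   `stage3` (or `NULL` for skipped stages), `enrichment` (lists
#'   `disease` and `drug` of `enrichment_result` frames), `vectors`
#'   (lists `disease` and `drug` of signature vectors), `scores` (a
#'   `"score_records"` frame).
#' @export
run_pipeline <- function(tables, pathways, cfg = run_config(),
                         filter_stages = TRUE, universe = NULL) {
  stages <- if (isTRUE(filter_stages)) c(1L, 2L, 3L)
            else if (isFALSE(filter_stages)) integer()
            else as.integer(filter_stages)
  set.seed(cfg$seed)
  if (is.null(universe)) {
    universe <- unique(c(tables$disease_deg$gene_id,
                         tables$drug_deg$gene_id,
                         tables$gwas$gene_id,
                         unlist(lapply(pathways, `[[`, "members"))))
  }

  s1 <- s2 <- s3 <- NULL
  if (1L %in% stages) {
    s1 <- filter_disease_gwas(tables$disease_deg, tables$gwas, cfg)
    disease_sigs <- s1$sets$sets
  } else {
    disease_sigs <- signatures_from_table(tables$disease_deg)
  }
  if (2L %in% stages) {
    s2 <- filter_drug_gwas(tables$drug_deg, tables$gwas,
                           tables$indications, cfg)
    drug_sigs <- s2$sets$sets
  } else {
    drug_sigs <- signatures_from_table(tables$drug_deg)
  }
  if (3L %in% stages) {
    if (is.null(s1) || is.null(s2)) {
      stop("stage 3 requires stages 1 and 2", call. = FALSE)
    }
    s3 <- filter_triple(s1$sets, s2$sets, cfg)
    drug_sigs <- s3$sets$sets
  }

  sort_by_name <- function(x) {
    if (length(x)) x[order(names(x))] else x
  }
  enrich_set <- function(sigs) {
    lapply(sigs, function(sg) run_enrichment(sg, universe, pathways, cfg))
  }
  disease_sigs <- sort_by_name(disease_sigs)
  drug_sigs <- sort_by_name(drug_sigs)
  enr_disease <- enrich_set(disease_sigs)
  enr_drug <- enrich_set(drug_sigs)

  vec_of <- function(enr, sigs) {
    v <- lapply(names(enr), function(nm) {
      sv <- build_signature_vector(enr[[nm]], cfg$q_pathway,
                                   entity_id = nm)
      attr(sv, "drug") <- sigs[[nm]]$drug
      attr(sv, "disease") <- sigs[[nm]]$disease
      sv
    })
    stats::setNames(v, names(enr))
  }
  disease_vectors <- vec_of(enr_disease, disease_sigs)
  drug_vectors <- vec_of(enr_drug, drug_sigs)
  drug_vectors <- drug_vectors[lengths(drug_vectors) > 0L]

  scores <- suppressWarnings(
    score_all(drug_vectors, disease_vectors, cfg))

  structure(list(stage1 = s1, stage2 = s2, stage3 = s3,
                 enrichment = list(disease = enr_disease, drug = enr_drug),
                 vectors = list(disease = disease_vectors,
                                drug = drug_vectors),
                 scores = scores),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>", length(x$vectors$disease), "disease and",
      length(x$vectors$drug), "drug signature vectors;",
      nrow(x$scores), "scored pairs\n")
  invisible(x)
}
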