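#' Build a signed pathway signature vector from enrichment results
#'
#' Keeps only pathways that are significantly dysregulated
#' (`p_g_fdr < q_threshold`) with a nonzero direction, and encodes
#' activated pathways as +1 and inhibited ones as -1. All other
#' pathways are implicitly 0.
#'
#' @param records an `enrichment_result` data frame from
#'   [run_enrichment()].
#' @param q_threshold FDR threshold (default 0.05).
#' @param entity_id optional entity label stored on the vector.
#' @return A named numeric vector of class `"signature_vector"` with
#'   values in \{-1, +1\}, named by [pathway_key()]; possibly empty.
#' @export
build_signature_vector <- function(records, q_threshold = 0.05,
                                   entity_id = NULL) {
  keep <- records$p_g_fdr < q_threshold & records$status != "none"
  r <- records[keep, , drop = FALSE]
  v <- ifelse(r$status == "activated", 1, -1)
  names(v) <- pathway_key(r$database, r$pathway_id)
  structure(as.numeric(v), names = names(v), entity_id = entity_id,
            class = "signature_vector")
}

#' @export
print.signature_vector <- function(x, ...) {
  cat("<signature_vector>", attr(x, "entity_id") %||% "", "/",
      length(x), "pathways (", sum(x > 0), "up,", sum(x < 0), "down )\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

support <- function(v) names(v)

# materialize a signature vector over an explicit index set, 0-filled
materialize <- function(v, idx) {
  out <- stats::setNames(numeric(length(idx)), idx)
  common <- intersect(names(v), idx)
  out[common] <- v[common]
  out
}

#' Pearson correlation between drug and disease pathway signatures
#'
#' Materializes both +/-1 vectors over a common pathway index set --
#' the union of their supports (default) or the disease support only
#' -- filling absent pathways with 0, and returns their Pearson
#' correlation. If either materialized vector is constant (zero
#' standard deviation) or the index set is empty, the correlation is
#' undefined and `NA` is returned.
#'
#' @param drug,disease [build_signature_vector()] outputs.
#' @param index_policy `"union"` or `"disease_only"`.
#' @return Correlation in \[-1, 1\], or `NA_real_` if undefined.
#' @export
correlation_score <- function(drug, disease,
                              index_policy = c("union", "disease_only")) {
  index_policy <- match.arg(index_policy)
  idx <- switch(index_policy,
                union = union(support(drug), support(disease)),
                disease_only = support(disease))
  if (length(idx) < 2L) return(NA_real_)
  x <- materialize(drug, idx)
  y <- materialize(disease, idx)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y)
}

#' Percentage of disease pathways also affected by a drug
#'
#' Counts how many of the disease's significantly dysregulated
#' pathways are also significantly dysregulated by the drug (in either
#' direction) and expresses it as a percentage of the disease's
#' pathway count.
#'
#' @param drug,disease signature vectors; the disease support must be
#'   nonempty.
#' @return A list with `pct`, `n_shared`, `n_disease`.
#' @export
affected_pct <- function(drug, disease) {
  n_disease <- length(disease)
  if (!n_disease) {
    stop("disease has an empty pathway signature", call. = FALSE)
  }
  n_shared <- length(intersect(support(drug), support(disease)))
  list(pct = 100 * n_shared / n_disease, n_shared = n_shared,
       n_disease = n_disease)
}

#' Levenshtein dissimilarity between signature vectors
#'
#' Materializes both vectors over a deterministic total order of the
#' union index set (lexicographic pathway keys by default) as strings
#' over the alphabet \{-1, 0, +1\} and computes the standard
#' unit-cost edit distance (insert/delete/substitute). Provided as the
#' alternative dissimilarity score; rankings use the correlation.
#'
#' @param drug,disease signature vectors.
#' @param ordering optional character vector fixing the index order;
#'   defaults to the sorted union of supports.
#' @return Integer edit distance.
#' @export
levenshtein_score <- function(drug, disease, ordering = NULL) {
  idx <- ordering %||% sort(union(support(drug), support(disease)))
  enc <- function(v) {
    paste(c("a", "b", "c")[materialize(v, idx) + 2], collapse = "")
  }
  as.integer(utils::adist(enc(drug), enc(disease)))
}

#' Combine two drug signatures into a pair signature
#'
#' Elementwise sign-of-sum over the union of supports: pathways where
#' the two drugs agree keep their shared sign, pathways affected by
#' only one drug keep that drug's sign, and pathways with conflicting
#' signs cancel (treated as no change and dropped). Commutative, and
#' idempotent on agreeing entries.
#'
#' @param a,b signature vectors built on the same pathway collection.
#' @return A `"signature_vector"` for the pair.
#' @export
combine_pair <- function(a, b) {
  idx <- union(support(a), support(b))
  s <- sign(materialize(a, idx) + materialize(b, idx))
  s <- s[s != 0]
  structure(as.numeric(s), names = names(s),
            entity_id = paste(attr(a, "entity_id") %||% "a",
                              attr(b, "entity_id") %||% "b", sep = " + "),
            class = "signature_vector")
}

#' Score every (drug, disease) signature pair
#'
#' Computes the correlation score, affected-pathway percentage and
#' Levenshtein dissimilarity for every drug vector against every
#' disease vector. Drug vectors carrying a `disease` attribute (from
#' the filtered cascade, where drug signatures are computed per
#' disease context) are scored only against that disease. Diseases
#' with empty signatures are skipped with a warning. Pairs with
#' undefined correlation are kept in the output with `NA` correlation;
#' [prioritize()] and ranking exclude them.
#'
#' @param drug_vectors named list of drug signature vectors.
#' @param disease_vectors named list of disease signature vectors.
#' @param cfg a [run_config()] (index policy).
#' @return A data frame of class `"score_records"` with columns
#'   `drug_key`, `disease`, `correlation`, `affected_pct`,
#'   `levenshtein`, `n_disease_pathways`, `n_shared`.
#' @export
score_all <- function(drug_vectors, disease_vectors, cfg = run_config()) {
  rows <- list()
  for (d in names(disease_vectors)) {
    dv <- disease_vectors[[d]]
    if (!length(dv)) {
      warning("disease ", d, " has an empty signature; skipped")
      next
    }
    for (dr in names(drug_vectors)) {
      v <- drug_vectors[[dr]]
      ctx <- attr(v, "disease")
      if (!is.null(ctx) && !identical(ctx, d)) next
      drug_id <- attr(v, "drug") %||% dr
      rows[[length(rows) + 1L]] <-
        score_one(drug_id, d, v, dv, cfg$index_policy)
    }
  }
  finish_scores(rows)
}

score_one <- function(drug_key, disease, v, dv, index_policy) {
  ap <- affected_pct(v, dv)
  data.frame(drug_key = drug_key, disease = disease,
             correlation = correlation_score(v, dv, index_policy),
             affected_pct = ap$pct,
             levenshtein = levenshtein_score(v, dv),
             n_disease_pathways = ap$n_disease, n_shared = ap$n_shared,
             stringsAsFactors = FALSE)
}

finish_scores <- function(rows) {
  if (!length(rows)) {
    df <- data.frame(drug_key = character(), disease = character(),
                     correlation = numeric(), affected_pct = numeric(),
                     levenshtein = integer(),
                     n_disease_pathways = integer(), n_shared = integer(),
                     stringsAsFactors = FALSE)
  } else {
    df <- do.call(rbind, rows)
  }
  rownames(df) <- NULL
  class(df) <- c("score_records", "data.frame")
  df
}

#' Score all two-drug combinations against each disease
#'
#' Combines every unordered pair of distinct drugs applicable to a
#' disease via [combine_pair()] and scores the combined signature as
#' in [score_all()]. With n applicable drugs this yields C(n, 2)
#' records per disease; a drug is never paired with itself.
#'
#' @inheritParams score_all
#' @return A `"score_records"` data frame; `drug_key` is
#'   `"drugA + drugB"` with the two names sorted.
#' @export
score_pairs <- function(drug_vectors, disease_vectors, cfg = run_config()) {
  rows <- list()
  for (d in names(disease_vectors)) {
    dv <- disease_vectors[[d]]
    if (!length(dv)) {
      warning("disease ", d, " has an empty signature; skipped")
      next
    }
    applicable <- names(drug_vectors)[vapply(drug_vectors, function(v) {
      ctx <- attr(v, "disease")
      is.null(ctx) || identical(ctx, d)
    }, NA)]
    if (length(applicable) < 2L) next
    drug_ids <- vapply(applicable, function(nm)
      attr(drug_vectors[[nm]], "drug") %||% nm, "")
    for (i in seq_len(length(applicable) - 1L)) {
      for (j in seq((i + 1L), length(applicable))) {
        comb <- combine_pair(drug_vectors[[applicable[i]]],
                             drug_vectors[[applicable[j]]])
        key <- paste(sort(c(drug_ids[i], drug_ids[j])), collapse = " + ")
        rows[[length(rows) + 1L]] <-
          score_one(key, d, comb, dv, cfg$index_policy)
      }
    }
  }
  finish_scores(rows)
}

#' Shortlist and rank scored drug--disease records
#'
#' In `"invert"` mode (repositioning): keeps records with
#' `correlation <= corr_max` and `affected_pct > affected_min_pct`,
#' ranked by ascending correlation. In `"mimic"` mode (drugs that
#' reproduce the disease signature): keeps `correlation >=
#' |corr_max|` with the same coverage rule, ranked by descending
#' correlation. Records with undefined (`NA`) correlation are always
#' excluded. Ties break on higher coverage, then lexicographic drug
#' key, so the ranking is total and deterministic.
#'
#' @param records a `"score_records"` data frame.
#' @param corr_max correlation threshold (default -0.4).
#' @param affected_min_pct strict lower bound on coverage (default 50).
#' @param mode `"invert"` or `"mimic"`.
#' @return The retained records, ranked, with a `rank` column.
#' @export
prioritize <- function(records, corr_max = -0.4, affected_min_pct = 50,
                       mode = c("invert", "mimic")) {
  mode <- match.arg(mode)
  df <- records[!is.na(records$correlation), , drop = FALSE]
  if (mode == "invert") {
    df <- df[df$correlation <= corr_max &
               df$affected_pct > affected_min_pct, , drop = FALSE]
    ord <- order(df$correlation, -df$affected_pct, df$drug_key)
  } else {
    df <- df[df$correlation >= abs(corr_max) &
               df$affected_pct > affected_min_pct, , drop = FALSE]
    ord <- order(-df$correlation, -df$affected_pct, df$drug_key)
  }
  df <- df[ord, , drop = FALSE]
  if (nrow(df)) df$rank <- seq_len(nrow(df))
  rownames(df) <- NULL
  df
}
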