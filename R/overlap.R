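#' One-sided Fisher's exact test for gene-set overlap
#'
#' Tests whether two gene sets overlap more than expected by chance in
#' a finite gene universe. The p-value is the hypergeometric upper tail
#' P(X >= |A intersect B|) with parameters (|U|, |A|, |B|) -- the
#' one-sided (enrichment) alternative of Fisher's exact test on the
#' 2x2 membership table. The odds ratio is the cross-product ratio of
#' that table; a 0/0 configuration yields `NaN` as the
#' undefined-marker, and a zero denominator alone yields `Inf`.
#'
#' @param set_a,set_b character vectors of gene ids, subsets of the
#'   universe.
#' @param universe character vector of background gene ids, or a single
#'   number giving the background size (in which case subset checks are
#'   skipped and only the set sizes are used).
#' @return A list of class `"overlap_result"` with fields
#'   `n_universe`, `n_a`, `n_b`, `n_overlap`, `odds_ratio`, `p_value`
#'   and `intersection`.
#' @examples
#' fisher_overlap(paste0("g", 1:10), paste0("g", 6:15), paste0("g", 1:100))
#' @export
fisher_overlap <- function(set_a, set_b, universe) {
  set_a <- unique(as.character(set_a))
  set_b <- unique(as.character(set_b))
  if (is.numeric(universe) && length(universe) == 1L) {
    n_u <- as.integer(universe)
  } else {
    universe <- unique(as.character(universe))
    if (!all(set_a %in% universe) || !all(set_b %in% universe)) {
      stop("sets must be subsets of the universe", call. = FALSE)
    }
    n_u <- length(universe)
  }
  if (n_u < 1L) stop("universe must be nonempty", call. = FALSE)
  inter <- intersect(set_a, set_b)
  n_a <- length(set_a); n_b <- length(set_b); k <- length(inter)
  if (n_a > n_u || n_b > n_u) {
    stop("set larger than universe", call. = FALSE)
  }
  p <- stats::phyper(k - 1L, n_a, n_u - n_a, n_b, lower.tail = FALSE)
  num <- k * (n_u - n_a - n_b + k)
  den <- (n_a - k) * (n_b - k)
  odds <- if (num == 0 && den == 0) NaN else num / den
  structure(list(n_universe = n_u, n_a = n_a, n_b = n_b, n_overlap = k,
                 odds_ratio = odds, p_value = p, intersection = inter),
            class = "overlap_result")
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Adjusts a family of p-values by the BH step-up procedure:
#' `q_(i) = min_{j >= i} m * p_(j) / j`, capped at 1 and returned in
#' the input order. Inputs must lie in (0, 1].
#'
#' @param p_values numeric vector of raw p-values.
#' @return Numeric vector of q-values in input order.
#' @export
bh_adjust <- function(p_values) {
  p_values <- as.numeric(p_values)
  if (!length(p_values)) return(numeric())
  if (any(!is.finite(p_values) | p_values <= 0 | p_values > 1)) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  stats::p.adjust(p_values, method = "BH")
}

# Assemble the per-pair overlap data frame for a stage.
overlap_frame <- function(pairs, sets_a, sets_b, universe) {
  res <- vector("list", nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    res[[i]] <- fisher_overlap(sets_a[[pairs$entity_a[i]]],
                               sets_b[[pairs$entity_b[i]]], universe)
  }
  df <- data.frame(
    entity_a = pairs$entity_a, entity_b = pairs$entity_b,
    n_universe = vapply(res, `[[`, 0L, "n_universe"),
    n_a = vapply(res, `[[`, 0L, "n_a"),
    n_b = vapply(res, `[[`, 0L, "n_b"),
    n_overlap = vapply(res, `[[`, 0L, "n_overlap"),
    odds_ratio = vapply(res, `[[`, 0, "odds_ratio"),
    p_value = vapply(res, `[[`, 0, "p_value"),
    stringsAsFactors = FALSE)
  df$q_value <- bh_adjust(df$p_value)
  df$intersection <- I(lapply(res, `[[`, "intersection"))
  df
}

split_genes <- function(table) {
  split(table$gene_id, table$entity_id)
}

# effects of `genes` for entity `id` in a DEG table, collapsed already
entity_effects <- function(table, id, genes) {
  rows <- table[table$entity_id == id & table$gene_id %in% genes, ,
                drop = FALSE]
  stats::setNames(rows$effect, rows$gene_id)
}

#' Stage 1: contextualize disease signatures with GWAS evidence
#'
#' Runs the one-sided Fisher overlap test between every disease's DEG
#' gene set and every disease's GWAS gene set, adjusts all pairs
#' jointly by BH, and keeps pairs with `q <= cfg$q_disease_gwas`. The
#' retained same-disease pairs become the disease-specific gene sets:
#' genes both genetically associated and differentially expressed in
#' the same disease, carrying their DEG effects.
#'
#' @param deg a `disease_deg` [association_table()].
#' @param gwas a `gwas` [association_table()].
#' @param cfg a [run_config()].
#' @return A list with `all_pairs` (a data frame of overlap results
#'   with `q_value`) and `sets` (a [filtered_gene_sets()] of stage
#'   `"disease_specific"`, keyed by disease).
#' @export
filter_disease_gwas <- function(deg, gwas, cfg = run_config()) {
  stopifnot(assoc_kind(deg) == "disease_deg", assoc_kind(gwas) == "gwas")
  if (!nrow(deg) || !nrow(gwas)) {
    warning("empty input table: no overlap tests performed")
    return(list(all_pairs = NULL,
                sets = filtered_gene_sets("disease_specific", list())))
  }
  deg_sets <- split_genes(deg)
  gwas_sets <- split_genes(gwas)
  universe <- resolve_universe(cfg$universe_policy, deg$gene_id, gwas$gene_id)
  pairs <- expand.grid(entity_a = names(deg_sets), entity_b = names(gwas_sets),
                       stringsAsFactors = FALSE)
  df <- overlap_frame(pairs, deg_sets, gwas_sets, universe)
  keep <- df$q_value <= cfg$q_disease_gwas
  same <- keep & df$entity_a == df$entity_b
  sets <- list()
  for (i in which(same)) {
    d <- df$entity_a[i]
    genes <- df$intersection[[i]]
    if (!length(genes)) next
    sets[[d]] <- gene_signature(d, entity_effects(deg, d, genes))
  }
  list(all_pairs = df,
       sets = filtered_gene_sets("disease_specific", sets))
}

#' Stage 2: contextualize drug signatures with disease GWAS evidence
#'
#' Tests each candidate (drug, disease) pair -- by default restricted
#' to pairs present in the indications table, or all pairs when
#' `cfg$all_pairs` -- for overlap between the drug's DEG gene set and
#' the disease's GWAS gene set. Because drug perturbation signatures
#' carry no intrinsic disease context, retention uses the stringent
#' `q <= cfg$q_drug_gwas` (default 1e-10). Retained sets carry the
#' drug's effects on the intersection and are keyed
#' `"drug|disease"`.
#'
#' @param drug_deg a `drug_deg` [association_table()].
#' @param gwas a `gwas` [association_table()].
#' @param indications an `indication` [association_table()] (drug in
#'   `entity_id`, disease in `gene_id`), or `NULL` with
#'   `cfg$all_pairs = TRUE`.
#' @param cfg a [run_config()].
#' @return A list with `all_pairs` and `sets` (stage
#'   `"drug_in_disease"`); each retained [gene_signature()] carries
#'   `drug` and `disease` fields.
#' @export
filter_drug_gwas <- function(drug_deg, gwas, indications = NULL,
                             cfg = run_config()) {
  stopifnot(assoc_kind(drug_deg) == "drug_deg", assoc_kind(gwas) == "gwas")
  drug_sets <- split_genes(drug_deg)
  gwas_sets <- split_genes(gwas)
  empty_drugs <- names(drug_sets)[lengths(drug_sets) == 0L]
  if (length(empty_drugs)) {
    warning("skipping drugs with empty DEG sets: ",
            paste(empty_drugs, collapse = ", "))
    drug_sets <- drug_sets[lengths(drug_sets) > 0L]
  }
  if (cfg$all_pairs) {
    pairs <- expand.grid(entity_a = names(drug_sets),
                         entity_b = names(gwas_sets),
                         stringsAsFactors = FALSE)
  } else {
    if (is.null(indications)) {
      stop("indication-restricted mode requires an indications table",
           call. = FALSE)
    }
    stopifnot(assoc_kind(indications) == "indication")
    pairs <- data.frame(entity_a = indications$entity_id,
                        entity_b = indications$gene_id,
                        stringsAsFactors = FALSE)
    pairs <- pairs[pairs$entity_a %in% names(drug_sets) &
                     pairs$entity_b %in% names(gwas_sets), , drop = FALSE]
    pairs <- pairs[!duplicated(pairs), , drop = FALSE]
  }
  if (!nrow(pairs)) {
    warning("no candidate (drug, disease) pairs to test")
    return(list(all_pairs = NULL,
                sets = filtered_gene_sets("drug_in_disease", list())))
  }
  universe <- resolve_universe(cfg$universe_policy,
                               drug_deg$gene_id, gwas$gene_id)
  df <- overlap_frame(pairs, drug_sets, gwas_sets, universe)
  sets <- list()
  for (i in which(df$q_value <= cfg$q_drug_gwas)) {
    genes <- df$intersection[[i]]
    if (!length(genes)) next
    key <- paste(df$entity_a[i], df$entity_b[i], sep = "|")
    sets[[key]] <- gene_signature(
      key, entity_effects(drug_deg, df$entity_a[i], genes),
      drug = df$entity_a[i], disease = df$entity_b[i])
  }
  list(all_pairs = df, sets = filtered_gene_sets("drug_in_disease", sets))
}

#' Stage 3: three-way overlap of drug sets with disease-specific sets
#'
#' For every stage-2 (drug, disease) gene set whose disease also has a
#' stage-1 disease-specific set, tests the overlap of the two sets,
#' adjusts jointly by BH, and keeps pairs with `q <= cfg$q_triple`.
#' The retained gene set is the intersection with the drug's effects
#' attached, so stage-3 sets are contained in both parent sets.
#'
#' @param disease_specific stage-1 result of [filter_disease_gwas()]
#'   (the `sets` element, or the full list).
#' @param drug_in_disease stage-2 result of [filter_drug_gwas()].
#' @param cfg a [run_config()].
#' @return A list with `all_pairs` and `sets` (stage `"triple"`, keyed
#'   `"drug|disease"`).
#' @export
filter_triple <- function(disease_specific, drug_in_disease,
                          cfg = run_config()) {
  if (!inherits(disease_specific, "filtered_gene_sets")) {
    disease_specific <- disease_specific$sets
  }
  if (!inherits(drug_in_disease, "filtered_gene_sets")) {
    drug_in_disease <- drug_in_disease$sets
  }
  stopifnot(disease_specific$stage == "disease_specific",
            drug_in_disease$stage == "drug_in_disease")
  d_sets <- disease_specific$sets
  dr_sets <- drug_in_disease$sets
  keep_keys <- names(dr_sets)[vapply(dr_sets, function(s)
    s$disease %in% names(d_sets), NA)]
  if (!length(keep_keys)) {
    return(list(all_pairs = NULL, sets = filtered_gene_sets("triple", list())))
  }
  all_genes_a <- unique(unlist(lapply(dr_sets, `[[`, "genes")))
  all_genes_b <- unique(unlist(lapply(d_sets, `[[`, "genes")))
  universe <- resolve_universe(cfg$universe_policy, all_genes_a, all_genes_b)
  p <- numeric(length(keep_keys))
  inters <- vector("list", length(keep_keys))
  for (i in seq_along(keep_keys)) {
    s2 <- dr_sets[[keep_keys[i]]]
    s1 <- d_sets[[s2$disease]]
    r <- fisher_overlap(s2$genes, s1$genes, universe)
    p[i] <- r$p_value
    inters[[i]] <- r$intersection
  }
  q <- bh_adjust(p)
  df <- data.frame(entity_a = keep_keys,
                   entity_b = vapply(dr_sets[keep_keys], `[[`, "", "disease"),
                   p_value = p, q_value = q, stringsAsFactors = FALSE)
  df$intersection <- I(inters)
  sets <- list()
  for (i in which(q <= cfg$q_triple)) {
    genes <- inters[[i]]
    if (!length(genes)) next
    s2 <- dr_sets[[keep_keys[i]]]
    sets[[keep_keys[i]]] <- gene_signature(
      keep_keys[i], s2$delta_e[genes], drug = s2$drug, disease = s2$disease)
  }
  list(all_pairs = df, sets = filtered_gene_sets("triple", sets))
}
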