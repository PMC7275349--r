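#' Run configuration for the repositioning workflow
#'
#' Bundles every tunable threshold of the pipeline. Defaults follow the
#' workflow's published operating point: q <= 0.05 to keep a
#' disease-DEG/GWAS overlap, a far more stringent q <= 1e-10 for drug
#' signatures (which lack intrinsic disease context), q <= 0.05 for the
#' final three-way overlap and for calling a pathway significantly
#' dysregulated, and the prioritization cut-offs of correlation <= -0.4
#' with > 50% of the disease's dysregulated pathways covered (single
#' drugs) or <= -0.50 and >= 80% (drug pairs, applied as > 80 per the
#' strict-coverage convention used throughout).
#'
#' @param q_disease_gwas BH-adjusted significance threshold for the
#'   disease-DEG vs GWAS overlap stage.
#' @param q_drug_gwas threshold for the drug-DEG vs GWAS stage.
#' @param q_triple threshold for the three-way overlap stage.
#' @param q_pathway FDR threshold below which a pathway enters a
#'   signature vector.
#' @param corr_max keep drugs with correlation `<=` this (invert mode).
#' @param affected_min_pct keep drugs covering strictly more than this
#'   percentage of the disease's dysregulated pathways.
#' @param pair_corr_max,pair_affected_min_pct the same thresholds for
#'   two-drug combinations.
#' @param n_boot bootstrap replicates for the perturbation null and for
#'   AUC confidence intervals.
#' @param seed integer seed for all stochastic steps.
#' @param universe_policy `"observed_union"` (background = union of the
#'   genes observed in the two tables being compared), an explicit
#'   character vector of gene ids, or a single number giving the
#'   universe size.
#' @param index_policy `"union"` or `"disease_only"`: the pathway index
#'   set over which signature vectors are correlated.
#' @param all_pairs if `TRUE`, the drug--GWAS stage tests every
#'   (drug, disease) pair instead of only indicated ones.
#' @param paths optional named list of file locations.
#' @return A list of class `"run_config"`.
#' @export
run_config <- function(q_disease_gwas = 0.05,
                       q_drug_gwas = 1e-10,
                       q_triple = 0.05,
                       q_pathway = 0.05,
                       corr_max = -0.4,
                       affected_min_pct = 50,
                       pair_corr_max = -0.50,
                       pair_affected_min_pct = 80,
                       n_boot = 2000L,
                       seed = 1L,
                       universe_policy = "observed_union",
                       index_policy = c("union", "disease_only"),
                       all_pairs = FALSE,
                       paths = list()) {
  index_policy <- match.arg(index_policy)
  cfg <- list(q_disease_gwas = q_disease_gwas, q_drug_gwas = q_drug_gwas,
              q_triple = q_triple, q_pathway = q_pathway,
              corr_max = corr_max, affected_min_pct = affected_min_pct,
              pair_corr_max = pair_corr_max,
              pair_affected_min_pct = pair_affected_min_pct,
              n_boot = as.integer(n_boot), seed = as.integer(seed),
              universe_policy = universe_policy,
              index_policy = index_policy, all_pairs = isTRUE(all_pairs),
              paths = paths)
  for (q in c("q_disease_gwas", "q_drug_gwas", "q_triple", "q_pathway")) {
    if (!(cfg[[q]] > 0 && cfg[[q]] <= 1)) {
      stop(q, " must lie in (0, 1]", call. = FALSE)
    }
  }
  for (r in c("corr_max", "pair_corr_max")) {
    if (abs(cfg[[r]]) > 1) stop(r, " must lie in [-1, 1]", call. = FALSE)
  }
  for (p in c("affected_min_pct", "pair_affected_min_pct")) {
    if (cfg[[p]] < 0 || cfg[[p]] > 100) {
      stop(p, " must lie in [0, 100]", call. = FALSE)
    }
  }
  if (cfg$n_boot < 1L) stop("n_boot must be >= 1", call. = FALSE)
  structure(cfg, class = "run_config")
}

#' Read a run configuration from YAML
#'
#' The YAML keys mirror the [run_config()] argument names; unknown keys
#' are rejected so typos do not silently fall back to defaults.
#'
#' @param path YAML file path.
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(run_config, vals)
}

#' Write a run configuration to YAML
#' @param cfg a [run_config()].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

# Resolve the Fisher background for a comparison of two gene pools.
# Returns a character vector of gene ids or a single integer size.
resolve_universe <- function(policy, genes_a, genes_b) {
  if (is.numeric(policy)) return(as.integer(policy))
  if (is.character(policy) && length(policy) == 1L &&
      policy == "observed_union") {
    return(union(genes_a, genes_b))
  }
  if (is.character(policy)) return(unique(policy))
  stop("unsupported universe policy", call. = FALSE)
}
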