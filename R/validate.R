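#' Area under the ROC curve via the rank-sum identity
#'
#' AUC = (sum of positive ranks - n_pos(n_pos+1)/2) / (n_pos * n_neg),
#' with midranks so tied scores contribute 1/2 per tied pair. Scores
#' must be oriented so that larger values are more positive-like (for
#' invert-mode repositioning, pass the negated correlation).
#'
#' @param scores numeric predictor values.
#' @param labels 0/1 class labels (both classes present).
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels), all(labels %in% 0:1))
  n_pos <- sum(labels == 1L); n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L) {
    stop("both classes must be present", call. = FALSE)
  }
  r <- rank(scores)
  (sum(r[labels == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Percentile-bootstrap confidence interval for the AUC
#'
#' Resamples (score, label) pairs with replacement `n_boot` times and
#' takes the percentile interval of the resampled AUCs. Resamples that
#' lose one class are redrawn (up to 10 x n_boot attempts overall
#' before a degenerate-data error).
#'
#' @param scores,labels as in [roc_auc()].
#' @param n_boot number of bootstrap resamples (>= 100).
#' @param level confidence level (default 0.95).
#' @param seed optional integer seed.
#' @return A list of class `"roc_result"` with `auc`, `ci_low`,
#'   `ci_high`, `n_pos`, `n_neg`, `n_boot`, `seed`.
#' @export
bootstrap_auc_ci <- function(scores, labels, n_boot = 2000L, level = 0.95,
                             seed = NULL) {
  stopifnot(n_boot >= 100L)
  if (!is.null(seed)) set.seed(seed)
  labels <- as.integer(labels)
  auc <- roc_auc(scores, labels)
  n <- length(scores)
  boots <- numeric(n_boot)
  attempts <- 0L
  for (b in seq_len(n_boot)) {
    repeat {
      attempts <- attempts + 1L
      if (attempts > 10L * n_boot) {
        stop("bootstrap resamples persistently single-class", call. = FALSE)
      }
      idx <- sample.int(n, n, replace = TRUE)
      if (length(unique(labels[idx])) == 2L) break
    }
    boots[b] <- roc_auc(scores[idx], labels[idx])
  }
  alpha <- (1 - level) / 2
  ci <- unname(stats::quantile(boots, c(alpha, 1 - alpha)))
  structure(list(auc = auc, ci_low = ci[1L], ci_high = ci[2L],
                 n_pos = sum(labels == 1L), n_neg = sum(labels == 0L),
                 n_boot = n_boot, seed = seed),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("AUC = %.3f (%.0f%% CI %.3f-%.3f; %d pos / %d neg)\n",
              x$auc, 95, x$ci_low, x$ci_high, x$n_pos, x$n_neg))
  invisible(x)
}

#' Mann--Whitney U test between two samples
#'
#' Exact enumeration for small untied samples (combined n <= 20),
#' normal approximation with tie correction otherwise.
#'
#' @param sample_a,sample_b nonempty numeric vectors.
#' @param alternative `"two.sided"` (default), `"less"` (a
#'   stochastically smaller than b) or `"greater"`.
#' @return A list with `u` (the U statistic of `sample_a`) and `p`.
#' @export
mann_whitney <- function(sample_a, sample_b,
                         alternative = c("two.sided", "less", "greater")) {
  alternative <- match.arg(alternative)
  stopifnot(length(sample_a) >= 1L, length(sample_b) >= 1L)
  n <- length(sample_a) + length(sample_b)
  exact <- n <= 20L && !anyDuplicated(c(sample_a, sample_b))
  wt <- suppressWarnings(stats::wilcox.test(
    sample_a, sample_b, alternative = alternative, exact = exact))
  list(u = unname(wt$statistic), p = wt$p.value)
}

#' Moment and Q-Q summary of a score distribution
#'
#' Reports mean, standard deviation, skewness and excess kurtosis
#' (population moments of the standardized scores), plus `n_qq` pairs
#' of equally spaced standard-normal theoretical quantiles against the
#' empirical quantiles of the standardized scores -- the data behind a
#' Q-Q plot, used to judge normality descriptively.
#'
#' @param scores numeric vector, n >= 3, nonzero variance.
#' @param n_qq number of quantile points (default 100).
#' @return A list of class `"dist_summary"` with `n`, `mean`, `sd`,
#'   `skewness`, `excess_kurtosis`, `qq_points` (data frame with
#'   columns `theoretical`, `empirical`).
#' @export
distribution_summary <- function(scores, n_qq = 100L) {
  scores <- as.numeric(scores)
  if (length(scores) < 3L) stop("need at least 3 scores", call. = FALSE)
  s <- stats::sd(scores)
  if (s == 0) stop("scores have zero variance", call. = FALSE)
  z <- (scores - mean(scores)) / s
  probs <- seq_len(n_qq) / (n_qq + 1)
  qq <- data.frame(theoretical = stats::qnorm(probs),
                   empirical = unname(stats::quantile(z, probs)))
  structure(list(n = length(scores), mean = mean(scores), sd = s,
                 skewness = mean(z^3), excess_kurtosis = mean(z^4) - 3,
                 qq_points = qq),
            class = "dist_summary")
}

#' @export
print.dist_summary <- function(x, ...) {
  cat(sprintf(
    "n = %d, mean = %.3f, sd = %.3f, skewness = %.3f, ex. kurtosis = %.3f\n",
    x$n, x$mean, x$sd, x$skewness, x$excess_kurtosis))
  invisible(x)
}

#' Validate an end-to-end run on the synthetic benchmark
#'
#' Quantifies how well the workflow recovers the planted signal:
#' \itemize{
#'   \item the rank of each planted inverter among its disease's
#'     defined-correlation drugs (ascending correlation; rank 1 =
#'     strongest reversal);
#'   \item ROC AUC (with percentile-bootstrap CI) using the negated
#'     correlation as predictor and presence in the indications table
#'     -- i.e. the planted inverter flag -- as positive label;
#'   \item a one-sided Mann--Whitney comparison of combined
#'     enrichment p-values between true and size/topology-matched
#'     simulated pathways, pooled over diseases (true expected
#'     smaller);
#'   \item a moment/Q-Q summary of each disease's correlation scores.
#' }
#'
#' @param world a [generate_benchmark()] world.
#' @param scores a `"score_records"` data frame for the world's drugs
#'   and diseases.
#' @param cfg a [run_config()].
#' @param null_seed seed for the simulated-pathway comparison.
#' @param out_dir optional directory for a TSV + text report.
#' @return A list of class `"benchmark_report"` with elements `ranks`
#'   (data frame), `roc` (a `"roc_result"`), `true_vs_simulated`
#'   (list with `p`, `u`, `n_true`, `n_simulated`), `distributions`
#'   (per-disease `"dist_summary"` or `NULL`).
#' @export
validate_benchmark <- function(world, scores, cfg = run_config(),
                               null_seed = cfg$seed + 1L, out_dir = NULL) {
  stopifnot(inherits(world, "synthetic_world"))
  defined <- scores[!is.na(scores$correlation), , drop = FALSE]

  # (i) inverter ranks within each disease
  ranks <- list()
  for (disease in names(world$disease_truth)) {
    rows <- defined[defined$disease == disease, , drop = FALSE]
    if (!nrow(rows)) next
    ord <- order(rows$correlation, -rows$affected_pct, rows$drug_key)
    rows <- rows[ord, , drop = FALSE]
    inv <- paste0("inv_", disease)
    pos <- which(rows$drug_key == inv)
    ranks[[disease]] <- data.frame(
      disease = disease, inverter = inv,
      rank = if (length(pos)) pos[1L] else NA_integer_,
      n_ranked = nrow(rows),
      correlation = if (length(pos)) rows$correlation[pos[1L]] else NA_real_,
      affected_pct = if (length(pos)) rows$affected_pct[pos[1L]] else NA_real_,
      stringsAsFactors = FALSE)
  }
  ranks <- if (length(ranks)) do.call(rbind, ranks) else NULL
  if (!is.null(ranks)) rownames(ranks) <- NULL

  # (ii) ROC against indication labels
  ind <- world$tables$indications
  lab <- as.integer(paste(defined$drug_key, defined$disease) %in%
                      paste(ind$entity_id, ind$gene_id))
  roc <- if (length(unique(lab)) == 2L) {
    bootstrap_auc_ci(-defined$correlation, lab,
                     n_boot = max(100L, cfg$n_boot), seed = null_seed)
  } else NULL

  # (iii) true vs simulated pathway p-values, pooled over diseases
  set.seed(null_seed)
  sim <- simulate_null_pathways(world$pathways, world$genes)
  dis_sig <- signatures_from_table(world$tables$disease_deg)
  p_true <- numeric(); p_sim <- numeric()
  for (sg in dis_sig) {
    p_true <- c(p_true,
                run_enrichment(sg, world$genes, world$pathways, cfg)$p_g)
    p_sim <- c(p_sim, run_enrichment(sg, world$genes, sim, cfg)$p_g)
  }
  mw <- mann_whitney(p_true, p_sim, alternative = "less")
  tvs <- list(p = mw$p, u = mw$u, n_true = length(p_true),
              n_simulated = length(p_sim))

  # (iv) per-disease score distribution summaries
  dists <- lapply(split(defined$correlation, defined$disease), function(x) {
    if (length(x) >= 3L && stats::sd(x) > 0) {
      distribution_summary(x, n_qq = min(100L, length(x)))
    } else NULL
  })

  report <- structure(list(ranks = ranks, roc = roc,
                           true_vs_simulated = tvs,
                           distributions = dists),
                      class = "benchmark_report")
  if (!is.null(out_dir)) write_benchmark_report(report, out_dir)
  report
}

write_benchmark_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(report$ranks)) {
    write_table(report$ranks, file.path(out_dir, "inverter_ranks.tsv"))
  }
  txt <- utils::capture.output(print(report))
  writeLines(txt, file.path(out_dir, "report.txt"))
  invisible(out_dir)
}

#' @export
print.benchmark_report <- function(x, ...) {
  cat("== synthetic benchmark validation ==\n")
  if (!is.null(x$ranks)) {
    cat("inverter ranks:\n")
    print.data.frame(x$ranks, row.names = FALSE)
  }
  if (!is.null(x$roc)) {
    cat("ROC (negated correlation vs indication labels): ")
    print(x$roc)
  }
  cat(sprintf(
    "true vs simulated pathways: one-sided Mann-Whitney p = %.3g (%d vs %d p-values)\n",
    x$true_vs_simulated$p, x$true_vs_simulated$n_true,
    x$true_vs_simulated$n_simulated))
  invisible(x)
}
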