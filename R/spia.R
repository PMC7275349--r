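#' Solve the pathway perturbation propagation system
#'
#' The topology-based enrichment model propagates gene-level expression
#' changes through a pathway's signed edges. The perturbation factor of
#' gene i satisfies
#' \deqn{PF(i) = \Delta E(i) + \sum_j \beta_{ij} PF(j) / N_{ds}(j)}
#' where the sum runs over upstream genes j with an edge j -> i,
#' `beta` is +1 for activation and -1 for inhibition, and `N_ds(j)` is
#' the number of outgoing edges of j (self-loops count once). In matrix
#' form `(I - B_norm) PF = deltaE` with
#' `B_norm[i, j] = beta_ij / N_ds(j)`. The net accumulation of gene i
#' is `Acc(i) = PF(i) - deltaE(i)` (exactly zero for genes with no
#' incoming edges) and the pathway's total accumulation is
#' `tA = sum(Acc)`, whose sign gives the direction of dysregulation.
#'
#' @param graph a [pathway_graph()].
#' @param delta_e named numeric vector of signed expression changes;
#'   members absent from it get 0.
#' @return A list of class `"perturbation_solution"` with `pf`, `acc`
#'   (named numeric over the members) and `t_a`; or `NULL` with a
#'   warning if `(I - B_norm)` is singular (smallest singular value
#'   below 1e-10), in which case the caller should skip the pathway.
#' @examples
#' g <- pathway_graph("db", "p", c("A", "B"),
#'                    data.frame(source = "A", target = "B",
#'                               relation = "activation"))
#' solve_perturbation(g, c(A = 1))
#' @export
solve_perturbation <- function(graph, delta_e) {
  m <- graph$members
  de <- stats::setNames(numeric(length(m)), m)
  common <- intersect(names(delta_e), m)
  de[common] <- delta_e[common]
  if (any(!is.finite(de))) stop("delta_e must be finite", call. = FALSE)
  A <- perturbation_matrix(graph)
  if (min(svd(A, nu = 0, nv = 0)$d) < 1e-10) {
    warning("singular perturbation system for pathway ",
            pathway_key(graph$database, graph$pathway_id),
            "; pathway skipped")
    return(NULL)
  }
  pf <- drop(solve(A, de))
  no_in <- !(m %in% graph$edges$target)
  pf[no_in] <- de[no_in]
  acc <- pf - de
  structure(list(pf = pf, acc = acc, t_a = sum(acc)),
            class = "perturbation_solution")
}

# I - B_norm for a pathway graph, rows/cols in member order
perturbation_matrix <- function(graph) {
  m <- graph$members
  n <- length(m)
  A <- diag(n)
  e <- graph$edges
  if (nrow(e)) {
    outdeg <- table(factor(e$source, levels = m))
    si <- match(e$source, m)
    ti <- match(e$target, m)
    for (r in seq_len(nrow(e))) {
      A[ti[r], si[r]] <- A[ti[r], si[r]] - e$beta[r] / outdeg[[si[r]]]
    }
  }
  dimnames(A) <- list(m, m)
  A
}

#' Over-representation p-value of DE genes on a pathway
#'
#' Hypergeometric upper tail P(X >= n_de_on_pathway) for drawing
#' `n_de_total` DE genes from a universe of `n_universe` genes of which
#' `n_pathway` lie on the pathway.
#'
#' @param n_universe,n_pathway,n_de_total,n_de_on_pathway margins of
#'   the 2x2 table; must satisfy
#'   `n_de_on_pathway <= min(n_pathway, n_de_total) <= n_universe`.
#' @return The upper-tail probability.
#' @export
p_nde <- function(n_universe, n_pathway, n_de_total, n_de_on_pathway) {
  if (n_de_on_pathway > min(n_pathway, n_de_total) ||
      max(n_pathway, n_de_total) > n_universe || n_de_on_pathway < 0) {
    stop("infeasible hypergeometric margins", call. = FALSE)
  }
  stats::phyper(n_de_on_pathway - 1L, n_pathway, n_universe - n_pathway,
                n_de_total, lower.tail = FALSE)
}

#' Bootstrap p-value for the total pathway perturbation
#'
#' Builds the null distribution of `tA` by reassigning the observed
#' nonzero expression changes to uniformly random subsets of the
#' pathway's members (same cardinality) and re-solving the propagation
#' system for each replicate. The two-sided, median-centred tail
#' estimate is `p = (1 + #\{|tA_b - med| >= |tA_obs - med|\}) /
#' (n_boot + 1)`, which can never be exactly zero. All replicates share
#' one matrix factorization, so the cost is a single multi-right-hand-
#' side solve per pathway.
#'
#' @param graph a [pathway_graph()].
#' @param delta_e_observed named numeric vector of observed changes.
#' @param n_boot number of bootstrap replicates (>= 1).
#' @return A list with `p`, `null_median`, `t_a` (observed); all-zero
#'   input yields `p = 1`, `t_a = 0`. `NULL` if the system is singular.
#' @export
p_pert <- function(graph, delta_e_observed, n_boot = 2000L) {
  stopifnot(n_boot >= 1L)
  m <- graph$members
  n <- length(m)
  de <- stats::setNames(numeric(n), m)
  common <- intersect(names(delta_e_observed), m)
  de[common] <- delta_e_observed[common]
  vals <- de[de != 0]
  if (!length(vals)) {
    return(list(p = 1, null_median = 0, t_a = 0))
  }
  A <- perturbation_matrix(graph)
  if (min(svd(A, nu = 0, nv = 0)$d) < 1e-10) {
    warning("singular perturbation system for pathway ",
            pathway_key(graph$database, graph$pathway_id),
            "; pathway skipped")
    return(NULL)
  }
  nv <- length(vals)
  E <- matrix(0, n, n_boot + 1L)
  E[, 1L] <- de
  for (b in seq_len(n_boot)) {
    E[sample.int(n, nv), b + 1L] <- vals
  }
  no_in <- !(m %in% graph$edges$target)
  pf <- solve(A, E)
  pf[no_in, ] <- E[no_in, ]
  # tA = sum(PF) - sum(deltaE); the reassigned values keep their sum
  t_all <- colSums(pf) - sum(vals)
  t_obs <- t_all[1L]
  t_null <- t_all[-1L]
  med <- stats::median(t_null)
  p <- (1 + sum(abs(t_null - med) >= abs(t_obs - med))) / (n_boot + 1)
  list(p = p, null_median = med, t_a = t_obs)
}

#' Combine over-representation and perturbation p-values
#'
#' Fisher product combination: with `c = p_nde * p_pert`, the combined
#' p-value is `c - c * log(c)` (1 when `c = 1`). This is the exact tail
#' probability of the product of two independent uniforms.
#'
#' @param p_nde,p_pert probabilities in (0, 1].
#' @return Combined probability in (0, 1].
#' @export
combine_p <- function(p_nde, p_pert) {
  if (any(c(p_nde, p_pert) <= 0) || any(c(p_nde, p_pert) > 1)) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  cc <- p_nde * p_pert
  ifelse(cc >= 1, 1, cc - cc * log(cc))
}

#' Topology-based pathway enrichment of one gene signature
#'
#' For every pathway with at least one differentially expressed member,
#' computes the over-representation p-value (`p_nde`), the total net
#' accumulation `t_a` with its bootstrap significance (`p_pert`), the
#' combined `p_g`, and a BH adjustment of `p_g` across all pathways of
#' this run (`p_g_fdr` -- each entity's enrichment is its own family).
#' The pathway status is `"activated"` for `t_a > 0`, `"inhibited"`
#' for `t_a < 0`, `"none"` for `t_a = 0`. Pathways with no DE members
#' or a singular propagation system are omitted.
#'
#' @param signature a [gene_signature()].
#' @param universe character vector of background gene ids (the
#'   signature's genes must be contained in it).
#' @param pathways list of [pathway_graph()] objects.
#' @param cfg a [run_config()]; `cfg$n_boot` bootstrap replicates.
#' @param seed optional integer; if given, seeds the RNG for this run.
#' @return A data frame of class `"enrichment_result"` with one row per
#'   analyzed pathway: `database`, `pathway_id`, `n_de_on_pathway`,
#'   `p_nde`, `t_a`, `p_pert`, `p_g`, `p_g_fdr`, `status`.
#' @export
run_enrichment <- function(signature, universe, pathways,
                           cfg = run_config(), seed = NULL) {
  stopifnot(inherits(signature, "gene_signature"))
  if (!is.null(seed)) set.seed(seed)
  universe <- unique(as.character(universe))
  if (!all(signature$genes %in% universe)) {
    stop("signature genes must be contained in the universe", call. = FALSE)
  }
  de <- signature$delta_e[signature$delta_e != 0]
  if (!length(de)) {
    warning("empty signature for ", signature$entity_id)
    return(empty_enrichment())
  }
  n_u <- length(universe)
  n_de <- length(de)
  rows <- vector("list", length(pathways))
  for (i in seq_along(pathways)) {
    g <- pathways[[i]]
    members <- intersect(g$members, universe)
    k <- sum(names(de) %in% members)
    if (k == 0L) next
    pn <- p_nde(n_u, length(members), n_de, k)
    pp <- p_pert(g, de, n_boot = cfg$n_boot)
    if (is.null(pp)) next
    status <- if (pp$t_a > 0) "activated" else if (pp$t_a < 0) "inhibited" else "none"
    rows[[i]] <- data.frame(
      database = g$database, pathway_id = g$pathway_id,
      n_de_on_pathway = k, p_nde = pn, t_a = pp$t_a, p_pert = pp$p,
      p_g = combine_p(pn, pp$p), status = status, stringsAsFactors = FALSE)
  }
  rows <- rows[!vapply(rows, is.null, NA)]
  if (!length(rows)) return(empty_enrichment())
  df <- do.call(rbind, rows)
  df$p_g_fdr <- bh_adjust(df$p_g)
  df <- df[, c("database", "pathway_id", "n_de_on_pathway", "p_nde",
               "t_a", "p_pert", "p_g", "p_g_fdr", "status")]
  rownames(df) <- NULL
  class(df) <- c("enrichment_result", "data.frame")
  df
}

empty_enrichment <- function() {
  df <- data.frame(database = character(), pathway_id = character(),
                   n_de_on_pathway = integer(), p_nde = numeric(),
                   t_a = numeric(), p_pert = numeric(), p_g = numeric(),
                   p_g_fdr = numeric(), status = character(),
                   stringsAsFactors = FALSE)
  class(df) <- c("enrichment_result", "data.frame")
  df
}

#' Size- and topology-preserving simulated pathways
#'
#' For each true pathway, draws a random pathway of the same size from
#' the gene universe and relabels the edges accordingly, preserving the
#' topology exactly. Running enrichment on these label-randomized
#' constructs gives the null against which true pathways' significance
#' is compared.
#'
#' @param pathways list of [pathway_graph()] templates.
#' @param universe character vector of gene ids to draw from.
#' @param seed optional integer seed.
#' @return A named list of simulated [pathway_graph()] objects; ids are
#'   the template ids suffixed with `"_sim"`.
#' @export
simulate_null_pathways <- function(pathways, universe, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  universe <- unique(as.character(universe))
  out <- lapply(pathways, function(g) {
    if (length(g$members) > length(universe)) {
      stop("universe smaller than pathway ", g$pathway_id, call. = FALSE)
    }
    new_members <- sample(universe, length(g$members))
    relabel <- stats::setNames(new_members, g$members)
    e <- g$edges
    if (nrow(e)) {
      e$source <- unname(relabel[e$source])
      e$target <- unname(relabel[e$target])
    }
    pathway_graph(g$database, paste0(g$pathway_id, "_sim"),
                  new_members, e, description = g$description)
  })
  stats::setNames(out, vapply(out, function(g)
    pathway_key(g$database, g$pathway_id), ""))
}
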