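#' Configuration for the synthetic benchmark generator
#'
#' The generator builds a small in-silico world in which every
#' downstream stage of the workflow has a known answer: random signed
#' pathway graphs; diseases that dysregulate a planted subset of
#' "driver" pathways (GWAS hits and DEGs concentrated in driver
#' members, with DEG signs following the planted pathway sign); and
#' drugs that exactly invert, exactly mimic, or are unrelated to each
#' disease's gene-level signature.
#'
#' Defaults describe the benchmark's study conditions: a 2,000-gene
#' universe, 50 pathways of 10--30 genes, 5 diseases each driving 10
#' pathways (half up-, half down-regulated -- a disease dysregulating
#' every pathway in the same direction would have a constant signature
#' vector and no defined correlations), GWAS/DEG hit rates of 0.5/0.8
#' inside driver pathways against a 0.01 background, 5% sign noise,
#' and 20 unrelated drugs.
#'
#' @param n_genes size of the gene universe.
#' @param n_pathways number of pathways.
#' @param pathway_size_range inclusive (min, max) member counts
#'   (min >= 3).
#' @param n_diseases number of diseases.
#' @param drivers_per_disease planted driver pathways per disease
#'   (<= n_pathways).
#' @param n_random_drugs number of unrelated drugs in the world (each
#'   is scored against every disease).
#' @param gwas_hit_rate_in_driver,gwas_background_rate per-gene GWAS
#'   association probabilities inside/outside driver pathways.
#' @param deg_hit_rate_in_driver,deg_background_rate per-gene DEG
#'   probabilities inside/outside driver pathways.
#' @param sign_noise probability that a driver DEG's sign is flipped
#'   relative to the planted pathway sign.
#' @param inhibition_edge_prob probability that an edge is inhibitory
#'   (beta = -1).
#' @param seed integer seed; the whole world is a pure function of
#'   this configuration.
#' @return A list of class `"synth_config"`.
#' @export
synth_config <- function(n_genes = 2000L, n_pathways = 50L,
                         pathway_size_range = c(10L, 30L),
                         n_diseases = 5L, drivers_per_disease = 10L,
                         n_random_drugs = 20L,
                         gwas_hit_rate_in_driver = 0.5,
                         gwas_background_rate = 0.01,
                         deg_hit_rate_in_driver = 0.8,
                         deg_background_rate = 0.01,
                         sign_noise = 0.05,
                         inhibition_edge_prob = 0.25,
                         seed = 20231L) {
  cfg <- list(n_genes = as.integer(n_genes),
              n_pathways = as.integer(n_pathways),
              pathway_size_range = as.integer(pathway_size_range),
              n_diseases = as.integer(n_diseases),
              drivers_per_disease = as.integer(drivers_per_disease),
              n_random_drugs = as.integer(n_random_drugs),
              gwas_hit_rate_in_driver = gwas_hit_rate_in_driver,
              gwas_background_rate = gwas_background_rate,
              deg_hit_rate_in_driver = deg_hit_rate_in_driver,
              deg_background_rate = deg_background_rate,
              sign_noise = sign_noise,
              inhibition_edge_prob = inhibition_edge_prob,
              seed = as.integer(seed))
  rates <- c("gwas_hit_rate_in_driver", "gwas_background_rate",
             "deg_hit_rate_in_driver", "deg_background_rate",
             "sign_noise", "inhibition_edge_prob")
  for (r in rates) {
    if (cfg[[r]] < 0 || cfg[[r]] > 1) {
      stop(r, " must lie in [0, 1]", call. = FALSE)
    }
  }
  if (cfg$pathway_size_range[1L] < 3L) {
    stop("pathway sizes must be >= 3", call. = FALSE)
  }
  if (cfg$drivers_per_disease > cfg$n_pathways) {
    stop("drivers_per_disease must be <= n_pathways", call. = FALSE)
  }
  structure(cfg, class = "synth_config")
}

synth_universe <- function(cfg) sprintf("g%05d", seq_len(cfg$n_genes))

#' Generate random signed pathway graphs
#'
#' Draws `n_pathways` pathways with member sets sampled from the gene
#' universe (pathways may overlap). Each graph is weakly connected by
#' construction: a random spanning tree over the members plus roughly
#' one extra random edge per two members, each edge inhibitory with
#' probability `inhibition_edge_prob` and activating otherwise.
#' Consumes the current RNG stream; seed via [generate_benchmark()] or
#' `set.seed()`.
#'
#' @param cfg a [synth_config()].
#' @return A named list of [pathway_graph()] objects.
#' @export
generate_pathways <- function(cfg) {
  universe <- synth_universe(cfg)
  out <- vector("list", cfg$n_pathways)
  sizes <- seq(cfg$pathway_size_range[1L], cfg$pathway_size_range[2L])
  for (p in seq_len(cfg$n_pathways)) {
    size <- sizes[sample.int(length(sizes), 1L)]
    members <- sample(universe, size)
    # random spanning tree: each node after the first attaches to an
    # earlier node, so the graph is weakly connected
    src <- members[vapply(seq(2L, size), function(i)
      sample.int(i - 1L, 1L), 0L)]
    tgt <- members[seq(2L, size)]
    n_extra <- max(0L, floor(size / 2))
    if (n_extra > 0L) {
      es <- sample(members, n_extra, replace = TRUE)
      et <- sample(members, n_extra, replace = TRUE)
      src <- c(src, es)
      tgt <- c(tgt, et)
    }
    edges <- unique(data.frame(source = src, target = tgt,
                               stringsAsFactors = FALSE))
    edges$relation <- ifelse(
      stats::runif(nrow(edges)) < cfg$inhibition_edge_prob,
      "inhibition", "activation")
    out[[p]] <- pathway_graph("synthdb", sprintf("P%03d", p),
                              members, edges,
                              description = "synthetic pathway")
  }
  stats::setNames(out, vapply(out, function(g)
    pathway_key(g$database, g$pathway_id), ""))
}

# draw a DEG signature concentrated in `driver_signs` pathways:
# driver members expressed at the driver rate with the planted sign
# (flipped with prob sign_noise), background genes at the background
# rate with random signs; |effect| ~ U(0.5, 3)
draw_structured_deg <- function(cfg, pathways, driver_keys, driver_signs,
                                universe) {
  genes <- character(); signs <- numeric()
  driver_members <- character()
  for (i in seq_along(driver_keys)) {
    m <- pathways[[driver_keys[i]]]$members
    driver_members <- union(driver_members, m)
    hit <- m[stats::runif(length(m)) < cfg$deg_hit_rate_in_driver]
    s <- rep(driver_signs[i], length(hit))
    flip <- stats::runif(length(hit)) < cfg$sign_noise
    s[flip] <- -s[flip]
    genes <- c(genes, hit); signs <- c(signs, s)
  }
  bg <- setdiff(universe, driver_members)
  bg_hit <- bg[stats::runif(length(bg)) < cfg$deg_background_rate]
  genes <- c(genes, bg_hit)
  signs <- c(signs, sample(c(-1, 1), length(bg_hit), replace = TRUE))
  effect <- signs * stats::runif(length(genes), 0.5, 3)
  list(genes = genes, effect = effect)
}

# balanced planted signs for k driver pathways, shuffled
balanced_signs <- function(k) {
  sample(c(rep(1, ceiling(k / 2)), rep(-1, floor(k / 2))))
}

#' Generate coupled GWAS and disease-DEG tables with planted drivers
#'
#' For each disease, samples `drivers_per_disease` driver pathways
#' with balanced planted signs, then draws GWAS associations from
#' driver members at `gwas_hit_rate_in_driver` (background genes at
#' `gwas_background_rate`) and DEGs at the DEG rates with signs tied
#' to the planted pathway sign. Consumes the current RNG stream.
#'
#' @param cfg a [synth_config()].
#' @param pathways output of [generate_pathways()].
#' @return A list with `gwas` and `deg` [association_table()]s and
#'   `disease_truth`: per disease, a named vector of planted pathway
#'   signs keyed by [pathway_key()].
#' @export
generate_disease_data <- function(cfg, pathways) {
  universe <- synth_universe(cfg)
  gwas_e <- character(); gwas_g <- character()
  deg_e <- character(); deg_g <- character(); deg_eff <- numeric()
  truth <- list()
  for (d in seq_len(cfg$n_diseases)) {
    disease <- sprintf("D%02d", d)
    drivers <- sample(names(pathways), cfg$drivers_per_disease)
    signs <- balanced_signs(cfg$drivers_per_disease)
    truth[[disease]] <- stats::setNames(signs, drivers)
    driver_members <- unique(unlist(lapply(pathways[drivers],
                                           `[[`, "members")))
    hit <- driver_members[stats::runif(length(driver_members)) <
                            cfg$gwas_hit_rate_in_driver]
    bg <- setdiff(universe, driver_members)
    bg_hit <- bg[stats::runif(length(bg)) < cfg$gwas_background_rate]
    g <- c(hit, bg_hit)
    gwas_e <- c(gwas_e, rep(disease, length(g)))
    gwas_g <- c(gwas_g, g)
    deg <- draw_structured_deg(cfg, pathways, drivers, signs, universe)
    deg_e <- c(deg_e, rep(disease, length(deg$genes)))
    deg_g <- c(deg_g, deg$genes)
    deg_eff <- c(deg_eff, deg$effect)
  }
  list(gwas = association_table(gwas_e, gwas_g, kind = "gwas",
                                source = "synthetic"),
       deg = association_table(deg_e, deg_g, effect = deg_eff,
                               kind = "disease_deg", source = "synthetic"),
       disease_truth = truth)
}

#' Generate drug perturbation signatures and indication labels
#'
#' Plants, for every disease, one inverter drug whose DEG rows are the
#' disease's rows with effects negated and one mimicker with effects
#' copied, plus `n_random_drugs` unrelated drugs. Unrelated drugs are
#' pathway-structured: each perturbs its own random driver pathways,
#' drawn by the same mechanism as the diseases, so that they produce
#' nonempty pathway signatures and defined (but uninformative)
#' correlation scores. The indications table marks each inverter as
#' trialed for its disease; unrelated drugs carry no label. With
#' `coupled = FALSE` the inverters and mimickers are replaced by
#' independently drawn structured signatures (labels kept), yielding a
#' signal-free benchmark in which the indication labels carry no
#' information about the scores.
#'
#' @param cfg a [synth_config()].
#' @param disease_deg the disease DEG table from
#'   [generate_disease_data()].
#' @param disease_truth planted disease signs (same origin).
#' @param pathways output of [generate_pathways()].
#' @param coupled logical; see above.
#' @return A list with `drug_deg` and `indications`
#'   [association_table()]s and `drug_truth`: a data frame with
#'   columns `drug`, `role` (`"inverter"`, `"mimicker"`, `"random"`),
#'   `disease` (`NA` for unrelated drugs).
#' @export
generate_drug_data <- function(cfg, disease_deg, disease_truth, pathways,
                               coupled = TRUE) {
  universe <- synth_universe(cfg)
  ent <- character(); gene <- character(); eff <- numeric()
  ind_drug <- character(); ind_disease <- character()
  truth <- list()
  add_structured <- function(drug) {
    drivers <- sample(names(pathways), cfg$drivers_per_disease)
    signs <- balanced_signs(cfg$drivers_per_disease)
    deg <- draw_structured_deg(cfg, pathways, drivers, signs, universe)
    ent <<- c(ent, rep(drug, length(deg$genes)))
    gene <<- c(gene, deg$genes)
    eff <<- c(eff, deg$effect)
  }
  for (disease in names(disease_truth)) {
    rows <- disease_deg[disease_deg$entity_id == disease, , drop = FALSE]
    inv <- paste0("inv_", disease)
    mim <- paste0("mim_", disease)
    if (coupled) {
      ent <- c(ent, rep(inv, nrow(rows)), rep(mim, nrow(rows)))
      gene <- c(gene, rows$gene_id, rows$gene_id)
      eff <- c(eff, -rows$effect, rows$effect)
    } else {
      add_structured(inv)
      add_structured(mim)
    }
    ind_drug <- c(ind_drug, inv)
    ind_disease <- c(ind_disease, disease)
    truth[[inv]] <- data.frame(drug = inv, role = "inverter",
                               disease = disease, stringsAsFactors = FALSE)
    truth[[mim]] <- data.frame(drug = mim, role = "mimicker",
                               disease = disease, stringsAsFactors = FALSE)
  }
  for (r in seq_len(cfg$n_random_drugs)) {
    drug <- sprintf("rnd_%02d", r)
    add_structured(drug)
    truth[[drug]] <- data.frame(drug = drug, role = "random",
                                disease = NA_character_,
                                stringsAsFactors = FALSE)
  }
  drug_truth <- do.call(rbind, truth)
  rownames(drug_truth) <- NULL
  list(drug_deg = association_table(ent, gene, effect = eff,
                                    kind = "drug_deg", source = "synthetic"),
       indications = association_table(ind_drug, ind_disease,
                                       kind = "indication",
                                       source = "synthetic"),
       drug_truth = drug_truth)
}

#' Generate the full synthetic benchmark world
#'
#' Seeds the RNG with `cfg$seed` and generates pathways, disease data
#' and drug data in a fixed order, so the world is a pure function of
#' the configuration. If `out_dir` is given, all fixture files are
#' written in the formats the package readers consume (four TSV
#' tables, a GMT membership file, a topology TSV) plus a
#' `manifest.yaml` echoing the configuration.
#'
#' @param cfg a [synth_config()].
#' @param out_dir optional directory to write fixture files into.
#' @param coupled passed to [generate_drug_data()]; `FALSE` yields the
#'   signal-free (label-decoupled) benchmark.
#' @return A list of class `"synthetic_world"`: `pathways`, `genes`,
#'   `tables` (gwas, disease_deg, drug_deg, indications),
#'   `disease_truth`, `drug_truth`, `cfg`.
#' @export
generate_benchmark <- function(cfg = synth_config(), out_dir = NULL,
                               coupled = TRUE) {
  set.seed(cfg$seed)
  pathways <- generate_pathways(cfg)
  dd <- generate_disease_data(cfg, pathways)
  dr <- generate_drug_data(cfg, dd$deg, dd$disease_truth, pathways,
                           coupled = coupled)
  world <- structure(
    list(pathways = pathways, genes = synth_universe(cfg),
         tables = list(gwas = dd$gwas, disease_deg = dd$deg,
                       drug_deg = dr$drug_deg,
                       indications = dr$indications),
         disease_truth = dd$disease_truth, drug_truth = dr$drug_truth,
         cfg = cfg),
    class = "synthetic_world")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_table(world$tables$gwas, file.path(out_dir, "gwas.tsv"))
    write_table(world$tables$disease_deg,
                file.path(out_dir, "disease_deg.tsv"))
    write_table(world$tables$drug_deg, file.path(out_dir, "drug_deg.tsv"))
    write_table(world$tables$indications,
                file.path(out_dir, "indications.tsv"))
    write_gmt(pathways, file.path(out_dir, "pathways.gmt"))
    write_topology(pathways, file.path(out_dir, "topology.tsv"))
    yaml::write_yaml(c(unclass(cfg), list(coupled = coupled)),
                     file.path(out_dir, "manifest.yaml"))
  }
  world
}

#' @export
print.synthetic_world <- function(x, ...) {
  cat("<synthetic_world>", x$cfg$n_genes, "genes,",
      length(x$pathways), "pathways,", x$cfg$n_diseases, "diseases,",
      nrow(x$drug_truth), "drugs (seed", x$cfg$seed, ")\n")
  invisible(x)
}
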