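# Shared fixture builders (all generated in code, nothing on disk).

# two-gene chain A -> B with the given relation
chain_graph <- function(relation = "activation") {
  pathway_graph("db", "chain", c("A", "B"),
                data.frame(source = "A", target = "B",
                           relation = relation,
                           stringsAsFactors = FALSE))
}

# random signed graph over n nodes (allows cycles and self-loops)
random_signed_graph <- function(n, p_edge = 0.35, id = "rg") {
  members <- paste0("n", seq_len(n))
  pairs <- expand.grid(source = members, target = members,
                       stringsAsFactors = FALSE)
  pairs <- pairs[stats::runif(nrow(pairs)) < p_edge, , drop = FALSE]
  if (!nrow(pairs)) {
    pairs <- data.frame(source = members[1], target = members[min(2, n)],
                        stringsAsFactors = FALSE)
  }
  pairs$relation <- sample(c("activation", "inhibition"), nrow(pairs),
                           replace = TRUE)
  pathway_graph("db", id, members, pairs)
}

# a named signature vector over pathway keys
sig_vec <- function(values, entity = "x") {
  structure(as.numeric(values), names = names(values),
            entity_id = entity, class = "signature_vector")
}

# scaled-down benchmark configuration for fast unit tests
small_synth_cfg <- function(seed = 7L) {
  synth_config(n_genes = 400L, n_pathways = 12L,
               pathway_size_range = c(6L, 12L), n_diseases = 3L,
               drivers_per_disease = 6L, n_random_drugs = 4L,
               seed = seed)
}

small_run_cfg <- function(seed = 5L, ...) {
  run_config(n_boot = 100L, seed = seed, ...)
}
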