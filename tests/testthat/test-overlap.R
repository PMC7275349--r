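test_that("fisher_overlap matches the combinatorial oracle", {
  u <- paste0("g", 1:100)
  r <- fisher_overlap(u[1:10], u[6:15], u)
  expect_equal(r$n_overlap, 5L)
  expect_equal(r$p_value, hyper_upper_oracle(100, 10, 10, 5),
               tolerance = 1e-12)
  expect_setequal(r$intersection, u[6:10])

  # no overlap: P(X >= 0) = 1
  r0 <- fisher_overlap(u[1:10], u[11:20], u)
  expect_equal(r0$p_value, 1)

  # A = B = A intersect B: minimal tail at those margins
  rab <- fisher_overlap(u[1:5], u[1:5], u)
  expect_equal(rab$p_value, hyper_upper_oracle(100, 5, 5, 5),
               tolerance = 1e-12)
  ps <- vapply(0:5, function(k)
    hyper_upper_oracle(100, 5, 5, k), 0)
  expect_equal(rab$p_value, min(ps), tolerance = 1e-12)
})

test_that("fisher_overlap enforces subset contract and odds conventions", {
  u <- paste0("g", 1:20)
  expect_error(fisher_overlap(c(u[1:3], "zz"), u[1:5], u), "subsets")
  # A = universe, B = universe: 2x2 off-diagonals vanish -> NaN marker
  r <- fisher_overlap(u, u, u)
  expect_true(is.nan(r$odds_ratio))
  # numeric universe skips membership checks
  r2 <- fisher_overlap(u[1:5], u[3:7], 50)
  expect_equal(r2$n_universe, 50L)
  expect_equal(r2$p_value, hyper_upper_oracle(50, 5, 5, 3),
               tolerance = 1e-12)
})

test_that("overlap p-value grows as the intersection shrinks", {
  # monotonicity at fixed margins
  ps <- vapply(0:8, function(k) hyper_upper_oracle(40, 8, 10, k), 0)
  expect_true(all(diff(ps) < 0))
  u <- paste0("g", 1:40)
  p_big <- fisher_overlap(u[1:8], u[1:10], u)$p_value
  p_small <- fisher_overlap(u[1:8], u[c(1:5, 11:15)], u)$p_value
  expect_lt(p_big, p_small)
})

test_that("bh_adjust applies step-up correction in input order", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.42), 0.42)
  expect_error(bh_adjust(c(0.5, 0)), "\\(0, 1\\]")
  expect_error(bh_adjust(c(0.5, 1.2)), "\\(0, 1\\]")

  set.seed(8)
  for (i in 1:10) {
    p <- stats::runif(sample(3:40, 1))
    q <- bh_adjust(p)
    expect_equal(q, bh_oracle(p), tolerance = 1e-12)
    expect_true(all(q >= p - 1e-15) && all(q <= 1))
    # permutation invariance
    perm <- sample(length(p))
    expect_equal(bh_adjust(p[perm]), q[perm], tolerance = 1e-12)
  }
})

test_that("stage 1 retains same-disease pairs with planted overlap", {
  w <- generate_benchmark(synth_config())
  cfg <- small_run_cfg()
  s1 <- filter_disease_gwas(w$tables$disease_deg, w$tables$gwas, cfg)
  df <- s1$all_pairs
  same <- df$entity_a == df$entity_b
  expect_true(all(df$q_value[same] <= cfg$q_disease_gwas))
  expect_lt(median(df$q_value[same]), median(df$q_value[!same]))
  expect_setequal(names(s1$sets$sets), names(w$disease_truth))
  # stage-1 genes are in both the disease's GWAS and DEG tables
  for (d in names(s1$sets$sets)) {
    genes <- s1$sets$sets[[d]]$genes
    gwas_g <- w$tables$gwas$gene_id[w$tables$gwas$entity_id == d]
    deg_g <- w$tables$disease_deg$gene_id[
      w$tables$disease_deg$entity_id == d]
    expect_true(all(genes %in% gwas_g) && all(genes %in% deg_g))
  }
})

test_that("a disease absent from GWAS yields no disease-specific set", {
  deg <- association_table(rep(c("d1", "d2"), each = 4),
                           paste0("g", c(1:4, 1:4)),
                           effect = rep(c(1, -1), 4),
                           kind = "disease_deg")
  gwas <- association_table(rep("d1", 4), paste0("g", 1:4), kind = "gwas")
  s1 <- filter_disease_gwas(deg, gwas, run_config())
  expect_false("d2" %in% names(s1$sets$sets))
})

test_that("stage 2 respects indication restriction and stringency", {
  w <- generate_benchmark(synth_config())
  cfg <- small_run_cfg()
  # indication-restricted: only inverters are candidates
  s2 <- filter_drug_gwas(w$tables$drug_deg, w$tables$gwas,
                         w$tables$indications, cfg)
  expect_true(all(grepl("^inv_", s2$all_pairs$entity_a)))
  inv_keys <- paste0("inv_", names(w$disease_truth), "|",
                     names(w$disease_truth))
  expect_true(all(inv_keys %in% names(s2$sets$sets)))
  expect_true(all(s2$all_pairs$q_value[
    s2$all_pairs$entity_a == paste0("inv_", s2$all_pairs$entity_b)] <=
      cfg$q_drug_gwas))

  # all-pairs mode also tests unlabeled drugs
  cfg2 <- small_run_cfg(all_pairs = TRUE)
  s2b <- filter_drug_gwas(w$tables$drug_deg, w$tables$gwas,
                          w$tables$indications, cfg2)
  expect_gt(nrow(s2b$all_pairs), nrow(s2$all_pairs))
  mim_keys <- paste0("mim_", names(w$disease_truth), "|",
                     names(w$disease_truth))
  expect_true(all(mim_keys %in% names(s2b$sets$sets)))
})

test_that("stage 3 sets are contained in both parent stages", {
  w <- generate_benchmark(synth_config())
  cfg <- small_run_cfg(all_pairs = TRUE)
  s1 <- filter_disease_gwas(w$tables$disease_deg, w$tables$gwas, cfg)
  s2 <- filter_drug_gwas(w$tables$drug_deg, w$tables$gwas,
                         w$tables$indications, cfg)
  s3 <- filter_triple(s1$sets, s2$sets, cfg)
  expect_gt(length(s3$sets$sets), 0L)
  for (k in names(s3$sets$sets)) {
    s <- s3$sets$sets[[k]]
    expect_true(all(s$genes %in% s2$sets$sets[[k]]$genes))
    expect_true(all(s$genes %in% s1$sets$sets[[s$disease]]$genes))
    # drug effects inherited from the stage-2 (drug) side
    expect_equal(s$delta_e, s2$sets$sets[[k]]$delta_e[names(s$delta_e)])
  }
  # identical parent sets give a maximal, retained overlap
  inv_keys <- paste0("inv_", names(w$disease_truth), "|",
                     names(w$disease_truth))
  expect_true(all(inv_keys %in% names(s3$sets$sets)))
})

test_that("empty inputs produce empty stages with a warning", {
  deg <- association_table(character(), character(), effect = numeric(),
                           kind = "disease_deg")
  gwas <- association_table("d1", "g1", kind = "gwas")
  expect_warning(s1 <- filter_disease_gwas(deg, gwas, run_config()),
                 "empty")
  expect_length(s1$sets$sets, 0L)
})
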