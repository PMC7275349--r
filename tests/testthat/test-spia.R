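test_that("perturbation solver handles hand-solvable systems", {
  # edgeless pathway: PF = deltaE, no accumulation
  g0 <- pathway_graph("db", "p0", c("A", "B"))
  s <- solve_perturbation(g0, c(A = 1, B = -2))
  expect_equal(unname(s$pf), c(1, -2))
  expect_equal(unname(s$acc), c(0, 0))
  expect_equal(s$t_a, 0)

  # chain A -> B activation: PF = (1, 1), Acc = (0, 1), tA = 1
  s1 <- solve_perturbation(chain_graph("activation"), c(A = 1))
  expect_equal(s1$pf, c(A = 1, B = 1))
  expect_equal(s1$acc, c(A = 0, B = 1))
  expect_equal(s1$t_a, 1)

  # same chain with inhibition: PF = (1, -1), tA = -1
  s2 <- solve_perturbation(chain_graph("inhibition"), c(A = 1))
  expect_equal(s2$pf, c(A = 1, B = -1))
  expect_equal(s2$t_a, -1)
})

test_that("solver agrees with an independent dense oracle on random graphs", {
  set.seed(12)
  for (i in 1:60) {
    n <- sample(2:8, 1)
    g <- random_signed_graph(n)
    de <- stats::setNames(stats::rnorm(n), g$members)
    s <- suppressWarnings(solve_perturbation(g, de))
    if (is.null(s)) next # singular; covered below
    expect_lt(max(abs(s$pf - pf_oracle(g, de))), 1e-9)
    expect_lt(pf_residual(g, de, s$pf), 1e-9)
    # acc is exactly zero for genes with no incoming edges
    no_in <- !(g$members %in% g$edges$target)
    expect_true(all(s$acc[no_in] == 0))
  }
})

test_that("perturbation response is linear in the input changes", {
  set.seed(13)
  repeat {
    g <- random_signed_graph(6)
    de <- stats::setNames(stats::rnorm(6), g$members)
    s <- suppressWarnings(solve_perturbation(g, de))
    if (!is.null(s)) break
  }
  for (c_scale in c(-3, 0.5, 10)) {
    sc <- solve_perturbation(g, de * c_scale)
    expect_equal(sc$pf, s$pf * c_scale)
    expect_equal(sc$t_a, s$t_a * c_scale)
  }
})

test_that("singular propagation systems are skipped, not solved", {
  # A <-> B with activation both ways: I - B_norm = [[1,-1],[-1,1]]
  g <- pathway_graph("db", "sing", c("A", "B"),
                     data.frame(source = c("A", "B"), target = c("B", "A"),
                                relation = "activation"))
  expect_warning(s <- solve_perturbation(g, c(A = 1)), "singular")
  expect_null(s)
})

test_that("p_nde is the hypergeometric upper tail with margin checks", {
  expect_equal(p_nde(20, 5, 4, 3), hyper_upper_oracle(20, 5, 4, 3),
               tolerance = 1e-12)
  expect_equal(p_nde(20, 5, 4, 0), 1)
  # pathway covering the whole universe: any feasible overlap is forced
  expect_equal(p_nde(20, 20, 4, 4), 1)
  expect_error(p_nde(20, 5, 4, 5), "infeasible")
  expect_error(p_nde(20, 25, 4, 3), "infeasible")
})

test_that("bootstrap perturbation p-value follows its conventions", {
  # edgeless pathway: every bootstrap tA = 0 = observed, p = 1
  g0 <- pathway_graph("db", "p0", c("A", "B", "C"))
  r <- p_pert(g0, c(A = 1, B = -1), n_boot = 50)
  expect_equal(r$p, 1)
  expect_equal(r$t_a, 0)

  # all-zero input: p = 1, tA = 0
  r0 <- p_pert(chain_graph(), c(A = 0), n_boot = 50)
  expect_equal(r0$p, 1)
  expect_equal(r0$t_a, 0)

  # seeded reruns are identical, p never zero
  set.seed(4)
  g <- random_signed_graph(7)
  de <- stats::setNames(c(2, -1, 1.5, 0, 0, 0, 0), g$members)
  set.seed(42); a <- p_pert(g, de, n_boot = 200)
  set.seed(42); b <- p_pert(g, de, n_boot = 200)
  expect_identical(a, b)
  expect_gt(a$p, 0)
  expect_lte(a$p, 1)
})

test_that("combine_p implements the product tail combination", {
  expect_equal(combine_p(1, 1), 1)
  cc <- 0.05 * 0.05
  expect_equal(combine_p(0.05, 0.05), cc - cc * log(cc))
  expect_equal(combine_p(0.05, 0.05), 0.017479, tolerance = 1e-4)
  expect_error(combine_p(0, 0.5), "\\(0, 1\\]")
  set.seed(5)
  p1 <- stats::runif(50); p2 <- stats::runif(50)
  pg <- combine_p(p1, p2)
  expect_true(all(pg >= p1 * p2) && all(pg <= 1))
})

test_that("enrichment ranks the truly perturbed pathway first", {
  set.seed(6)
  cfgp <- synth_config(n_genes = 60, n_pathways = 2,
                       pathway_size_range = c(8, 8), n_diseases = 1,
                       drivers_per_disease = 1, seed = 6)
  pw <- generate_pathways(cfgp)
  universe <- sprintf("g%05d", 1:60)
  hit <- pw[[1L]]$members
  sg <- gene_signature("x", stats::setNames(rep(2, 6), hit[1:6]))
  enr <- run_enrichment(sg, universe, pw, small_run_cfg(), seed = 9)
  expect_s3_class(enr, "enrichment_result")
  p1 <- enr$p_g[enr$pathway_id == pw[[1L]]$pathway_id]
  p2 <- enr$p_g[enr$pathway_id == pw[[2L]]$pathway_id]
  expect_true(length(p2) == 0L || p1 < p2)
  expect_true(all(enr$status[enr$t_a > 0] == "activated"))
  expect_true(all(enr$status[enr$t_a < 0] == "inhibited"))
  expect_equal(enr$p_g_fdr, bh_oracle(enr$p_g), tolerance = 1e-12)
})

test_that("negating every effect negates tA and flips statuses", {
  w <- generate_benchmark(small_synth_cfg())
  sg <- signatures_from_table(w$tables$disease_deg)[[1L]]
  neg <- gene_signature(sg$entity_id, -sg$delta_e)
  cfg <- small_run_cfg()
  a <- run_enrichment(sg, w$genes, w$pathways, cfg, seed = 3)
  b <- run_enrichment(neg, w$genes, w$pathways, cfg, seed = 3)
  expect_equal(a$pathway_id, b$pathway_id)
  expect_equal(b$t_a, -a$t_a)
  expect_equal(a$p_nde, b$p_nde)
})

test_that("empty signatures warn and return an empty result", {
  w <- generate_benchmark(small_synth_cfg())
  sg <- gene_signature("none", stats::setNames(numeric(), character()),
                       genes = character())
  expect_warning(enr <- run_enrichment(sg, w$genes, w$pathways,
                                       small_run_cfg()),
                 "empty signature")
  expect_equal(nrow(enr), 0L)
})

test_that("simulated pathways preserve size and topology", {
  w <- generate_benchmark(small_synth_cfg())
  sim <- simulate_null_pathways(w$pathways, w$genes, seed = 10)
  sim2 <- simulate_null_pathways(w$pathways, w$genes, seed = 10)
  expect_identical(lapply(sim, `[[`, "members"),
                   lapply(sim2, `[[`, "members"))
  for (i in seq_along(w$pathways)) {
    expect_length(sim[[i]]$members, length(w$pathways[[i]]$members))
    expect_equal(nrow(sim[[i]]$edges), nrow(w$pathways[[i]]$edges))
    expect_equal(sim[[i]]$edges$beta, w$pathways[[i]]$edges$beta)
  }

  # mean DE-overlap of relabeled pathways matches |members||DE|/|U|
  universe <- paste0("u", 1:200)
  template <- list(pathway_graph("db", "t", paste0("u", 1:20)))
  de_genes <- paste0("u", 1:50)
  set.seed(11)
  overlaps <- replicate(1000, {
    s <- simulate_null_pathways(template, universe)[[1L]]
    sum(s$members %in% de_genes)
  })
  expected <- 20 * 50 / 200
  se <- stats::sd(overlaps) / sqrt(1000)
  expect_lt(abs(mean(overlaps) - expected), 3 * se + 1e-9)
})
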