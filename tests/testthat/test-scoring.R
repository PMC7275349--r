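enr_row <- function(pid, fdr, status) {
  data.frame(database = "db", pathway_id = pid, n_de_on_pathway = 3L,
              p_nde = 0.01, t_a = switch(status, activated = 2,
                                         inhibited = -2, none = 0),
              p_pert = 0.01, p_g = 0.001, p_g_fdr = fdr, status = status,
              stringsAsFactors = FALSE)
}

test_that("signature vectors keep only significant directed pathways", {
  rec <- rbind(enr_row("P1", 0.01, "activated"),
               enr_row("P2", 0.20, "inhibited"),
               enr_row("P3", 0.01, "none"),
               enr_row("P4", 0.04, "inhibited"))
  v <- build_signature_vector(rec, q_threshold = 0.05)
  expect_equal(unclass(v)[order(names(v))],
               c("db|P1" = 1, "db|P4" = -1))
  # boundary is strict: fdr exactly at the threshold is excluded
  v2 <- build_signature_vector(rbind(enr_row("P9", 0.05, "activated")),
                               q_threshold = 0.05)
  expect_length(v2, 0L)
})

test_that("correlation score has its closed forms and undefined cases", {
  v <- sig_vec(c("a|P1" = 1, "a|P2" = -1, "a|P3" = 1))
  expect_equal(correlation_score(v, v), 1)
  neg <- sig_vec(-unclass(v)); names(neg) <- names(v)
  expect_equal(correlation_score(neg, v), -1)

  # constant vectors over the union index are undefined
  c1 <- sig_vec(c("a|P1" = 1, "a|P2" = 1))
  expect_true(is.na(correlation_score(c1, c1)))

  # hand-computed Pearson on union-materialized vectors
  disease <- sig_vec(c("a|P1" = 1, "a|P2" = -1, "a|P3" = 1))
  drug <- sig_vec(c("a|P1" = -1, "a|P2" = 1))
  expect_equal(correlation_score(drug, disease, "union"),
               -sqrt(3) / 2, tolerance = 1e-12)
  # disease_only policy drops the drug-only coordinates
  drug2 <- sig_vec(c("a|P1" = -1, "a|P2" = 1, "a|P9" = 1))
  expect_equal(correlation_score(drug2, disease, "disease_only"),
               -sqrt(3) / 2, tolerance = 1e-12)

  # empty index set is undefined
  expect_true(is.na(correlation_score(sig_vec(numeric()),
                                      sig_vec(numeric()))))
})

test_that("affected percentage counts shared disease pathways", {
  mk <- function(keys) sig_vec(stats::setNames(rep(1, length(keys)), keys))
  same <- mk(paste0("db|P", 1:5))
  expect_equal(affected_pct(same, same)$pct, 100)
  expect_equal(affected_pct(mk(paste0("db|Q", 1:5)), same)$pct, 0)
  r <- affected_pct(mk(paste0("db|P", 1:20)), mk(paste0("db|P", 1:27)))
  expect_equal(round(r$pct, 4), 74.0741)
  expect_equal(r$n_shared, 20L)
  expect_error(affected_pct(same, sig_vec(numeric())), "empty")
})

test_that("levenshtein dissimilarity matches the DP oracle", {
  v1 <- sig_vec(c("db|P1" = 1, "db|P2" = -1))
  v2 <- sig_vec(c("db|P1" = -1, "db|P2" = 1))
  expect_equal(levenshtein_score(v1, v1), 0L)
  expect_equal(levenshtein_score(v1, v2), 2L)

  # exhaustive enumeration over short {-1,0,+1} strings
  alphabet <- c(-1, 0, 1)
  codes <- expand.grid(rep(list(alphabet), 3))
  keys <- paste0("db|P", 1:3)
  for (i in seq_len(nrow(codes))) {
    for (j in seq_len(nrow(codes))) {
      a <- unlist(codes[i, ]); b <- unlist(codes[j, ])
      va <- sig_vec(stats::setNames(a[a != 0], keys[a != 0]))
      vb <- sig_vec(stats::setNames(b[b != 0], keys[b != 0]))
      expect_equal(levenshtein_score(va, vb, ordering = keys),
                   lev_oracle(a, b))
    }
  }

  # random longer index sets
  set.seed(14)
  keys8 <- paste0("db|P", 1:8)
  for (i in 1:200) {
    a <- sample(alphabet, 8, replace = TRUE)
    b <- sample(alphabet, 8, replace = TRUE)
    va <- sig_vec(stats::setNames(a[a != 0], keys8[a != 0]))
    vb <- sig_vec(stats::setNames(b[b != 0], keys8[b != 0]))
    d <- levenshtein_score(va, vb, ordering = keys8)
    expect_equal(d, lev_oracle(a, b))
    expect_lte(d, 8L)
  }
})

test_that("pair combination is sign-of-sum with conflict cancellation", {
  a <- sig_vec(c("db|P1" = 1, "db|P2" = 1))
  b <- sig_vec(c("db|P1" = 1, "db|P2" = -1, "db|P3" = -1))
  ab <- combine_pair(a, b)
  expect_equal(unclass(ab)[order(names(ab))],
               c("db|P1" = 1, "db|P3" = -1))
  ba <- combine_pair(b, a)
  expect_equal(unclass(ab)[order(names(ab))],
               unclass(ba)[order(names(ba))])
  aa <- combine_pair(a, a)
  expect_equal(unclass(aa)[order(names(aa))],
               unclass(a)[order(names(a))])
})

test_that("score_pairs enumerates unordered pairs without self-pairs", {
  dis <- list(D1 = sig_vec(c("db|P1" = 1, "db|P2" = -1), "D1"))
  drugs <- list(
    a = sig_vec(c("db|P1" = -1, "db|P2" = 1), "a"),
    b = sig_vec(c("db|P1" = 1), "b"),
    c = sig_vec(c("db|P2" = -1), "c"),
    d = sig_vec(c("db|P1" = -1), "d"))
  ps <- score_pairs(drugs, dis, run_config())
  expect_equal(nrow(ps), choose(4, 2))
  expect_false(any(vapply(strsplit(ps$drug_key, " \\+ "), function(x)
    x[1] == x[2], NA)))
  # a pair covering at least the pathways of each member when signs agree
  single <- score_all(drugs, dis, run_config())
  cd <- ps$affected_pct[ps$drug_key == "c + d"]
  expect_gte(cd, single$affected_pct[single$drug_key == "c"])
  expect_gte(cd, single$affected_pct[single$drug_key == "d"])
})

test_that("score_all respects drug disease-context restriction", {
  dis <- list(D1 = sig_vec(c("db|P1" = 1, "db|P2" = -1), "D1"),
              D2 = sig_vec(c("db|P1" = -1, "db|P3" = 1), "D2"))
  free <- sig_vec(c("db|P1" = -1, "db|P2" = 1), "free")
  bound <- sig_vec(c("db|P1" = 1), "bound")
  attr(bound, "disease") <- "D2"
  sc <- score_all(list(free = free, bound = bound), dis, run_config())
  expect_equal(nrow(sc), 3L)
  expect_false(any(sc$drug_key == "bound" & sc$disease == "D1"))
})

test_that("prioritize applies documented boundary semantics and ordering", {
  rec <- data.frame(
    drug_key = c("crizo", "sepan", "deepcov", "edgecorr", "edgecov", "na"),
    disease = "mel",
    correlation = c(-0.64, -0.21, -0.90, -0.40, -0.64, NA),
    affected_pct = c(74.07, 74.07, 40, 74.07, 50, 80),
    levenshtein = 1L, n_disease_pathways = 27L, n_shared = 20L,
    stringsAsFactors = FALSE)
  kept <- prioritize(rec, corr_max = -0.4, affected_min_pct = 50)
  # corr exactly at the threshold is kept; coverage exactly at it is not
  expect_setequal(kept$drug_key, c("crizo", "edgecorr"))
  expect_equal(kept$drug_key, c("crizo", "edgecorr")) # ascending corr
  expect_equal(kept$rank, 1:2)

  # mimic mode keeps strong positive correlations
  rec2 <- rec
  rec2$correlation <- -rec2$correlation
  kept2 <- prioritize(rec2, corr_max = -0.4, affected_min_pct = 50,
                      mode = "mimic")
  expect_setequal(kept2$drug_key, c("crizo", "edgecorr"))
  expect_equal(kept2$correlation, c(0.64, 0.40))

  # deterministic tie-break on the drug key
  rec3 <- rec[c(1, 1), ]
  rec3$drug_key <- c("zeta", "alpha")
  expect_equal(prioritize(rec3)$drug_key, c("alpha", "zeta"))
})
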