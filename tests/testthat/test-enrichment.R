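universe_n <- function(n) sprintf("u%03d", seq_len(n))

test_that("hypergeom_enrichment reproduces the exact worked examples", {
  u <- universe_n(10)
  res <- hypergeom_enrichment(u[1:5], u[c(1:4)], u)
  expect_equal(res$expected, 2.0)
  expect_equal(res$observed, 4L)
  expect_equal(res$ratio, 2.0)
  expect_equal(res$p_value, 6 / 252, tolerance = 1e-12)

  # observed = 0 gives p = 1 (tail includes everything)
  res0 <- hypergeom_enrichment(u[5:6], u[1:4], u[c(1:4, 5:10)])
  expect_equal(res0$observed, 0L)
  expect_equal(res0$p_value, 1.0)

  u100 <- universe_n(100)
  res2 <- hypergeom_enrichment(u100[c(1:5, 21:35)], u100[1:10], u100)
  expect_equal(res2$expected, 2.0)
  expect_equal(res2$ratio, 2.5)
  expect_equal(res2$p_value, oracle_hyper_tail(5, 100, 10, 20),
               tolerance = 1e-12)

  expect_error(hypergeom_enrichment(c(u, "alien"), u[1:2], u), "subset")
  none <- hypergeom_enrichment(u[1:3], "elsewhere", u)
  expect_false(none$testable)
  expect_true(is.na(none$p_value))
})

test_that("the hypergeometric tail equals exhaustive enumeration of query draws", {
  set.seed(53)
  for (i in 1:40) {
    N <- sample(4:12, 1)
    K <- sample(1:(N - 1), 1)
    n <- sample(1:(N - 1), 1)
    obs <- sample(max(0, n + K - N):min(n, K), 1)
    expect_equal(oracle_hyper_tail(obs, N, K, n),
                 oracle_hyper_enum(obs, N, K, n), tolerance = 1e-12)
    u <- universe_n(N)
    q <- u[c(seq_len(obs), if (n > obs) K + seq_len(n - obs))]
    res <- hypergeom_enrichment(q, u[seq_len(K)], u)
    expect_equal(res$p_value, oracle_hyper_tail(res$observed, N, K, n),
                 tolerance = 1e-12)
  }
})

test_that("the enrichment ratio centers at 1 under uniform random queries", {
  set.seed(59)
  u <- universe_n(200)
  ref <- u[1:40]
  ratios <- replicate(1000, {
    hypergeom_enrichment(sample(u, 50), ref, u)$ratio
  })
  se <- sd(ratios) / sqrt(1000)
  expect_lt(abs(mean(ratios) - 1), 3 * se)
})

test_that("enrich_collection adjusts across testable sets only", {
  u <- universe_n(50)
  coll <- gene_set_collection(list(one = u[1:10]), source_label = "t")
  res1 <- enrich_collection(u[1:10], coll, u)
  expect_equal(res1$adj_p, res1$p_value)   # m = 1

  coll2 <- gene_set_collection(list(hit = u[1:10], nothere = c("z1", "z2")),
                               source_label = "t")
  res2 <- enrich_collection(u[1:10], coll2, u)
  expect_false(res2$testable[res2$set_name == "nothere"])
  # untestable sets are excluded from BH's m
  expect_equal(res2$adj_p[res2$set_name == "hit"],
               res2$p_value[res2$set_name == "hit"])
})

test_that("adding a p = 1 set never decreases another set's adjusted p", {
  set.seed(61)
  u <- universe_n(100)
  base_sets <- list(s1 = sample(u, 15), s2 = sample(u, 20),
                    s3 = sample(u, 10))
  q <- sample(u, 25)
  res_base <- enrich_collection(q, gene_set_collection(base_sets,
                                                       source_label = "b"), u)
  # a set disjoint from the query has p = 1
  disjoint <- setdiff(u, q)[1:10]
  res_more <- enrich_collection(
    q, gene_set_collection(c(base_sets, list(null_set = disjoint)),
                           source_label = "b"), u)
  for (nm in names(base_sets)) {
    expect_gte(res_more$adj_p[res_more$set_name == nm],
               res_base$adj_p[res_base$set_name == nm])
  }
})

test_that("planted reference sets are recovered and decoys are not", {
  hits <- decoys <- logical(60)
  for (s in 1:60) {
    pair <- simulate_pair(study_config(s))
    tab <- pair$table_a
    sig <- extract_signature(tab)
    res <- enrich_collection(sig$up, pair$reference_sets, tab$gene)
    hits[s] <- res$significant[res$set_name == "program1"] &&
      res$ratio[res$set_name == "program1"] > 1
    decoys[s] <- res$significant[res$set_name == "decoy_program1"]
  }
  expect_gte(mean(hits), 0.9)
  expect_lte(mean(decoys), 0.1)
})

test_that("tf_enrichment scores directions and respects the swap symmetry", {
  u <- universe_n(100)
  up <- u[1:10]
  down <- u[11:30]
  targets <- gene_set_collection(
    list(TFup = up, TFnone = u[91:100], TFdown = u[11:20]),
    source_label = "tf")
  res <- tf_enrichment(up, down, targets, u)
  expect_gt(res$display_score[res$tf_name == "TFup"], 0)
  expect_lt(res$display_score[res$tf_name == "TFdown"], 0)

  # disjoint targets: both sides p = 1, score 0
  none <- tf_enrichment(u[1:5], u[6:10],
                        gene_set_collection(list(tf = u[50:60]),
                                            source_label = "t"), u)
  expect_equal(none$p_up, 1)
  expect_equal(none$p_down, 1)
  expect_equal(none$display_score, 0)

  swapped <- tf_enrichment(down, up, targets, u)
  expect_equal(swapped$display_score, -res$display_score)

  # worked example: up of 20 containing 5 of 10 targets in a universe of 100
  res3 <- tf_enrichment(u[c(1:5, 21:35)], u[61:70],
                        gene_set_collection(list(tf = u[1:10]),
                                            source_label = "t"), u)
  expect_equal(res3$expected_up, 2.0)
  expect_equal(res3$ratio_up, 2.5)
  expect_equal(res3$p_up, oracle_hyper_tail(5, 100, 10, 20),
               tolerance = 1e-12)

  expect_error(tf_enrichment(u[1:3], u[3:5], targets, u), "disjoint")
})

test_that("project_cell_states summarizes markers and tests their shift exactly", {
  tab <- de_table(c("g1", "g2", "g3", "g4"), c(2, 4, 0, 0),
                  rep(0.5, 4), rep(0.5, 4), label = "t",
                  species = "synthetic")
  markers <- gene_set_collection(list(S1 = c("g1", "g2")),
                                 source_label = "sc")
  res <- project_cell_states(tab, markers, min_members = 2,
                             alternative = "top_enriched")
  expect_equal(res$median_fc, 3.0)
  expect_equal(res$p_value, 1 / 6, tolerance = 1e-12)

  # marker set absent from the table is untestable
  res2 <- project_cell_states(tab, gene_set_collection(
    list(S2 = c("zz1", "zz2", "zz3")), source_label = "sc"))
  expect_false(res2$testable)
  expect_true(is.na(res2$median_fc))
})

test_that("random marker sets center on the global median under the null", {
  set.seed(67)
  fc <- rnorm(500)
  tab <- de_table(sprintf("g%03d", 1:500), fc, runif(500), runif(500),
                  label = "null", species = "synthetic")
  meds <- replicate(100, {
    m <- gene_set_collection(list(s = sample(tab$gene, 20)),
                             source_label = "x")
    project_cell_states(tab, m)$median_fc
  })
  se <- sd(meds) / sqrt(100)
  expect_lt(abs(mean(meds) - median(fc)), 3 * se)
})
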