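ranked_toy <- function(fc) rank_by_fc(toy_table(fc), "descending")

test_that("spearman_rho matches the Pearson-of-ranks oracle, with ties", {
  expect_equal(spearman_rho(data.frame(fc_a = c(1, 2, 3),
                                       fc_b = c(3, 1, 2))), -0.5)
  mono <- data.frame(fc_a = c(-2, 0, 1, 5), fc_b = c(0.1, 0.2, 0.5, 9))
  expect_equal(spearman_rho(mono), 1)
  rev <- data.frame(fc_a = 1:5, fc_b = 5:1)
  expect_equal(spearman_rho(rev), -1)

  set.seed(3)
  for (i in 1:25) {
    n <- sample(3:40, 1)
    a <- sample(round(rnorm(n), 1), n, replace = TRUE)  # provoke ties
    b <- sample(round(rnorm(n), 1), n, replace = TRUE)
    if (sd(a) == 0 || sd(b) == 0) next
    expect_equal(spearman_rho(data.frame(fc_a = a, fc_b = b)),
                 oracle_spearman(a, b), tolerance = 1e-12)
  }
  expect_warning(res <- spearman_rho(data.frame(fc_a = c(1, 1, 1),
                                                fc_b = c(1, 2, 3))),
                 "undefined")
  expect_true(is.na(res))
  expect_error(spearman_rho(data.frame(fc_a = 1:2, fc_b = 2:1)), "3 pairs")
})

test_that("rank_comparisons orders by rs with deterministic tie-breaks", {
  res <- rank_comparisons(data.frame(
    comparison_id = c("P1", "A1", "P2"), rs = c(0.5, -0.1, 0.3)))
  expect_equal(res$comparison_id, c("P1", "P2", "A1"))
  expect_equal(res$rank, 1:3)

  tie <- rank_comparisons(data.frame(comparison_id = c("B", "A"),
                                     rs = c(0.2, 0.2)))
  expect_equal(tie$comparison_id, c("A", "B"))
  expect_error(rank_comparisons(data.frame(comparison_id = c("X", "X"),
                                           rs = c(1, 0))), "duplicate")
})

test_that("cumulative_overlap reproduces the hand-computed toy areas", {
  r <- ranked_toy(c(g1 = 4, g2 = 3, g3 = 2, g4 = 1))
  top <- cumulative_overlap(r, c("g1", "g2"))
  expect_equal(top$curve$y, c(0.5, 1, 1, 1))
  expect_equal(top$area, 0.25)
  expect_equal(cumulative_overlap(r, c("g3", "g4"))$area, -0.25)
  expect_equal(cumulative_overlap(r, c("g1", "g3"))$area, 0.125)
  # dropped query genes are counted, curve properties hold
  withdrop <- cumulative_overlap(r, c("g1", "g3", "notthere"))
  expect_equal(withdrop$n_query_dropped, 1L)
  expect_equal(withdrop$k_query, 2L)
  expect_error(cumulative_overlap(r, "absent"), "no query gene")
})

test_that("overlap-curve invariants hold on random instances", {
  set.seed(31)
  for (i in 1:50) {
    n <- sample(5:60, 1)
    fc <- setNames(rnorm(n), sprintf("g%03d", 1:n))
    q <- sample(names(fc), sample(1:(n - 1), 1))
    cv <- cumulative_overlap(ranked_toy(fc), q)
    expect_true(all(diff(cv$curve$y) >= 0))
    expect_equal(cv$curve$y[n], 1)
    steps <- diff(c(0, cv$curve$y)) * cv$k_query
    expect_true(all(abs(steps) < 1e-9 | abs(steps - 1) < 1e-9))
    expect_gt(cv$area, -0.5)
    expect_lt(cv$area, 0.5)
    expect_equal(cv$area,
                 oracle_area(rank_by_fc(toy_table(fc), "descending")$gene, q),
                 tolerance = 1e-12)
  }
})

test_that("reversing the reference ranking exactly negates the area", {
  set.seed(37)
  for (i in 1:50) {
    n <- sample(4:50, 1)
    fc <- setNames(rnorm(n), sprintf("g%03d", 1:n))
    tab <- toy_table(fc)
    q <- sample(names(fc), sample(1:(n - 1), 1))
    a_desc <- cumulative_overlap(rank_by_fc(tab, "descending"), q)$area
    a_asc <- cumulative_overlap(rank_by_fc(tab, "ascending"), q)$area
    expect_equal(a_desc, -a_asc, tolerance = 1e-12)
  }
})

test_that("rank_sum_test exact path equals the toy enumeration and full enumeration", {
  r <- ranked_toy(c(g1 = 4, g2 = 3, g3 = 2, g4 = 1))
  expect_equal(rank_sum_test(r, c("g1", "g2"), "top_enriched"), 1 / 6)
  expect_equal(rank_sum_test(r, c("g1", "g2"), "two_sided"), 1 / 3)
  expect_error(rank_sum_test(r, c("g1", "g2", "g3", "g4")), "degenerate")

  set.seed(41)
  for (i in 1:30) {
    n <- sample(4:12, 1)
    fc <- setNames(rnorm(n), sprintf("g%02d", 1:n))
    rk <- ranked_toy(fc)
    k <- sample(1:(n - 1), 1)
    q <- sample(names(fc), k)
    pos <- which(rk$gene %in% q)
    enum <- oracle_ranksum_enum(pos, n)
    expect_equal(rank_sum_test(rk, q, "top_enriched"), enum$p_low,
                 tolerance = 1e-12)
    expect_equal(rank_sum_test(rk, q, "bottom_enriched"), enum$p_high,
                 tolerance = 1e-12)
    expect_equal(rank_sum_test(rk, q, "two_sided"),
                 min(1, 2 * min(enum$p_low, enum$p_high)),
                 tolerance = 1e-12)
  }
})

test_that("normal approximation tracks the exact rank-sum p for N = 20", {
  set.seed(43)
  fc <- setNames(rnorm(20), sprintf("g%02d", 1:20))
  rk <- ranked_toy(fc)
  for (i in 1:100) {
    q <- sample(names(fc), 5)
    for (alt in c("two_sided", "top_enriched", "bottom_enriched")) {
      p_exact <- rank_sum_test(rk, q, alt, exact = TRUE)
      p_approx <- rank_sum_test(rk, q, alt, exact = FALSE)
      expect_lt(abs(p_exact - p_approx), 0.01)
    }
  }
})

test_that("the area's sign agrees with the better one-sided rank-sum direction", {
  set.seed(47)
  for (i in 1:40) {
    n <- sample(6:40, 1)
    fc <- setNames(rnorm(n), sprintf("g%03d", 1:n))
    rk <- ranked_toy(fc)
    q <- sample(names(fc), sample(2:(n - 2), 1))
    cv <- cumulative_overlap(rk, q)
    p_top <- rank_sum_test(rk, q, "top_enriched")
    p_bottom <- rank_sum_test(rk, q, "bottom_enriched")
    if (cv$area > 0) expect_lte(p_top, p_bottom)
    if (cv$area < 0) expect_lte(p_bottom, p_top)
  }
})

test_that("overlap_summary computes counts and percentages", {
  s <- overlap_summary(c("a", "b", "c", "d"), c("b", "c", "e"))
  expect_equal(s$n_intersection, 2L)
  expect_equal(s$pct_of_a, 50.0)
  expect_equal(s$pct_of_b, 100 * 2 / 3)
  expect_equal(overlap_summary(c("x", "y"), c("p"))$pct_of_a, 0)
  expect_equal(overlap_summary(c("x"), c("x", "y"))$pct_of_a, 100.0)
  expect_error(overlap_summary(character(0), "a"), "non-empty")
})
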