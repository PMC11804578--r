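test_that("overlap randomization matches the exhaustive oracle", {
  universe <- c("g1", "g2", "g3")
  a <- call_table(c(g1 = "up", g2 = "down", g3 = "ns"))
  b <- call_table(c(g1 = "up", g2 = "ns", g3 = "ns"))
  r <- overlap_randomization(a, b, universe, n_permutations = 10000L,
                             seed = 3L)
  expect_identical(r$observed_overlap, 1L)
  null_counts <- exact_overlap_null(a, n_up = 1, n_dn = 0, universe)
  p_exact <- mean(null_counts >= 1)  # = 1/3
  expect_equal(p_exact, 1 / 3)
  expect_lt(abs(r$p_value - p_exact), 0.02)
  expect_lt(abs(r$expected_overlap - mean(null_counts)), 0.02)
})

test_that("overlap randomization agrees with enumeration on larger sets", {
  universe <- paste0("g", 1:7)
  a <- call_table(setNames(c("up", "up", "down", "down", "ns", "ns",
                             "up"), universe))
  b <- call_table(setNames(c("up", "down", "down", "ns", "up", "ns",
                             "ns"), universe))
  r <- overlap_randomization(a, b, universe, n_permutations = 10000L,
                             seed = 5L)
  obs <- r$observed_overlap
  null_counts <- exact_overlap_null(a, n_up = 2, n_dn = 2, universe)
  expect_lt(abs(r$p_value - mean(null_counts >= obs)), 0.02)
  expect_lt(abs(r$expected_overlap - mean(null_counts)), 0.05)
})

test_that("overlap randomization degenerate cases", {
  universe <- c("g1", "g2", "g3")
  a <- call_table(c(g1 = "up", g2 = "down", g3 = "ns"))
  b_ns <- call_table(c(g1 = "ns", g2 = "ns", g3 = "ns"))
  r <- overlap_randomization(a, b_ns, universe, 100L, seed = 1L)
  expect_identical(r$observed_overlap, 0L)
  expect_equal(r$p_value, 1)
  # A = B all significant: every permutation matches the ceiling
  full <- call_table(c(g1 = "up", g2 = "up", g3 = "up"))
  r2 <- overlap_randomization(full, full, universe, 500L, seed = 1L)
  expect_identical(r2$observed_overlap, 3L)
  expect_equal(r2$p_value, 1)
  expect_error(overlap_randomization(full, full, c("g1", "g2"), 10L),
               "universe smaller|defined on every")
})

test_that("randomization p-values are super-uniform under independence", {
  set.seed(77)
  universe <- sprintf("g%03d", 1:80)
  pvals <- replicate(120, {
    a <- call_table(setNames(sample(c("up", "down", "ns"), 80, TRUE,
                                    prob = c(0.1, 0.1, 0.8)), universe))
    b <- call_table(setNames(sample(c("up", "down", "ns"), 80, TRUE,
                                    prob = c(0.1, 0.1, 0.8)), universe))
    overlap_randomization(a, b, universe, 200L,
                          seed = sample.int(1e6, 1))$p_value
  })
  for (al in c(0.05, 0.1, 0.25)) {
    se <- sqrt(al * (1 - al) / 120)
    expect_lte(mean(pvals <= al), al + 3 * se)
  }
  expect_true(all(pvals >= 1 / 201))
})

test_that("proportion chi-square matches the closed formula", {
  r <- proportion_chisq(30, 100, 0.3)
  expect_equal(r$chi2, 0)
  expect_equal(r$p_value, 1)
  r2 <- proportion_chisq(50, 100, 0.25)
  expect_equal(round(r2$chi2, 2), 33.33)
  expect_equal(r2$chi2, (50 - 100 * 0.25)^2 / (100 * 0.25 * 0.75))
  # continuity correction shrinks the statistic
  r3 <- proportion_chisq(50, 100, 0.25, continuity = TRUE)
  expect_lt(r3$chi2, r2$chi2)
  # monotone in |x/n - p0|
  stats <- vapply(c(30, 40, 50, 60), function(x)
    proportion_chisq(x, 100, 0.3)$chi2, 0)
  expect_true(all(diff(stats) > 0))
  expect_error(proportion_chisq(5, 10, 0), "strictly between")
})

test_that("chance_proportion approaches the product of marginals", {
  # rule requiring two independent up-calls; each contrast has 10% up
  universe <- sprintf("g%03d", 1:300)
  set.seed(9)
  up1 <- sample(universe, 30); up2 <- sample(universe, 30)
  P <- list("salt.Coast-W" = setNames(rep("up", 30), up1),
            "salt.Coast-E" = setNames(rep("up", 30), up2))
  cat <- make_catalog(universe, P = P)
  rule_two_up <- function(catalog) {
    a <- setNames(catalog$P[["salt.Coast-W"]]$call,
                  catalog$P[["salt.Coast-W"]]$gene_id)
    b <- setNames(catalog$P[["salt.Coast-E"]]$call,
                  catalog$P[["salt.Coast-E"]]$gene_id)
    catalog$universe[a[catalog$universe] == "up" &
                       b[catalog$universe] == "up"]
  }
  est <- chance_proportion(cat, rule_two_up, n_permutations = 400L,
                           seed = 13L)
  expect_lt(abs(est$p0 - 0.01), 0.002)
  # impossible rule -> p0 = 0
  est0 <- chance_proportion(cat, function(catalog) character(0),
                            n_permutations = 20L, seed = 1L)
  expect_identical(est0$p0, 0)
  # Monte-Carlo scaling: 4x permutations roughly halves the SE
  e1 <- chance_proportion(cat, rule_two_up, n_permutations = 100L,
                          seed = 2L)
  e2 <- chance_proportion(cat, rule_two_up, n_permutations = 400L,
                          seed = 2L)
  expect_lt(abs(e2$se / e1$se - 0.5), 0.3)
})

test_that("PST closed forms hold", {
  # constructed data with equal variance components -> PST = 1/3
  pop <- c("a", "a", "b", "b")
  x <- c(-1, 1, -1 + 2, 1 + 2)   # within var = 2, between var = 2
  p1 <- pst_statistic(x, pop)
  expect_equal(p1$sigma2_between, p1$sigma2_within)
  expect_equal(p1$pst, 1 / 3)
  # identical population means -> 0
  p2 <- pst_statistic(c(1, 3, 1, 3), pop)
  expect_equal(p2$pst, 0)
  # zero within-population variance with distinct means -> 1
  p3 <- pst_statistic(c(5, 5, 9, 9), pop)
  expect_equal(p3$pst, 1)
  # both components zero -> undefined, flagged
  p4 <- pst_statistic(c(2, 2, 2, 2), pop)
  expect_false(p4$defined)
  expect_true(is.na(p4$pst))
  # invariance: shift and scale
  y <- c(0.3, 1.2, 4.5, 3.3, 2.2, 5.1)
  pp <- rep(c("a", "b"), each = 3)
  base <- pst_statistic(y, pp)$pst
  expect_equal(pst_statistic(y + 100, pp)$pst, base)
  expect_equal(pst_statistic(y * 7, pp)$pst, base)
  # c/h2 enters as the stated scalar
  p5 <- pst_statistic(x, pop, c_over_h2 = 2)
  expect_equal(p5$pst, 2 / (2 + 2))
})

test_that("PST bootstrap intervals behave", {
  set.seed(15)
  v <- c(rnorm(200, 0, 0.05), rnorm(200, 3, 0.05))
  pop <- rep(c("a", "b"), each = 200)
  b <- pst_bootstrap(v, pop, reps = 200L, seed = 8L)
  expect_lt(b$ci_high - b$ci_low, 0.01)  # consistency: CI collapses
  expect_gte(b$pst, b$ci_low)
  expect_lte(b$pst, b$ci_high)
  b2 <- pst_bootstrap(v, pop, reps = 200L, seed = 8L)
  expect_identical(b[c("ci_low", "ci_high")], b2[c("ci_low", "ci_high")])
  expect_error(pst_bootstrap(c(1, 2, 3), c("a", "b", "b"), reps = 100L),
               "more than one sample")
  expect_error(pst_bootstrap(v, pop, reps = 50L), ">= 100")
})

test_that("exceedance fraction calibrates against its own null", {
  f <- simulate_fst_null(10000L, 2, 8, seed = 31L)
  # PST drawn from the FST distribution itself -> fraction ~ alpha
  ex <- fraction_exceeding(f$values, f, alpha = 0.05)
  expect_lt(abs(ex$fraction - 0.05), 0.01)
  # all PST = 1 above an FST distribution below 1 -> fraction 1
  ex1 <- fraction_exceeding(rep(1, 50), f, alpha = 0.05)
  expect_equal(ex1$fraction, 1)
  # empty gene set -> flagged undefined
  ex0 <- fraction_exceeding(numeric(0), f)
  expect_false(ex0$defined)
  expect_true(is.na(ex0$fraction))
})
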