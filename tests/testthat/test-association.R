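test_that("spearman correlation hits the monotone anchors and the rank oracle", {
  x <- 1:12
  expect_equal(spearman_cor(x, x * 3 + 2)$rho, 1)
  expect_equal(spearman_cor(x, -x^3)$rho, -1)

  # 12 paired values with ties: rho equals Pearson on mid-ranks, done by hand
  set.seed(61)
  xv <- c(1, 1, 2, 3, 3, 3, 4, 5, 6, 6, 7, 8)
  yv <- c(2, 1, 2, 5, 4, 4, 6, 6, 9, 8, 8, 12)
  got <- spearman_cor(xv, yv)
  expect_equal(got$rho, cor(rank(xv), rank(yv)), tolerance = 1e-12)
  expect_equal(got$rho, cor.test(xv, yv, method = "spearman", exact = FALSE)$estimate[[1]],
               tolerance = 1e-12)
  # n = 12 uses the t approximation; compare with the closed form
  tstat <- got$rho * sqrt(10 / (1 - got$rho^2))
  expect_equal(got$p_value, 2 * pt(-abs(tstat), df = 10), tolerance = 1e-12)

  expect_error(spearman_cor(rep(1, 8), 1:8), "constant")
  expect_error(spearman_cor(1:3, 3:1), "at least 4")
})

test_that("spearman is invariant to strictly monotone transforms", {
  set.seed(62)
  x <- rnorm(15); y <- rnorm(15)
  base <- spearman_cor(x, y)
  expect_equal(spearman_cor(exp(x), y)$rho, base$rho)
  expect_equal(spearman_cor(x, 5 * y + 1)$p_value, base$p_value)
})

test_that("small-sample spearman p is the permutation tail computed independently", {
  # n = 5: enumerate the 120 permutations with a different generator (expand.grid)
  x <- c(3, 1, 4, 1.5, 9)
  y <- c(2, 7, 1, 8, 2.5)
  got <- spearman_cor(x, y)
  grid <- expand.grid(a = 1:5, b = 1:5, c = 1:5, d = 1:5, e = 1:5)
  perms <- grid[apply(grid, 1, function(r) length(unique(r)) == 5), ]
  rx <- rank(x); ry <- rank(y)
  null <- apply(perms, 1, function(idx) cor(rx, ry[idx]))
  expect_equal(got$p_value, mean(abs(null) >= abs(got$rho) - 1e-12), tolerance = 1e-12)
  expect_equal(got$method, "exact permutation")
})

test_that("resampling null is seeded, reproducible, and obeys its counting definition", {
  set.seed(63)
  vals <- matrix(rpois(300 * 20, 5), nrow = 300,
                 dimnames = list(sprintf("g%03d", 1:300), sprintf("s%02d", 1:20)))
  m <- log_normalize(count_matrix(vals, "raw_counts"), "sc_library_size")
  sig <- gene_signature("s", rownames(vals)[1:10], "human")
  ext <- rnorm(20)

  r1 <- resampling_null(m, sig, ext, n_resamples = 100, seed = 7)
  r2 <- resampling_null(m, sig, ext, n_resamples = 100, seed = 7)
  expect_identical(r1$null_rhos, r2$null_rhos)
  r3 <- resampling_null(m, sig, ext, n_resamples = 100, seed = 8)
  expect_false(identical(r1$null_rhos, r3$null_rhos))

  # counting definition: p = (1 + #{null >= observed}) / (1 + n)
  expect_equal(r1$empirical_p,
               (1 + sum(r1$null_rhos >= r1$observed_rho)) / 101, tolerance = 1e-12)
  expect_gte(r1$empirical_p, 1 / 101)
  expect_length(r1$null_rhos, 100)

  # two-sided option compares |rho|
  rt <- resampling_null(m, sig, ext, n_resamples = 100, seed = 7,
                        alternative = "two_sided")
  expect_equal(rt$empirical_p,
               (1 + sum(abs(rt$null_rhos) >= abs(rt$observed_rho))) / 101,
               tolerance = 1e-12)

  expect_error(resampling_null(m, sig, ext, sig_size = 400, n_resamples = 10),
               "universe")
})

test_that("a signature beating every null draw reports p = 1/(n+1)", {
  # plant a signature whose score tracks the external measure exactly
  set.seed(64)
  n_s <- 24
  vals <- matrix(rpois(200 * n_s, 3), nrow = 200,
                 dimnames = list(sprintf("g%03d", 1:200), sprintf("s%02d", 1:n_s)))
  strength <- seq(1, 60, length.out = n_s)
  for (g in 1:10) vals[g, ] <- rpois(n_s, strength)
  m <- log_normalize(count_matrix(vals, "raw_counts"), "sc_library_size")
  sig <- gene_signature("planted", rownames(vals)[1:10], "human")
  r <- resampling_null(m, sig, strength, n_resamples = 1000, seed = 9)
  expect_equal(sum(r$null_rhos >= r$observed_rho), 0)
  expect_equal(r$empirical_p, 1 / 1001, tolerance = 1e-12)
  expect_lt(r$empirical_p, 0.001)
})

test_that("two-group comparisons match exact rank-sum enumeration", {
  # identical groups: no evidence
  same <- group_compare(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3),
                        design = "two_group_unpaired")
  expect_equal(same$p_value, 1)

  # (1,2,3) vs (11,12,13): enumerate all 20 assignments of 3-of-6 labels
  got <- group_compare(c(1, 2, 3, 11, 12, 13), rep(c("a", "b"), each = 3),
                       design = "two_group_unpaired")
  vals <- c(1, 2, 3, 11, 12, 13)
  obs_sum <- sum(rank(vals)[1:3])
  combos <- combn(6, 3)
  null_sums <- apply(combos, 2, function(idx) sum(rank(vals)[idx]))
  exact_p <- mean(abs(null_sums - 10.5) >= abs(obs_sum - 10.5))
  expect_equal(got$p_value, exact_p, tolerance = 1e-12)
  expect_equal(got$stars, "ns")  # 0.1 at n=3+3
})

test_that("paired design demands complete pairs and uses the signed-rank test", {
  scores <- c(10, 12, 14, 11, 15, 18)
  groups <- rep(c("pre", "post"), each = 3)
  pairs <- c("p1", "p2", "p3", "p1", "p2", "p3")
  got <- group_compare(scores, groups, design = "two_group_paired", pair_ids = pairs)
  ref <- suppressWarnings(wilcox.test(c(10, 12, 14), c(11, 15, 18), paired = TRUE))
  expect_equal(got$p_value, ref$p.value)

  bad_pairs <- c("p1", "p2", "p3", "p1", "p2", "p4")
  expect_error(group_compare(scores, groups, design = "two_group_paired",
                             pair_ids = bad_pairs), "p3|p4")
  expect_error(group_compare(scores, groups, design = "two_group_paired"), "pair_ids")
})

test_that("multi-group dispatch: Tukey p-values match multcomp reference", {
  set.seed(65)
  g <- rep(c("a", "b", "c"), each = 10)
  y <- rnorm(30) + rep(c(0, 1, 2.5), each = 10)
  got <- group_compare(y, g, design = "multi_group", normality_ok = TRUE)
  expect_equal(nrow(got), 3)
  expect_true(all(got$test == "ANOVA + Tukey HSD"))

  # direct studentized-range oracle: p = P(q(3, df) >= |diff| / (se/sqrt(2)))
  mse <- sum(resid(aov(y ~ factor(g)))^2) / 27
  means <- tapply(y, g, mean)
  ref_p <- vapply(list(c("b", "a"), c("c", "a"), c("c", "b")), function(pr) {
    q <- abs(means[[pr[1]]] - means[[pr[2]]]) / sqrt(mse * (1 / 10 + 1 / 10) / 2)
    ptukey(q, nmeans = 3, df = 27, lower.tail = FALSE)
  }, numeric(1))
  expect_equal(got$p_value, ref_p, tolerance = 1e-8)

  # independent library route agrees to its own (simulation-based) accuracy
  skip_if_not_installed("multcomp")
  fit <- aov(y ~ gf, data = data.frame(y = y, gf = factor(g)))
  ref <- summary(multcomp::glht(fit, linfct = multcomp::mcp(gf = "Tukey")),
                 test = multcomp::adjusted("single-step"))
  expect_lt(max(abs(got$p_value - as.numeric(ref$test$pvalues))), 1e-3)
})

test_that("non-normal groups fall through to Kruskal-Wallis with Dunn post-hoc", {
  set.seed(66)
  g <- rep(c("a", "b", "c"), each = 12)
  y <- c(rlnorm(12, 0, 1.5), rlnorm(12, 1, 1.5), rlnorm(12, 2, 1.5))
  got <- group_compare(y, g, design = "multi_group", normality_ok = FALSE)
  expect_true(all(got$test == "Kruskal-Wallis + Dunn"))
  expect_equal(nrow(got), 3)

  # hand-check one Dunn z statistic (no ties in lognormal draws)
  r <- rank(y); N <- 36
  mr <- tapply(r, g, mean)
  se <- sqrt((N * (N + 1) / 12) * (1 / 12 + 1 / 12))
  z_ab <- (mr[["a"]] - mr[["b"]]) / se
  row_ab <- got[got$comparison %in% c("a vs b", "b vs a"), ]
  expect_equal(abs(row_ab$statistic), abs(z_ab), tolerance = 1e-10)
  expect_equal(row_ab$p_value, 2 * pnorm(-abs(z_ab)), tolerance = 1e-10)

  # automatic gate: heavily skewed data chooses the rank path
  auto <- group_compare(y, g, design = "multi_group")
  expect_true(all(auto$test == "Kruskal-Wallis + Dunn"))
})

test_that("significance stars follow the conventional cutpoints", {
  got <- group_compare(c(1, 2, 3, 11, 12, 13), rep(c("a", "b"), each = 3),
                       design = "two_group_unpaired")
  expect_true(got$stars %in% c("ns", "*", "**", "***", "****"))
  expect_equal(as.character(myosig:::p_stars(c(0.03, 0.004, 4e-4, 5e-5, 0.2))),
               c("*", "**", "***", "****", "ns"))
})
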