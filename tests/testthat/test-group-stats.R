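test_that("normality screen routes samples as expected", {
  set.seed(30)
  g <- normality_check(rnorm(80))
  expect_true(g$normal)
  skew_fail <- mean(replicate(40, !normality_check(rexp(50))$normal))
  expect_gt(skew_fail, 0.9)
  const <- normality_check(rep(3, 10))
  expect_true(const$degenerate)
  expect_false(const$normal)
  expect_true(normality_check(c(1, 2))$degenerate)
})

test_that("SNK with two groups reduces exactly to the pooled t-test", {
  set.seed(33)
  for (i in 1:10) {
    x <- rnorm(6); y <- rnorm(6, mean = runif(1, 0, 2))
    res <- one_way_anova_snk(list(a = x, b = y))
    tt <- t.test(x, y, var.equal = TRUE)
    expect_equal(res$pairwise$p_adj, tt$p.value, tolerance = 1e-6)
    expect_equal(res$pairwise$q, sqrt(2) * abs(tt$statistic),
                 ignore_attr = TRUE, tolerance = 1e-9)
  }
})

test_that("SNK flags exactly the shifted group in a 4-group design", {
  # identical groups: F = 0, nothing significant
  g0 <- list(a = c(1, 2, 3), b = c(1, 2, 3), c = c(1, 2, 3))
  r0 <- one_way_anova_snk(g0)
  expect_equal(r0$statistic, 0)
  expect_true(all(!r0$pairwise$significant))
  # one group strongly shifted: the 3 pairs involving it significant
  set.seed(34)
  ok <- replicate(30, {
    g <- list(a = rnorm(6), b = rnorm(6), c = rnorm(6), d = rnorm(6, 4))
    r <- one_way_anova_snk(g)
    with_d <- grepl("d", paste(r$pairwise$group1, r$pairwise$group2))
    all(r$pairwise$significant[with_d]) && !any(r$pairwise$significant[!with_d])
  })
  expect_gt(mean(ok), 0.8)
  # relabeling invariance
  set.seed(35)
  g <- list(a = rnorm(6), b = rnorm(6, 1), c = rnorm(6, 2))
  r1 <- one_way_anova_snk(g)
  r2 <- one_way_anova_snk(g[c("c", "a", "b")])
  key <- function(r) {
    k <- apply(r$pairwise[, c("group1", "group2")], 1,
               function(z) paste(sort(z), collapse = "-"))
    r$pairwise$p_adj[order(k)]
  }
  expect_equal(key(r1), key(r2), tolerance = 1e-12)
})

test_that("two-way ANOVA with Sidak adjustment behaves per contract", {
  set.seed(36)
  d <- expand.grid(factor1 = c("s1", "s2", "s3"),
                   factor2 = c("day", "night"), rep = 1:6)
  d$value <- rnorm(nrow(d)) + ifelse(d$factor2 == "night", 3, 0)
  r <- two_way_anova_sidak(d, within = "factor1")
  # programmed day/night difference: significant within every stratum
  expect_true(all(r$pairwise$significant))
  # Sidak relation p_adj = 1 - (1 - p)^m holds, reducing to p at m = 1
  m <- nrow(r$pairwise)
  expect_equal(r$pairwise$p_adj, 1 - (1 - r$pairwise$p)^m)
  expect_equal(1 - (1 - r$pairwise$p)^1, r$pairwise$p)
  # missing cells rejected
  bad <- d[!(d$factor1 == "s1" & d$factor2 == "day"), ]
  expect_error(two_way_anova_sidak(bad), "empty cells")
})

test_that("Kruskal-Wallis H matches the tie-corrected rank formula", {
  # identical groups: H = 0
  r0 <- kruskal_dunn(list(a = c(2, 2, 2), b = c(2, 2, 2)))
  expect_equal(r0$statistic, 0)
  # brute-force oracle on small instances (total n <= 10), with ties
  brute_h <- function(g) {
    x <- unlist(g); N <- length(x); rk <- rank(x)
    ns <- lengths(g)
    rbar <- tapply(rk, rep(seq_along(g), ns), mean)
    h <- 12 / (N * (N + 1)) * sum(ns * (rbar - (N + 1) / 2)^2)
    ties <- table(x)
    h / (1 - sum(ties^3 - ties) / (N^3 - N))
  }
  set.seed(37)
  for (i in 1:20) {
    g <- list(a = sample(1:5, 3, TRUE), b = sample(1:5, 3, TRUE),
              c = sample(1:5, 4, TRUE))
    if (sd(unlist(g)) == 0) next
    expect_equal(kruskal_dunn(g)$statistic, unname(brute_h(g)),
                 tolerance = 1e-9)
  }
  # monotone shift: ordered mean ranks, and invariance under monotone maps
  g <- list(a = c(1, 2, 3), b = c(4, 5, 6), c = c(7, 8, 9))
  r <- kruskal_dunn(g)
  expect_true(all(diff(unlist(r$mean_ranks)) > 0))
  g2 <- lapply(g, function(v) exp(v))
  r2 <- kruskal_dunn(g2)
  expect_equal(r$statistic, r2$statistic)
  expect_equal(r$pairwise$p_adj, r2$pairwise$p_adj)
})

test_that("descriptives match their sort-based definitions", {
  d <- describe_groups(list(g = c(1, 2, 3)))
  expect_equal(d$mean, 2)
  expect_equal(d$sem, sd(c(1, 2, 3)) / sqrt(3))
  expect_equal(d$median, 2)
  # symmetric sample: mean = median
  s <- c(-2, -1, 0, 1, 2)
  ds <- describe_groups(list(g = s))
  expect_equal(ds$mean, ds$median)
  # percentiles against an independent type-7 implementation
  set.seed(38)
  x <- rnorm(37)
  dx <- describe_groups(list(g = x))
  expect_equal(dx$p5, naive_quantile7(x, 0.05))
  expect_equal(dx$q1, naive_quantile7(x, 0.25))
  expect_equal(dx$q3, naive_quantile7(x, 0.75))
  expect_equal(dx$p95, naive_quantile7(x, 0.95))
  # ordering invariant
  expect_true(dx$p5 <= dx$q1 && dx$q1 <= dx$median &&
                dx$median <= dx$q3 && dx$q3 <= dx$p95)
  expect_identical(significance_stars(c(0.2, 0.04, 0.004, 0.0004)),
                   c("", "*", "**", "***"))
})
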