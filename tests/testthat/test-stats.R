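test_that("factorial_anova matches the closed-form balanced-design F", {
  # balanced 2x2, pure main effect of f1 with known cell shift
  set.seed(41)
  n <- 10
  d <- tidyr::expand_grid(f1 = c("a", "b"), f2 = c("x", "y"),
                          rep = seq_len(n))
  d$y <- rnorm(nrow(d))
  d$y[d$f1 == "b"] <- d$y[d$f1 == "b"] + 0.8
  fit <- factorial_anova(d, "y", c("f1", "f2"))
  tab <- tidy(fit)

  # closed form for a balanced two-way layout
  cell <- d |>
    dplyr::group_by(f1, f2) |>
    dplyr::summarise(m = mean(y), .groups = "drop")
  gm <- mean(d$y)
  m1 <- tapply(d$y, d$f1, mean); m2 <- tapply(d$y, d$f2, mean)
  ss1 <- 2 * n * sum((m1 - gm)^2)
  ss2 <- 2 * n * sum((m2 - gm)^2)
  ssi <- n * sum((cell$m - m1[cell$f1] - m2[cell$f2] + gm)^2)
  sse <- sum((d$y - cell$m[match(paste(d$f1, d$f2),
                                 paste(cell$f1, cell$f2))])^2)
  mse <- sse / (4 * (n - 1))
  expect_equal(tab$statistic[tab$effect == "f1"], ss1 / mse,
               tolerance = 1e-8)
  expect_equal(tab$statistic[tab$effect == "f2"], ss2 / mse,
               tolerance = 1e-8)
  expect_equal(tab$statistic[tab$effect == "f1:f2"], ssi / mse,
               tolerance = 1e-8)
  expect_equal(glance(fit)$n, nrow(d))
})

test_that("identical cell means give F near 0 and rank deficiency errors", {
  d <- tidyr::expand_grid(f1 = c("a", "b"), f2 = c("x", "y"), rep = 1:4)
  d$y <- rep(c(0.1, -0.1), length.out = nrow(d))  # same pattern per cell
  tab <- tidy(factorial_anova(d, "y", c("f1", "f2")))
  expect_true(all(tab$statistic < 1e-20))
  # aliased design (f2 constant within f1 levels)
  d2 <- data.frame(f1 = rep(c("a", "b"), each = 4),
                   f2 = rep(c("x", "y"), each = 4), y = rnorm(8))
  expect_error(factorial_anova(d2, "y", c("f1", "f2")), "aliased|levels")
})

test_that("posthoc_pairwise matches the hand-computed pooled t", {
  d <- data.frame(y = c(1, 2, 3, 4, 5, 6), g = rep(c("a", "b"), each = 3))
  out <- posthoc_pairwise(d, "y", "g")
  expect_equal(out$statistic, -3 / sqrt(2 / 3), tolerance = 1e-10)
  expect_equal(out$df, 4)
  # Bonferroni arithmetic: raw p scaled by the number of comparisons
  d7 <- tidyr::expand_grid(bin = paste0("t", 1:7), g = c("a", "b"),
                           rep = 1:4)
  set.seed(43)
  d7$y <- rnorm(nrow(d7))
  out7 <- posthoc_pairwise(d7, "y", "g", by = "bin")
  expect_equal(nrow(out7), 7)
  expect_equal(out7$p_adjusted, pmin(1, out7$p_value * 7))
  # identical groups -> t = 0, p = 1; zero-variance degenerate case flagged
  di <- data.frame(y = rep(c(1, 2), each = 3), g = rep(c("a", "b"), 3))
  di$y <- rep(c(1, 2, 3), 2)
  out_i <- posthoc_pairwise(di, "y", "g")
  expect_equal(out_i$statistic, 0)
  expect_equal(out_i$p_value, 1)
  dz <- data.frame(y = rep(5, 8), g = rep(c("a", "b"), each = 4))
  out_z <- posthoc_pairwise(dz, "y", "g")
  expect_equal(out_z$p_value, 1)
  expect_equal(out_z$flag, "degenerate_zero_variance")
})

test_that("pooled-error post-hoc uses the model residual df", {
  set.seed(44)
  d <- tidyr::expand_grid(bin = paste0("t", 1:8), g = c("a", "b"), rep = 1:4)
  d$y <- rnorm(nrow(d))
  out <- posthoc_pairwise(d, "y", "g", by = "bin", pooled_error = TRUE)
  expect_true(all(out$df == 64 - 16))   # t(48)-style df from the full model
  # direction of each t matches the cell-mean difference
  expect_equal(sign(out$statistic), sign(out$mean_1 - out$mean_2))
})

test_that("rm_ancova detects within/between effects and handles covariates", {
  set.seed(45)
  units <- paste0("u", 1:16)
  d <- tidyr::expand_grid(unit = units, w = c("zf", "can"))
  d$b <- rep(c("L", "R"), each = 2)[match(d$unit, units) %% 4 + 1]
  d$depth <- rep(runif(16, 300, 1200), each = 2)
  d$y <- rnorm(nrow(d)) - 0.001 * d$depth
  fit <- rm_ancova(d, "y", within = "w", between = "b", unit = "unit",
                   covariate = "depth")
  tab <- tidy(fit)
  expect_true(all(c("depth", "b", "w", "b:w") %in% tab$effect))
  # no mean difference between repeated categories -> its F ~ 0
  base <- rnorm(16)
  diffs <- rep(c(0.5, -0.5), 8)   # exactly mean-zero within-unit differences
  d2 <- d
  d2$y <- ifelse(d2$w == "zf", base[match(d2$unit, units)],
                 base[match(d2$unit, units)] + diffs[match(d2$unit, units)])
  tab2 <- tidy(rm_ancova(d2, "y", within = "w", between = "b",
                         unit = "unit"))
  expect_lt(tab2$statistic[tab2$effect == "w"], 1e-10)
  # constant covariate is dropped with a warning
  d$depth2 <- 5
  expect_warning(rm_ancova(d, "y", within = "w", between = "b",
                           unit = "unit", covariate = "depth2"), "constant")
  # units missing a within level are dropped with a report
  d3 <- d[!(d$unit == "u1" & d$w == "can"), ]
  expect_warning(rm_ancova(d3, "y", within = "w", between = "b",
                           unit = "unit"), "u1")
})

test_that("kruskal_wallis matches the rank-sum hand computation", {
  d <- data.frame(y = c(1, 2, 3, 4, 5, 6), g = rep(c("a", "b"), each = 3))
  out <- kruskal_wallis(d, "y", "g")
  # no ties: H = 12/(N(N+1)) * sum(R_i^2/n_i) - 3(N+1)
  expect_equal(out$statistic, 12 / 42 * (36 / 3 + 225 / 3) - 21,
               tolerance = 1e-10)
  # identical groups -> H ~ 0; all-identical values -> H = 0, p = 1
  di <- data.frame(y = rep(c(1, 2, 3), 2), g = rep(c("a", "b"), each = 3))
  expect_lt(kruskal_wallis(di, "y", "g")$statistic, 1e-10)
  dz <- data.frame(y = rep(2, 6), g = rep(c("a", "b"), each = 3))
  outz <- kruskal_wallis(dz, "y", "g")
  expect_equal(outz$statistic, 0)
  expect_equal(outz$p_value, 1)
})
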