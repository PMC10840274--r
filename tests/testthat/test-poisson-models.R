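test_that("sample scales are column sums normalized to mean one", {
  m <- expression_matrix(matrix(c(50L, 50L, 150L, 150L), 2,
                                dimnames = list(c("G1", "G2"),
                                                c("S1", "S2"))))
  expect_equal(unname(estimate_sample_scales(m)), c(0.5, 1.5))
  same <- expression_matrix(matrix(5L, 2, 2,
                                   dimnames = list(c("G1", "G2"),
                                                   c("S1", "S2"))))
  expect_equal(unname(estimate_sample_scales(same)), c(1, 1))
  zero <- expression_matrix(matrix(c(1L, 2L, 0L, 0L), 2,
                                   dimnames = list(c("G1", "G2"),
                                                   c("S1", "S2"))))
  expect_error(estimate_sample_scales(zero), "S2")
})

test_that("constant-model MLE is the closed form sum(x)/sum(g)", {
  expect_equal(fit_constant(c(2, 4), c(1, 1))$params[["b0"]], 3)
  expect_equal(fit_constant(3, 0.5)$params[["b0"]], 6)
  f0 <- fit_constant(c(0, 0, 0))
  expect_equal(f0$params[["b0"]], 0)
  expect_equal(f0$deviance, 0)
  expect_equal(f0$rank, 1L)
  set.seed(11)
  for (i in 1:25) {
    n <- sample(5:80, 1)
    g <- rlnorm(n, 0, 0.4)
    x <- rpois(n, 7 * g)
    expect_equal(fit_constant(x, g)$params[["b0"]], sum(x) / sum(g),
                 tolerance = 1e-12)
  }
})

test_that("linear model recovers its generating parameters", {
  set.seed(21)
  cn <- draw_cn(500, c(0.1, 0.15, 0.3, 0.2, 0.1, 0.1, 0.05))
  g <- rlnorm(500, 0, 0.3); g <- g / mean(g)
  x <- rpois(500, (5 + 2 * cn$total) * g)
  fit <- fit_linear(x, cn$A, cn$B, g)
  expect_true(fit$converged)
  expect_lt(abs(fit$params[["a"]] - 2) / 2, 0.1)
  expect_lt(abs(fit$params[["b0"]] - 5) / 5, 0.25)
})

test_that("a CN-invariant design collapses the linear model onto the constant one", {
  set.seed(4)
  x <- rpois(40, 6)
  fit_l <- fit_linear(x, rep(2, 40), rep(1, 40))
  fit_c <- fit_constant(x)
  expect_equal(fit_l$loglik, fit_c$loglik, tolerance = 1e-6)
  expect_equal(fit_l$rank, 1L)
  zero <- fit_linear(rep(0, 10), rep(2, 10), rep(1, 10))
  expect_equal(unname(zero$params), c(0, 0), tolerance = 1e-8)
  expect_equal(zero$deviance, 0)
})

test_that("interaction sign classifies synergy within a tolerance band", {
  f <- fake_fit("interaction", c(b0 = 1, a = 1, c = 0.5))
  expect_equal(classify_interaction(f), "synergistic")
  f$params[["c"]] <- 0
  expect_equal(classify_interaction(f), "linear")
  f$params[["c"]] <- -1e-9
  expect_equal(classify_interaction(f, tol = 1e-6), "linear")
  f$params[["c"]] <- -0.2
  expect_equal(classify_interaction(f), "antagonistic")
  expect_error(classify_interaction(fake_fit("linear", c(b0 = 1, a = 1))),
               "interaction")
})

test_that("interaction model detects a planted major/minor asymmetry", {
  set.seed(31)
  n <- 400
  A <- sample(1:4, n, TRUE)
  B <- sample(0:2, n, TRUE)
  B <- pmin(A, B)
  x <- rpois(n, 2 + 1.5 * (A + B) + 1 * A * B)
  fit <- fit_linear(x, A, B, with_interaction = TRUE)
  expect_equal(classify_interaction(fit), "synergistic")
  expect_lt(abs(fit$params[["c"]] - 1), 0.4)
})

test_that("monotonic fits always nest the constant model and respect monotonicity", {
  set.seed(5)
  for (i in 1:30) {
    n <- 120
    cn <- draw_cn(n, dispersed_probs)
    b0 <- runif(1, 1, 15)
    a <- if (i %% 2 == 0) runif(1, 0.5, 4) else 0
    x <- rpois(n, b0 + a * cn$total)
    fit <- fit_monotonic(x, cn$A, cn$B)
    expect_gte(fit$loglik, fit_constant(x)$loglik - 1e-6)
    # fitted means non-decreasing in each allele's CN over the grid
    grid <- expand.grid(A = 0:8, B = 0:8)
    grid <- grid[grid$A >= grid$B, ]
    mu <- predict_mean(fit, grid$A, grid$B, g = rep(1, nrow(grid)))
    for (j in seq_len(nrow(grid))) {
      up_a <- which(grid$A == grid$A[j] + 1 & grid$B == grid$B[j])
      if (length(up_a)) expect_gte(mu[up_a] + 1e-9, mu[j])
      up_b <- which(grid$A == grid$A[j] & grid$B == grid$B[j] + 1)
      if (length(up_b)) expect_gte(mu[up_b] + 1e-9, mu[j])
    }
  }
})

test_that("monotonic model with no CN variation reduces to the constant fit", {
  set.seed(6)
  x <- rpois(50, 8)
  fit <- fit_monotonic(x, rep(1, 50), rep(1, 50))
  expect_equal(fit$rank, 1L)
  expect_equal(fit$loglik, fit_constant(x)$loglik, tolerance = 1e-6)
  zero <- fit_monotonic(rep(0, 20), rep(2, 20), rep(1, 20))
  expect_true(all(abs(zero$params) < 1e-8))
})

test_that("monotonic model recovers a planted single step", {
  set.seed(8)
  err <- replicate(20, {
    cn <- draw_cn(400, c(0.1, 0.2, 0.3, 0.25, 0.15))
    x <- rpois(400, 1 + 3 * ((cn$A >= 2) + (cn$B >= 2)))
    fit <- fit_monotonic(x, cn$A, cn$B, k_max = 4)
    abs(fit$params[["a2"]] - 3) / 3
  })
  expect_lt(median(err), 0.15)
})

test_that("stacked model places deviations on the truly deviating group", {
  set.seed(9)
  n <- 200
  groups <- rep(c("good", "poor"), each = n / 2)
  cn <- draw_cn(n, c(0.1, 0.2, 0.3, 0.25, 0.15))
  base <- 5 + 2 * ((cn$A >= 2) + (cn$B >= 2))
  mu <- base + 2 * ((cn$A >= 2) + (cn$B >= 2)) * (groups == "poor")
  x <- rpois(n, mu)
  fit <- fit_stacked_monotonic(x, cn$A, cn$B, groups = groups, k_max = 4)
  expect_equal(fit$direction, "poor")
  expect_gte(fit$loglik, fit_monotonic(x, cn$A, cn$B, k_max = 4)$loglik - 1e-6)
  expect_error(
    fit_stacked_monotonic(x[1:5], cn$A[1:5], cn$B[1:5],
                          groups = c("a", "a", "a", "a", "b")),
    "at least 2 samples")
})

test_that("stacked deviations vanish on label-shuffled null data", {
  set.seed(10)
  n <- 200
  cn <- draw_cn(n, c(0.1, 0.2, 0.4, 0.2, 0.1))
  x <- rpois(n, 6 + 1.5 * cn$total)
  groups <- sample(rep(c("g1", "g2"), each = n / 2))
  fit <- fit_stacked_monotonic(x, cn$A, cn$B, groups = groups, k_max = 4)
  plain <- fit_monotonic(x, cn$A, cn$B, k_max = 4)
  # the extra deviations buy at most chi-square-scale likelihood
  expect_lt(2 * (fit$loglik - plain$loglik), qchisq(0.999, df = 5))
  devs <- fit$params[grepl("^d", names(fit$params))]
  expect_lt(max(devs), 1)
})

test_that("predict_mean evaluates each family's mean function", {
  expect_equal(predict_mean(fake_fit("constant", c(b0 = 3)), g = c(1, 2)),
               c(3, 6))
  mono <- fake_monotonic(b0 = 1, steps = c(a1 = 2))
  expect_equal(predict_mean(mono, A = 1, B = 1, g = 1), 5)
  expect_equal(predict_mean(fake_monotonic(0), A = 3, B = 2, g = c(1)), 0)
  expect_error(predict_mean(fake_fit("stacked_monotonic", c(b0 = 1)),
                            A = 1, B = 1), "group")
})

test_that("likelihood-ratio tests follow the Wilks construction", {
  null <- fake_fit("constant", c(b0 = 2), loglik = -100, rank = 1)
  alt <- fake_fit("monotonic", c(b0 = 2, a1 = 0), loglik = -100, rank = 3)
  res <- lrt(null, alt)
  expect_equal(res$statistic, 0)
  expect_equal(res$df, 2L)
  expect_equal(res$p, 1)
  alt$loglik <- -100 + 3.841 / 2
  alt$rank <- 2
  expect_equal(lrt(null, alt)$p, 0.05, tolerance = 1e-3)
  alt$rank <- 3
  # numerical undershoot clamps to zero with a warning
  alt$loglik <- -100 - 1e-3
  expect_warning(res <- lrt(null, alt), "clamped")
  expect_equal(res$statistic, 0)
  # zero-df comparison has p = 1 by convention
  alt$rank <- 1
  alt$loglik <- -100
  expect_equal(lrt(null, alt)$p, 1)
  alt$rank <- 0
  expect_error(lrt(null, alt), "nested")
})

test_that("rescaling all sample scales leaves deviances and LRTs unchanged", {
  set.seed(12)
  n <- 150
  cn <- draw_cn(n, dispersed_probs)
  g <- rlnorm(n, 0, 0.3); g <- g / mean(g)
  x <- rpois(n, (4 + 1.5 * cn$total) * g)
  f1c <- fit_constant(x, g)
  f1m <- fit_monotonic(x, cn$A, cn$B, g)
  f2c <- fit_constant(x, g * 7)
  f2m <- fit_monotonic(x, cn$A, cn$B, g * 7)
  expect_equal(f1c$deviance, f2c$deviance, tolerance = 1e-6)
  expect_equal(f1m$deviance, f2m$deviance, tolerance = 1e-4)
  expect_equal(lrt(f1c, f1m)$statistic, lrt(f2c, f2m)$statistic,
               tolerance = 1e-4)
})
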