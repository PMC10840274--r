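test_that("residual deviance matches hand evaluations", {
  expect_equal(residual_deviance(c(3, 5), c(3, 5)), 0)
  expect_equal(residual_deviance(2, 1), 2 * (2 * log(2) - 1))
  expect_equal(residual_deviance(0, 1), 2)
  expect_error(residual_deviance(1, -1), "negative")
  expect_error(residual_deviance(1, 0), "zero fitted mean")
})

test_that("explained variance is the pooled deviance ratio complement", {
  mk <- function(dev, family = "monotonic") {
    fake_fit(family, c(b0 = 1), deviance = dev)
  }
  expect_equal(explained_variance(mk(0), mk(8, "constant")), 1)
  expect_equal(explained_variance(mk(8), mk(8, "constant")), 0)
  expect_equal(explained_variance(mk(2), mk(8, "constant")), 0.75)
  # zero null deviance defines EV = 0
  expect_equal(explained_variance(mk(0), mk(0, "constant")), 0)
  expect_error(explained_variance(mk(1), mk(1)), "constant")
})

test_that("noise-free dosage genes reach CNI near 1", {
  set.seed(41)
  cn <- draw_cn(80, c(0.1, 0.2, 0.3, 0.2, 0.1, 0.1))
  x <- 50L * cn$total
  res <- gene_cni(x, cn$A, cn$B)
  expect_gte(res$cni, 0.95)
  expect_lt(res$lrt$p, 1e-10)
})

test_that("a gene with constant CN has exactly zero CNI and a zero-df test", {
  set.seed(42)
  x <- rpois(60, 9)
  res <- gene_cni(x, rep(1, 60), rep(1, 60))
  expect_equal(res$explained_variance, 0)
  expect_equal(res$cni, 0)
  expect_equal(res$lrt$df, 0L)
  expect_equal(res$lrt$p, 1)
})

test_that("CN-independent genes score low CNI", {
  set.seed(43)
  vals <- replicate(20, {
    cn <- draw_cn(200, concentrated_probs)
    x <- rpois(200, runif(1, 2, 20))
    gene_cni(x, cn$A, cn$B)$cni
  })
  expect_gte(mean(vals <= 0.15), 0.8)
  expect_lt(median(vals), 0.1)
})

test_that("deviance- and MSE-based explained variance agree on strong dosage", {
  set.seed(47)
  cn <- draw_cn(150, dispersed_probs)
  x <- rpois(150, 5 * pmax(cn$total, 0.1))
  dev_ev <- gene_cni(x, cn$A, cn$B)$explained_variance
  mse_ev <- gene_cni(x, cn$A, cn$B, ev_method = "mse")$explained_variance
  expect_gt(dev_ev, 0.7)
  expect_gt(mse_ev, 0.7)
  expect_lt(abs(dev_ev - mse_ev), 0.2)
  # a CN-invariant gene stays at exactly zero under both realizations
  y <- rpois(50, 6)
  expect_equal(gene_cni(y, rep(1, 50), rep(1, 50),
                        ev_method = "mse")$explained_variance, 0)
})

test_that("explained variance is invariant under sample permutation", {
  set.seed(44)
  cn <- draw_cn(100, dispersed_probs)
  g <- rlnorm(100, 0, 0.2); g <- g / mean(g)
  x <- rpois(100, (3 + 2 * cn$total) * g)
  ref <- gene_cni(x, cn$A, cn$B, g)$explained_variance
  for (r in 1:3) {
    p <- sample(100)
    perm <- gene_cni(x[p], cn$A[p], cn$B[p], g[p])$explained_variance
    expect_equal(perm, ref, tolerance = 1e-6)
  }
})

test_that("pathway pooling reduces to the member identity and arithmetic", {
  gs <- data.frame(gene = c("G1", "G2"),
                   explained_variance = c(0.75, 0),
                   cni = c(sqrt(0.75), 0),
                   statistic = c(6, 0), df = c(2L, 2L),
                   p = c(0.05, 1), q = c(0.1, 1),
                   d_null = c(8, 4), d_alt = c(2, 4),
                   converged = c(TRUE, TRUE))
  single <- pathway_cni(gs, "G1")
  expect_equal(single$cni, gs$cni[1])
  expect_equal(single$contributions, c(G1 = 1))
  both <- pathway_cni(gs, c("G1", "G2"))
  expect_equal(both$pooled_ev, 0.5)           # 1 - 6/12
  expect_equal(both$cni, sqrt(0.5))
  expect_equal(both$lrt$statistic, 6)
  expect_equal(both$lrt$df, 4L)
  # unknown members are reported unused; all-unknown errors
  part <- pathway_cni(gs, c("G1", "G2", "G9"))
  expect_equal(part$genes_unused, "G9")
  expect_error(pathway_cni(gs, "G9"), "no usable member genes")
})

test_that("a pathway of zero-EV genes has zero CNI", {
  gs <- data.frame(gene = c("A", "B"), explained_variance = 0, cni = 0,
                   statistic = 0, df = 1L, p = 1, q = 1,
                   d_null = c(5, 7), d_alt = c(5, 7), converged = TRUE)
  expect_equal(pathway_cni(gs, c("A", "B"))$cni, 0)
})

test_that("pooled pathway EV equals the gene EV of concatenated member data", {
  set.seed(45)
  cn <- draw_cn(90, dispersed_probs)
  x <- rpois(90, 4 + 2 * cn$total)
  one <- gene_cni(x, cn$A, cn$B)
  # three identical member genes pool to the same EV as their concatenation
  gs <- data.frame(gene = c("G1", "G2", "G3"),
                   explained_variance = one$explained_variance,
                   cni = one$cni, statistic = one$lrt$statistic,
                   df = one$lrt$df, p = one$lrt$p, q = one$lrt$p,
                   d_null = one$d_null, d_alt = one$d_alt, converged = TRUE)
  pooled <- pathway_cni(gs, c("G1", "G2", "G3"))
  concat <- gene_cni(rep(x, 3), rep(cn$A, 3), rep(cn$B, 3))
  expect_equal(pooled$pooled_ev, concat$explained_variance, tolerance = 1e-4)
})

test_that("BH adjustment matches the hand-computed step-up", {
  expect_equal(adjust_pvalues(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(adjust_pvalues(0.2), 0.2)
  expect_equal(adjust_pvalues(c(1, 1, 1)), c(1, 1, 1))
  p <- c(0.001, 0.08, 0.04, 0.9)
  q <- adjust_pvalues(p)
  expect_true(all(q >= p))
  expect_equal(order(q), order(p))
  expect_error(adjust_pvalues(c(0.5, 1.2)), "0, 1")
})

test_that("cni_table ranks planted dosage genes above null genes", {
  set.seed(46)
  cfg <- sim_config(n_genes = 40, n_samples = 100, seed = 46,
                    n_pathways = 4L, pathway_size = c(3L, 5L),
                    cross_members = 0L)
  co <- simulate_cohort(cfg)
  tb <- cni_table(co$expr, co$cn)
  cls <- co$truth$genes$class[match(tb$gene, co$truth$genes$gene)]
  expect_gt(median(tb$cni[cls == "cn_driven"]),
            median(tb$cni[cls == "independent"]) + 0.3)
  expect_true(all(tb$q >= tb$p))
})
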