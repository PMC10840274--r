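mk_profile <- function(major, minor) {
  dimnames(major) <- list(paste0("G", seq_len(nrow(major))),
                          paste0("S", seq_len(ncol(major))))
  dimnames(minor) <- dimnames(major)
  copy_number_profile(major, minor)
}

test_that("mean CNA averages total or deviation copy number per gene", {
  cn <- mk_profile(matrix(c(1L, 2L, 1L, 4L), 2), matrix(c(1L, 1L, 1L, 3L), 2))
  mc <- mean_cna(cn)
  expect_equal(unname(mc), c(2, 5))          # (2+2)/2 and (3+7)/2
  expect_equal(unname(mean_cna(cn, "deviation")), c(0, 3))  # (|1|+|5|)/2
  empty <- structure(list(major = matrix(integer(0), 0, 0),
                          minor = matrix(integer(0), 0, 0)),
                     class = "CopyNumberProfile")
  expect_error(mean_cna(empty), "empty")
})

test_that("leave-one-out contributions isolate the driving gene", {
  one <- gene_contributions(data.frame(gene = "G1", d_null = 5, d_alt = 1))
  expect_equal(one, c(G1 = 1))
  twin <- gene_contributions(data.frame(gene = c("A", "B"),
                                        d_null = c(10, 10),
                                        d_alt = c(3, 3)))
  expect_equal(twin, c(A = 0.5, B = 0.5))
  # one strong gene: its removal drops pooled EV 0.6 -> 0.3, the others'
  # removals raise it (clipped to zero contribution)
  gs <- data.frame(gene = c("KEY", "N1", "N2"),
                   d_null = c(100, 50, 50), d_alt = c(10, 35, 35))
  p <- gene_contributions(gs)
  expect_equal(unname(p), c(1, 0, 0))
  # degenerate all-zero deltas fall back to uniform
  unif <- gene_contributions(data.frame(gene = c("A", "B"),
                                        d_null = c(10, 10),
                                        d_alt = c(10, 10)))
  expect_equal(unname(unif), c(0.5, 0.5))
})

test_that("perplexity is the exponential entropy of contributions", {
  expect_equal(perplexity(rep(0.25, 4)), 4, tolerance = 1e-9)
  expect_equal(perplexity(c(1, 0, 0)), 1, tolerance = 1e-9)
  expect_equal(perplexity(c(0.5, 0.25, 0.25)), 2^1.5, tolerance = 1e-9)
  expect_error(perplexity(c(0.5, 0.4)), "sum to 1")
  set.seed(61)
  for (i in 1:20) {
    k <- sample(2:10, 1)
    p <- rexp(k); p <- p / sum(p)
    pi <- perplexity(p)
    expect_gte(pi, 1)
    expect_lte(pi, k + 1e-9)
  }
})

test_that("threshold optimizer matches a brute-force oracle", {
  sep <- optimize_threshold(c(0.8, 0.9), c(0.1, 0.2))
  expect_equal(sep$accuracy, 1)
  expect_gt(sep$threshold, 0.2)
  expect_lte(sep$threshold, 0.8)
  same <- optimize_threshold(c(0.3, 0.5), c(0.3, 0.5))
  expect_equal(same$accuracy, 0.5)
  ex <- optimize_threshold(c(0.3, 0.7, 0.9), c(0.1, 0.4, 0.5))
  expect_equal(ex$accuracy, 5 / 6)
  expect_gt(ex$threshold, 0.5)
  expect_lte(ex$threshold, 0.7)
  # oracle: accuracy evaluated just below and above every pooled value
  brute <- function(pos, neg) {
    cand <- sort(c(unique(c(pos, neg)) - 1e-9, unique(c(pos, neg)) + 1e-9))
    max(vapply(cand, function(th) {
      (sum(pos >= th) + sum(neg < th)) / (length(pos) + length(neg))
    }, numeric(1)))
  }
  set.seed(62)
  for (i in 1:60) {
    np <- sample(1:12, 1); nn <- sample(1:12, 1)
    pos <- round(runif(np), 2)
    neg <- round(runif(nn) * 0.8, 2)
    res <- optimize_threshold(pos, neg)
    expect_equal(res$accuracy, brute(pos, neg))
    got <- (sum(pos >= res$threshold) + sum(neg < res$threshold)) / (np + nn)
    expect_equal(got, res$accuracy)
  }
})

test_that("reference resampling is reproducible and inert without drivers", {
  set.seed(63)
  cfg <- sim_config(n_genes = 60, n_samples = 60, seed = 63,
                    n_pathways = 8L, pathway_size = c(4L, 6L),
                    cross_members = 1L)
  co <- simulate_cohort(cfg)
  tb <- cni_table(co$expr, co$cn)
  args <- list(tb, co$pathways, co$truth$cn_drivers, co$truth$mut_drivers,
               co$cn, n_resamples = 5L, seed = 7L)
  r1 <- do.call(build_reference_distributions, args)
  r2 <- do.call(build_reference_distributions, args)
  expect_identical(r1, r2)
  # a pathway holding no replaceable gene contributes a constant statistic
  cls <- co$truth$genes
  pure <- list(PURE = cls$gene[cls$class == "cn_driven"][1:4],
               MUT_SIDE = cls$gene[cls$class == "independent"][1:4])
  r3 <- build_reference_distributions(tb, pure, co$truth$cn_drivers,
                                      co$truth$mut_drivers, co$cn,
                                      n_resamples = 4L, seed = 1L)
  expect_equal(length(unique(r3$cni$pos)), 1L)
})

test_that("resampled pathway statistics shift toward the genome background", {
  # toy: a 3-gene pathway where one member is a high-CNI mutation driver;
  # replacing it from a null-gene pool must lower the resampled CNI mean
  gs <- data.frame(gene = c("HI1", "HI2", "MUT", paste0("BG", 1:20)),
                   d_null = 100, d_alt = c(10, 10, 10, rep(95, 20)),
                   converged = TRUE)
  gs$statistic <- gs$d_null - gs$d_alt
  gs$df <- 1L; gs$p <- 0.5; gs$q <- 0.5
  gs$explained_variance <- 1 - gs$d_alt / gs$d_null
  gs$cni <- sqrt(pmax(gs$explained_variance, 0))
  major <- matrix(2L, nrow(gs), 4,
                  dimnames = list(gs$gene, paste0("S", 1:4)))
  cn <- copy_number_profile(major, major - 1L)
  ref <- build_reference_distributions(
    gs, list(PW = c("HI1", "HI2", "MUT"), MUTPW = c("MUT", "BG1", "BG2")),
    cn_drivers = c("HI1", "HI2"),
    mut_drivers = "MUT", cn = cn, genome_genes = paste0("BG", 1:20),
    n_resamples = 30L, seed = 2L)
  original <- sqrt(1 - 30 / 300)
  expect_lt(mean(ref$cni$pos), original)
})

test_that("quadrant labels follow the two calibrated thresholds", {
  thr <- list(cni_threshold = 0.5, cna_threshold = 3)
  stats <- data.frame(pathway = c("P1", "P2", "P3", "P4"),
                      cni = c(0.9, 0.9, 0.1, 0.1),
                      mean_cna = c(5, 2, 5, 2))
  got <- classify_quadrants(stats, thr)
  expect_equal(got$quadrant,
               c("cn_driven", "conserved", "passenger", "non_cn_driven"))
})

test_that("group enrichment labels pathways by significant gene directions", {
  stacked <- data.frame(gene = c("G1", "G2", "G3", "G4"),
                        direction = c("poor", "good", "poor", "good"),
                        statistic = c(30, 25, 1, 2), df = 3L,
                        p = c(1e-6, 1e-5, 0.8, 0.7),
                        q = c(4e-6, 2e-5, 0.8, 0.8),
                        converged = TRUE)
  pw <- list(P_poor = c("G1", "G3"), P_both = c("G1", "G2"),
             P_none = c("G3", "G4"), P_good = "G2")
  enr <- group_enrichment(stacked, pw)
  expect_equal(enr$enrichment[match(c("P_poor", "P_both", "P_none", "P_good"),
                                    enr$pathway)],
               c("poor", "both", "none", "good"))
  expect_error(group_enrichment(stacked[0, ], pw), "no stacked fits")
})
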