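#' Configuration for synthetic cohort generation
#'
#' Defines the study conditions the generator emulates: cohort size, the
#' copy-number state distributions per gene class, effect-size ranges for
#' the Poisson dosage models, sample-scale spread, pathway layout and the
#' binary response groups. Gene classes: `cn_driven` (dispersed CN, real
#' dosage effect), `passenger` (dispersed CN, no effect), `conserved`
#' (CN concentrated near 2, real effect), `independent` (CN concentrated
#' near 2, no effect) and `group_modulated` (dispersed CN, dosage effect
#' plus nonnegative deviations in one response group).
#'
#' @param n_genes,n_samples cohort dimensions.
#' @param seed integer seed used by all generator functions by default.
#' @param c_max maximum total copy number (dispersed states span 0..c_max).
#' @param class_fractions named fractions over the five gene classes
#'   (must sum to 1).
#' @param dispersed_probs probabilities over total CN `0:c_max` for
#'   dispersed classes.
#' @param concentrated_probs probabilities over total CN `0:c_max` for
#'   classes concentrated near 2 copies.
#' @param p_balanced probability that the allele split of a total CN is
#'   the balanced one (otherwise the minor allele count is uniform).
#' @param b0_range basal expression range (uniform draw per gene).
#' @param a_rel_range per-step effect size for dosage-responsive genes,
#'   relative to `b0 / 2`: a gene whose expression is exactly proportional
#'   to total copy number has slope `b0 / 2` per allele copy, so relative
#'   sizes near 1 emulate proportional dosage.
#' @param dev_rel_range group-deviation size for `group_modulated` genes,
#'   also relative to `b0 / 2`.
#' @param g_sdlog log-normal sd of the sample scales (renormalized to
#'   mean 1).
#' @param n_pathways number of planted pathways, split evenly over the
#'   four landscape quadrants.
#' @param pathway_size inclusive size range of a pathway.
#' @param cross_members how many mutation-driver (independent-class) genes
#'   are mixed into each cn_driven pathway, emulating real CN-driven
#'   pathways that also hold mutation drivers; these are what the
#'   landscape resampling replaces. Dosage genes are not planted into
#'   non_cn_driven pathways: under deviance pooling even one strong gene
#'   dominates a pathway, which would make the planted label wrong rather
#'   than noisy.
#' @param group_labels the two response-group labels.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 2000L, n_samples = 200L, seed = 1L,
                       c_max = 8L,
                       class_fractions = c(cn_driven = 0.2, passenger = 0.2,
                                           conserved = 0.2,
                                           independent = 0.3,
                                           group_modulated = 0.1),
                       dispersed_probs = c(0.05, 0.10, 0.25, 0.20, 0.15,
                                           0.10, 0.07, 0.05, 0.03),
                       concentrated_probs = c(0, 0.15, 0.70, 0.15,
                                              rep(0, 5)),
                       p_balanced = 0.7,
                       b0_range = c(2, 20), a_rel_range = c(0.5, 1.5),
                       dev_rel_range = c(0.5, 1.0), g_sdlog = 0.3,
                       n_pathways = 50L, pathway_size = c(10L, 40L),
                       cross_members = 2L,
                       group_labels = c("good", "poor")) {
  check(abs(sum(class_fractions) - 1) <= 1e-9, "class fractions must sum to 1")
  check(length(dispersed_probs) == c_max + 1L &&
          length(concentrated_probs) == c_max + 1L,
        "CN state distributions must cover 0..c_max")
  check(abs(sum(dispersed_probs) - 1) <= 1e-9 &&
          abs(sum(concentrated_probs) - 1) <= 1e-9,
        "CN state probabilities must sum to 1")
  check(all(b0_range > 0) && all(a_rel_range > 0) && all(dev_rel_range > 0),
        "effect-size ranges must be positive")
  structure(as.list(environment()), class = "sim_config")
}

assign_gene_classes <- function(config) {
  counts <- round(config$class_fractions * config$n_genes)
  counts[length(counts)] <- config$n_genes - sum(counts[-length(counts)])
  rep(names(counts), counts)
}

gene_ids <- function(n) sprintf("G%04d", seq_len(n))
sample_ids <- function(n) sprintf("S%03d", seq_len(n))

#' Simulate an allele-specific copy-number profile
#'
#' Total copy numbers are drawn per gene from the class-specific state
#' distribution (dispersed over `0:c_max` for cn_driven / passenger /
#' group_modulated, concentrated near 2 for conserved / independent); the
#' allele split is balanced with probability `p_balanced`, otherwise the
#' minor count is uniform over its admissible values. Deterministic given
#' the seed.
#'
#' @param config a [sim_config()].
#' @param seed integer seed (defaults to `config$seed`).
#' @return a [copy_number_profile()].
#' @export
simulate_copy_numbers <- function(config, seed = config$seed) {
  classes <- assign_gene_classes(config)
  ng <- config$n_genes
  ns <- config$n_samples
  with_seed(seed, {
    major <- matrix(0L, ng, ns, dimnames = list(gene_ids(ng), sample_ids(ns)))
    minor <- major
    for (i in seq_len(ng)) {
      probs <- if (classes[i] %in% c("conserved", "independent")) {
        config$concentrated_probs
      } else {
        config$dispersed_probs
      }
      tot <- sample(0:config$c_max, ns, replace = TRUE, prob = probs)
      b_max <- floor(tot / 2)
      balanced <- stats::runif(ns) < config$p_balanced
      b <- ifelse(balanced, b_max,
                  floor(stats::runif(ns) * (b_max + 1L)))
      minor[i, ] <- as.integer(b)
      major[i, ] <- as.integer(tot - b)
    }
    copy_number_profile(major, minor)
  })
}

draw_truth <- function(config, classes, seed) {
  ng <- config$n_genes
  ns <- config$n_samples
  k_max <- config$c_max
  with_seed(seed, {
    b0 <- stats::runif(ng, config$b0_range[1L], config$b0_range[2L])
    steps <- matrix(0, ng, k_max,
                    dimnames = list(gene_ids(ng), paste0("a", 1:k_max)))
    dev <- matrix(0, ng, k_max + 1L,
                  dimnames = list(gene_ids(ng),
                                  c("d0", paste0("d", 1:k_max))))
    direction <- rep(NA_character_, ng)
    profiles <- c("linear", "saturating", "threshold")
    for (i in seq_len(ng)) {
      cls <- classes[i]
      if (cls %in% c("cn_driven", "conserved", "group_modulated")) {
        a <- b0[i] / 2 *
          stats::runif(1, config$a_rel_range[1L], config$a_rel_range[2L])
        prof <- sample(profiles, 1L)
        steps[i, ] <- switch(prof,
          linear = rep(a, k_max),
          saturating = c(a, a, rep(0, k_max - 2L)),
          threshold = c(0, a, a, rep(0, k_max - 3L)))
      }
      if (cls == "group_modulated") {
        d <- b0[i] / 2 *
          stats::runif(1, config$dev_rel_range[1L], config$dev_rel_range[2L])
        direction[i] <- sample(config$group_labels, 1L)
        active <- steps[i, ] > 0
        dev[i, c(FALSE, active)] <- d
      }
    }
    g <- stats::rlnorm(ns, meanlog = 0, sdlog = config$g_sdlog)
    g <- g / mean(g)
    groups <- sample(rep(config$group_labels, length.out = ns))
    list(genes = data.frame(gene = gene_ids(ng), class = classes, b0 = b0,
                            direction = direction,
                            stringsAsFactors = FALSE),
         steps = steps, dev = dev,
         samples = data.frame(sample = sample_ids(ns), group = groups,
                              g = g, stringsAsFactors = FALSE),
         config = config)
  })
}

#' Simulate expression counts from planted truth
#'
#' Every gene's counts are Poisson with the mean dictated by its class:
#' the constant model for independent/passenger genes, the monotonic step
#' model for cn_driven/conserved genes, and the stacked model (nonnegative
#' deviations in the gene's recorded direction group) for group_modulated
#' genes, all multiplied by the sample scales.
#'
#' @param cn [copy_number_profile()] from [simulate_copy_numbers()].
#' @param truth truth bundle from [simulate_cohort()] / `draw_truth`.
#' @param seed integer seed.
#' @return a count matrix ([expression_matrix()]).
#' @export
simulate_expression <- function(cn, truth, seed = truth$config$seed) {
  ng <- nrow(cn$major)
  ns <- ncol(cn$major)
  g <- truth$samples$g
  grp <- truth$samples$group
  with_seed(seed, {
    x <- matrix(0L, ng, ns, dimnames = dimnames(cn$major))
    for (i in seq_len(ng)) {
      D <- step_design(cn$major[i, ], cn$minor[i, ],
                       ncol(truth$steps))
      mu <- truth$genes$b0[i] + drop(D %*% truth$steps[i, ])
      if (!is.na(truth$genes$direction[i])) {
        in_dev <- grp == truth$genes$direction[i]
        mu <- mu + (truth$dev[i, 1L] + drop(D %*% truth$dev[i, -1L])) * in_dev
      }
      check(all(mu >= 0), "negative simulated mean for gene %d", i)
      x[i, ] <- stats::rpois(ns, mu * g)
    }
    expression_matrix(x)
  })
}

#' Simulate a full synthetic cohort with planted truth
#'
#' Generates copy numbers, expression, response groups, pathway sets and
#' a truth table in one seeded call. Pathways are split evenly over the
#' four landscape quadrants and drawn from the matching gene-class pools
#' (`cn_driven` pathways from cn_driven genes, `passenger` from passenger
#' genes, `conserved` from conserved genes, `non_cn_driven` from
#' independent genes); `cross_members` mutation-driver genes are mixed
#' into each cn_driven pathway. When `outdir` is given,
#' the bundle is also written as `counts.tsv`, `gene_cn.tsv`,
#' `pathways.gmt`, `groups.tsv` and `truth.tsv`.
#'
#' @param config a [sim_config()].
#' @param seed integer seed (defaults to `config$seed`).
#' @param outdir optional output directory.
#' @return list with `expr`, `cn`, `pathways`, `groups`, `truth`; `truth`
#'   additionally carries `pathway_quadrant`, `cn_drivers`, `mut_drivers`.
#' @export
simulate_cohort <- function(config = sim_config(), seed = config$seed,
                            outdir = NULL) {
  classes <- assign_gene_classes(config)
  # independent seeds per stage, derived from the master seed
  cn <- simulate_copy_numbers(config, seed = seed)
  truth <- draw_truth(config, classes, seed = seed + 1L)
  expr <- simulate_expression(cn, truth, seed = seed + 2L)
  quadrants <- c("cn_driven", "passenger", "conserved", "non_cn_driven")
  pool_class <- c(cn_driven = "cn_driven", passenger = "passenger",
                  conserved = "conserved", non_cn_driven = "independent")
  pools <- lapply(pool_class, function(cl) {
    truth$genes$gene[truth$genes$class == cl]
  })
  # planted pathways split evenly over the quadrants whose class pool exists
  quadrants <- quadrants[vapply(pools[quadrants], length, integer(1)) > 0L]
  check(length(quadrants) > 0L, "no gene class available to build pathways")
  n_per <- diff(c(0, round(seq_along(quadrants) / length(quadrants) *
                             config$n_pathways)))
  pathways <- list()
  pw_quadrant <- character(0)
  with_seed(seed + 3L, {
    for (qi in seq_along(quadrants)) {
      quad <- quadrants[qi]
      if (n_per[qi] == 0L) next
      pool <- pools[[quad]]
      check(length(pool) >= config$pathway_size[2L],
            "gene class '%s' too small for pathway size %d",
            pool_class[[quad]], config$pathway_size[2L])
      for (r in seq_len(n_per[qi])) {
        sz <- sample(config$pathway_size[1L]:config$pathway_size[2L], 1L)
        members <- sample(pool, sz)
        if (quad == "cn_driven" && config$cross_members > 0L) {
          extra_pool <- truth$genes$gene[truth$genes$class == "independent"]
          members <- c(members, sample(extra_pool,
                                       min(config$cross_members,
                                           length(extra_pool))))
        }
        pathways[[sprintf("PW_%s_%02d", quad, r)]] <- members
        pw_quadrant <- c(pw_quadrant, quad)
      }
    }
  })
  truth$pathway_quadrant <- stats::setNames(pw_quadrant, names(pathways))
  truth$cn_drivers <- truth$genes$gene[truth$genes$class == "cn_driven"]
  truth$mut_drivers <- truth$genes$gene[truth$genes$class == "independent"]
  groups <- stats::setNames(truth$samples$group, truth$samples$sample)
  out <- list(expr = expr, cn = cn, pathways = pathways, groups = groups,
              truth = truth)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    write_counts(expr, file.path(outdir, "counts.tsv"))
    write_gene_cn(cn, file.path(outdir, "gene_cn.tsv"))
    write_gmt(pathways, file.path(outdir, "pathways.gmt"))
    utils::write.table(truth$samples[c("sample", "group")],
                       file.path(outdir, "groups.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE,
                       col.names = c("sample_id", "group"))
    utils::write.table(truth$genes, file.path(outdir, "truth.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  out
}
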