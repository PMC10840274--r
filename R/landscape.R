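#' Per-gene mean absolute copy number
#'
#' Mode `"total"` averages the total copy number `A + B` across samples
#' (the average of absolute CNAs); mode `"deviation"` averages
#' `|A + B - 2|`, which also exposes deletion-driven aberration that the
#' total mode cannot see. Missing pairs are excluded per gene; a gene with
#' no observed sample yields `NA` with a warning.
#'
#' @param cn a [copy_number_profile()].
#' @param mode `"total"` (default) or `"deviation"`.
#' @return named numeric vector over genes.
#' @export
mean_cna <- function(cn, mode = c("total", "deviation")) {
  mode <- match.arg(mode)
  check(nrow(cn$major) > 0L && ncol(cn$major) > 0L, "empty copy-number profile")
  tot <- cn$major + cn$minor
  v <- if (mode == "total") tot else abs(tot - 2)
  out <- rowMeans(v, na.rm = TRUE)
  out[rowSums(!is.na(v)) == 0L] <- NA_real_
  if (anyNA(out)) {
    warning(sprintf("%d gene(s) with no observed CN excluded from mean CNA",
                    sum(is.na(out))), call. = FALSE)
  }
  out
}

#' Leave-one-out gene contributions to a pathway's CNI
#'
#' For each member gene i, the pooled explained variance is recomputed
#' without i; the drop \eqn{\Delta_i} (clipped at 0) measures the gene's
#' contribution, and contributions are normalized to sum to 1. If no
#' gene's removal lowers the pooled EV, contributions are uniform.
#'
#' @param gene_stats data.frame with columns `gene`, `d_null`, `d_alt`
#'   (one row per member gene, e.g. a [cni_table()] subset).
#' @return named numeric vector `p` with `sum(p) == 1`.
#' @export
gene_contributions <- function(gene_stats) {
  k <- nrow(gene_stats)
  check(k >= 1L, "no member genes")
  if (k == 1L) return(stats::setNames(1, gene_stats$gene))
  s_null <- sum(gene_stats$d_null)
  s_alt <- sum(gene_stats$d_alt)
  ev_all <- if (s_null == 0) 0 else 1 - s_alt / s_null
  delta <- vapply(seq_len(k), function(i) {
    dn <- s_null - gene_stats$d_null[i]
    da <- s_alt - gene_stats$d_alt[i]
    ev_i <- if (dn == 0) 0 else 1 - da / dn
    max(ev_all - ev_i, 0)
  }, numeric(1))
  p <- if (sum(delta) == 0) rep(1 / k, k) else delta / sum(delta)
  stats::setNames(p, gene_stats$gene)
}

#' Perplexity of a contribution vector
#'
#' \deqn{\pi = \exp(-\sum_i p_i \log p_i)} with \eqn{0 \log 0 = 0}: the
#' effective number of genes carrying a pathway's copy-number impact.
#' Bounded by 1 (single dominant gene) and k (uniform contributions).
#'
#' @param p nonnegative vector summing to 1 (tolerance 1e-9).
#' @return perplexity in [1, length(p)].
#' @export
perplexity <- function(p) {
  check(all(p >= 0), "negative contribution")
  check(abs(sum(p) - 1) <= 1e-9, "contributions must sum to 1 (got %.12g)",
        sum(p))
  nz <- p[p > 0]
  exp(-sum(nz * log(nz)))
}

#' Driver-calibrated reference distributions for the landscape axes
#'
#' CN-driver pathways (those containing at least one known CN driver gene)
#' populate the high side of both axes, mutation-driver pathways the low
#' side. To free each side from the other class's signal, every resample
#' replaces the mutation driver genes inside CN-driver pathways (and,
#' symmetrically, the CN driver genes inside mutation-driver pathways)
#' with genes sampled uniformly from the genome pool, then recomputes the
#' pathway CNI and mean CNA from the per-gene statistics. Repeating the
#' replacement `n_resamples` times yields two reference distributions per
#' axis.
#'
#' @param gene_stats data.frame from [cni_table()].
#' @param pathways named list of gene sets.
#' @param cn_drivers,mut_drivers character vectors of driver gene ids.
#' @param cn [copy_number_profile()] for the CNA axis.
#' @param genome_genes replacement pool; defaults to all converged genes in
#'   `gene_stats`.
#' @param n_resamples number of resampling rounds (default 1000).
#' @param seed integer seed; output is bit-reproducible given the seed.
#' @param mean_cna_mode see [mean_cna()].
#' @return list with `cni` and `cna`, each holding `pos` (CN-driver side)
#'   and `neg` (mutation-driver side) samples, plus `n_resamples`, `seed`.
#' @export
build_reference_distributions <- function(gene_stats, pathways, cn_drivers,
                                          mut_drivers, cn,
                                          genome_genes = NULL,
                                          n_resamples = 1000L, seed = 1L,
                                          mean_cna_mode = "total") {
  check(length(cn_drivers) > 0L && length(mut_drivers) > 0L,
        "driver gene lists must be nonempty")
  usable <- gene_stats$gene[gene_stats$converged]
  pool <- genome_genes %||% usable
  pool <- intersect(pool, usable)
  check(length(pool) > 0L, "empty replacement gene pool")
  per_cna <- mean_cna(cn, mode = mean_cna_mode)
  stats_of <- function(members) {
    gs <- gene_stats[match(members, gene_stats$gene), , drop = FALSE]
    s_null <- sum(gs$d_null)
    ev <- if (s_null == 0) 0 else 1 - sum(gs$d_alt) / s_null
    c(cni = ev_to_cni(ev),
      cna = mean(per_cna[members][!is.na(per_cna[members])]))
  }
  members_of <- function(pw) intersect(pathways[[pw]], usable)
  # pathways holding both driver kinds count as CN-driver pathways: the
  # replacement strips their mutation drivers, whereas stripping the CN
  # drivers of a genuinely CN-driven pathway would fabricate a background
  # pathway on the mutation side
  cn_pw <- names(pathways)[vapply(names(pathways), function(pw) {
    length(intersect(members_of(pw), cn_drivers)) > 0L
  }, logical(1))]
  mut_pw <- setdiff(names(pathways)[vapply(names(pathways), function(pw) {
    length(intersect(members_of(pw), mut_drivers)) > 0L
  }, logical(1))], cn_pw)
  check(length(cn_pw) > 0L, "no pathway contains a CN driver gene")
  check(length(mut_pw) > 0L, "no pathway contains a mutation driver gene")
  resample_side <- function(pw_names, replace_set) {
    out_cni <- numeric(0)
    out_cna <- numeric(0)
    for (pw in pw_names) {
      members <- members_of(pw)
      if (length(members) == 0L) next
      repl <- intersect(members, replace_set)
      keep <- setdiff(members, repl)
      if (length(repl) == 0L) {
        st <- stats_of(members)
        out_cni <- c(out_cni, rep(st[["cni"]], n_resamples))
        out_cna <- c(out_cna, rep(st[["cna"]], n_resamples))
        next
      }
      avail <- setdiff(pool, keep)
      check(length(avail) >= length(repl),
            "replacement pool exhausted for pathway '%s'", pw)
      for (r in seq_len(n_resamples)) {
        new_members <- c(keep, sample(avail, length(repl)))
        st <- stats_of(new_members)
        out_cni <- c(out_cni, st[["cni"]])
        out_cna <- c(out_cna, st[["cna"]])
      }
    }
    list(cni = out_cni, cna = out_cna)
  }
  with_seed(seed, {
    pos <- resample_side(cn_pw, mut_drivers)
    neg <- resample_side(mut_pw, cn_drivers)
    list(cni = list(pos = pos$cni, neg = neg$cni),
         cna = list(pos = pos$cna, neg = neg$cna),
         n_resamples = as.integer(n_resamples), seed = as.integer(seed))
  })
}

#' Optimal separating threshold between two samples
#'
#' Exhaustive scan over the midpoints of adjacent order statistics of the
#' pooled sample (plus cuts below and above its range), declaring
#' positives at values >= threshold. Returns the cut maximizing accuracy
#' (TP + TN) / n; ties resolve to the smallest threshold.
#'
#' @param pos,neg numeric samples (positives expected high).
#' @return list with `threshold` and `accuracy`.
#' @export
optimize_threshold <- function(pos, neg) {
  check(length(pos) > 0L && length(neg) > 0L, "both samples must be nonempty")
  v <- sort(unique(c(pos, neg)))
  cand <- c(v[1L] - 1, if (length(v) > 1L) (v[-length(v)] + v[-1L]) / 2,
            v[length(v)] + 1)
  acc <- vapply(cand, function(th) {
    (sum(pos >= th) + sum(neg < th)) / (length(pos) + length(neg))
  }, numeric(1))
  best <- which(acc == max(acc))[1L]
  list(threshold = cand[best], accuracy = acc[best])
}

#' Calibrate landscape thresholds from reference distributions
#'
#' Thresholds on the CNI and mean-CNA axes are optimized independently
#' against the driver-calibrated reference distributions.
#'
#' @param ref output of [build_reference_distributions()].
#' @return list: `cni_threshold`, `cna_threshold`, `accuracy_cni`,
#'   `accuracy_cna`, `n_resamples`, `seed`.
#' @export
calibrate_landscape <- function(ref) {
  t1 <- optimize_threshold(ref$cni$pos, ref$cni$neg)
  t2 <- optimize_threshold(ref$cna$pos, ref$cna$neg)
  list(cni_threshold = t1$threshold, cna_threshold = t2$threshold,
       accuracy_cni = t1$accuracy, accuracy_cna = t2$accuracy,
       n_resamples = ref$n_resamples, seed = ref$seed)
}

#' Quadrant classification of pathways on the CNA-versus-CNI landscape
#'
#' High CNI with high mean CNA marks putative CN-driven pathways; high CNI
#' with low CNA conserved ones (strong dosage response but few aberrations
#' manifest); low CNI with high CNA passenger CN events; both low,
#' non-CN-driven pathways.
#'
#' @param pathway_stats data.frame with columns `pathway`, `cni`,
#'   `mean_cna` (e.g. from [pathway_cni_table()]).
#' @param thresholds list from [calibrate_landscape()].
#' @return the input with a `quadrant` column (`NA`, with a warning, where
#'   a statistic is missing).
#' @export
classify_quadrants <- function(pathway_stats, thresholds) {
  hi_cni <- pathway_stats$cni >= thresholds$cni_threshold
  hi_cna <- pathway_stats$mean_cna >= thresholds$cna_threshold
  q <- ifelse(hi_cni & hi_cna, "cn_driven",
              ifelse(hi_cni & !hi_cna, "conserved",
                     ifelse(!hi_cni & hi_cna, "passenger", "non_cn_driven")))
  if (anyNA(q)) {
    warning(sprintf("%d pathway(s) with missing statistics skipped",
                    sum(is.na(q))), call. = FALSE)
  }
  pathway_stats$quadrant <- q
  pathway_stats
}

#' Stacked-model tests for every gene of a two-group cohort
#'
#' Fits the constant and stacked monotonic models per gene, testing for
#' any group-dependent copy-number effect; the deviating group is
#' recorded per gene.
#'
#' @param expr count matrix.
#' @param cn aligned [copy_number_profile()].
#' @param groups named group labels covering the samples (two levels).
#' @param g sample scales; estimated when `NULL`.
#' @param k_max see [fit_monotonic()].
#' @return data.frame: `gene`, `direction`, `statistic`, `df`, `p`, `q`,
#'   `converged`.
#' @export
stacked_cni_table <- function(expr, cn, groups, g = NULL, k_max = 8L) {
  check(identical(rownames(expr), rownames(cn$major)) &&
          identical(colnames(expr), colnames(cn$major)),
        "expr and cn are not aligned; call align() first")
  grp <- groups[colnames(expr)]
  check(!anyNA(grp), "groups missing for some samples")
  if (is.null(g)) g <- estimate_sample_scales(expr)
  rows <- lapply(seq_len(nrow(expr)), function(i) {
    keep <- !is.na(cn$major[i, ])
    null_fit <- fit_constant(expr[i, keep], g[keep])
    alt <- fit_stacked_monotonic(expr[i, ], cn$major[i, ], cn$minor[i, ], g,
                                 groups = grp, k_max = k_max)
    test <- lrt(null_fit, alt)
    data.frame(gene = rownames(expr)[i], direction = alt$direction,
               statistic = test$statistic, df = test$df, p = test$p,
               converged = alt$converged)
  })
  out <- do.call(rbind, rows)
  out$q <- adjust_pvalues(out$p)
  rownames(out) <- NULL
  out[c("gene", "direction", "statistic", "df", "p", "q", "converged")]
}

#' Group-enrichment labels for pathways
#'
#' A gene is group-significant when its stacked-versus-constant LRT
#' q-value falls below `q_threshold`; its stacked fit's direction says
#' which group carries the extra dosage response. A pathway is labeled
#' with a group when it contains at least one significant gene deviating
#' toward that group, `"both"` when both directions occur, `"none"`
#' otherwise.
#'
#' @param stacked_stats data.frame from [stacked_cni_table()].
#' @param pathways named list of gene sets.
#' @param q_threshold FDR threshold (default 0.05).
#' @return data.frame with `pathway` and `enrichment`.
#' @export
group_enrichment <- function(stacked_stats, pathways, q_threshold = 0.05) {
  check(nrow(stacked_stats) > 0L, "no stacked fits given")
  sig <- stacked_stats[stacked_stats$q < q_threshold &
                         stacked_stats$converged, , drop = FALSE]
  lab <- vapply(names(pathways), function(pw) {
    dirs <- unique(sig$direction[sig$gene %in% pathways[[pw]]])
    if (length(dirs) == 0L) "none"
    else if (length(dirs) == 1L) dirs
    else "both"
  }, character(1))
  data.frame(pathway = names(pathways), enrichment = unname(lab))
}

#' Scatter plot of the CNA-versus-CNI landscape
#'
#' @param classified data.frame from [classify_quadrants()].
#' @param thresholds list from [calibrate_landscape()].
#' @param path optional PNG output path; plots to the active device when
#'   `NULL`.
#' @return invisibly, the classified table.
#' @export
plot_landscape <- function(classified, thresholds, path = NULL) {
  cols <- c(cn_driven = "magenta", conserved = "blue",
            non_cn_driven = "orange", passenger = "darkgreen")
  if (!is.null(path)) {
    grDevices::png(path, width = 900, height = 700, res = 120)
    on.exit(grDevices::dev.off())
  }
  graphics::plot(classified$mean_cna, classified$cni,
                 col = cols[classified$quadrant], pch = 19,
                 xlab = "mean absolute CNA", ylab = "CNI",
                 main = "CNA versus CNI landscape")
  graphics::abline(v = thresholds$cna_threshold, lty = 2)
  graphics::abline(h = thresholds$cni_threshold, lty = 2)
  graphics::legend("bottomright", legend = names(cols), col = cols,
                   pch = 19, cex = 0.8)
  invisible(classified)
}
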