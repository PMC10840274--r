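#' Residual Poisson deviance against the saturated model
#'
#' \deqn{D = 2 \sum_j [x_j \ln(x_j/\mu_j) - (x_j - \mu_j)]} with the
#' convention \eqn{x \ln(x/\mu) = 0} at \eqn{x = 0}.
#'
#' @param x observed counts.
#' @param mu fitted means (`mu > 0` wherever `x > 0`).
#' @return nonnegative deviance.
#' @export
residual_deviance <- function(x, mu) {
  check(length(x) == length(mu), "x and mu lengths differ")
  check(all(mu >= 0), "negative fitted mean")
  check(all(mu[x > 0] > 0), "zero fitted mean with positive count")
  t1 <- ifelse(x > 0, x * log(x / mu), 0)
  max(2 * sum(t1 - (x - mu)), 0)
}

#' Deviance-based explained variance of a copy-number model
#'
#' \eqn{EV = 1 - D_{alt}/D_{null}} where the null is the constant fit.
#' This is the Poisson analogue of R-squared over the constant model; it
#' reduces to the classical R-squared in the Gaussian limit. `EV` is 0 when
#' the null deviance is 0, and may be slightly negative before the clipping
#' applied inside the CNI square root.
#'
#' @param alt alternative-family `cni_fit`.
#' @param null constant-family `cni_fit` on the same data.
#' @return scalar explained variance (<= 1).
#' @export
explained_variance <- function(alt, null) {
  check(inherits(alt, "cni_fit") && inherits(null, "cni_fit"),
        "explained_variance needs cni_fit objects")
  check(null$family == "constant", "null must be the constant family")
  check(alt$n_obs == null$n_obs, "fits use different data")
  if (null$deviance == 0) return(0)
  1 - alt$deviance / null$deviance
}

ev_to_cni <- function(ev) sqrt(min(max(ev, 0), 1))

#' Gene-level copy-number impact
#'
#' Fits the constant model and the requested alternative to one gene,
#' returning the explained variance, its square root (the CNI), and the
#' likelihood-ratio test of any copy-number effect. When the gene's copy
#' number carries no usable variation (alternative design rank equal to the
#' constant model's), the alternative is the constant model itself: EV and
#' CNI are exactly 0 with a zero-df test.
#'
#' @inheritParams fit_monotonic
#' @param family alternative family: `"monotonic"` (default), `"linear"`,
#'   or `"interaction"`.
#' @param ev_method `"deviance"` (default; likelihood-consistent and used
#'   throughout the package) or `"mse"`, a classical R-squared on the
#'   scale-normalized counts `x / g`, offered for sensitivity analysis.
#' @return list with `explained_variance`, `cni`, `lrt`, `d_null`, `d_alt`,
#'   `converged`, and the two fits (`fit_null`, `fit_alt`).
#' @export
gene_cni <- function(x, A, B, g = rep(1, length(x)), family = "monotonic",
                     k_max = 8L, ev_method = c("deviance", "mse")) {
  family <- match.arg(family, c("monotonic", "linear", "interaction"))
  ev_method <- match.arg(ev_method)
  keep <- !is.na(A) & !is.na(B)
  null_fit <- fit_constant(x[keep], g[keep])
  alt_fit <- switch(family,
    monotonic = fit_monotonic(x, A, B, g, k_max = k_max),
    linear = fit_linear(x, A, B, g, with_interaction = FALSE),
    interaction = fit_linear(x, A, B, g, with_interaction = TRUE))
  if (alt_fit$rank <= null_fit$rank) {
    # no identifiable CN effect: collapse onto the constant model
    alt_fit$loglik <- null_fit$loglik
    alt_fit$deviance <- null_fit$deviance
    alt_fit$rank <- null_fit$rank
  }
  test <- lrt(null_fit, alt_fit)
  ev <- if (ev_method == "deviance") {
    explained_variance(alt_fit, null_fit)
  } else {
    y <- x[keep] / g[keep]
    ss_null <- sum((y - null_fit$params[["b0"]])^2)
    mu_alt <- if (alt_fit$rank <= null_fit$rank) {
      null_fit$params[["b0"]] * g[keep]
    } else {
      predict_mean(alt_fit, A[keep], B[keep], g[keep])
    }
    ss_alt <- sum((y - mu_alt / g[keep])^2)
    if (ss_null == 0) 0 else 1 - ss_alt / ss_null
  }
  cni <- if (alt_fit$converged) ev_to_cni(ev) else NA_real_
  list(explained_variance = ev, cni = cni, lrt = test,
       d_null = null_fit$deviance, d_alt = alt_fit$deviance,
       converged = alt_fit$converged, fit_null = null_fit, fit_alt = alt_fit)
}

#' Gene-level CNI for every gene of a cohort
#'
#' Convenience driver applying [gene_cni()] to each row of an aligned
#' expression/copy-number pair, with BH-adjusted LRT p-values across genes.
#'
#' @param expr count matrix ([expression_matrix()]).
#' @param cn matching [copy_number_profile()] (aligned axes).
#' @param g sample scales; estimated from `expr` when `NULL`.
#' @param family,k_max passed to [gene_cni()].
#' @return data.frame with one row per gene: `gene`, `explained_variance`,
#'   `cni`, `statistic`, `df`, `p`, `q`, `d_null`, `d_alt`, `converged`.
#' @export
cni_table <- function(expr, cn, g = NULL, family = "monotonic", k_max = 8L) {
  check(identical(rownames(expr), rownames(cn$major)) &&
          identical(colnames(expr), colnames(cn$major)),
        "expr and cn are not aligned; call align() first")
  if (is.null(g)) g <- estimate_sample_scales(expr)
  rows <- lapply(seq_len(nrow(expr)), function(i) {
    r <- gene_cni(expr[i, ], cn$major[i, ], cn$minor[i, ], g,
                  family = family, k_max = k_max)
    data.frame(gene = rownames(expr)[i],
               explained_variance = r$explained_variance, cni = r$cni,
               statistic = r$lrt$statistic, df = r$lrt$df, p = r$lrt$p,
               d_null = r$d_null, d_alt = r$d_alt, converged = r$converged)
  })
  out <- do.call(rbind, rows)
  out$q <- adjust_pvalues(out$p)
  rownames(out) <- NULL
  out[c("gene", "explained_variance", "cni", "statistic", "df", "p", "q",
        "d_null", "d_alt", "converged")]
}

#' Pathway-level copy-number impact by deviance pooling
#'
#' Member genes' alternative and null deviances are summed separately and
#' the pooled explained variance is \eqn{1 - \sum_i D_{alt,i} / \sum_i
#' D_{null,i}}; the pathway CNI is its clipped square root. The pooled LRT
#' sums member statistics and degrees of freedom. Per-gene leave-one-out
#' contributions and their perplexity (effective number of contributing
#' genes) are included, as is the pathway mean CNA when a copy-number
#' profile is supplied.
#'
#' @param gene_stats data.frame from [cni_table()].
#' @param members character vector of member gene ids.
#' @param pathway_id optional pathway label.
#' @param cn optional [copy_number_profile()] for the mean-CNA axis.
#' @param mean_cna_mode `"total"` or `"deviation"`, see [mean_cna()].
#' @return list with `pathway_id`, `genes_used`, `genes_unused`,
#'   `pooled_ev`, `cni`, `lrt`, `contributions`, `perplexity`, `mean_cna`.
#' @export
pathway_cni <- function(gene_stats, members, pathway_id = NA_character_,
                        cn = NULL, mean_cna_mode = "total") {
  idx <- match(members, gene_stats$gene)
  used <- members[!is.na(idx) & gene_stats$converged[idx]]
  unused <- setdiff(members, used)
  check(length(used) > 0L, "pathway '%s' has no usable member genes",
        pathway_id)
  gs <- gene_stats[match(used, gene_stats$gene), , drop = FALSE]
  s_null <- sum(gs$d_null)
  s_alt <- sum(gs$d_alt)
  pooled_ev <- if (s_null == 0) 0 else 1 - s_alt / s_null
  stat <- sum(gs$statistic)
  df <- sum(gs$df)
  p <- if (df == 0L) 1 else stats::pchisq(stat, df, lower.tail = FALSE)
  contrib <- gene_contributions(gs)
  mc <- if (is.null(cn)) NA_real_ else {
    per_gene <- mean_cna(cn, mode = mean_cna_mode)
    mean(per_gene[used][!is.na(per_gene[used])])
  }
  list(pathway_id = pathway_id, genes_used = used, genes_unused = unused,
       pooled_ev = pooled_ev, cni = ev_to_cni(pooled_ev),
       lrt = list(statistic = stat, df = df, p = p),
       contributions = contrib, perplexity = perplexity(contrib),
       mean_cna = mc)
}

#' Pathway-level CNI for a whole gene-set collection
#'
#' @param gene_stats data.frame from [cni_table()].
#' @param pathways named list of gene sets ([read_gmt()]).
#' @param cn optional [copy_number_profile()].
#' @param mean_cna_mode see [mean_cna()].
#' @return data.frame with one row per usable pathway (`pathway`,
#'   `n_genes`, `pooled_ev`, `cni`, `statistic`, `df`, `p`, `q`,
#'   `perplexity`, `mean_cna`).
#' @export
pathway_cni_table <- function(gene_stats, pathways, cn = NULL,
                              mean_cna_mode = "total") {
  rows <- lapply(names(pathways), function(pw) {
    r <- tryCatch(pathway_cni(gene_stats, pathways[[pw]], pathway_id = pw,
                              cn = cn, mean_cna_mode = mean_cna_mode),
                  error = function(e) NULL)
    if (is.null(r)) return(NULL)
    data.frame(pathway = pw, n_genes = length(r$genes_used),
               pooled_ev = r$pooled_ev, cni = r$cni,
               statistic = r$lrt$statistic, df = r$lrt$df, p = r$lrt$p,
               perplexity = r$perplexity, mean_cna = r$mean_cna)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  check(length(rows) > 0L, "no pathway has usable member genes")
  out <- do.call(rbind, rows)
  out$q <- adjust_pvalues(out$p)
  rownames(out) <- NULL
  out
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up FDR adjustment with monotonicity enforcement
#' (delegates to [stats::p.adjust()]); inputs outside [0, 1] are an error.
#'
#' @param p numeric vector of p-values.
#' @return adjusted q-values, `q >= p` elementwise.
#' @export
adjust_pvalues <- function(p) {
  check(all(is.finite(p)) && all(p >= 0) && all(p <= 1),
        "p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}
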