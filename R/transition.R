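#' One-dimensional dosage curve of a monotonic fit
#'
#' Reduces the two-allele step model to a curve over total copy number
#' \eqn{c = 0, 1, \ldots, 2 k_{max}} using the balanced allele split
#' \eqn{A = \lceil c/2 \rceil, B = \lfloor c/2 \rfloor} (or an all-major
#' split with `B` fixed at 0). Between integer grid points the curve is
#' linearly interpolated; it is non-decreasing by construction.
#'
#' @param fit converged `cni_fit` with family `"monotonic"`.
#' @param split `"balanced"` (default) or `"major"`.
#' @return list with `cn` (integer grid) and `mu` (fitted means).
#' @export
model_curve <- function(fit, split = c("balanced", "major")) {
  check(inherits(fit, "cni_fit") && fit$family == "monotonic",
        "model_curve needs a monotonic fit")
  split <- match.arg(split)
  cn <- 0:(2L * fit$k_max)
  if (split == "balanced") {
    A <- ceiling(cn / 2)
    B <- floor(cn / 2)
  } else {
    A <- cn
    B <- rep(0L, length(cn))
  }
  mu <- predict_mean(fit, A, B, g = rep(1, length(cn)))
  list(cn = cn, mu = mu)
}

# Invert a non-decreasing piecewise-linear curve at height y. The preimage
# of y is a (possibly degenerate) interval; its midpoint is returned, so a
# flat stretch at exactly y yields the middle of that stretch. Heights
# below/above the curve range clamp to the grid ends with a flag.
invert_curve <- function(curve, y) {
  cn <- curve$cn
  mu <- curve$mu
  n <- length(cn)
  if (y < mu[1L]) return(list(t = cn[1L], clamped = "low"))
  if (y > mu[n]) return(list(t = cn[n], clamped = "high"))
  j <- which(mu >= y)[1L]
  c_lo <- if (j == 1L) cn[1L] else {
    cn[j - 1L] + (y - mu[j - 1L]) / (mu[j] - mu[j - 1L]) * (cn[j] - cn[j - 1L])
  }
  i <- max(which(mu <= y))
  c_hi <- if (i == n) cn[n] else {
    cn[i] + (y - mu[i]) / (mu[i + 1L] - mu[i]) * (cn[i + 1L] - cn[i])
  }
  list(t = (c_lo + c_hi) / 2, clamped = "none")
}

#' Functional copy-number transition point of a gene
#'
#' The cohort's median and quartiles of scale-normalized expression
#' \eqn{y_j = x_j / g_j} are projected onto the fitted dosage curve and
#' the corresponding copy numbers are read off by linear interpolation:
#' the median crossing is the transition point `t`, the Q1/Q3 crossings
#' bracket the transition bandwidth. Projections at a flat stretch of the
#' curve return the midpoint of that stretch; heights outside the curve
#' range clamp to the grid ends with a flag. A completely flat curve has
#' no transition (`category "undefined"`). Quantiles use the
#' median-unbiased scheme (type 8).
#'
#' @param fit converged monotonic `cni_fit`.
#' @param x counts for the gene (>= 4 samples).
#' @param g sample scales.
#' @param split allele split for the curve, see [model_curve()].
#' @return list with `transition_point`, `band_low`, `band_high`,
#'   `bandwidth`, `category`, and `clamped` flags for (Q1, median, Q3).
#' @export
transition_point <- function(fit, x, g = rep(1, length(x)),
                             split = "balanced") {
  check(length(x) >= 4L, "transition_point needs at least 4 samples")
  check(isTRUE(fit$converged), "transition_point needs a converged fit")
  curve <- model_curve(fit, split = split)
  if (max(curve$mu) - min(curve$mu) <= 0) {
    return(list(transition_point = NA_real_, band_low = NA_real_,
                band_high = NA_real_, bandwidth = NA_real_,
                category = "undefined",
                clamped = c(q1 = NA, median = NA, q3 = NA)))
  }
  y <- x / g
  qs <- stats::quantile(y, probs = c(0.25, 0.5, 0.75), type = 8,
                        names = FALSE)
  inv <- lapply(qs, function(h) invert_curve(curve, h))
  t_med <- inv[[2L]]$t
  list(transition_point = t_med,
       band_low = inv[[1L]]$t, band_high = inv[[3L]]$t,
       bandwidth = inv[[3L]]$t - inv[[1L]]$t,
       category = categorize_transition(t_med),
       clamped = c(q1 = inv[[1L]]$clamped != "none",
                   median = inv[[2L]]$clamped != "none",
                   q3 = inv[[3L]]$clamped != "none"))
}

#' Five-level aberration category of a transition point
#'
#' Integer anchors: deletion at copy number 0, loss at 1, normal at 2,
#' gain for 2 < CNA <= 5, amplification for CNA > 5. Real-valued
#' transition points are assigned by the extended boundaries
#' `t <= 0.5` deletion, `<= 1.5` loss, `<= 2` normal, `<= 5` gain,
#' `> 5` amplification.
#'
#' @param t transition point (>= 0), or `NA` for undefined.
#' @return category string.
#' @export
categorize_transition <- function(t) {
  if (is.na(t)) return("undefined")
  check(t >= 0, "negative transition point")
  if (t <= 0.5) "deletion"
  else if (t <= 1.5) "loss"
  else if (t <= 2) "normal"
  else if (t <= 5) "gain"
  else "amplification"
}

#' Pathway-level transition category
#'
#' The modal category over a pathway's member genes (undefined genes are
#' ignored). Ties are broken toward the category more extreme relative to
#' normal; between gain and loss (equally extreme), gain wins; between
#' amplification and deletion, amplification wins.
#'
#' @param categories character vector of per-gene categories.
#' @return the pathway category (or `"undefined"` if all members are).
#' @export
pathway_transition <- function(categories) {
  lev <- c("deletion", "loss", "normal", "gain", "amplification")
  cats <- categories[categories %in% lev]
  if (length(cats) == 0L) return("undefined")
  counts <- table(factor(cats, levels = lev))
  top <- names(counts)[counts == max(counts)]
  if (length(top) == 1L) return(top)
  # tie-break: furthest from normal, gain side preferred
  extremeness <- c(deletion = 2, loss = 1, normal = 0, gain = 1,
                   amplification = 2)
  gain_side <- c(deletion = 0, loss = 0, normal = 0, gain = 1,
                 amplification = 1)
  top[order(-extremeness[top], -gain_side[top])][1L]
}

#' Transition points for every gene of a cohort
#'
#' Fits the monotonic model per gene (reusing fits if supplied) and
#' tabulates transition points, bandwidths and categories.
#'
#' @param expr count matrix.
#' @param cn aligned [copy_number_profile()].
#' @param g sample scales; estimated from `expr` when `NULL`.
#' @param k_max,split see [fit_monotonic()] and [model_curve()].
#' @return data.frame: `gene`, `transition_point`, `band_low`,
#'   `band_high`, `bandwidth`, `category`, `clamped_median`.
#' @export
transition_table <- function(expr, cn, g = NULL, k_max = 8L,
                             split = "balanced") {
  check(identical(rownames(expr), rownames(cn$major)) &&
          identical(colnames(expr), colnames(cn$major)),
        "expr and cn are not aligned; call align() first")
  if (is.null(g)) g <- estimate_sample_scales(expr)
  rows <- lapply(seq_len(nrow(expr)), function(i) {
    keep <- !is.na(cn$major[i, ])
    res <- if (sum(keep) < 4L) NULL else {
      fit <- fit_monotonic(expr[i, ], cn$major[i, ], cn$minor[i, ], g,
                           k_max = k_max)
      if (!fit$converged) NULL else {
        transition_point(fit, expr[i, keep], g[keep], split = split)
      }
    }
    if (is.null(res)) {
      res <- list(transition_point = NA_real_, band_low = NA_real_,
                  band_high = NA_real_, bandwidth = NA_real_,
                  category = "undefined", clamped = c(NA, median = NA, NA))
    }
    data.frame(gene = rownames(expr)[i],
               transition_point = res$transition_point,
               band_low = res$band_low, band_high = res$band_high,
               bandwidth = res$bandwidth, category = res$category,
               clamped_median = res$clamped[["median"]])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
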