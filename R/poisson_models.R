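#' Estimate per-sample global expression scales
#'
#' The scale \eqn{g_j} of sample j multiplies every gene's Poisson mean and
#' absorbs library-size differences. It is estimated as the sample's column
#' sum divided by the mean column sum, so that `mean(g) == 1`.
#'
#' @param expr count matrix from [expression_matrix()].
#' @return named numeric vector of positive scales, mean 1.
#' @export
estimate_sample_scales <- function(expr) {
  cs <- colSums(expr)
  zero <- names(cs)[cs <= 0]
  check(length(zero) == 0L, "sample '%s' has zero total count", zero[1L])
  cs / mean(cs)
}

new_model_fit <- function(family, params, loglik, rank, deviance, converged,
                          n_obs, k_max = NA_integer_, direction = NA_character_) {
  structure(list(family = family, params = params, direction = direction,
                 loglik = loglik, rank = rank, deviance = deviance,
                 converged = converged, n_obs = n_obs, k_max = k_max),
            class = "cni_fit")
}

#' @export
print.cni_fit <- function(x, ...) {
  cat(sprintf("<cni_fit %s> loglik=%.4f rank=%d deviance=%.4f converged=%s\n",
              x$family, x$loglik, x$rank, x$deviance, x$converged))
  nz <- x$params[x$params != 0]
  if (length(nz)) {
    cat("  ", paste(sprintf("%s=%.4g", names(nz), nz), collapse = " "), "\n")
  }
  if (!is.na(x$direction)) cat("  deviations on group:", x$direction, "\n")
  invisible(x)
}

# Monotonic step design: one column per step k with entries
# 1[A >= k] + 1[B >= k]. Allele CN above k_max still triggers all k <= k_max
# indicators (natural truncation of the step model).
step_design <- function(A, B, k_max) {
  D <- vapply(seq_len(k_max), function(k) (A >= k) + (B >= k),
              numeric(length(A)))
  D <- matrix(D, nrow = length(A))
  colnames(D) <- paste0("a", seq_len(k_max))
  D
}

# Maximize the identity-link Poisson likelihood over box-constrained
# coefficients. D includes the intercept column. `lower` is 0 for
# nonnegative coefficients, -Inf for sign-free ones. The mean is floored at
# a small epsilon inside the objective so the log stays finite when
# coefficients hit zero while x > 0. Initialization at the constant-model
# MLE guarantees the optimum is at least as good as the constant fit; on
# non-convergence a fixed ladder of deterministic restarts is tried.
fit_identity_poisson <- function(x, D, g, lower) {
  p <- ncol(D)
  eps <- 1e-10
  negll <- function(th) {
    m <- pmax(drop(D %*% th), eps)
    -sum(x * log(m * g) - m * g)
  }
  gradient <- function(th) {
    m <- pmax(drop(D %*% th), eps)
    -drop(crossprod(D, x / m - g))
  }
  b0_hat <- sum(x) / sum(g)
  inits <- list(c(b0_hat, rep(0, p - 1L)),
                c(b0_hat / 2, rep(b0_hat / (2 * max(p - 1L, 1L)), p - 1L)),
                rep(0.1, p),
                rep(1, p))
  best <- NULL
  converged <- FALSE
  for (init in inits) {
    init <- pmax(init, ifelse(is.finite(lower), lower, init))
    o <- tryCatch(
      stats::optim(init, negll, gradient, method = "L-BFGS-B", lower = lower,
                   control = list(maxit = 1000L, factr = 1e7)),
      error = function(e) NULL)
    if (is.null(o)) next
    if (is.null(best) || o$value < best$value) best <- o
    if (o$convergence == 0L) {
      converged <- TRUE
      best <- if (best$value <= o$value) best else o
      break
    }
  }
  check(!is.null(best), "Poisson optimizer failed on all starts")
  theta <- best$par
  theta[is.finite(lower)] <- pmax(theta[is.finite(lower)],
                                  lower[is.finite(lower)])
  mu <- pmax(drop(D %*% theta), 0) * g
  mu_safe <- ifelse(x > 0, pmax(mu, eps), mu)
  list(theta = theta, mu = mu,
       loglik = sum(stats::dpois(x, mu_safe, log = TRUE)),
       converged = converged || best$convergence == 0L)
}

drop_missing_cn <- function(x, A, B, g) {
  keep <- !is.na(A) & !is.na(B)
  list(x = x[keep], A = A[keep], B = B[keep], g = g[keep], n = sum(keep))
}

# Identifiable-parameter count: rank of the design restricted to columns
# not structurally zero (step levels never observed stay fixed at 0).
design_rank <- function(D) {
  active <- colSums(abs(D)) > 0
  if (!any(active)) return(0L)
  qr(D[, active, drop = FALSE])$rank
}

#' Fit the constant (basal) expression model
#'
#' Model: \eqn{X_j \sim Poi(b_0 g_j)} with \eqn{b_0 \ge 0}. The MLE is the
#' closed form \eqn{b_0 = \sum_j x_j / \sum_j g_j}.
#'
#' @param x nonnegative integer counts for one gene.
#' @param g positive sample scales (same length).
#' @return a `cni_fit` with family `"constant"`.
#' @export
fit_constant <- function(x, g = rep(1, length(x))) {
  check(length(x) == length(g), "x and g lengths differ")
  check(all(g > 0), "sample scales must be positive")
  b0 <- sum(x) / sum(g)
  mu <- b0 * g
  new_model_fit("constant", c(b0 = b0),
                loglik = sum(stats::dpois(x, mu, log = TRUE)),
                rank = 1L, deviance = residual_deviance(x, mu),
                converged = TRUE, n_obs = length(x))
}

#' Fit the linear (and optionally interaction) copy-number model
#'
#' Model: \eqn{X_j \sim Poi((b_0 + a (A_j + B_j) + c A_j B_j) g_j)} with
#' \eqn{b_0, a \ge 0}; the interaction coefficient `c` is free in sign and
#' only present with `with_interaction = TRUE` (`c > 0` synergistic,
#' `c = 0` linear, `c < 0` antagonistic between the major and minor allele
#' numbers). Pairs with missing CN are excluded.
#'
#' @param x counts for one gene.
#' @param A,B major and minor allele copy numbers (`NA` = missing).
#' @param g positive sample scales.
#' @param with_interaction include the `c * A * B` term.
#' @return a `cni_fit` with family `"linear"` or `"interaction"`.
#' @export
fit_linear <- function(x, A, B, g = rep(1, length(x)),
                       with_interaction = FALSE) {
  check(length(x) == length(A) && length(A) == length(B) &&
          length(B) == length(g), "input lengths differ")
  d <- drop_missing_cn(x, A, B, g)
  check(d$n > 0L, "no samples with observed CN")
  D <- cbind(b0 = 1, a = d$A + d$B)
  lower <- c(0, 0)
  if (with_interaction) {
    D <- cbind(D, c = d$A * d$B)
    lower <- c(lower, -Inf)
  }
  f <- fit_identity_poisson(d$x, D, d$g, lower)
  params <- stats::setNames(f$theta, colnames(D))
  new_model_fit(if (with_interaction) "interaction" else "linear", params,
                loglik = f$loglik, rank = design_rank(D),
                deviance = residual_deviance(d$x, f$mu),
                converged = f$converged, n_obs = d$n)
}

#' Classify the major/minor allele interaction of an interaction fit
#'
#' @param fit a `cni_fit` with family `"interaction"`.
#' @param tol tolerance band around zero.
#' @return one of `"synergistic"`, `"linear"`, `"antagonistic"`.
#' @export
classify_interaction <- function(fit, tol = 1e-6) {
  check(inherits(fit, "cni_fit") && fit$family == "interaction",
        "classify_interaction needs an interaction-family fit")
  cc <- fit$params[["c"]]
  if (cc > tol) "synergistic" else if (cc < -tol) "antagonistic" else "linear"
}

#' Fit the monotonic step copy-number model
#'
#' Model: \eqn{X_j \sim Poi((b_0 + \sum_{k=1}^{K} a_k (1[A_j \ge k] +
#' 1[B_j \ge k])) g_j)} with all coefficients nonnegative, so the fitted
#' mean is non-decreasing in each allele's copy number by construction.
#' `a_k` is the expression increment when an allele's copy number rises
#' from k-1 to k. Step levels never observed in the data are fixed at 0 and
#' excluded from the rank; allele CN above `k_max` triggers all indicators
#' up to `k_max`.
#'
#' @inheritParams fit_linear
#' @param k_max highest modeled step (default 8).
#' @return a `cni_fit` with family `"monotonic"`.
#' @export
fit_monotonic <- function(x, A, B, g = rep(1, length(x)), k_max = 8L) {
  check(length(x) == length(A) && length(A) == length(B) &&
          length(B) == length(g), "input lengths differ")
  check(k_max >= 1L, "k_max must be >= 1")
  d <- drop_missing_cn(x, A, B, g)
  check(d$n > 0L, "no samples with observed CN")
  D <- cbind(b0 = 1, step_design(d$A, d$B, k_max))
  f <- fit_identity_poisson(d$x, D, d$g, rep(0, ncol(D)))
  params <- stats::setNames(f$theta, colnames(D))
  params[colSums(abs(D)) == 0] <- 0
  new_model_fit("monotonic", params, loglik = f$loglik,
                rank = design_rank(D),
                deviance = residual_deviance(d$x, f$mu),
                converged = f$converged, n_obs = d$n, k_max = as.integer(k_max))
}

#' Fit the stacked two-group monotonic model
#'
#' One group follows the base monotonic model; the other adds nonnegative
#' deviations \eqn{d_0, d_k} to the basal level and to every step, so the
#' deviating group's dosage response is at least the base group's
#' everywhere. Both direction variants (deviations on either group) are
#' fitted and the better-likelihood one returned, with the deviating group
#' recorded in `direction`.
#'
#' @inheritParams fit_monotonic
#' @param groups character/factor vector of two group labels per sample.
#' @return a `cni_fit` with family `"stacked_monotonic"`; deviation
#'   coefficients are named `d0`, `d1`, ...
#' @export
fit_stacked_monotonic <- function(x, A, B, g = rep(1, length(x)), groups,
                                  k_max = 8L) {
  check(length(groups) == length(x), "groups length differs from x")
  d <- drop_missing_cn(x, A, B, g)
  grp <- as.character(groups)[!is.na(A) & !is.na(B)]
  levs <- sort(unique(grp))
  check(length(levs) == 2L, "exactly two groups required, got %d",
        length(levs))
  check(all(table(grp) >= 2L), "each group needs at least 2 samples")
  base <- cbind(b0 = 1, step_design(d$A, d$B, k_max))
  fit_dir <- function(dev_group) {
    ind <- as.numeric(grp == dev_group)
    Ddev <- base * ind
    colnames(Ddev) <- sub("^b0$", "d0", sub("^a", "d", colnames(base)))
    D <- cbind(base, Ddev)
    f <- fit_identity_poisson(d$x, D, d$g, rep(0, ncol(D)))
    list(f = f, D = D)
  }
  cands <- lapply(levs, fit_dir)
  pick <- which.max(vapply(cands, function(z) z$f$loglik, numeric(1)))
  f <- cands[[pick]]$f
  D <- cands[[pick]]$D
  params <- stats::setNames(f$theta, colnames(D))
  params[colSums(abs(D)) == 0] <- 0
  new_model_fit("stacked_monotonic", params, loglik = f$loglik,
                rank = design_rank(D),
                deviance = residual_deviance(d$x, f$mu),
                converged = f$converged, n_obs = d$n,
                k_max = as.integer(k_max), direction = levs[pick])
}

#' Evaluate a fitted model's mean at given copy numbers
#'
#' @param fit a `cni_fit`.
#' @param A,B allele copy numbers (ignored for the constant family).
#' @param g sample scales.
#' @param groups group labels (stacked family only).
#' @return nonnegative fitted means, one per sample.
#' @export
predict_mean <- function(fit, A = NULL, B = NULL, g = 1, groups = NULL) {
  check(inherits(fit, "cni_fit"), "fit must be a cni_fit")
  p <- fit$params
  base_mu <- switch(fit$family,
    constant = rep(p[["b0"]], max(length(g), 1L)),
    linear = p[["b0"]] + p[["a"]] * (A + B),
    interaction = p[["b0"]] + p[["a"]] * (A + B) + p[["c"]] * A * B,
    monotonic = drop(cbind(1, step_design(A, B, fit$k_max)) %*%
                       p[c("b0", paste0("a", seq_len(fit$k_max)))]),
    stacked_monotonic = {
      check(!is.null(groups), "stacked fit needs group labels")
      base <- cbind(1, step_design(A, B, fit$k_max))
      bpar <- p[c("b0", paste0("a", seq_len(fit$k_max)))]
      dpar <- p[c("d0", paste0("d", seq_len(fit$k_max)))]
      drop(base %*% bpar) +
        drop(base %*% dpar) * (as.character(groups) == fit$direction)
    },
    stop("unknown family: ", fit$family))
  pmax(base_mu, 0) * g
}

#' Likelihood-ratio test between nested model fits
#'
#' The statistic is the conventional Wilks deviance difference
#' \eqn{2 (\ell_{alt} - \ell_{null})}, clamped at 0 (with a warning) if the
#' alternative's likelihood falls numerically below the null's, with
#' degrees of freedom equal to the rank difference and an upper-tail
#' chi-square p-value. With zero degrees of freedom the p-value is 1.
#' Nonnegativity constraints make the chi-square reference conservative.
#'
#' @param null_fit,alt_fit `cni_fit` objects on the same data, null nested
#'   in alternative.
#' @return list with `statistic`, `df`, `p`.
#' @export
lrt <- function(null_fit, alt_fit) {
  check(inherits(null_fit, "cni_fit") && inherits(alt_fit, "cni_fit"),
        "lrt needs two cni_fit objects")
  check(null_fit$n_obs == alt_fit$n_obs,
        "fits use different numbers of observations")
  df <- alt_fit$rank - null_fit$rank
  check(df >= 0L, "alternative rank below null rank; models not nested")
  delta <- 2 * (alt_fit$loglik - null_fit$loglik)
  if (delta < 0) {
    if (delta < -1e-6) {
      warning(sprintf("alternative loglik below null by %.3g; statistic clamped to 0",
                      -delta / 2), call. = FALSE)
    }
    delta <- 0
  }
  p <- if (df == 0L) 1 else stats::pchisq(delta, df = df, lower.tail = FALSE)
  list(statistic = delta, df = df, p = p)
}
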