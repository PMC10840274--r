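# Shared fixture builders; everything is generated in code under fixed seeds.

# Draw allele-specific CN vectors: totals from `probs` over 0:(length-1),
# balanced split.
draw_cn <- function(n, probs) {
  tot <- sample(seq_along(probs) - 1L, n, replace = TRUE, prob = probs)
  list(A = ceiling(tot / 2), B = floor(tot / 2), total = tot)
}

dispersed_probs <- c(0.05, 0.10, 0.25, 0.20, 0.15, 0.10, 0.07, 0.05, 0.03)
concentrated_probs <- c(0, 0.15, 0.70, 0.15, rep(0, 5))

# Minimal hand-built model fit (for contract tests of consumers that only
# need params/family, e.g. curves and LRT arithmetic).
fake_fit <- function(family, params, loglik = 0, rank = length(params),
                     deviance = 0, n_obs = 10L, k_max = 8L,
                     converged = TRUE, direction = NA_character_) {
  structure(list(family = family, params = params, direction = direction,
                 loglik = loglik, rank = rank, deviance = deviance,
                 converged = converged, n_obs = n_obs,
                 k_max = as.integer(k_max)),
            class = "cni_fit")
}

# Fully-specified monotonic fit with steps a1..a8 (missing steps = 0).
fake_monotonic <- function(b0, steps = numeric(0), k_max = 8L, ...) {
  a <- stats::setNames(rep(0, k_max), paste0("a", seq_len(k_max)))
  a[names(steps)] <- steps
  fake_fit("monotonic", c(b0 = b0, a), k_max = k_max, ...)
}

small_counts_matrix <- function() {
  m <- matrix(c(0L, 3L, 10L, 2L, 5L, 7L), nrow = 3,
              dimnames = list(c("G1", "G2", "G3"), c("S1", "S2")))
  expression_matrix(m)
}
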