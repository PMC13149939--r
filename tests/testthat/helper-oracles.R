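# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: the variance-component oracle goes through
# least-squares sums of squares (Henderson method-of-moments on the balanced
# layout), the WAASB oracle re-derives scores from a fresh SVD with explicit
# loops, and the double-centering helper supports interaction invariants.

# Expected-mean-square estimators for the balanced crossed model
#   y = mu + E + B(E) + G + GE + e  (all random):
#   E[MS_E]  = s2e + g s2B + r s2GE + g r s2E
#   E[MS_B]  = s2e + g s2B
#   E[MS_G]  = s2e + r s2GE + e r s2G
#   E[MS_GE] = s2e + r s2GE
anova_components_oracle <- function(data) {
  d <- as.data.frame(data)
  d$ENV <- factor(d$ENV); d$GEN <- factor(d$GEN); d$BLOCK <- factor(d$BLOCK)
  g <- nlevels(d$GEN); e <- nlevels(d$ENV); r <- nlevels(d$BLOCK)
  a <- anova(aov(VALUE ~ ENV + GEN + ENV:BLOCK + ENV:GEN, data = d))
  ms <- setNames(a[["Mean Sq"]], trimws(rownames(a)))
  c(sigma2_env = (ms[["ENV"]] - ms[["ENV:BLOCK"]] - ms[["ENV:GEN"]] +
                    ms[["Residuals"]]) / (g * r),
    sigma2_block_env = (ms[["ENV:BLOCK"]] - ms[["Residuals"]]) / g,
    sigma2_gen = (ms[["GEN"]] - ms[["ENV:GEN"]]) / (e * r),
    sigma2_gei = (ms[["ENV:GEN"]] - ms[["Residuals"]]) / r,
    sigma2_resid = ms[["Residuals"]])
}

# Brute-force WAASB: fresh SVD, explicit |score| * EP sums, no shared code.
brute_waasb <- function(ge) {
  s <- svd(ge)
  n <- min(dim(ge)) - 1L
  lam <- s$d[seq_len(n)]
  ep <- lam^2 / sum(lam^2)
  out <- numeric(nrow(ge))
  for (i in seq_len(nrow(ge))) {
    acc <- 0
    for (k in seq_len(n))
      acc <- acc + abs(s$u[i, k] * sqrt(lam[k])) * ep[k]
    out[i] <- acc / sum(ep)
  }
  out
}

double_center <- function(m) {
  sweep(sweep(m, 1, rowMeans(m)), 2, colMeans(m)) + mean(m)
}

# Small balanced dataset for fast LMM tests; any sim_config field can be
# overridden through ...
quick_sim <- function(seed, ...) {
  args <- list(seed = seed, grand_mean = 10, sigma2_env = 1,
               sigma2_block_env = 0.5, sigma2_gen = 1, sigma2_resid = 1,
               gei_mode = "iid", sigma2_gei = 0.5)
  dots <- list(...)
  args[names(dots)] <- dots
  simulate_met(do.call(sim_config, args))
}

# Fabricated fitted-model skeleton for arithmetic-level checks.
fake_fit <- function(g, env_means, ge, components = NULL,
                     n_env = length(env_means), n_blocks = 3L) {
  structure(list(
    trait = "T1", genotype_role = "random",
    components = components,
    sigma2_phen = sum(components, na.rm = TRUE),
    mu_hat = mean(env_means), env_means = env_means,
    g = g, ge = ge, reml_loglik = NA_real_, converged = TRUE,
    boundary = FALSE, n_iter = NA_integer_,
    n_env = n_env, n_blocks = n_blocks
  ), class = "met_fit")
}
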