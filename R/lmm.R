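#' Fit the combined multi-environment mixed model by REML
#'
#' Fits `y = mu + E + B(E) + G + GE + e` to one trait of a long-format MET
#' dataset. Environment, block-within-environment and the genotype-by-
#' environment interaction are always random; the genotype term is random
#' (the parameterization behind BLUP genotypic values and every stability
#' index) or fixed (the parameterization behind the significance ANOVA).
#' Estimation is REML through [lme4::lmer()]; negative variance components
#' are handled by lme4's boundary constraint (estimates clipped at zero with
#' the profile re-optimized).
#'
#' @param data a `met_data` tibble or any data frame with columns
#'   `ENV, GEN, BLOCK, TRAIT, VALUE`.
#' @param trait trait name to fit; defaults to the only trait present.
#' @param genotype_role `"random"` or `"fixed"`.
#' @return An object of class `met_fit` with elements
#'   \describe{
#'     \item{components}{named variance components `sigma2_env`,
#'       `sigma2_block_env`, `sigma2_gen` (random-G fits only),
#'       `sigma2_gei`, `sigma2_resid`, plus `sigma2_phen` (their sum) and
#'       `phen_shares` (fractions of the phenotypic variance).}
#'     \item{mu_hat}{intercept estimate.}
#'     \item{env_means}{`u_j = mu_hat + BLUP(E_j)` per environment.}
#'     \item{g}{genotype BLUPs (or fixed-effect estimates, sum-centered).}
#'     \item{ge}{genotype x environment BLUP interaction matrix.}
#'     \item{reml_loglik, converged, n_iter, boundary}{fit diagnostics.}
#'   }
#' @export
#' @examples
#' dat <- simulate_met(sim_config(seed = 42))
#' fit <- fit_met(dat)
#' fit$components
fit_met <- function(data, trait = NULL, genotype_role = c("random", "fixed")) {
  genotype_role <- match.arg(genotype_role)
  d <- validate_met_frame(data)
  if (is.null(trait)) {
    traits <- unique(d$TRAIT)
    if (length(traits) > 1L)
      stop("multiple traits present; pass `trait`", call. = FALSE)
    trait <- traits
  }
  d <- d[d$TRAIT == trait, , drop = FALSE]
  if (nrow(d) == 0L) stop("trait not found: ", trait, call. = FALSE)
  for (f in c("ENV", "GEN", "BLOCK"))
    if (length(unique(d[[f]])) < 2L)
      stop("design error: factor ", f, " has fewer than 2 levels",
           call. = FALSE)
  env_per_gen <- tapply(d$ENV, d$GEN, function(x) length(unique(x)))
  if (any(env_per_gen < 2L))
    stop("design error: every genotype must appear in >= 2 environments",
         call. = FALSE)
  d$ENV <- factor(d$ENV, levels = unique(d$ENV))
  d$GEN <- factor(d$GEN, levels = unique(d$GEN))
  d$BLOCK <- factor(d$BLOCK)

  form <- if (genotype_role == "random")
    VALUE ~ 1 + (1 | ENV) + (1 | ENV:BLOCK) + (1 | GEN) + (1 | GEN:ENV)
  else
    VALUE ~ 0 + GEN + (1 | ENV) + (1 | ENV:BLOCK) + (1 | GEN:ENV)
  fit <- fit_lmer_best(form, d)

  vc <- as.data.frame(lme4::VarCorr(fit))
  comp_of <- function(grp) {
    v <- vc$vcov[vc$grp == grp]
    if (length(v)) v else NA_real_
  }
  components <- c(
    sigma2_env = comp_of("ENV"),
    sigma2_block_env = comp_of("ENV:BLOCK"),
    sigma2_gen = if (genotype_role == "random") comp_of("GEN") else NA_real_,
    sigma2_gei = comp_of("GEN:ENV"),
    sigma2_resid = comp_of("Residual")
  )
  incl <- !is.na(components)
  sigma2_phen <- sum(components[incl])
  phen_shares <- components[incl] / sigma2_phen

  re <- lme4::ranef(fit, condVar = FALSE)
  genotypes <- levels(d$GEN); envs <- levels(d$ENV)
  env_blup <- setNames(rep(0, length(envs)), envs)
  ev <- re[["ENV"]]
  env_blup[rownames(ev)] <- ev[, 1]

  if (genotype_role == "random") {
    mu_hat <- unname(lme4::fixef(fit)[1])
    g <- setNames(rep(0, length(genotypes)), genotypes)
    gv <- re[["GEN"]]
    g[rownames(gv)] <- gv[, 1]
  } else {
    fe <- lme4::fixef(fit)
    gm <- setNames(fe[paste0("GEN", genotypes)], genotypes)
    mu_hat <- mean(gm)
    g <- gm - mu_hat   # sum-to-zero deviations, comparable to BLUPs
  }

  ge <- matrix(0, length(genotypes), length(envs),
               dimnames = list(genotypes, envs))
  gei <- re[["GEN:ENV"]]
  if (!is.null(gei)) {
    parts <- strsplit(rownames(gei), ":", fixed = TRUE)
    gidx <- vapply(parts, `[`, "", 1L)
    eidx <- vapply(parts, `[`, "", 2L)
    ge[cbind(gidx, eidx)] <- gei[, 1]
  }
  # Interaction BLUPs can carry small margin components (the mixed-model
  # equations split marginal signal between main effects and interaction by
  # variance ratios). The IPCA/AMMI machinery requires a pure-interaction,
  # double-centered matrix, so the margins are folded into g and u_j; the
  # fitted surface u_j + g_i + ge_ij is unchanged.
  if (genotype_role == "random") {
    rm_ <- rowMeans(ge); cm_ <- colMeans(ge); gm_ <- mean(ge)
    ge <- ge - outer(rm_, rep(1, length(envs))) -
      outer(rep(1, length(genotypes)), cm_) + gm_
    g <- g + rm_ - gm_
    env_blup <- env_blup + cm_
  }

  opt <- fit@optinfo
  converged <- length(opt$conv$lme4) == 0 &&
    (is.null(opt$conv$opt) || opt$conv$opt == 0)
  boundary <- any(vc$sdcor[vc$grp != "Residual"] < 1e-8)
  if (!converged)
    warning("REML fit did not converge cleanly; inspect `converged`",
            call. = FALSE)

  structure(list(
    trait = trait,
    genotype_role = genotype_role,
    components = components,
    sigma2_phen = sigma2_phen,
    phen_shares = phen_shares,
    mu_hat = mu_hat,
    env_means = mu_hat + env_blup,
    g = g,
    ge = ge,
    reml_loglik = as.numeric(logLik(fit)),
    converged = converged,
    boundary = boundary,
    n_iter = if (!is.null(opt$feval)) opt$feval else NA_integer_,
    n_env = length(envs),
    n_blocks = length(unique(d$BLOCK)),
    lmer_fit = fit
  ), class = "met_fit")
}

#' @export
print.met_fit <- function(x, ...) {
  cat("MET mixed-model fit (REML), trait:", x$trait,
      "| genotype", x$genotype_role, "\n")
  comp <- x$components[!is.na(x$components)]
  tab <- data.frame(component = names(comp), variance = unname(comp),
                    share = unname(comp / x$sigma2_phen))
  print(tab, row.names = FALSE, digits = 4)
  cat("REML log-likelihood:", format(x$reml_loglik, digits = 8),
      "| converged:", x$converged, "\n")
  invisible(x)
}

# REML profiles with near-zero variance components can trap a tightly tuned
# optimizer in a local basin, while loose tolerances leave 1e-3-relative
# error in interior components. Fit with both settings and keep whichever
# attains the higher restricted likelihood.
fit_lmer_best <- function(form, d) {
  controls <- list(
    lme4::lmerControl(check.conv.singular = "ignore", calc.derivs = FALSE,
                      optCtrl = list(xtol_rel = 1e-12, ftol_rel = 1e-14,
                                     xtol_abs = 1e-12, ftol_abs = 1e-14,
                                     maxeval = 1e5)),
    lme4::lmerControl(check.conv.singular = "ignore", calc.derivs = FALSE)
  )
  fits <- lapply(controls, function(ctl) withCallingHandlers(
    tryCatch(lme4::lmer(form, data = d, REML = TRUE, control = ctl),
             error = function(e) NULL),
    message = function(m) invokeRestart("muffleMessage"),
    warning = function(w) invokeRestart("muffleWarning")
  ))
  fits <- Filter(Negate(is.null), fits)
  if (!length(fits)) stop("REML fit failed", call. = FALSE)
  ll <- vapply(fits, function(f) as.numeric(logLik(f)), 0)
  best <- fits[[which.max(ll)]]
  # polish: restart the tight optimizer from the winning basin
  polished <- withCallingHandlers(
    tryCatch(lme4::lmer(form, data = d, REML = TRUE,
                        start = list(theta = lme4::getME(best, "theta")),
                        control = controls[[1]]),
             error = function(e) NULL),
    message = function(m) invokeRestart("muffleMessage"),
    warning = function(w) invokeRestart("muffleWarning")
  )
  if (!is.null(polished) &&
      as.numeric(logLik(polished)) >= max(ll) - 1e-10) polished else best
}

#' Likelihood-ratio test for a random term
#'
#' Refits the model without one random term (same fixed structure, REML) and
#' compares restricted log-likelihoods. The statistic
#' `chi2 = 2 (l_full - l_reduced)` (clipped at zero) is referred to a
#' chi-squared distribution with 1 df by default; because the null value of
#' a variance lies on the boundary of the parameter space, the calibrated
#' reference is the 50:50 mixture of a point mass at zero and chi-squared 1
#' — enable it with `boundary_correct = TRUE` (halves the p-value for
#' positive statistics).
#'
#' @param data MET data frame.
#' @param trait trait name (default: the only trait).
#' @param term one of `"ENV"`, `"BLOCK"`, `"GEI"`, `"GEN"` (`"GEN"` only in
#'   the genotype-random parameterization).
#' @param genotype_role passed to [fit_met()].
#' @param boundary_correct logical; apply the boundary mixture reference.
#' @return list of class `met_lrt`: `term`, `chi2`, `df`, `p_value`,
#'   log-likelihoods of both fits.
#' @export
lrt_random_term <- function(data, trait = NULL,
                            term = c("GEI", "ENV", "BLOCK", "GEN"),
                            genotype_role = c("fixed", "random"),
                            boundary_correct = FALSE) {
  term <- match.arg(term)
  genotype_role <- match.arg(genotype_role)
  if (term == "GEN" && genotype_role != "random")
    stop("usage error: term GEN requires genotype_role = 'random'",
         call. = FALSE)
  full <- fit_met(data, trait, genotype_role)
  drop_term <- switch(term, ENV = "(1 | ENV)", BLOCK = "(1 | ENV:BLOCK)",
                      GEN = "(1 | GEN)", GEI = "(1 | GEN:ENV)")
  keep <- setdiff(c("(1 | ENV)", "(1 | ENV:BLOCK)",
                    if (genotype_role == "random") "(1 | GEN)",
                    "(1 | GEN:ENV)"), drop_term)
  lhs <- if (genotype_role == "random") "VALUE ~ 1 + " else "VALUE ~ 0 + GEN + "
  form <- as.formula(paste(lhs, paste(keep, collapse = " + ")))
  d <- validate_met_frame(data)
  if (is.null(trait)) trait <- unique(d$TRAIT)[1]
  d <- d[d$TRAIT == full$trait, , drop = FALSE]
  d$ENV <- factor(d$ENV); d$GEN <- factor(d$GEN); d$BLOCK <- factor(d$BLOCK)
  red <- fit_lmer_best(form, d)
  ll_full <- full$reml_loglik
  ll_red <- as.numeric(logLik(red))
  chi2 <- max(0, 2 * (ll_full - ll_red))
  p <- pchisq(chi2, df = 1, lower.tail = FALSE)
  if (boundary_correct) p <- if (chi2 > 0) p / 2 else 1
  structure(list(term = term, chi2 = chi2, df = 1L, p_value = p,
                 loglik_full = ll_full, loglik_reduced = ll_red,
                 boundary_correct = boundary_correct),
            class = "met_lrt")
}

#' @export
print.met_lrt <- function(x, ...) {
  cat(sprintf("LRT for random term %s: chi2(1) = %.4f, p = %.4g%s\n",
              x$term, x$chi2, x$p_value,
              if (x$boundary_correct) " (boundary-corrected)" else ""))
  invisible(x)
}

#' F test for the fixed genotype effect
#'
#' With `mode = "combined"` (default), fits the genotype-fixed combined
#' model and computes a Wald-type F for the genotype term at the REML
#' estimates, with denominator degrees of freedom from the containment
#' method: the genotype effect is contained in the genotype-by-environment
#' stratum, giving `(g - 1)(e - 1)` denominator df. With
#' `mode = "single_env"` each environment is analysed as a textbook RCBD
#' (`y = mu + block + genotype`) by least-squares ANOVA.
#'
#' @param data MET data frame.
#' @param trait trait name.
#' @param mode `"combined"` or `"single_env"`.
#' @return data frame of class `met_anova`: one row per test with
#'   `term, df1, df2, F, p_value` (plus `ENV` in single-environment mode).
#' @export
anova_genotype <- function(data, trait = NULL,
                           mode = c("combined", "single_env")) {
  mode <- match.arg(mode)
  d <- validate_met_frame(data)
  if (is.null(trait)) {
    traits <- unique(d$TRAIT)
    if (length(traits) > 1L)
      stop("multiple traits present; pass `trait`", call. = FALSE)
    trait <- traits
  }
  d <- d[d$TRAIT == trait, , drop = FALSE]
  if (mode == "single_env") {
    out <- do.call(rbind, lapply(split(d, d$ENV), function(dd) {
      dd$GEN <- factor(dd$GEN); dd$BLOCK <- factor(dd$BLOCK)
      a <- summary(aov(VALUE ~ BLOCK + GEN, data = dd))[[1]]
      data.frame(ENV = dd$ENV[1], term = "GEN",
                 df1 = a["GEN", "Df"], df2 = a["Residuals", "Df"],
                 F = a["GEN", "F value"], p_value = a["GEN", "Pr(>F)"])
    }))
    rownames(out) <- NULL
    class(out) <- c("met_anova", class(out))
    return(out)
  }
  fit <- fit_met(d, trait, genotype_role = "fixed")
  g <- length(fit$g); e <- fit$n_env
  # Wald F for equality of all genotype means from the GLS fit
  lfit <- fit$lmer_fit
  b <- lme4::fixef(lfit)
  V <- as.matrix(vcov(lfit))
  L <- cbind(diag(g - 1), -1)            # contrasts gen_i - gen_g
  q <- g - 1L
  Fstat <- drop(t(L %*% b) %*% solve(L %*% V %*% t(L), L %*% b)) / q
  df2 <- (g - 1) * (e - 1)               # containment: G within GxE stratum
  out <- data.frame(term = "GEN", df1 = q, df2 = df2, F = Fstat,
                    p_value = pf(Fstat, q, df2, lower.tail = FALSE))
  class(out) <- c("met_anova", class(out))
  out
}

#' BLUP genotypic values
#'
#' `GV_ij = u_j + g_i + ge_ij`: the predicted value of genotype `i` in
#' environment `j` from the genotype-random REML fit. Complete for every
#' cell, including ones with no observed plots (BLUP prediction fills them).
#'
#' @param fit a `met_fit` with `genotype_role = "random"`.
#' @return genotype x environment numeric matrix.
#' @export
genotypic_values <- function(fit) {
  stopifnot(inherits(fit, "met_fit"))
  if (fit$genotype_role != "random")
    stop("usage error: genotypic values need a genotype-random fit; ",
         "refit with fit_met(..., genotype_role = 'random')", call. = FALSE)
  outer(fit$g, fit$env_means, `+`) + fit$ge
}

#' Broad-sense heritability
#'
#' Default is the genotype-mean basis used for predicted means across a MET:
#' `h2 = s2_g / (s2_g + s2_gei / e + s2_resid / (e r))` with `e` environments
#' and `r` blocks. `basis = "plot"` returns the plot-level share
#' `s2_g / s2_phen`.
#'
#' @param fit a genotype-random `met_fit`.
#' @param basis `"mean"` (default) or `"plot"`.
#' @return a number in `[0, 1]`.
#' @export
heritability <- function(fit, basis = c("mean", "plot")) {
  basis <- match.arg(basis)
  stopifnot(inherits(fit, "met_fit"))
  if (fit$genotype_role != "random")
    stop("usage error: heritability needs a genotype-random fit",
         call. = FALSE)
  cmp <- fit$components
  if (basis == "plot") {
    if (fit$sigma2_phen <= 0)
      stop("undefined: zero total variance", call. = FALSE)
    return(unname(cmp["sigma2_gen"] / fit$sigma2_phen))
  }
  denom <- cmp["sigma2_gen"] + cmp["sigma2_gei"] / fit$n_env +
    cmp["sigma2_resid"] / (fit$n_env * fit$n_blocks)
  if (denom <= 0) stop("undefined: zero total variance", call. = FALSE)
  unname(cmp["sigma2_gen"] / denom)
}
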