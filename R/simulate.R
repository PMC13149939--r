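#' Simulation configuration for a synthetic multi-environment trial
#'
#' Defines the layout and ground-truth parameters of a randomized complete
#' block design (RCBD) repeated across environments: additive random
#' environment, block-within-environment and genotype effects, a low-rank
#' bilinear genotype-by-environment interaction (GEI) term with a controlled
#' singular-value spectrum, and i.i.d. Gaussian residuals. Defaults mirror a
#' rice grain-yield trial of 18 genotypes in 6 environments (2 years x 3
#' locations) with 3 blocks and a grand mean of 4360 kg/ha.
#'
#' @param n_gen,n_env,n_blocks positive integers: genotypes, environments,
#'   blocks per environment.
#' @param grand_mean trait grand mean, in trait units.
#' @param sigma2_env,sigma2_block_env,sigma2_gen,sigma2_resid non-negative
#'   variances (squared trait units) of the environment, block-within-
#'   environment, genotype and residual effects.
#' @param gei_rank integer in `[0, min(n_gen, n_env) - 1]`: number of
#'   bilinear GEI axes. `0` means no interaction.
#' @param gei_mode `"lowrank"` (default): exact bilinear interaction with a
#'   controlled IPCA spectrum and zero row/column margins; `"iid"`:
#'   unstructured cell-level interaction, `GE_ij ~ N(0, sigma2_gei)` drawn
#'   independently per cell — the structure the REML variance-component
#'   model assumes, so parameter-recovery studies centre on the nominal
#'   values. In lowrank mode the genotype margins of GE are exactly zero,
#'   which attenuates the expected genotype variance estimate by
#'   `sigma2_gei / n_env`.
#' @param sigma2_gei interaction variance for `gei_mode = "iid"` (ignored
#'   in lowrank mode, where `gei_axis_scales` sets the magnitude).
#' @param gei_axis_scales non-increasing positive vector of length
#'   `gei_rank`: the singular value contributed by each axis, in trait
#'   units. See [gei_scales_for_variance()] to derive scales from a target
#'   per-cell GEI variance.
#' @param n_traits number of traits to simulate (multi-trait generation
#'   correlates only the genotype effects across traits).
#' @param gen_corr `n_traits x n_traits` correlation matrix of genotype
#'   effects across traits (symmetric, PSD, unit diagonal).
#' @param trait_directions character vector, one of `"higher"`/`"lower"`
#'   per trait: the desirable direction, carried through to index stages.
#' @param seed integer root seed; independent sub-streams are derived per
#'   effect family so adding traits does not perturb earlier draws.
#'
#' @return An object of class `sim_config` (a validated list).
#' @export
#' @examples
#' cfg <- sim_config(n_gen = 18, n_env = 6, n_blocks = 3, seed = 1)
#' dat <- simulate_met(cfg)
sim_config <- function(n_gen = 18L, n_env = 6L, n_blocks = 3L,
                       grand_mean = 4360,
                       sigma2_env = 500^2,
                       sigma2_block_env = 100^2,
                       sigma2_gen = 300^2,
                       sigma2_resid = 400^2,
                       gei_rank = 3L,
                       gei_axis_scales = NULL,
                       gei_mode = c("lowrank", "iid"),
                       sigma2_gei = 0,
                       n_traits = 1L,
                       gen_corr = NULL,
                       trait_directions = NULL,
                       seed = 1L) {
  n_gen <- as.integer(n_gen); n_env <- as.integer(n_env)
  n_blocks <- as.integer(n_blocks); n_traits <- as.integer(n_traits)
  if (n_gen < 1L || n_env < 1L || n_blocks < 1L || n_traits < 1L)
    stop("invalid config: n_gen, n_env, n_blocks, n_traits must be positive",
         call. = FALSE)
  vars <- c(sigma2_env = sigma2_env, sigma2_block_env = sigma2_block_env,
            sigma2_gen = sigma2_gen, sigma2_resid = sigma2_resid)
  if (any(!is.finite(vars)) || any(vars < 0))
    stop("invalid config: variances must be finite and non-negative",
         call. = FALSE)
  gei_mode <- match.arg(gei_mode)
  if (gei_mode == "iid") {
    if (!is.finite(sigma2_gei) || sigma2_gei < 0)
      stop("invalid config: sigma2_gei must be finite and non-negative",
           call. = FALSE)
    gei_rank <- 0L
    gei_axis_scales <- numeric(0)
  }
  gei_rank <- as.integer(gei_rank)
  max_rank <- min(n_gen, n_env) - 1L
  if (gei_rank < 0L || gei_rank > max_rank)
    stop(sprintf("invalid config: gei_rank must be in [0, %d]", max_rank),
         call. = FALSE)
  if (is.null(gei_axis_scales)) {
    # default spectrum: dominant first axis, decaying like a field trial's
    # IPCA scree (roughly 70/15/10 shares of the interaction sum of squares)
    gei_axis_scales <- if (gei_rank > 0L) {
      shares <- c(0.70, 0.15, 0.10, rep(0.05, max(0L, gei_rank - 3L)))[seq_len(gei_rank)]
      shares <- shares / sum(shares)
      sqrt(shares * 220^2 * n_gen * n_env)
    } else numeric(0)
  }
  gei_axis_scales <- as.numeric(gei_axis_scales)
  if (length(gei_axis_scales) != gei_rank)
    stop("invalid config: gei_axis_scales must have length gei_rank",
         call. = FALSE)
  if (gei_rank > 0L) {
    if (any(gei_axis_scales <= 0))
      stop("invalid config: gei_axis_scales must be positive", call. = FALSE)
    if (any(diff(gei_axis_scales) > 1e-12))
      stop("invalid config: gei_axis_scales must be non-increasing",
           call. = FALSE)
  }
  if (is.null(gen_corr)) gen_corr <- diag(n_traits)
  gen_corr <- as.matrix(gen_corr)
  if (!all(dim(gen_corr) == n_traits))
    stop("invalid config: gen_corr must be n_traits x n_traits", call. = FALSE)
  if (max(abs(gen_corr - t(gen_corr))) > 1e-8 ||
      max(abs(diag(gen_corr) - 1)) > 1e-8)
    stop("invalid config: gen_corr must be symmetric with unit diagonal",
         call. = FALSE)
  ev <- eigen(gen_corr, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8)
    stop("invalid config: gen_corr must be positive semi-definite",
         call. = FALSE)
  if (is.null(trait_directions)) trait_directions <- rep("higher", n_traits)
  trait_directions <- match.arg(trait_directions, c("higher", "lower"),
                                several.ok = TRUE)
  if (length(trait_directions) == 1L)
    trait_directions <- rep(trait_directions, n_traits)
  if (length(trait_directions) != n_traits)
    stop("invalid config: trait_directions must cover every trait",
         call. = FALSE)
  structure(list(
    n_gen = n_gen, n_env = n_env, n_blocks = n_blocks,
    grand_mean = grand_mean,
    sigma2_env = sigma2_env, sigma2_block_env = sigma2_block_env,
    sigma2_gen = sigma2_gen, sigma2_resid = sigma2_resid,
    gei_rank = gei_rank, gei_axis_scales = gei_axis_scales,
    gei_mode = gei_mode, sigma2_gei = sigma2_gei,
    n_traits = n_traits, gen_corr = gen_corr,
    trait_directions = trait_directions,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("MET simulation config:", x$n_gen, "genotypes x", x$n_env,
      "environments x", x$n_blocks, "blocks,", x$n_traits, "trait(s)\n")
  cat("  grand mean", x$grand_mean,
      "| var(E, B(E), G, resid) =", x$sigma2_env, x$sigma2_block_env,
      x$sigma2_gen, x$sigma2_resid, "\n")
  cat("  GEI rank", x$gei_rank,
      if (x$gei_rank > 0) paste("scales", paste(signif(x$gei_axis_scales, 4),
                                                collapse = ", ")) else "",
      "| seed", x$seed, "\n")
  invisible(x)
}

# Deterministic sub-stream seed per (effect family, trait index): seed the
# generator with the root seed once and read the value at a fixed position
# of its output stream. Positions depend only on (family, index), so adding
# traits or families never perturbs earlier draws, and nearby root seeds
# give decorrelated sub-seeds (a linear hash of the root seed does not —
# consecutive seeds then share structure across replicate studies).
substream_seed <- function(seed, family, index = 1L) {
  families <- c("env", "block", "gen", "gei", "gei_u", "gei_v", "resid")
  fam <- match(family, families)
  if (is.na(fam)) stop("unknown effect family: ", family, call. = FALSE)
  index <- as.integer(index)
  if (index < 1L || index > 512L)
    stop("substream index out of range [1, 512]", call. = FALSE)
  pos <- (fam - 1L) * 512L + index
  set.seed(as.integer(as.double(seed) %% 2147483647))
  sample.int(2147483646L, pos)[pos]
}

#' Low-rank bilinear genotype-by-environment interaction matrix
#'
#' Builds `sum_k scale_k * u_k v_k'` with random orthonormal axis vectors
#' `u_k` (genotypes) and `v_k` (environments), each centered so that every
#' row and column of the result sums to zero — the double-centering the
#' AMMI/IPCA decomposition assumes. The singular values of the result equal
#' `axis_scales`, giving full control over the IPCA spectrum of the
#' simulated interaction.
#'
#' @param n_gen,n_env matrix dimensions.
#' @param rank number of bilinear axes, at most `min(n_gen, n_env) - 1`.
#' @param axis_scales positive non-increasing vector of singular values,
#'   length `rank`.
#' @param seed integer seed.
#' @return `n_gen x n_env` numeric matrix with zero row and column sums.
#' @export
#' @examples
#' ge <- make_gei_lowrank(10, 5, rank = 2, axis_scales = c(3, 1), seed = 7)
#' svd(ge)$d[1:2]  # 3, 1
make_gei_lowrank <- function(n_gen, n_env, rank, axis_scales, seed) {
  n_gen <- as.integer(n_gen); n_env <- as.integer(n_env)
  rank <- as.integer(rank)
  max_rank <- min(n_gen, n_env) - 1L
  if (rank < 0L || rank > max_rank)
    stop(sprintf("invalid config: rank must be in [0, %d]", max_rank),
         call. = FALSE)
  if (rank == 0L) return(matrix(0, n_gen, n_env))
  if (length(axis_scales) != rank || any(axis_scales <= 0))
    stop("invalid config: axis_scales must be positive, length rank",
         call. = FALSE)
  centered_orthonormal <- function(n, k, s) {
    set.seed(s)
    m <- matrix(rnorm(n * k), n, k)
    m <- sweep(m, 2, colMeans(m))          # orthogonal to the ones vector
    qr.Q(qr(m))[, seq_len(k), drop = FALSE] # Gram-Schmidt keeps centering
  }
  u <- centered_orthonormal(n_gen, rank, substream_seed(seed, "gei_u"))
  v <- centered_orthonormal(n_env, rank, substream_seed(seed, "gei_v"))
  u %*% (axis_scales * t(v))
}

#' Axis scales matching a target per-cell GEI variance
#'
#' Converts a nominal interaction variance component into the
#' `axis_scales` argument of [make_gei_lowrank()]: equal scales such that
#' the interaction sum of squares equals
#' `sigma2_gei * (n_gen - 1) * (n_env - 1)`, the expected sum of squares of
#' a double-centered i.i.d. Gaussian interaction with that variance. With
#' `rank = min(n_gen, n_env) - 1` this emulates unstructured cell-level GEI
#' whose REML variance component centres on `sigma2_gei`.
#'
#' @param sigma2_gei target interaction variance (squared trait units).
#' @param n_gen,n_env layout dimensions.
#' @param rank number of axes.
#' @return numeric vector of length `rank`.
#' @export
gei_scales_for_variance <- function(sigma2_gei, n_gen, n_env,
                                    rank = min(n_gen, n_env) - 1L) {
  if (sigma2_gei < 0) stop("sigma2_gei must be non-negative", call. = FALSE)
  if (rank == 0L) return(numeric(0))
  ss <- sigma2_gei * (n_gen - 1) * (n_env - 1)
  rep(sqrt(ss / rank), rank)
}

met_layout <- function(cfg) {
  expand.grid(
    BLOCK = sprintf("B%d", seq_len(cfg$n_blocks)),
    GEN = sprintf("G%d", seq_len(cfg$n_gen)),
    ENV = sprintf("E%d", seq_len(cfg$n_env)),
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
}

simulate_one_trait <- function(cfg, trait_idx, gen_effects) {
  draw <- function(family, n, s2) {
    set.seed(substream_seed(cfg$seed, family, trait_idx))
    if (s2 > 0) rnorm(n, 0, sqrt(s2)) else numeric(n)
  }
  env_eff <- draw("env", cfg$n_env, cfg$sigma2_env)
  blk_eff <- matrix(draw("block", cfg$n_blocks * cfg$n_env,
                         cfg$sigma2_block_env),
                    cfg$n_blocks, cfg$n_env)
  ge <- if (cfg$gei_mode == "iid" && cfg$sigma2_gei > 0) {
    set.seed(substream_seed(cfg$seed, "gei", trait_idx))
    matrix(rnorm(cfg$n_gen * cfg$n_env, 0, sqrt(cfg$sigma2_gei)),
           cfg$n_gen, cfg$n_env)
  } else if (cfg$gei_rank > 0L) {
    make_gei_lowrank(cfg$n_gen, cfg$n_env, cfg$gei_rank, cfg$gei_axis_scales,
                     substream_seed(cfg$seed, "gei", trait_idx))
  } else matrix(0, cfg$n_gen, cfg$n_env)
  layout <- met_layout(cfg)
  ib <- as.integer(sub("^B", "", layout$BLOCK))
  ig <- as.integer(sub("^G", "", layout$GEN))
  ie <- as.integer(sub("^E", "", layout$ENV))
  resid <- draw("resid", nrow(layout), cfg$sigma2_resid)
  value <- cfg$grand_mean + env_eff[ie] + blk_eff[cbind(ib, ie)] +
    gen_effects[ig] + ge[cbind(ig, ie)] + resid
  list(
    records = tibble::tibble(
      ENV = layout$ENV, GEN = layout$GEN, BLOCK = layout$BLOCK,
      TRAIT = sprintf("T%d", trait_idx), VALUE = value
    ),
    truth = list(env = setNames(env_eff, sprintf("E%d", seq_len(cfg$n_env))),
                 block_env = blk_eff,
                 gen = setNames(gen_effects, sprintf("G%d", seq_len(cfg$n_gen))),
                 gei = ge,
                 resid = resid)
  )
}

#' Simulate a single-trait multi-environment RCBD trial
#'
#' Generates plot values
#' `y_ijk = mu + E_j + B_k(j) + G_i + GE_ij + e_ijk` with independent
#' zero-mean Gaussian effects at the configured variances and a low-rank
#' bilinear GEI term from [make_gei_lowrank()]. The realized effect vectors
#' travel with the dataset as a `truth` attribute for parameter-recovery
#' checks; the same seed always reproduces the identical dataset.
#'
#' @param cfg a [sim_config()].
#' @return A tibble of class `met_data` with columns
#'   `ENV, GEN, BLOCK, TRAIT, VALUE` and attribute `truth` (list of realized
#'   effects, one entry per trait).
#' @export
simulate_met <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(substream_seed(cfg$seed, "gen", 1L))
  gen_effects <- if (cfg$sigma2_gen > 0)
    rnorm(cfg$n_gen, 0, sqrt(cfg$sigma2_gen)) else numeric(cfg$n_gen)
  one <- simulate_one_trait(cfg, 1L, gen_effects)
  out <- one$records
  attr(out, "truth") <- list(T1 = one$truth)
  class(out) <- c("met_data", class(out))
  out
}

#' Simulate a multi-trait multi-environment RCBD trial
#'
#' As [simulate_met()], but genotype effect vectors are drawn jointly across
#' traits from a zero-mean Gaussian with covariance
#' `diag(sd_g) %*% gen_corr %*% diag(sd_g)`; environment, block and residual
#' effects are independent per trait. Each trait's marginal model is
#' identical to the single-trait generator.
#'
#' @param cfg a [sim_config()] with `n_traits >= 2`.
#' @return A `met_data` tibble with one `TRAIT` level per trait and a
#'   `truth` attribute holding realized effects per trait.
#' @export
simulate_multitrait_met <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$n_traits < 2L)
    stop("use simulate_met() for a single trait", call. = FALSE)
  # joint genotype effects: Cholesky-like factor via eigen (PSD-safe)
  ev <- eigen(cfg$gen_corr, symmetric = TRUE)
  rot <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), cfg$n_traits)
  set.seed(substream_seed(cfg$seed, "gen", 1L))
  z <- matrix(rnorm(cfg$n_gen * cfg$n_traits), cfg$n_gen, cfg$n_traits)
  gen_mat <- sqrt(cfg$sigma2_gen) * (z %*% t(rot))
  pieces <- lapply(seq_len(cfg$n_traits), function(t)
    simulate_one_trait(cfg, t, gen_mat[, t]))
  out <- do.call(rbind, lapply(pieces, `[[`, "records"))
  truth <- lapply(pieces, `[[`, "truth")
  names(truth) <- sprintf("T%d", seq_len(cfg$n_traits))
  attr(out, "truth") <- truth
  class(out) <- c("met_data", class(out))
  out
}

#' Ground truth attached to a simulated dataset
#' @param data a `met_data` tibble from [simulate_met()] or
#'   [simulate_multitrait_met()].
#' @return named list of realized effect vectors per trait.
#' @export
met_truth <- function(data) attr(data, "truth")
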