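#' Singular value decomposition of the BLUP GEI matrix into IPCA axes
#'
#' Decomposes the genotype-by-environment interaction BLUP matrix into
#' interaction principal component axes (IPCA). Scores use the symmetric
#' scaling `singular vector * sqrt(lambda)` for both margins, so summing
#' `genotype score x environment score` over axes reconstructs the matrix.
#' Explained proportions are `EP_k = lambda_k^2 / sum(lambda^2)`. Each axis
#' sign is fixed so the genotype score largest in magnitude is positive.
#'
#' @param ge genotype x environment numeric matrix (typically `fit$ge` or
#'   the double-centered part of a genotypic-value matrix).
#' @return list of class `ipca_decomp`: `lambda` (descending singular
#'   values), `gen_scores`, `env_scores` (matrices with one column per
#'   axis), `ep` (explained proportions), `n_axes`.
#' @export
#' @examples
#' dec <- gei_svd(matrix(c(1, -1, -1, 1), 2, 2))
#' dec$ep  # first axis explains everything
gei_svd <- function(ge) {
  ge <- as.matrix(ge)
  if (any(!is.finite(ge))) stop("ge must be finite", call. = FALSE)
  if (nrow(ge) < 2L || ncol(ge) < 2L)
    stop("ge must be at least 2 x 2", call. = FALSE)
  n_max <- min(dim(ge)) - 1L
  if (max(abs(ge)) < 1e-12) {
    warning("all-zero interaction matrix: no IPCA axes", call. = FALSE)
    return(structure(list(
      lambda = numeric(0),
      gen_scores = matrix(0, nrow(ge), 0, dimnames = list(rownames(ge), NULL)),
      env_scores = matrix(0, ncol(ge), 0, dimnames = list(colnames(ge), NULL)),
      ep = numeric(0), n_axes = 0L
    ), class = "ipca_decomp"))
  }
  s <- svd(ge)
  keep <- which(s$d > max(s$d) * 1e-12)
  keep <- keep[seq_len(min(length(keep), n_max))]
  lambda <- s$d[keep]
  u <- s$u[, keep, drop = FALSE]
  v <- s$v[, keep, drop = FALSE]
  for (k in seq_along(keep)) {     # deterministic sign: top |gen score| > 0
    i <- which.max(abs(u[, k]))
    if (u[i, k] < 0) { u[, k] <- -u[, k]; v[, k] <- -v[, k] }
  }
  gen_scores <- sweep(u, 2, sqrt(lambda), `*`)
  env_scores <- sweep(v, 2, sqrt(lambda), `*`)
  rownames(gen_scores) <- rownames(ge)
  rownames(env_scores) <- colnames(ge)
  colnames(gen_scores) <- colnames(env_scores) <- paste0("IPCA", seq_along(keep))
  structure(list(lambda = lambda, gen_scores = gen_scores,
                 env_scores = env_scores, ep = lambda^2 / sum(lambda^2),
                 n_axes = length(keep)),
            class = "ipca_decomp")
}

#' @export
print.ipca_decomp <- function(x, ...) {
  cat("IPCA decomposition:", x$n_axes, "axes\n")
  if (x$n_axes > 0)
    print(data.frame(axis = seq_len(x$n_axes), lambda = x$lambda,
                     explained = x$ep, cumulative = cumsum(x$ep)),
          row.names = FALSE, digits = 4)
  invisible(x)
}

#' WAASB: weighted average of absolute IPCA scores
#'
#' `WAASB_i = sum_k |IPCA_ik| EP_k / sum_k EP_k` over the first `n_axes`
#' axes (default all). The genotype with the lowest WAASB is the most
#' stable; a genotype contributing nothing to the interaction scores 0.
#' Environment WAASB is computed identically from environment scores.
#'
#' @param decomp an `ipca_decomp` from [gei_svd()].
#' @param n_axes number of axes to use, or `"all"`.
#' @param margin `"gen"` or `"env"`.
#' @return named non-negative vector, one value per genotype (or
#'   environment).
#' @export
waasb_scores <- function(decomp, n_axes = "all", margin = c("gen", "env")) {
  margin <- match.arg(margin)
  stopifnot(inherits(decomp, "ipca_decomp"))
  scores <- if (margin == "gen") decomp$gen_scores else decomp$env_scores
  if (identical(n_axes, "all")) n_axes <- decomp$n_axes
  n_axes <- as.integer(n_axes)
  if (n_axes > decomp$n_axes)
    stop("n_axes exceeds available axes (", decomp$n_axes, ")",
         call. = FALSE)
  if (n_axes == 0L) {
    warning("no IPCA axes: WAASB is zero for every entry", call. = FALSE)
    return(setNames(rep(0, nrow(scores)), rownames(scores)))
  }
  ep <- decomp$ep[seq_len(n_axes)]
  w <- abs(scores[, seq_len(n_axes), drop = FALSE]) %*% ep / sum(ep)
  setNames(drop(w), rownames(scores))
}

#' Rescale values to the 0-100 desirability scale
#'
#' Linear map to `[0, 100]`: with `direction = "higher"` the maximum maps to
#' 100; with `"lower"` the minimum maps to 100. Used for the rescaled mean
#' performance (`rG`) and rescaled WAASB (`rW`) entering the WAASBY index.
#'
#' @param values numeric vector with at least 2 distinct values.
#' @param direction `"higher"` or `"lower"` = which end is desirable.
#' @return numeric vector in `[0, 100]`, names preserved.
#' @export
rescale_0_100 <- function(values, direction = c("higher", "lower")) {
  direction <- match.arg(direction)
  rng <- range(values)
  if (diff(rng) == 0) {
    warning("constant vector: rescaled values set to 50", call. = FALSE)
    return(setNames(rep(50, length(values)), names(values)))
  }
  out <- 100 * (values - rng[1]) / diff(rng)
  if (direction == "lower") out <- 100 - out
  out
}

#' WAASBY: weighted superiority index of performance and stability
#'
#' `WAASBY_i = (rG_i * theta_y + rW_i * theta_s) / (theta_y + theta_s)`,
#' where `rG` is mean performance rescaled 0-100 in the trait's desirable
#' direction and `rW` is WAASB rescaled 0-100 with lower WAASB better.
#' Equal weights give equal emphasis on performance and stability.
#'
#' @param mean_perf per-genotype predicted means (trait units).
#' @param waasb per-genotype WAASB values.
#' @param theta_y,theta_s non-negative weights for performance and
#'   stability; they need not sum to any constant.
#' @param direction desirable direction of the trait (`"higher"`/`"lower"`).
#' @return named vector of WAASBY values in `[0, 100]`.
#' @export
waasby <- function(mean_perf, waasb, theta_y = 50, theta_s = 50,
                   direction = c("higher", "lower")) {
  direction <- match.arg(direction)
  if (theta_y < 0 || theta_s < 0 || theta_y + theta_s <= 0)
    stop("usage error: weights must be non-negative with a positive sum",
         call. = FALSE)
  stopifnot(length(mean_perf) == length(waasb))
  rg <- rescale_0_100(mean_perf, direction)
  rw <- rescale_0_100(waasb, "lower")
  (rg * theta_y + rw * theta_s) / (theta_y + theta_s)
}

#' Performance/stability quadrant classification
#'
#' Splits the mean-performance x WAASB plane at the unweighted means of the
#' two coordinates. Quadrant I: below-mean performance, above-mean WAASB
#' (unstable, low-yielding); II: above, above (high-yielding, unstable);
#' III: below, below (stable, low-yielding); IV: above-mean performance and
#' below-mean WAASB — the desirable corner. Values equal to a divider count
#' as the desirable side. Applies to genotypes and environments alike.
#'
#' @param mean_perf,waasb numeric vectors, same length.
#' @return character vector of labels `"I" ... "IV"`.
#' @export
quadrant_classify <- function(mean_perf, waasb) {
  stopifnot(length(mean_perf) == length(waasb),
            all(is.finite(mean_perf)), all(is.finite(waasb)))
  hi_perf <- mean_perf >= mean(mean_perf)
  lo_waasb <- waasb <= mean(waasb)
  out <- ifelse(hi_perf & !lo_waasb, "II",
         ifelse(hi_perf & lo_waasb, "IV",
         ifelse(!hi_perf & lo_waasb, "III", "I")))
  setNames(out, names(mean_perf))
}

#' Per-genotype stability table
#'
#' Convenience wrapper combining predicted means, WAASB, the 0-100
#' rescalings, WAASBY and quadrant labels for one trait.
#'
#' @param fit genotype-random `met_fit`.
#' @param n_axes axes used for WAASB (default all).
#' @param theta_y,theta_s WAASBY weights.
#' @param direction desirable direction of the trait.
#' @return tibble of class `stability_table` with columns
#'   `GEN, MEAN, WAASB, rG, rW, WAASBY, QUADRANT`.
#' @export
stability_table <- function(fit, n_axes = "all", theta_y = 50, theta_s = 50,
                            direction = c("higher", "lower")) {
  direction <- match.arg(direction)
  stopifnot(inherits(fit, "met_fit"))
  if (fit$genotype_role != "random")
    stop("usage error: stability table needs a genotype-random fit",
         call. = FALSE)
  dec <- gei_svd(fit$ge)
  wb <- waasb_scores(dec, n_axes = n_axes)
  mean_perf <- fit$mu_hat + fit$g            # predicted mean across envs
  rg <- rescale_0_100(mean_perf, direction)
  rw <- rescale_0_100(wb, "lower")
  wy <- waasby(mean_perf, wb, theta_y, theta_s, direction)
  out <- tibble::tibble(
    GEN = names(fit$g), MEAN = unname(mean_perf), WAASB = unname(wb[names(fit$g)]),
    rG = unname(rg), rW = unname(rw[names(fit$g)]), WAASBY = unname(wy),
    QUADRANT = unname(quadrant_classify(mean_perf, wb[names(fit$g)]))
  )
  class(out) <- c("stability_table", class(out))
  out
}

#' Genotype ranks across a stability-weight grid
#'
#' For each stability weight `theta_s` on the grid `0, step, ..., 100`
#' (with `theta_y = 100 - theta_s`), ranks genotypes by WAASBY descending
#' (rank 1 = best). Ties are broken by genotype label order.
#'
#' @param mean_perf,waasb per-genotype vectors (names used as labels).
#' @param grid_step positive integer dividing 100.
#' @param direction desirable direction of the trait.
#' @return list of class `weight_grid`: `theta_s` (grid) and `ranks`
#'   (genotype x weight integer matrix; every column a permutation).
#' @export
rank_across_weights <- function(mean_perf, waasb, grid_step = 5,
                                direction = c("higher", "lower")) {
  direction <- match.arg(direction)
  if (100 %% grid_step != 0)
    stop("grid_step must divide 100", call. = FALSE)
  theta_s <- seq(0, 100, by = grid_step)
  labels <- names(mean_perf)
  if (is.null(labels)) labels <- sprintf("G%d", seq_along(mean_perf))
  ranks <- sapply(theta_s, function(ts) {
    wy <- waasby(mean_perf, waasb, theta_y = 100 - ts, theta_s = ts,
                 direction = direction)
    rank(-wy, ties.method = "first")   # label order breaks ties
  })
  dimnames(ranks) <- list(labels, paste0("theta_s_", theta_s))
  structure(list(theta_s = theta_s, ranks = ranks), class = "weight_grid")
}
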