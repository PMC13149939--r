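#' Harmonic mean of genotypic values (HMGV)
#'
#' `HMGV_i = E / sum_j (1 / GV_ij)` over the `E` environments. Penalizes
#' genotypes with uneven performance: by the arithmetic-harmonic mean
#' inequality HMGV never exceeds the row's arithmetic mean, with equality
#' only for a constant row, so HMGV rewards stability in the trait's own
#' units.
#'
#' @param gv genotype x environment matrix of genotypic values, all > 0.
#' @return named per-genotype vector.
#' @export
hmgv <- function(gv) {
  gv <- as.matrix(gv)
  check_positive_gv(gv)
  ncol(gv) / rowSums(1 / gv)
}

#' Relative performance of genotypic values (RPGV)
#'
#' `RPGV_i = (1/E) sum_j GV_ij / u_j`: the mean across environments of the
#' genotypic value relative to the environment mean. Dimensionless; 1 means
#' average performance, and multiplying by the overall mean returns it to
#' trait units ([scale_by_mean()]).
#'
#' @param gv genotype x environment matrix of genotypic values.
#' @param env_means per-environment means `u_j`, all > 0 (length =
#'   `ncol(gv)`).
#' @return named per-genotype vector.
#' @export
rpgv <- function(gv, env_means) {
  gv <- as.matrix(gv)
  if (length(env_means) != ncol(gv))
    stop("env_means must have one entry per environment", call. = FALSE)
  if (any(env_means <= 0))
    stop("domain error: non-positive environment mean(s): ",
         paste(which(env_means <= 0), collapse = ", "), call. = FALSE)
  rowMeans(sweep(gv, 2, env_means, `/`))
}

#' Harmonic mean of relative performance of genotypic values (HMRPGV)
#'
#' `HMRPGV_i = E / sum_j (u_j / GV_ij)`: the harmonic mean of the
#' per-environment relative performances `GV_ij / u_j`. Combines stability,
#' adaptability and performance in one dimensionless number; never exceeds
#' RPGV, with equality only when relative performance is constant across
#' environments.
#'
#' @inheritParams rpgv
#' @return named per-genotype vector.
#' @export
hmrpgv <- function(gv, env_means) {
  gv <- as.matrix(gv)
  check_positive_gv(gv)
  if (length(env_means) != ncol(gv))
    stop("env_means must have one entry per environment", call. = FALSE)
  if (any(env_means <= 0))
    stop("domain error: non-positive environment mean(s): ",
         paste(which(env_means <= 0), collapse = ", "), call. = FALSE)
  ncol(gv) / rowSums(sweep(1 / gv, 2, env_means, `*`))
}

check_positive_gv <- function(gv) {
  bad <- which(gv <= 0, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    cells <- apply(bad, 1, function(ij)
      paste0("(", rownames(gv)[ij[1]] %||% ij[1], ",",
             colnames(gv)[ij[2]] %||% ij[2], ")"))
    stop("domain error: harmonic mean undefined for non-positive genotypic ",
         "values at ", paste(utils::head(cells, 10), collapse = " "),
         if (nrow(bad) > 10) " ..." else "",
         "; shift the trait explicitly before calling", call. = FALSE)
  }
  invisible(gv)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Rescale a dimensionless index to trait units
#'
#' Multiplies a relative index (RPGV, HMRPGV) by the overall mean, returning
#' it to trait units; a positive scalar, so rankings are unchanged.
#'
#' @param index per-genotype dimensionless index values.
#' @param mu overall mean, > 0.
#' @return vector in trait units.
#' @export
scale_by_mean <- function(index, mu) {
  if (mu <= 0) stop("mu must be positive", call. = FALSE)
  index * mu
}

#' Percent gain of an index or a selected set over a reference
#'
#' For a dimensionless relative index (reference 1): `100 (value - 1)`.
#' For trait-unit values against a reference mean:
#' `100 (mean(values) / reference - 1)`.
#'
#' @param values index value(s) or trait-unit values of the selected set.
#' @param reference reference mean in trait units; omit (default `NULL`)
#'   for a dimensionless index already relative to 1.
#' @return percent gain (single number).
#' @export
#' @examples
#' percent_gain(1.306)           # 30.6
#' percent_gain(c(110, 90), 100) # 0
percent_gain <- function(values, reference = NULL) {
  if (is.null(reference)) return(100 * (mean(values) - 1))
  if (reference <= 0) stop("reference must be positive", call. = FALSE)
  100 * (mean(values) / reference - 1)
}

#' Genotypic-value index table (HMGV / RPGV / HMRPGV)
#'
#' Computes all three genotypic-value indices from a fitted model, the
#' trait-unit rescalings RPGV*mu and HMRPGV*mu, and the ranking by HMRPGV.
#'
#' @param fit genotype-random `met_fit`, or a list with elements `gv`
#'   (genotype x environment matrix) and `env_means`.
#' @return tibble of class `gv_table` with columns
#'   `GEN, HMGV, RPGV, RPGV_MU, HMRPGV, HMRPGV_MU, RANK`, plus attributes
#'   `mu` (overall mean of genotypic values) and `n_env`.
#' @export
genotypic_value_table <- function(fit) {
  if (inherits(fit, "met_fit")) {
    gv <- genotypic_values(fit)
    u <- fit$env_means
  } else {
    gv <- as.matrix(fit$gv); u <- fit$env_means
  }
  mu <- mean(gv)
  h <- hmgv(gv)
  r <- rpgv(gv, u)
  hr <- hmrpgv(gv, u)
  out <- tibble::tibble(
    GEN = rownames(gv),
    HMGV = unname(h),
    RPGV = unname(r), RPGV_MU = unname(scale_by_mean(r, mu)),
    HMRPGV = unname(hr), HMRPGV_MU = unname(scale_by_mean(hr, mu)),
    RANK = unname(rank(-hr, ties.method = "first"))
  )
  attr(out, "mu") <- mu
  attr(out, "n_env") <- ncol(gv)
  class(out) <- c("gv_table", class(out))
  out
}
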