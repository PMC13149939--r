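#' Genotype x trait WAASBY index matrix
#'
#' Stacks per-trait stability tables into the genotype-by-trait matrix of
#' WAASBY values that feeds the multi-trait stability index. Each column is
#' computed with its trait's desirability direction, so 100 is always best:
#' for lower-better traits (e.g. plant height, unfilled grains) the
#' performance rescaling is reversed before blending with stability.
#'
#' @param per_trait_stability named list of `stability_table` objects, one
#'   per trait (built with the right `direction` per trait).
#' @return genotype x trait numeric matrix of class `index_matrix`, entries
#'   in `[0, 100]`.
#' @export
build_index_matrix <- function(per_trait_stability) {
  stopifnot(is.list(per_trait_stability), length(per_trait_stability) >= 1)
  traits <- names(per_trait_stability)
  if (is.null(traits) || any(traits == ""))
    stop("per_trait_stability must be a named list (trait names)",
         call. = FALSE)
  gens <- per_trait_stability[[1]]$GEN
  cols <- lapply(traits, function(tr) {
    st <- per_trait_stability[[tr]]
    if (!setequal(st$GEN, gens) || length(st$GEN) != length(gens))
      stop("alignment error: trait ", tr,
           " has a different genotype set (",
           paste(symdiff_chr(st$GEN, gens), collapse = ", "), ")",
           call. = FALSE)
    setNames(st$WAASBY, st$GEN)[gens]
  })
  m <- do.call(cbind, cols)
  dimnames(m) <- list(gens, traits)
  constant <- apply(m, 2, function(x) diff(range(x)) == 0)
  if (any(constant))
    stop("constant WAASBY column(s): ", paste(traits[constant], collapse = ", "),
         call. = FALSE)
  class(m) <- c("index_matrix", class(m))
  m
}

symdiff_chr <- function(a, b) union(setdiff(a, b), setdiff(b, a))

# population (n) standardization used throughout the factor-analysis stage
pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

varimax_criterion <- function(L) {
  # raw varimax objective: sum over factors of the variance of squared loadings
  sum(apply(L^2, 2, function(s) mean((s - mean(s))^2)))
}

#' Exploratory factor analysis of an index matrix
#'
#' Principal-component extraction from the trait correlation matrix:
#' factors with eigenvalue >= 1 are retained (Kaiser rule, minimum one),
#' initial loadings are `eigenvector * sqrt(eigenvalue)`, and retained
#' loadings are varimax-rotated (Kaiser-normalized, tolerance 1e-6).
#' Communality is the row sum of squared rotated loadings; factor scores use
#' the regression method `Z R^-1 L` with `Z` the column-standardized matrix
#' (population SD), `R` the correlation matrix and `L` the rotated loadings.
#'
#' @param m an `index_matrix` (or any genotype x trait numeric matrix).
#' @return list of class `factor_model`: `eigenvalues`, `n_retained`,
#'   `loadings` (trait x factor, rotated), `communality`, `uniqueness`,
#'   `scores` (genotype x factor), `rotation` matrix, `means`/`sds` used
#'   for standardization, `criterion_before`/`criterion_after` (varimax
#'   objective).
#' @export
factor_analysis <- function(m) {
  m <- unclass(as.matrix(m))
  n_gen <- nrow(m); n_traits <- ncol(m)
  if (n_gen <= n_traits)
    warning("fewer genotypes than traits + 1: factor model is unstable",
            call. = FALSE)
  mu <- colMeans(m)
  sds <- apply(m, 2, pop_sd)
  if (any(sds == 0)) stop("constant column in index matrix", call. = FALSE)
  z <- sweep(sweep(m, 2, mu), 2, sds, `/`)
  R <- cor(m)
  ev <- eigen(R, symmetric = TRUE)
  n_ret <- max(1L, sum(ev$values >= 1))
  L0 <- ev$vectors[, seq_len(n_ret), drop = FALSE] %*%
    diag(sqrt(ev$values[seq_len(n_ret)]), n_ret)
  if (n_ret > 1L) {
    rot <- varimax(L0, normalize = TRUE, eps = 1e-6)
    L <- unclass(rot$loadings)
    rotmat <- rot$rotmat
  } else {
    L <- L0
    rotmat <- matrix(1, 1, 1)
  }
  # deterministic sign: dominant loading of each factor positive
  for (k in seq_len(n_ret)) {
    i <- which.max(abs(L[, k]))
    if (L[i, k] < 0) { L[, k] <- -L[, k]; rotmat[, k] <- -rotmat[, k] }
  }
  dimnames(L) <- list(colnames(m), paste0("FA", seq_len(n_ret)))
  communality <- rowSums(L^2)
  Rinv <- tryCatch(solve(R), error = function(e) {
    warning("singular correlation matrix: ridge-regularized inverse used",
            call. = FALSE)
    solve(R + diag(1e-8, n_traits))
  })
  scores <- z %*% Rinv %*% L
  dimnames(scores) <- list(rownames(m), colnames(L))
  structure(list(
    eigenvalues = ev$values,
    n_retained = n_ret,
    loadings = L,
    communality = communality,
    uniqueness = 1 - communality,
    scores = scores,
    rotation = rotmat,
    means = mu, sds = sds, Rinv = Rinv,
    criterion_before = varimax_criterion(L0),
    criterion_after = varimax_criterion(L)
  ), class = "factor_model")
}

#' @export
print.factor_model <- function(x, ...) {
  cat("Factor model:", x$n_retained, "factor(s) retained (eigenvalue >= 1)\n")
  cat("Eigenvalues:", paste(signif(x$eigenvalues, 4), collapse = ", "), "\n")
  cat("Explained by retained factors:",
      sprintf("%.1f%%", 100 * sum(x$eigenvalues[seq_len(x$n_retained)]) /
                length(x$eigenvalues)), "\n")
  print(round(cbind(x$loadings, communality = x$communality), 3))
  invisible(x)
}

#' Factor scores of the ideotype
#'
#' The ideotype is a virtual genotype scoring 100 (best) on every trait
#' index. Its row is standardized with the index matrix's column means and
#' SDs and pushed through the same regression score equation as the real
#' genotypes.
#'
#' @param fa a `factor_model` fitted on `m`.
#' @param m the `index_matrix` the model was fitted on.
#' @return named per-factor numeric vector.
#' @export
ideotype_scores <- function(fa, m) {
  stopifnot(inherits(fa, "factor_model"))
  m <- unclass(as.matrix(m))
  ideal <- rep(100, ncol(m))
  z <- (ideal - fa$means) / fa$sds
  drop(z %*% fa$Rinv %*% fa$loadings)
}

#' Multi-trait stability index and selection
#'
#' `MTSI_i = sqrt(sum_j (F_ij - F_j)^2)`: the Euclidean distance between a
#' genotype's factor scores and the ideotype's. Genotypes are ranked
#' ascending (closest to the ideotype first) and the
#' `max(1, round(intensity/100 * n_gen))` lowest-MTSI genotypes are selected
#' (round half up, so 18 genotypes at 15 % select 3). Factor contributions
#' `(F_ij - F_j)^2 / MTSI_i^2` show which trait group drives each
#' genotype's distance.
#'
#' @param fa a `factor_model`.
#' @param ideotype per-factor ideotype scores from [ideotype_scores()].
#' @param intensity selection intensity in percent, in `(0, 100]`.
#' @return list of class `mtsi_result`: tibble `table`
#'   (`GEN, MTSI, RANK, SELECTED`), `selected` ids, `cutoff` (MTSI of the
#'   last selected genotype), `intensity`, `n_selected`, and `contributions`
#'   (genotype x factor proportions, rows summing to 1).
#' @export
mtsi_scores <- function(fa, ideotype, intensity = 15) {
  stopifnot(inherits(fa, "factor_model"))
  if (intensity <= 0 || intensity > 100)
    stop("intensity must be in (0, 100]", call. = FALSE)
  dev <- sweep(fa$scores, 2, ideotype)
  mtsi <- sqrt(rowSums(dev^2))
  n_gen <- length(mtsi)
  n_sel <- max(1L, as.integer(floor(intensity / 100 * n_gen + 0.5)))
  ord <- order(mtsi, names(mtsi))      # label order breaks exact ties
  rank_vec <- integer(n_gen); rank_vec[ord] <- seq_len(n_gen)
  selected <- names(mtsi)[ord[seq_len(n_sel)]]
  contrib <- dev^2 / ifelse(mtsi^2 > 0, mtsi^2, 1)
  contrib[mtsi == 0, ] <- 1 / ncol(dev)  # at the ideotype: equal shares
  tab <- tibble::tibble(GEN = names(mtsi), MTSI = unname(mtsi),
                        RANK = rank_vec,
                        SELECTED = names(mtsi) %in% selected)
  structure(list(table = tab, selected = selected,
                 cutoff = unname(mtsi[ord[n_sel]]),
                 intensity = intensity, n_selected = n_sel,
                 contributions = contrib),
            class = "mtsi_result")
}

#' @export
print.mtsi_result <- function(x, ...) {
  cat(sprintf("MTSI selection at %g%% intensity: %d of %d genotypes (cutoff %.3f)\n",
              x$intensity, x$n_selected, nrow(x$table), x$cutoff))
  cat("Selected:", paste(x$selected, collapse = ", "), "\n")
  invisible(x)
}

#' Selection differentials and gains
#'
#' For each trait and each target scale (typically the BLUP mean performance
#' and the WAASBY index), compares the selected genotypes' mean `Xs` with
#' the population mean `X0`: selection differential `SD = Xs - X0`,
#' percentage differential `%SD = 100 SD / X0`, selection gain
#' `SG = SD * h2` and `%SG = %SD * h2`.
#'
#' @param values named list: per target name, a named per-genotype vector
#'   (names = genotype ids) on that target's scale.
#' @param selected character vector of selected genotype ids.
#' @param h2 heritability per target (single value or named vector matching
#'   `values`), each in `[0, 1]`.
#' @return tibble of class `gain_table` with columns
#'   `target, X0, Xs, SD, SD_pct, SG, SG_pct, h2`.
#' @export
selection_gains <- function(values, selected, h2) {
  stopifnot(is.list(values), length(selected) >= 1)
  if (length(h2) == 1L) h2 <- setNames(rep(h2, length(values)), names(values))
  if (any(h2 < 0 | h2 > 1)) stop("h2 must be in [0, 1]", call. = FALSE)
  rows <- lapply(names(values), function(nm) {
    v <- values[[nm]]
    if (!all(selected %in% names(v)))
      stop("selected ids missing from target ", nm, call. = FALSE)
    x0 <- mean(v); xs <- mean(v[selected])
    sd_ <- xs - x0
    sd_pct <- if (x0 != 0) 100 * sd_ / x0 else NA_real_
    tibble::tibble(target = nm, X0 = x0, Xs = xs, SD = sd_,
                   SD_pct = sd_pct, SG = sd_ * h2[[nm]],
                   SG_pct = sd_pct * h2[[nm]], h2 = h2[[nm]])
  })
  out <- do.call(rbind, rows)
  class(out) <- c("gain_table", class(out))
  out
}
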