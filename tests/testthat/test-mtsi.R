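make_stab <- function(gens, waasby_values) {
  out <- tibble::tibble(GEN = gens, MEAN = NA_real_, WAASB = NA_real_,
                        rG = NA_real_, rW = NA_real_,
                        WAASBY = waasby_values, QUADRANT = NA_character_)
  class(out) <- c("stability_table", class(out))
  out
}

test_that("the index matrix stacks per-trait WAASBY columns in genotype order", {
  gens <- paste0("G", 1:4)
  st1 <- make_stab(gens, c(10, 20, 30, 40))
  # shuffled genotype order in the second trait must be realigned
  st2 <- make_stab(gens[c(3, 1, 4, 2)], c(70, 50, 80, 60))
  m <- build_index_matrix(list(A = st1, B = st2))
  expect_equal(dim(m), c(4L, 2L))
  expect_equal(unname(m[, "A"]), c(10, 20, 30, 40))
  expect_equal(unname(m[, "B"]), c(50, 60, 70, 80))

  expect_error(build_index_matrix(list(A = st1, B = make_stab(paste0("H", 1:4), 1:4))),
               "alignment error")
  expect_error(build_index_matrix(list(A = make_stab(gens, rep(5, 4)))),
               "constant")
})

test_that("lower-better traits award the top index value to the lowest raw mean", {
  dat <- simulate_met(sim_config(n_gen = 12, seed = 19))
  fit <- fit_met(dat)
  st_low <- stability_table(fit, direction = "lower", theta_s = 0)
  expect_equal(st_low$GEN[which.max(st_low$WAASBY)],
               st_low$GEN[which.min(st_low$MEAN)])
})

test_that("two perfectly correlated traits collapse to one factor with full communality", {
  gens <- paste0("G", 1:10)
  x <- seq(10, 90, length.out = 10)
  m <- build_index_matrix(list(A = make_stab(gens, x),
                               B = make_stab(gens, x / 2 + 5)))
  expect_warning(fa <- factor_analysis(m), "singular")
  expect_equal(fa$eigenvalues, c(2, 0), tolerance = 1e-8)
  expect_equal(fa$n_retained, 1L)
  expect_equal(unname(fa$communality), c(1, 1), tolerance = 1e-6)
})

test_that("independent traits give near-unit eigenvalues and exercise the Kaiser boundary", {
  set.seed(31)
  m <- matrix(runif(2000 * 4, 0, 100), 2000, 4,
              dimnames = list(paste0("G", 1:2000), paste0("T", 1:4)))
  fa <- factor_analysis(m)
  expect_true(all(abs(fa$eigenvalues - 1) < 0.1))
  expect_equal(sum(fa$eigenvalues), 4, tolerance = 1e-8)
  expect_equal(fa$n_retained, sum(fa$eigenvalues >= 1))
  expect_gte(fa$n_retained, 1L)
})

test_that("factor-model bookkeeping: communality + uniqueness = 1, rotation never hurts", {
  set.seed(12)
  for (rep in 1:5) {
    base <- matrix(rnorm(18 * 2), 18, 2)
    m <- cbind(base, base[, 1] + rnorm(18, 0, .4),
               base[, 2] + rnorm(18, 0, .4), rnorm(18)) * 10 + 50
    dimnames(m) <- list(paste0("G", 1:18), paste0("T", 1:5))
    fa <- factor_analysis(m)
    expect_equal(unname(fa$communality + fa$uniqueness), rep(1, 5),
                 tolerance = 1e-8)
    expect_true(all(fa$communality >= 0 & fa$communality <= 1 + 1e-8))
    expect_gte(fa$criterion_after, fa$criterion_before - 1e-12)
  }
})

pop_sd_test <- function(x) sqrt(mean((x - mean(x))^2))

test_that("regression factor scores match the explicit Z R^-1 L product", {
  set.seed(5)
  m <- matrix(runif(8 * 3, 20, 90), 8, 3,
              dimnames = list(paste0("G", 1:8), paste0("T", 1:3)))
  fa <- factor_analysis(m)
  z <- sweep(sweep(m, 2, colMeans(m)), 2, apply(m, 2, pop_sd_test), `/`)
  expected <- z %*% solve(cor(m)) %*% fa$loadings
  expect_equal(unname(fa$scores), unname(expected), tolerance = 1e-10)
  # a genotype identical to the ideotype row would get the ideotype scores
  ideo <- ideotype_scores(fa, m)
  z100 <- (rep(100, 3) - colMeans(m)) / apply(m, 2, pop_sd_test)
  expect_equal(unname(ideo),
               unname(drop(z100 %*% solve(cor(m)) %*% fa$loadings)),
               tolerance = 1e-10)
})

test_that("MTSI is the Euclidean distance to the ideotype with exact contributions", {
  fa <- structure(list(
    scores = matrix(c(0, 3, 1, 0, 4, 1), 3, 2,
                    dimnames = list(c("G1", "G2", "G3"), c("FA1", "FA2"))),
    n_retained = 2L), class = "factor_model")
  ideo <- c(FA1 = 0, FA2 = 0)
  res <- mtsi_scores(fa, ideo, intensity = 40)
  expect_equal(res$table$MTSI, c(0, 5, sqrt(2)))
  expect_equal(res$table$RANK, c(1L, 3L, 2L))
  # deviations (3, 4): contributions 9/25 and 16/25
  expect_equal(unname(res$contributions["G2", ]), c(0.36, 0.64))
  expect_equal(unname(rowSums(res$contributions)), rep(1, 3), tolerance = 1e-10)
  # genotype at the ideotype: distance 0, rank 1
  expect_equal(res$table$GEN[res$table$RANK == 1], "G1")
  expect_error(mtsi_scores(fa, ideo, intensity = 0), "intensity")
})

test_that("selection count rounds half up with a floor of one", {
  mk <- function(n) structure(list(
    scores = matrix(seq_len(n), n, 1,
                    dimnames = list(paste0("G", seq_len(n)), "FA1")),
    n_retained = 1L), class = "factor_model")
  expect_equal(mtsi_scores(mk(18), c(FA1 = 0), 15)$n_selected, 3L)
  expect_equal(mtsi_scores(mk(20), c(FA1 = 0), 15)$n_selected, 3L)
  expect_equal(mtsi_scores(mk(10), c(FA1 = 0), 15)$n_selected, 2L)  # 1.5 up
  expect_equal(mtsi_scores(mk(4), c(FA1 = 0), 5)$n_selected, 1L)    # floor
  # selected set = lowest-MTSI genotypes, cutoff = last selected
  r <- mtsi_scores(mk(18), c(FA1 = 0), 15)
  expect_equal(r$selected, c("G1", "G2", "G3"))
  expect_equal(r$cutoff, 3)
})

test_that("MTSI behaves as a metric and is invariant to joint orthogonal rotation", {
  set.seed(9)
  scores <- matrix(rnorm(12 * 2), 12, 2,
                   dimnames = list(paste0("G", 1:12), c("FA1", "FA2")))
  fa <- structure(list(scores = scores, n_retained = 2L),
                  class = "factor_model")
  ideo <- c(FA1 = 1, FA2 = -1)
  d <- mtsi_scores(fa, ideo, 25)$table$MTSI
  expect_true(all(d >= 0))
  # triangle inequality on random triples (distance to ideotype vs pairwise)
  for (rep in 1:10) {
    ij <- sample(12, 2)
    dij <- sqrt(sum((scores[ij[1], ] - scores[ij[2], ])^2))
    expect_lte(d[ij[1]], d[ij[2]] + dij + 1e-12)
  }
  # joint rotation of scores and ideotype preserves every distance
  th <- 0.7; R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  fa_rot <- structure(list(scores = scores %*% R, n_retained = 2L),
                      class = "factor_model")
  d_rot <- mtsi_scores(fa_rot, drop(ideo %*% R), 25)$table$MTSI
  expect_equal(d_rot, d, tolerance = 1e-10)
})

test_that("moving a genotype's whole profile toward the ideotype shrinks its distance", {
  set.seed(14)
  m <- matrix(runif(15 * 4, 30, 90), 15, 4,
              dimnames = list(paste0("G", 1:15), paste0("T", 1:4)))
  fa <- factor_analysis(m)
  ideo <- ideotype_scores(fa, m)
  d0 <- sqrt(rowSums(sweep(fa$scores, 2, ideo)^2))
  # frozen loadings/standardization: pull the full row halfway to 100s —
  # the score map is affine, so the distance must halve exactly
  for (g in c(2, 7, 11)) {
    row2 <- m[g, ] + 0.5 * (100 - m[g, ])
    z2 <- (row2 - fa$means) / fa$sds
    s2 <- drop(z2 %*% fa$Rinv %*% fa$loadings)
    d2 <- sqrt(sum((s2 - ideo)^2))
    expect_equal(d2, 0.5 * d0[[g]], tolerance = 1e-10)
  }
})

test_that("selection differentials and gains follow the differential x heritability rule", {
  vals <- list(yield = c(G1 = 120, G2 = 100, G3 = 80))
  g <- selection_gains(vals, selected = "G1", h2 = 0.5)
  expect_equal(g$X0, 100); expect_equal(g$Xs, 120)
  expect_equal(g$SD, 20); expect_equal(g$SD_pct, 20)
  expect_equal(g$SG, 10); expect_equal(g$SG_pct, 10)
  # worked arithmetic: Xs 110, X0 100, h2 .5 -> SD 10, SG 5
  g2 <- selection_gains(list(t = c(A = 110, B = 105, C = 85)),
                        selected = c("A"), h2 = 0.5)
  expect_equal(g2$SD, 10); expect_equal(g2$SG, 5)
  # whole population selected: zero differential; h2 = 0: zero gain
  gall <- selection_gains(vals, selected = paste0("G", 1:3), h2 = 1)
  expect_equal(gall$SD, 0)
  g0 <- selection_gains(vals, selected = "G1", h2 = 0)
  expect_equal(g0$SG, 0)
  expect_error(selection_gains(vals, "G9", 0.5), "missing")
  expect_error(selection_gains(vals, "G1", 1.5), "h2")
})

test_that("the eight-trait synthetic pipeline yields a well-formed index matrix and selection", {
  dat <- simulate_multitrait_met(sim_config(n_traits = 8, seed = 77))
  fits <- lapply(paste0("T", 1:8), function(tr) fit_met(dat, tr))
  names(fits) <- paste0("T", 1:8)
  stabs <- lapply(fits, stability_table)
  m <- build_index_matrix(stabs)
  expect_equal(dim(m), c(18L, 8L))
  expect_true(all(m >= 0 & m <= 100))
  fa <- factor_analysis(m)
  res <- mtsi_scores(fa, ideotype_scores(fa, m), 15)
  expect_equal(res$n_selected, 3L)
  expect_equal(sort(res$table$MTSI[res$table$SELECTED]),
               sort(res$table$MTSI)[1:3])
})
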