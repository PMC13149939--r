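test_that("noise-free data are fitted exactly: zero residual variance, exact environment means", {
  cfg <- sim_config(n_gen = 10, n_env = 4, n_blocks = 3, grand_mean = 10,
                    sigma2_env = 1, sigma2_block_env = 0, sigma2_gen = 1,
                    sigma2_resid = 1e-7, gei_rank = 0,
                    gei_axis_scales = numeric(0), seed = 8)
  dat <- simulate_met(cfg)
  fit <- fit_met(dat)
  expect_lte(fit$components[["sigma2_resid"]], 1e-6)
  # with no block/interaction/residual noise the environment means are
  # unshrunk: u_j equals the realized environment mean exactly
  env_means <- tapply(dat$VALUE, dat$ENV, mean)
  expect_equal(as.numeric(fit$env_means[names(env_means)]),
               as.numeric(env_means), tolerance = 1e-6)
})

test_that("REML equals the balanced-ANOVA estimators on balanced data with interior estimates", {
  dat <- quick_sim(102, sigma2_gei = 1, sigma2_block_env = 1)
  oc <- anova_components_oracle(dat)
  expect_true(all(oc > 0))   # this draw is interior, so equality must hold
  fit <- fit_met(dat)
  expect_false(fit$boundary)
  expect_lt(max(abs(fit$components[names(oc)] - oc) / oc), 1e-5)
})

test_that("phenotypic variance bookkeeping is consistent in both parameterizations", {
  dat <- quick_sim(55)
  fr <- fit_met(dat, genotype_role = "random")
  comp <- fr$components[!is.na(fr$components)]
  expect_equal(fr$sigma2_phen, sum(comp))
  expect_equal(sum(fr$phen_shares), 1, tolerance = 1e-10)
  expect_true("sigma2_gen" %in% names(comp))
  ff <- fit_met(dat, genotype_role = "fixed")
  expect_false("sigma2_gen" %in% names(ff$components[!is.na(ff$components)]))
  expect_equal(sum(ff$phen_shares), 1, tolerance = 1e-10)
})

test_that("interaction BLUP rows and columns are centered and genotype BLUPs shrink raw means", {
  dat <- quick_sim(7)
  fit <- fit_met(dat)
  expect_lt(max(abs(rowSums(fit$ge))), 1e-5)
  expect_lt(max(abs(colSums(fit$ge))), 1e-5)
  raw_dev <- tapply(dat$VALUE, dat$GEN, mean) - mean(dat$VALUE)
  expect_true(all(abs(fit$g) <= abs(raw_dev[names(fit$g)]) + 1e-8))
})

test_that("relabeling genotypes and environments permutes outputs identically", {
  dat <- quick_sim(13)
  fit <- fit_met(dat)
  perm <- as.data.frame(dat)
  perm$GEN <- sprintf("Z%02d", as.integer(sub("G", "", perm$GEN)))
  perm$ENV <- sprintf("Y%d", as.integer(sub("E", "", perm$ENV)))
  fit2 <- fit_met(perm)
  expect_equal(unname(fit2$components), unname(fit$components),
               tolerance = 1e-8)
  g2 <- setNames(fit2$g, sub("Z0?", "G", names(fit2$g)))
  expect_equal(g2[names(fit$g)], fit$g, tolerance = 1e-6)
})

test_that("likelihood-ratio test flags a strong interaction and not an absent one", {
  strong <- quick_sim(77, sigma2_gei = 2)
  l1 <- lrt_random_term(strong, term = "GEI")
  expect_gt(l1$chi2, 0)
  expect_lt(l1$p_value, 0.01)
  expect_equal(l1$chi2, 2 * (l1$loglik_full - l1$loglik_reduced))

  none <- quick_sim(78, sigma2_gei = 0)
  l0 <- lrt_random_term(none, term = "GEI")
  expect_gt(l0$p_value, 0.05)
  # boundary correction halves positive-statistic p-values, maps chi2=0 to 1
  lb <- lrt_random_term(none, term = "GEI", boundary_correct = TRUE)
  expect_equal(lb$p_value, if (lb$chi2 > 0) l0$p_value / 2 else 1)
})

test_that("environment LRT has power when environments differ strongly", {
  dat <- simulate_met(sim_config(seed = 99, grand_mean = 10, sigma2_env = 5,
                                 sigma2_block_env = 0.1, sigma2_gen = 1,
                                 sigma2_resid = 1, gei_mode = "iid",
                                 sigma2_gei = 0.2))
  expect_lt(lrt_random_term(dat, term = "ENV")$p_value, 0.01)
})

test_that("single-environment genotype ANOVA matches textbook RCBD sums of squares", {
  dat <- quick_sim(17)
  d1 <- as.data.frame(dat)[as.data.frame(dat)$ENV == "E1", ]
  res <- anova_genotype(dat, mode = "single_env")
  row <- res[res$ENV == "E1", ]
  # textbook RCBD by explicit sums of squares
  g <- length(unique(d1$GEN)); r <- length(unique(d1$BLOCK))
  tot <- sum((d1$VALUE - mean(d1$VALUE))^2)
  ss_g <- r * sum((tapply(d1$VALUE, d1$GEN, mean) - mean(d1$VALUE))^2)
  ss_b <- g * sum((tapply(d1$VALUE, d1$BLOCK, mean) - mean(d1$VALUE))^2)
  ss_e <- tot - ss_g - ss_b
  f_hand <- (ss_g / (g - 1)) / (ss_e / ((g - 1) * (r - 1)))
  expect_equal(row$F, f_hand, tolerance = 1e-8)
  expect_equal(row$df1, g - 1)
  expect_equal(row$df2, (g - 1) * (r - 1))
})

test_that("combined genotype F test matches the mean-squares ratio on balanced data", {
  dat <- quick_sim(23, sigma2_gei = 1, sigma2_env = 4)
  oc <- anova_components_oracle(dat)
  expect_true(all(oc > 0))   # interior draw: GLS Wald F = MS_G / MS_GE
  res <- anova_genotype(dat)
  d <- as.data.frame(dat)
  for (cn in c("ENV", "GEN", "BLOCK")) d[[cn]] <- factor(d[[cn]])
  a <- anova(aov(VALUE ~ ENV + GEN + ENV:BLOCK + ENV:GEN, data = d))
  ms <- setNames(a[["Mean Sq"]], trimws(rownames(a)))
  # containment: genotype tested against the genotype x environment stratum
  expect_equal(res$F, ms[["GEN"]] / ms[["ENV:GEN"]], tolerance = 1e-6)
  expect_equal(res$df1, 17)
  expect_equal(res$df2, 17 * 5)
})

test_that("combined genotype F test holds its size under the null", {
  n_rep <- 150
  p <- numeric(n_rep)
  for (i in seq_len(n_rep)) {
    d <- simulate_met(sim_config(n_gen = 10, n_env = 4, n_blocks = 3,
                                 grand_mean = 10, sigma2_env = 1,
                                 sigma2_block_env = 0.5, sigma2_gen = 0,
                                 sigma2_resid = 1, gei_mode = "iid",
                                 sigma2_gei = 0.5, seed = 40000 + i))
    p[i] <- anova_genotype(d)$p_value
  }
  rate <- mean(p < 0.05)
  expect_gte(rate, 0.02)
  expect_lte(rate, 0.09)
})

test_that("genotypic values follow GV = u_j + g_i + ge_ij cell by cell", {
  u <- c(E1 = 10, E2 = 20)
  g <- c(G1 = 1, G2 = -1)
  ge <- matrix(c(0.5, -0.5, -0.5, 0.5), 2, 2,
               dimnames = list(names(g), names(u)))
  fit <- fake_fit(g, u, ge)
  gv <- genotypic_values(fit)
  for (i in 1:2) for (j in 1:2)
    expect_equal(gv[i, j], u[[j]] + g[[i]] + ge[i, j])
  # column means return the environment mean when ge columns are centered
  expect_equal(unname(colMeans(gv)), unname(u + mean(g)))

  # zero genotype and interaction variance: every column constant = u_j
  fit0 <- fake_fit(c(G1 = 0, G2 = 0), u, ge * 0)
  gv0 <- genotypic_values(fit0)
  expect_true(all(gv0[1, ] == gv0[2, ]))
  expect_equal(unname(gv0[1, ]), unname(u))
})

test_that("genotype-fixed fits refuse BLUP-only downstream operations", {
  dat <- quick_sim(3)
  ff <- fit_met(dat, genotype_role = "fixed")
  expect_error(genotypic_values(ff), "genotype-random")
  expect_error(heritability(ff), "genotype-random")
  expect_error(lrt_random_term(dat, term = "GEN", genotype_role = "fixed"),
               "usage error")
})

test_that("heritability follows the genotype-mean formula", {
  mk <- function(s2g, s2i, s2e) fake_fit(
    c(G1 = 0, G2 = 0), c(E1 = 0, E2 = 0), matrix(0, 2, 2),
    components = c(sigma2_env = 1, sigma2_block_env = 1, sigma2_gen = s2g,
                   sigma2_gei = s2i, sigma2_resid = s2e),
    n_env = 6, n_blocks = 3)
  expect_equal(heritability(mk(0, 1, 1)), 0)
  expect_equal(heritability(mk(1, 0, 0)), 1)
  expect_equal(heritability(mk(1, 1, 1)), 1 / (1 + 1 / 6 + 1 / 18),
               tolerance = 1e-4)
  expect_error(heritability(mk(0, 0, 0)), "undefined")
  # plot basis is the phenotypic share
  expect_equal(heritability(mk(1, 1, 1), basis = "plot"), 1 / 5)
})

test_that("degenerate designs are rejected with a design error", {
  dat <- as.data.frame(quick_sim(2))
  expect_error(fit_met(dat[dat$ENV == "E1", ]), "design error")
  two_env <- dat[dat$ENV %in% c("E1", "E2"), ]
  drop_g1 <- two_env[!(two_env$GEN == "G1" & two_env$ENV == "E2"), ]
  expect_error(fit_met(drop_g1), ">= 2 environments")
})
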