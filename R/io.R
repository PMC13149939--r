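validate_met_frame <- function(data) {
  d <- as.data.frame(data)
  names(d) <- toupper(names(d))
  required <- c("ENV", "GEN", "BLOCK", "TRAIT", "VALUE")
  missing <- setdiff(required, names(d))
  if (length(missing))
    stop("missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (!is.numeric(d$VALUE))
    stop("VALUE must be numeric", call. = FALSE)
  if (any(!is.finite(d$VALUE)))
    stop("non-finite VALUE at row(s): ",
         paste(utils::head(which(!is.finite(d$VALUE)), 10), collapse = ", "),
         call. = FALSE)
  key <- paste(d$ENV, d$GEN, d$BLOCK, d$TRAIT, sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup))
    stop("duplicate plot row(s) at line(s): ",
         paste(utils::head(dup + 1L, 10), collapse = ", "),
         " (env,gen,block,trait must be unique)", call. = FALSE)
  d[required]
}

#' Read a multi-environment trial CSV
#'
#' Long format is canonical: header `ENV,GEN,BLOCK,TRAIT,VALUE`
#' (case-insensitive). Wide files — `ENV,GEN,BLOCK` plus one numeric column
#' per trait — are auto-detected and melted. Duplicate plot rows and
#' non-numeric values are rejected with the offending line numbers.
#'
#' @param path CSV file path.
#' @return a validated `met_data` tibble.
#' @export
read_met_csv <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  names(d) <- toupper(names(d))
  base_cols <- c("ENV", "GEN", "BLOCK")
  if (!all(base_cols %in% names(d)))
    stop("missing column(s): ",
         paste(setdiff(base_cols, names(d)), collapse = ", "), call. = FALSE)
  if (!all(c("TRAIT", "VALUE") %in% names(d))) {
    trait_cols <- setdiff(names(d), base_cols)
    if (length(trait_cols) == 0)
      stop("no trait columns found", call. = FALSE)
    long <- do.call(rbind, lapply(trait_cols, function(tc) {
      v <- d[[tc]]
      if (!is.numeric(v))
        stop("non-numeric trait column: ", tc, call. = FALSE)
      data.frame(ENV = d$ENV, GEN = d$GEN, BLOCK = d$BLOCK,
                 TRAIT = tc, VALUE = v, stringsAsFactors = FALSE)
    }))
    d <- long
  }
  out <- tibble::as_tibble(validate_met_frame(d))
  class(out) <- c("met_data", class(out))
  out
}

#' Write a MET dataset as long-format CSV
#' @param data `met_data` tibble.
#' @param path output path.
#' @export
write_met_csv <- function(data, path) {
  d <- validate_met_frame(data)
  write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a simulation configuration from a YAML file
#'
#' Field names mirror the arguments of [sim_config()]; `gen_corr` may be
#' given as a nested list of rows.
#'
#' @param path YAML file path.
#' @return a validated [sim_config()].
#' @export
read_sim_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$gen_corr))
    y$gen_corr <- do.call(rbind, lapply(y$gen_corr, unlist))
  do.call(sim_config, y)
}

#' Pipeline configuration
#'
#' Bundles everything [run_pipeline()] needs: the input data (or a
#' [sim_config()] to generate them), the traits to analyse with their
#' desirability directions, WAASBY weights, the number of IPCA axes for
#' WAASB, the MTSI selection intensity, and the trait whose genotypic
#' values are ranked by HMGV/RPGV/HMRPGV.
#'
#' @param data a `met_data` tibble, a path to a MET CSV, or `NULL` to
#'   simulate from `sim`.
#' @param sim a [sim_config()] used when `data` is `NULL`.
#' @param directions named character vector (`"higher"`/`"lower"`) per
#'   analysed trait; default: every trait higher-better.
#' @param theta_y,theta_s WAASBY weights (default equal emphasis).
#' @param n_axes IPCA axes for WAASB (`"all"` or integer).
#' @param intensity MTSI selection intensity in percent (default 15).
#' @param gv_trait trait for the genotypic-value index table (default the
#'   first trait).
#' @param out_dir output directory, or `NULL` to skip writing files.
#' @param seed integer seed recorded in the manifest (and used for
#'   simulation when `data` is `NULL`).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(data = NULL, sim = sim_config(),
                            directions = NULL,
                            theta_y = 50, theta_s = 50, n_axes = "all",
                            intensity = 15, gv_trait = NULL,
                            out_dir = NULL, seed = 1L) {
  if (intensity <= 0 || intensity > 100)
    stop("intensity must be in (0, 100]", call. = FALSE)
  if (!is.null(directions)) {
    if (is.null(names(directions)) || any(names(directions) == ""))
      stop("directions must be a named vector (trait names)", call. = FALSE)
    bad <- !directions %in% c("higher", "lower")
    if (any(bad))
      stop("unknown trait direction(s): ",
           paste(unique(directions[bad]), collapse = ", "), call. = FALSE)
  }
  structure(list(data = data, sim = sim, directions = directions,
                 theta_y = theta_y, theta_s = theta_s, n_axes = n_axes,
                 intensity = intensity, gv_trait = gv_trait,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full stability-selection pipeline
#'
#' Chains every stage on every configured trait: REML fits in both genotype
#' parameterizations, likelihood-ratio tests for the random environment and
#' interaction terms, the fixed-genotype ANOVA, IPCA decomposition of the
#' BLUP GEI matrix, WAASB/WAASBY stability tables with quadrant labels and
#' the weight-grid ranking, the MTSI factor-analysis selection with
#' selection differentials and gains, and the HMGV/RPGV/HMRPGV table for
#' the target trait. When `out_dir` is set, every table is written as CSV
#' and a JSON manifest records outputs, seed, parameterizations and
#' decisions taken (boundary estimates, tie-breaks).
#'
#' @param config a [pipeline_config()].
#' @return list of class `met_pipeline` with elements `data`, `fits`,
#'   `lrt`, `anova`, `decomp`, `stability` (per trait), `weight_grid`,
#'   `index_matrix`, `fa`, `ideotype`, `mtsi`, `gains`, `gv`, `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  notes <- character(0)
  data <- config$data
  if (is.null(data)) {
    sim <- config$sim
    sim$seed <- config$seed
    data <- if (sim$n_traits > 1L) simulate_multitrait_met(sim)
            else simulate_met(sim)
    notes <- c(notes, sprintf("data simulated (seed %d)", config$seed))
  } else if (is.character(data)) {
    data <- read_met_csv(data)
  }
  d <- validate_met_frame(data)
  traits <- unique(d$TRAIT)
  directions <- config$directions
  if (is.null(directions))
    directions <- setNames(rep("higher", length(traits)), traits)
  missing_dir <- setdiff(traits, names(directions))
  if (length(missing_dir))
    stop("directions missing for trait(s): ",
         paste(missing_dir, collapse = ", "), call. = FALSE)

  fits_random <- lapply(traits, function(tr) fit_met(d, tr, "random"))
  names(fits_random) <- traits
  fits_fixed <- lapply(traits, function(tr) fit_met(d, tr, "fixed"))
  names(fits_fixed) <- traits
  for (tr in traits)
    if (fits_random[[tr]]$boundary)
      notes <- c(notes, sprintf("trait %s: variance component at boundary (clipped to 0)", tr))

  lrt <- lapply(traits, function(tr) list(
    ENV = lrt_random_term(d, tr, "ENV"),
    GEI = lrt_random_term(d, tr, "GEI")
  ))
  names(lrt) <- traits
  anova_tab <- lapply(traits, function(tr) anova_genotype(d, tr))
  names(anova_tab) <- traits

  decomp <- lapply(fits_random, function(f) gei_svd(f$ge))
  stab <- lapply(traits, function(tr)
    stability_table(fits_random[[tr]], n_axes = config$n_axes,
                    theta_y = config$theta_y, theta_s = config$theta_s,
                    direction = directions[[tr]]))
  names(stab) <- traits

  gv_trait <- config$gv_trait %||% traits[1]
  st1 <- stab[[gv_trait]]
  wgrid <- rank_across_weights(setNames(st1$MEAN, st1$GEN),
                               setNames(st1$WAASB, st1$GEN),
                               direction = directions[[gv_trait]])

  mtsi_res <- fa <- ideo <- gains <- im <- NULL
  if (length(traits) >= 2) {
    im <- build_index_matrix(stab)
    fa <- factor_analysis(im)
    ideo <- ideotype_scores(fa, im)
    mtsi_res <- mtsi_scores(fa, ideo, intensity = config$intensity)
    vals <- c(
      setNames(lapply(traits, function(tr)
        setNames(fits_random[[tr]]$mu_hat + fits_random[[tr]]$g,
                 names(fits_random[[tr]]$g))),
        paste0(traits, "_mean")),
      setNames(lapply(traits, function(tr)
        setNames(stab[[tr]]$WAASBY, stab[[tr]]$GEN)),
        paste0(traits, "_WAASBY"))
    )
    h2 <- vapply(traits, function(tr) heritability(fits_random[[tr]]), 0)
    h2_all <- setNames(rep(h2, 2), names(vals))
    gains <- selection_gains(vals, mtsi_res$selected, h2_all)
  }

  gv_tab <- genotypic_value_table(fits_random[[gv_trait]])

  manifest <- list(
    seed = config$seed,
    traits = as.list(setNames(directions[traits], traits)),
    theta_y = config$theta_y, theta_s = config$theta_s,
    intensity = config$intensity,
    gv_trait = gv_trait,
    parameterizations = list(indices = "genotype_random",
                             significance = "genotype_fixed"),
    notes = notes,
    outputs = character(0)
  )

  res <- structure(list(
    data = data, fits = list(random = fits_random, fixed = fits_fixed),
    lrt = lrt, anova = anova_tab, decomp = decomp, stability = stab,
    weight_grid = wgrid, index_matrix = im, fa = fa, ideotype = ideo,
    mtsi = mtsi_res, gains = gains, gv = gv_tab, manifest = manifest
  ), class = "met_pipeline")

  if (!is.null(config$out_dir)) res <- write_pipeline(res, config$out_dir)
  res
}

write_pipeline <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  outputs <- character(0)
  put <- function(obj, name) {
    p <- file.path(out_dir, name)
    write.csv(obj, p, row.names = FALSE, quote = FALSE)
    outputs <<- c(outputs, name)
  }
  write_met_csv(res$data, file.path(out_dir, "met_data.csv"))
  outputs <- c(outputs, "met_data.csv")
  traits <- names(res$fits$random)
  vc <- do.call(rbind, lapply(traits, function(tr) {
    f <- res$fits$random[[tr]]
    data.frame(TRAIT = tr, component = names(f$components),
               variance = unname(f$components),
               share = unname(f$components) / f$sigma2_phen)
  }))
  put(vc[!is.na(vc$variance), ], "variance_components.csv")
  lrt_tab <- do.call(rbind, lapply(traits, function(tr)
    do.call(rbind, lapply(res$lrt[[tr]], function(l)
      data.frame(TRAIT = tr, term = l$term, chi2 = l$chi2,
                 p_value = l$p_value)))))
  put(lrt_tab, "lrt.csv")
  put(do.call(rbind, lapply(traits, function(tr)
    cbind(TRAIT = tr, as.data.frame(res$anova[[tr]])))), "anova_genotype.csv")
  for (tr in traits)
    put(as.data.frame(res$stability[[tr]]), paste0("stability_", tr, ".csv"))
  put(cbind(GEN = rownames(res$weight_grid$ranks),
            as.data.frame(res$weight_grid$ranks)), "weight_grid_ranks.csv")
  dec <- res$decomp[[res$manifest$gv_trait]]
  jsonlite::write_json(
    list(lambda = dec$lambda, ep = dec$ep,
         gen_scores = as.data.frame(dec$gen_scores),
         env_scores = as.data.frame(dec$env_scores)),
    file.path(out_dir, "ipca_decomposition.json"), digits = NA)
  outputs <- c(outputs, "ipca_decomposition.json")
  if (!is.null(res$mtsi)) {
    put(data.frame(axis = seq_along(res$fa$eigenvalues),
                   eigenvalue = res$fa$eigenvalues,
                   explained_pct = 100 * res$fa$eigenvalues /
                     length(res$fa$eigenvalues)), "fa_eigenvalues.csv")
    put(cbind(TRAIT = rownames(res$fa$loadings),
              as.data.frame(res$fa$loadings),
              communality = res$fa$communality), "fa_loadings.csv")
    put(as.data.frame(res$mtsi$table), "mtsi_ranking.csv")
    put(cbind(GEN = rownames(res$mtsi$contributions),
              as.data.frame(res$mtsi$contributions)),
        "mtsi_factor_contributions.csv")
    put(as.data.frame(res$gains), "selection_gains.csv")
  }
  put(as.data.frame(res$gv), "genotypic_values.csv")
  jsonlite::write_json(list(mu = attr(res$gv, "mu"),
                            n_env = attr(res$gv, "n_env")),
                       file.path(out_dir, "gv_meta.json"),
                       auto_unbox = TRUE, digits = NA)
  outputs <- c(outputs, "gv_meta.json")
  res$manifest$outputs <- outputs
  jsonlite::write_json(res$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  res
}

#' @export
print.met_pipeline <- function(x, ...) {
  traits <- names(x$fits$random)
  cat("MET stability pipeline:", length(traits), "trait(s),",
      length(x$fits$random[[1]]$g), "genotypes,",
      x$fits$random[[1]]$n_env, "environments\n")
  if (!is.null(x$mtsi)) print(x$mtsi)
  invisible(x)
}
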