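#' Build a run configuration
#'
#' A run configuration drives [run_pipeline()]: where the data come from
#' (a vials CSV + Newick tree, or a seeded simulation), which Bayesian models
#' to fit and at what MCMC budget, the diversity-set and DSI* settings, and
#' the output directory. Configurations round-trip through YAML
#' ([read_run_config()] / [write_run_config()]).
#'
#' @param seed Master seed; every stochastic stage derives its stream from it.
#' @param output_dir Output directory (`NULL` for no file output).
#' @param vials_csv,tree_newick Input paths; leave `NULL` to simulate.
#' @param simulate Logical; generate data with [simulate_experiment()].
#' @param design,params Overrides for [experiment_design()] / [true_params()]
#'   (lists of arguments) when simulating.
#' @param models List: `run` (fit the Bayesian models), `include_phylo`,
#'   `loo` (also fit the non-phylogenetic variant and compare by PSIS-LOO),
#'   `baseline_temperature`, `mcmc` (see [model_spec()]), `strict`.
#' @param diversity List: `n_sets`, `q`, `n_rand` (replicate-order shuffles;
#'   0 disables the sensitivity analysis).
#' @param dsi List: `n_null`.
#' @return List of class `"run_config"`.
#' @export
run_config <- function(seed = 1L, output_dir = NULL,
                       vials_csv = NULL, tree_newick = NULL,
                       simulate = is.null(vials_csv),
                       design = list(), params = list(),
                       models = list(), diversity = list(), dsi = list()) {
  models <- utils::modifyList(
    list(run = TRUE, include_phylo = TRUE, loo = FALSE,
         baseline_temperature = 24,
         mcmc = list(chains = 8, warmup = 1000, draws_per_chain = 1250, adapt = 500),
         strict = FALSE),
    models)
  diversity <- utils::modifyList(list(n_sets = 7, q = 1, n_rand = 0), diversity)
  dsi <- utils::modifyList(list(n_null = 999), dsi)
  structure(list(seed = as.integer(seed), output_dir = output_dir,
                 vials_csv = vials_csv, tree_newick = tree_newick,
                 simulate = simulate, design = design, params = params,
                 models = models, diversity = diversity, dsi = dsi),
            class = "run_config")
}

#' @rdname run_config
#' @param path YAML file path.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(run_config, cfg)
}

#' @rdname run_config
#' @param config A `"run_config"`.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

stage <- function(name, expr, output_dir = NULL) {
  tryCatch(expr, error = function(e) {
    if (!is.null(output_dir)) {
      writeLines(paste0("FAILED at stage '", name, "': ", conditionMessage(e)),
                 file.path(output_dir, "FAILED"))
    }
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full analysis pipeline
#'
#' Stages, in order: load or simulate vial records; per-vial interaction
#' metrics; Bayesian binomial models (larval and pupal parasitism success and
#' degree of infestation, host developmental success) with odds-ratio
#' contrasts and optional PSIS-LOO comparison against the non-phylogenetic
#' variant; diet-breadth diversity sets with temperature contrasts, available
#' host diversity, and the optional replicate-shuffling sensitivity analysis;
#' the DSI* specialization panel. Outputs are written as CSV/JSON into
#' `config$output_dir` together with a checksum manifest. With a fixed seed
#' the whole report is reproducible.
#'
#' @param config A [run_config()].
#' @return List of class `"run_report"` with elements `vials, tree, outcomes,
#'   adjustment, contrasts, loo, sd_summaries, breadth, availability,
#'   randomization, dsi, manifest, config`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  outdir <- config$output_dir
  if (!is.null(outdir) && !dir.exists(outdir)) {
    dir.create(outdir, recursive = TRUE)
  }

  tree <- stage("tree_io", {
    if (!is.null(config$tree_newick)) read_host_tree(config$tree_newick)
    else example_host_tree()
  }, outdir)

  vials <- stage("data", {
    if (config$simulate) {
      design <- do.call(experiment_design, config$design)
      params <- do.call(true_params, c(list(design = design), config$params))
      simulate_experiment(design, params, tree, seed = config$seed)
    } else {
      read_vials(config$vials_csv)
    }
  }, outdir)

  outcomes <- stage("interaction_metrics", treatment_outcomes(vials), outdir)
  adjustment <- adjustment_summary(outcomes)

  contrasts <- list(); loo <- list(); sds <- list()
  if (isTRUE(config$models$run)) {
    guild_of <- function(p) {
      if (config$simulate) {
        design <- do.call(experiment_design, config$design)
        design$parasitoids[[p]]
      } else if (p == "Trichopria") "pupal" else "larval"
    }
    pars <- unique(outcomes$parasitoid)
    larval <- pars[vapply(pars, guild_of, "") == "larval"]
    pupal <- pars[vapply(pars, guild_of, "") == "pupal"]
    jobs <- list()
    for (kind in c("parasitism", "infestation")) {
      if (length(larval)) jobs[[paste0("larval_", kind)]] <-
          list(kind = kind, guild = "larval", pars = larval)
      if (length(pupal)) jobs[[paste0("pupal_", kind)]] <-
          list(kind = kind, guild = "pupal", pars = pupal)
    }
    fits <- stage("glmm", {
      lapply(jobs, function(job) {
        ob <- model_observations(outcomes, job$kind)
        ob <- ob[ob$parasitoid %in% job$pars, ]
        spec <- model_spec(job$kind, job$guild,
                           include_phylo = config$models$include_phylo,
                           baseline_temperature = config$models$baseline_temperature,
                           mcmc = config$models$mcmc)
        fit <- fit_glmm(ob, tree, spec, seed = config$seed,
                        strict = isTRUE(config$models$strict))
        res <- list(contrasts = contrast_odds_ratios(fit), sd = sd_summary(fit))
        if (isTRUE(config$models$loo)) {
          spec0 <- spec; spec0$include_phylo <- FALSE
          fit0 <- fit_glmm(ob, tree = NULL, spec0, seed = config$seed,
                           strict = isTRUE(config$models$strict))
          cmp <- compare_loo(fit, fit0)
          res$loo <- data.frame(elpd_phylo = cmp$elpd[1],
                                elpd_nonphylo = cmp$elpd[2],
                                elpd_diff = cmp$elpd_diff, se_diff = cmp$se_diff,
                                significant = cmp$significant)
        }
        res
      })
    }, outdir)
    # host developmental success model on control vials
    fits$host_development <- stage("host_dev_glmm", {
      hd <- host_dev_success(vials)
      spec <- model_spec("host_development", "none",
                         include_phylo = config$models$include_phylo,
                         baseline_temperature = config$models$baseline_temperature,
                         mcmc = config$models$mcmc)
      fit <- fit_glmm(hd, tree, spec, seed = config$seed,
                      strict = isTRUE(config$models$strict))
      list(contrasts = contrast_odds_ratios(fit), sd = sd_summary(fit))
    }, outdir)
    contrasts <- lapply(fits, `[[`, "contrasts")
    sds <- lapply(fits, `[[`, "sd")
    loo <- Filter(Negate(is.null), lapply(fits, `[[`, "loo"))
  }

  trt <- vials[vials$parasitoid != "CONTROL", ]
  breadth <- stage("diet_breadth", {
    sets <- assign_sets(trt, n_sets = config$diversity$n_sets)
    fit_breadth_lm(set_diversity(sets, tree, config$diversity$q),
                   ambient = config$models$baseline_temperature)
  }, outdir)
  availability <- stage("available_diversity", {
    av <- available_diversity(vials, tree, q = config$diversity$q,
                              n_sets = config$diversity$n_sets)
    fit_breadth_lm(av, ambient = config$models$baseline_temperature)
  }, outdir)
  randomization <- NULL
  if (config$diversity$n_rand > 0) {
    randomization <- stage("randomization", {
      randomization_sensitivity(vials, tree, n_rand = config$diversity$n_rand,
                                seed = config$seed,
                                n_sets = config$diversity$n_sets,
                                q = config$diversity$q,
                                ambient = config$models$baseline_temperature)
    }, outdir)
  }

  dsi <- stage("specialization", {
    dsi_panel(vials, tree, n_null = config$dsi$n_null, seed = config$seed)
  }, outdir)

  report <- structure(list(
    vials = vials, tree = tree, outcomes = outcomes, adjustment = adjustment,
    contrasts = contrasts, loo = loo, sd_summaries = sds,
    breadth = breadth, availability = availability,
    randomization = randomization, dsi = dsi,
    manifest = NULL, config = config
  ), class = "run_report")

  if (!is.null(outdir)) {
    report$manifest <- write_report(report, outdir)
  }
  report
}

write_report <- function(report, outdir) {
  paths <- character()
  put_csv <- function(d, name) {
    p <- file.path(outdir, name)
    utils::write.csv(d, p, row.names = FALSE)
    paths <<- c(paths, p)
  }
  put_csv(report$vials, "vials.csv")
  put_csv(as.data.frame(report$outcomes), "treatment_outcomes.csv")
  put_csv(report$adjustment, "adjustment_summary.csv")
  for (nm in names(report$contrasts)) {
    put_csv(report$contrasts[[nm]], paste0("contrasts_", nm, ".csv"))
  }
  if (length(report$loo)) {
    put_csv(do.call(rbind, Map(cbind, model = names(report$loo), report$loo)),
            "loo_comparison.csv")
  }
  put_csv(report$breadth$contrasts, "breadth_contrasts.csv")
  put_csv(report$availability$contrasts, "availability_contrasts.csv")
  if (!is.null(report$randomization)) {
    put_csv(report$randomization$summary, "randomization_summary.csv")
  }
  put_csv(report$dsi, "dsi_panel.csv")
  p <- file.path(outdir, "tree.nwk")
  writeLines(write_newick(report$tree), p)
  paths <- c(paths, p)
  manifest <- data.frame(file = basename(paths),
                         md5 = unname(tools::md5sum(paths)))
  utils::write.csv(manifest, file.path(outdir, "manifest.csv"), row.names = FALSE)
  manifest
}

#' Human-readable summary tables from a run report
#'
#' @param report A `"run_report"` (possibly partial).
#' @return List of data frames: `interactions` (mean parasitism success and
#'   degree of infestation per host x parasitoid x temperature, with the
#'   plus/minus significance annotation per parasitoid-guild contrast),
#'   `host_development` (mean survival per host x temperature),
#'   `or_contrasts`, `breadth`, `availability`, `dsi`.
#' @export
render_summary <- function(report) {
  empty <- data.frame()
  out <- list(interactions = empty, host_development = empty,
              or_contrasts = empty, breadth = empty, availability = empty,
              dsi = empty)
  oc <- report$outcomes
  if (!is.null(oc) && nrow(oc)) {
    agg <- stats::aggregate(
      cbind(parasitism_success, degree_of_infestation) ~
        host + parasitoid + temperature, data = oc, FUN = mean, na.action = stats::na.omit)
    out$interactions <- agg[order(agg$host, agg$parasitoid, agg$temperature), ]
    rownames(out$interactions) <- NULL
  }
  if (!is.null(report$vials) && nrow(report$vials)) {
    hd <- host_dev_success(report$vials)
    hd$survival <- hd$successes / hd$trials
    out$host_development <- stats::aggregate(survival ~ host + temperature,
                                             data = hd, FUN = mean)
  }
  if (length(report$contrasts)) {
    tab <- do.call(rbind, Map(cbind, model = names(report$contrasts),
                              report$contrasts))
    tab$sign <- ifelse(!tab$significant, "",
                       ifelse(tab$median_or > 1, "+", "-"))
    rownames(tab) <- NULL
    out$or_contrasts <- tab
  }
  if (!is.null(report$breadth)) out$breadth <- report$breadth$contrasts
  if (!is.null(report$availability)) out$availability <- report$availability$contrasts
  if (!is.null(report$dsi)) out$dsi <- report$dsi
  out
}
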