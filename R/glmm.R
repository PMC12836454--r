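#' Specification of a Bayesian multilevel binomial model
#'
#' Three variants share one likelihood, `y_j ~ Binomial(n_j, p_j)` with
#' `logit(p_j) = beta_temp + a_host + b_host,temp (+ c_par + d_par,temp)
#' (+ g_host)`:
#' * `guild = "larval"`: pools the larval parasitoid species; parasitoid
#'   random intercept and categorical temperature random slope included.
#' * `guild = "pupal"`: a single parasitoid species, so no parasitoid terms.
#' * `guild = "none"` (host development): control vials, no parasitoid terms.
#'
#' `g` is the phylogenetically correlated host effect,
#' `g ~ MVN(0, sd_g^2 * C)` with `C` the depth-normalized tree correlation;
#' it enters once per host species. Temperature uses index coding (one
#' `beta` per temperature); contrasts are computed post hoc so the coding
#' cannot change results.
#'
#' Priors are pinned weakly informative defaults: `Normal(0, 5)` on fixed
#' effects, `half-Student-t(3, 0, 2.5)` on every standard deviation.
#'
#' @param outcome_kind `"parasitism"`, `"infestation"` or
#'   `"host_development"` (bookkeeping label).
#' @param guild `"larval"`, `"pupal"` or `"none"`.
#' @param include_phylo Include the tree-correlated host effect?
#' @param baseline_temperature Ambient baseline for contrasts (default 24).
#' @param priors Named list: `fixed_sd`, `sd_scale`, `sd_df`.
#' @param mcmc Named list: `chains`, `warmup`, `draws_per_chain`, `adapt`.
#'   The reporting default (8 chains x 1250 draws after 1000 warmup, 10000
#'   posterior samples) can be scaled down for quick runs.
#' @return A list of class `"model_spec"`.
#' @export
model_spec <- function(outcome_kind = c("parasitism", "infestation", "host_development"),
                       guild = c("larval", "pupal", "none"),
                       include_phylo = TRUE,
                       baseline_temperature = 24,
                       priors = list(fixed_sd = 5, sd_scale = 2.5, sd_df = 3),
                       mcmc = list(chains = 8, warmup = 1000,
                                   draws_per_chain = 1250, adapt = 500)) {
  outcome_kind <- match.arg(outcome_kind)
  guild <- match.arg(guild)
  if (outcome_kind == "host_development" && guild != "none") {
    stop("host_development models have no parasitoid terms; use guild = 'none'",
         call. = FALSE)
  }
  defaults <- list(chains = 8, warmup = 1000, draws_per_chain = 1250, adapt = 500)
  mcmc <- utils::modifyList(defaults, mcmc)
  pdef <- list(fixed_sd = 5, sd_scale = 2.5, sd_df = 3)
  priors <- utils::modifyList(pdef, priors)
  structure(list(outcome_kind = outcome_kind, guild = guild,
                 include_phylo = include_phylo,
                 baseline_temperature = baseline_temperature,
                 priors = priors, mcmc = mcmc),
            class = "model_spec")
}

jags_model_string <- function(has_par, has_phylo) {
  paste0(
    "model {\n",
    "  for (j in 1:N) {\n",
    "    y[j] ~ dbin(p[j], trials[j])\n",
    "    logit(p[j]) <- beta[temp[j]] + a[host[j]] + b[host[j], temp[j]]",
    if (has_par) " + c[par[j]] + d[par[j], temp[j]]",
    if (has_phylo) " + g[host[j]]",
    "\n  }\n",
    "  for (t in 1:Tn) { beta[t] ~ dnorm(0, prec_beta) }\n",
    "  for (s in 1:S) {\n",
    "    a[s] ~ dnorm(0, pow(sd_a, -2))\n",
    "    for (t in 1:Tn) { b[s, t] ~ dnorm(0, pow(sd_b, -2)) }\n",
    "  }\n",
    "  sd_a ~ dt(0, prec_sd, df_sd) T(0,)\n",
    "  sd_b ~ dt(0, prec_sd, df_sd) T(0,)\n",
    if (has_par) paste0(
      "  for (k in 1:K) {\n",
      "    c[k] ~ dnorm(0, pow(sd_c, -2))\n",
      "    for (t in 1:Tn) { d[k, t] ~ dnorm(0, pow(sd_d, -2)) }\n",
      "  }\n",
      "  sd_c ~ dt(0, prec_sd, df_sd) T(0,)\n",
      "  sd_d ~ dt(0, prec_sd, df_sd) T(0,)\n"),
    if (has_phylo) paste0(
      "  g_raw[1:S] ~ dmnorm(zeros, Cinv)\n",
      "  for (s in 1:S) { g[s] <- sd_g * g_raw[s] }\n",
      "  sd_g ~ dt(0, prec_sd, df_sd) T(0,)\n"),
    "}\n")
}

#' Fit a Bayesian multilevel binomial model
#'
#' Vial-level binomial observations, hierarchical host (and optionally
#' parasitoid) intercepts and categorical temperature random slopes, and an
#' optional phylogenetically correlated host effect (non-centered
#' parameterization). Sampled with JAGS; chain RNG seeds derive from `seed`,
#' so a fixed seed reproduces the fit exactly.
#'
#' Convergence is assessed on identified quantities — the level-averaged
#' temperature margins (whose pairwise differences are the reported
#' contrasts) and the standard deviations — because with categorical random
#' slopes the raw `beta` are additively confounded with slope means and mix
#' slowly without being scientifically meaningful.
#'
#' @param obs Data frame with columns `successes, trials, host, temperature`
#'   and `parasitoid` when `spec$guild == "larval"`.
#' @param tree Host phylogeny; required when `spec$include_phylo`.
#' @param spec A [model_spec()].
#' @param seed Integer seed.
#' @param strict If `TRUE`, error when max R-hat on identified quantities
#'   exceeds 1.05; otherwise the fit is flagged.
#' @return Object of class `"pg_fit"`: `draws` (a `coda::mcmc.list`),
#'   `data`, `levels`, `spec`, `diagnostics` (`rhat_max`, `ess_min`,
#'   `flagged`).
#' @export
fit_glmm <- function(obs, tree = NULL, spec = model_spec(), seed = 1L,
                     strict = FALSE) {
  stopifnot(inherits(spec, "model_spec"))
  need <- c("successes", "trials", "host", "temperature")
  if (spec$guild == "larval") need <- c(need, "parasitoid")
  miss <- setdiff(need, names(obs))
  if (length(miss)) stop("obs is missing columns: ", paste(miss, collapse = ", "),
                         call. = FALSE)
  obs <- obs[obs$trials > 0, ]
  if (any(obs$successes < 0 | obs$successes > obs$trials)) {
    stop("successes outside [0, trials]", call. = FALSE)
  }
  hosts <- sort(unique(obs$host))
  temps <- sort(unique(obs$temperature))
  if (!spec$baseline_temperature %in% temps) {
    stop("baseline temperature ", spec$baseline_temperature,
         " absent from observations", call. = FALSE)
  }
  has_par <- spec$guild == "larval"
  pars <- if (has_par) sort(unique(obs$parasitoid)) else character()

  dat <- list(
    y = as.integer(obs$successes), trials = as.integer(obs$trials),
    host = match(obs$host, hosts), temp = match(obs$temperature, temps),
    N = nrow(obs), S = length(hosts), Tn = length(temps),
    prec_beta = 1 / spec$priors$fixed_sd^2,
    prec_sd = 1 / spec$priors$sd_scale^2, df_sd = spec$priors$sd_df
  )
  if (has_par) {
    dat$par <- match(obs$parasitoid, pars)
    dat$K <- length(pars)
  }
  if (spec$include_phylo) {
    if (is.null(tree)) stop("include_phylo = TRUE requires a tree", call. = FALSE)
    check_tree_covers(tree, hosts)
    C <- phylo_correlation(tree)[hosts, hosts]
    dat$Cinv <- solve(C + diag(1e-10, length(hosts)))
    dat$zeros <- rep(0, length(hosts))
  }

  inits <- lapply(seq_len(spec$mcmc$chains), function(ch) {
    list(.RNG.name = "base::Mersenne-Twister",
         .RNG.seed = (abs(seed) %% 1000000L) * 1000L + ch)
  })
  jm <- rjags::jags.model(
    textConnection(jags_model_string(has_par, spec$include_phylo)),
    data = dat, inits = inits, n.chains = spec$mcmc$chains,
    n.adapt = spec$mcmc$adapt, quiet = TRUE)
  stats::update(jm, spec$mcmc$warmup, progress.bar = "none")
  monitors <- c("beta", "a", "b", "sd_a", "sd_b",
                if (has_par) c("c", "d", "sd_c", "sd_d"),
                if (spec$include_phylo) c("g", "sd_g"))
  draws <- rjags::coda.samples(jm, monitors, n.iter = spec$mcmc$draws_per_chain,
                               progress.bar = "none")

  fit <- structure(list(
    draws = draws, data = obs, spec = spec,
    levels = list(hosts = hosts, parasitoids = pars, temperatures = temps)
  ), class = "pg_fit")
  fit$diagnostics <- fit_diagnostics(fit)
  if (fit$diagnostics$flagged) {
    msg <- paste0("convergence flagged: max R-hat ",
                  signif(fit$diagnostics$rhat_max, 4), ", min ESS ",
                  round(fit$diagnostics$ess_min))
    if (strict) stop(msg, call. = FALSE) else warning(msg, call. = FALSE)
  }
  fit
}

# level-averaged temperature margin per draw: beta_t + mean_s b[s,t]
# (+ mean_k d[k,t]); the identified functional behind the reported contrasts
margin_draws <- function(fit, chain = NULL) {
  m <- if (is.null(chain)) as.matrix(fit$draws) else as.matrix(fit$draws[[chain]])
  S <- length(fit$levels$hosts)
  K <- length(fit$levels$parasitoids)
  temps <- fit$levels$temperatures
  out <- sapply(seq_along(temps), function(t) {
    v <- m[, sprintf("beta[%d]", t)] +
      rowMeans(m[, sprintf("b[%d,%d]", seq_len(S), t), drop = FALSE])
    if (K > 0) {
      v <- v + rowMeans(m[, sprintf("d[%d,%d]", seq_len(K), t), drop = FALSE])
    }
    v
  })
  colnames(out) <- as.character(temps)
  out
}

fit_diagnostics <- function(fit) {
  chains <- length(fit$draws)
  temps <- as.character(fit$levels$temperatures)
  base <- as.character(fit$spec$baseline_temperature)
  sd_cols <- grep("^sd_", coda::varnames(fit$draws), value = TRUE)
  contr <- coda::as.mcmc.list(lapply(seq_len(chains), function(ch) {
    mg <- margin_draws(fit, ch)
    x <- mg[, setdiff(temps, base), drop = FALSE] - mg[, base]
    colnames(x) <- paste0("margin_", setdiff(temps, base))
    coda::mcmc(x)
  }))
  rhat_of <- function(ml) {
    if (chains < 2) return(NA_real_)
    max(coda::gelman.diag(ml, multivariate = FALSE, autoburnin = FALSE)$psrf[, 1],
        na.rm = TRUE)
  }
  rhat <- rhat_of(contr)
  rhat_sds <- rhat_of(fit$draws[, sd_cols, drop = FALSE])
  ess <- min(coda::effectiveSize(contr))
  # the flag polices the reported contrasts; variance hyperparameters with
  # few levels mix slowly under Gibbs without affecting the contrasts
  list(rhat_max = rhat, rhat_sds = rhat_sds, ess_min = ess,
       flagged = is.finite(rhat) && rhat > 1.05)
}

#' Temperature contrasts as median odds ratios with 95% HPD intervals
#'
#' For each posterior draw the odds ratio of temperature `t` against the
#' ambient baseline is `exp(margin_t - margin_baseline)`. By default the
#' margin averages the categorical random slopes over their observed levels
#' on the link scale (an estimated-marginal-mean); `marginal = "zero"`
#' instead conditions every random effect at its population mean of zero —
#' the two differ only by slope-mean differences, which are near zero unless
#' few levels exist. Significance means the 95% HPD interval excludes 1.
#'
#' @param fit A `"pg_fit"`.
#' @param marginal `"average"` (default) or `"zero"`.
#' @param per_species If `TRUE`, also return per host (x parasitoid)
#'   contrasts with that species' own random slopes added before
#'   exponentiating.
#' @return Data frame `comparison, median_or, hpd_low, hpd_high,
#'   significant`, with attribute `per_species` when requested.
#' @export
contrast_odds_ratios <- function(fit, marginal = c("average", "zero"),
                                 per_species = FALSE) {
  marginal <- match.arg(marginal)
  temps <- as.character(fit$levels$temperatures)
  base <- as.character(fit$spec$baseline_temperature)
  m <- as.matrix(fit$draws)
  mg <- if (marginal == "average") {
    margin_draws(fit)
  } else {
    out <- sapply(seq_along(temps), function(t) m[, sprintf("beta[%d]", t)])
    colnames(out) <- temps
    out
  }
  one <- function(lor) {
    hpd <- coda::HPDinterval(coda::mcmc(exp(lor)), prob = 0.95)
    # median on the log scale, so relabelling the baseline inverts the OR
    # exactly (exp and median commute only up to even-sample interpolation)
    c(median_or = exp(stats::median(lor)), hpd_low = hpd[1, 1], hpd_high = hpd[1, 2])
  }
  others <- setdiff(temps, base)
  res <- t(vapply(others, function(t) one(mg[, t] - mg[, base]), numeric(3)))
  out <- data.frame(comparison = paste0(others, "/", base), res,
                    row.names = NULL)
  out$significant <- out$hpd_low > 1 | out$hpd_high < 1
  if (per_species) {
    S <- length(fit$levels$hosts); K <- length(fit$levels$parasitoids)
    sp <- list()
    for (s in seq_len(S)) {
      ks <- if (K > 0) seq_len(K) else 0L
      for (k in ks) {
        for (t in others) {
          ti <- match(t, temps); bi <- match(base, temps)
          lor <- (mg[, t] - mg[, base]) +
            (m[, sprintf("b[%d,%d]", s, ti)] - m[, sprintf("b[%d,%d]", s, bi)])
          if (K > 0) {
            lor <- lor + m[, sprintf("d[%d,%d]", k, ti)] -
              m[, sprintf("d[%d,%d]", k, bi)]
          }
          v <- one(lor)
          sp[[length(sp) + 1L]] <- data.frame(
            host = fit$levels$hosts[s],
            parasitoid = if (K > 0) fit$levels$parasitoids[k] else NA_character_,
            comparison = paste0(t, "/", base),
            median_or = v[1], hpd_low = v[2], hpd_high = v[3])
        }
      }
    }
    sp <- do.call(rbind, sp)
    sp$significant <- sp$hpd_low > 1 | sp$hpd_high < 1
    rownames(sp) <- NULL
    attr(out, "per_species") <- sp
  }
  out
}

#' Pointwise log-likelihood matrix of a fitted model
#'
#' Reconstructs the linear predictor for every observation and posterior
#' draw and evaluates the binomial log-likelihood; input to [psis_loo()].
#'
#' @param fit A `"pg_fit"`.
#' @return Matrix, draws x observations.
#' @export
log_lik_matrix <- function(fit) {
  m <- as.matrix(fit$draws)
  obs <- fit$data
  temps <- fit$levels$temperatures
  hi <- match(obs$host, fit$levels$hosts)
  ti <- match(obs$temperature, temps)
  has_par <- length(fit$levels$parasitoids) > 0
  if (has_par) ki <- match(obs$parasitoid, fit$levels$parasitoids)
  has_g <- fit$spec$include_phylo
  ll <- matrix(NA_real_, nrow(m), nrow(obs))
  for (j in seq_len(nrow(obs))) {
    eta <- m[, sprintf("beta[%d]", ti[j])] +
      m[, sprintf("a[%d]", hi[j])] +
      m[, sprintf("b[%d,%d]", hi[j], ti[j])]
    if (has_par) {
      eta <- eta + m[, sprintf("c[%d]", ki[j])] +
        m[, sprintf("d[%d,%d]", ki[j], ti[j])]
    }
    if (has_g) eta <- eta + m[, sprintf("g[%d]", hi[j])]
    ll[, j] <- stats::dbinom(obs$successes[j], obs$trials[j],
                             stats::plogis(eta), log = TRUE)
  }
  ll
}

#' Posterior summary of random-effect standard deviations
#' @param fit A `"pg_fit"`.
#' @return Data frame `parameter, median, hpd_low, hpd_high`.
#' @export
sd_summary <- function(fit) {
  m <- as.matrix(fit$draws)
  cols <- grep("^sd_", colnames(m), value = TRUE)
  out <- do.call(rbind, lapply(cols, function(cn) {
    hpd <- coda::HPDinterval(coda::mcmc(m[, cn]), prob = 0.95)
    data.frame(parameter = cn, median = stats::median(m[, cn]),
               hpd_low = hpd[1, 1], hpd_high = hpd[1, 2])
  }))
  rownames(out) <- NULL
  out
}
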