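#' Experimental design of a factorial vial experiment
#'
#' Describes the vial layout: every host crossed with every parasitoid at
#' every temperature, replicated, plus unparasitized control vials per host
#' and temperature. Defaults emulate a tropical drosophilid-parasitoid
#' rearing experiment: 7 hosts, 4 parasitoids (three larval, one pupal),
#' temperatures 20/24/28 degrees C with 24 the ambient rearing temperature,
#' 50 host eggs per vial, 10 replicate vials per parasitized cell and 7
#' control vials per host x temperature.
#'
#' @param hosts Character vector of host species labels.
#' @param parasitoids Named character vector: names are parasitoid labels,
#'   values their guild, `"larval"` or `"pupal"`.
#' @param temperatures Numeric vector of rearing temperatures (deg C); must
#'   include the ambient baseline.
#' @param ambient The baseline temperature (default 24).
#' @param replicates_per_cell Replicate vials per host x parasitoid x
#'   temperature.
#' @param controls_per_cell Control vials per host x temperature.
#' @param eggs_per_vial Host eggs per vial.
#' @return A list of class `"experiment_design"`.
#' @export
experiment_design <- function(hosts = paste0("H", 1:7),
                              parasitoids = c(Asobara = "larval",
                                              Leptopilina = "larval",
                                              Ganaspis = "larval",
                                              Trichopria = "pupal"),
                              temperatures = c(20, 24, 28),
                              ambient = 24,
                              replicates_per_cell = 10,
                              controls_per_cell = 7,
                              eggs_per_vial = 50) {
  stopifnot(eggs_per_vial > 0, replicates_per_cell >= 1, controls_per_cell >= 1)
  if (!ambient %in% temperatures) {
    stop("ambient temperature ", ambient, " must be one of the treatment temperatures",
         call. = FALSE)
  }
  if (is.null(names(parasitoids)) || !all(parasitoids %in% c("larval", "pupal"))) {
    stop("parasitoids must be a named vector with values 'larval' or 'pupal'",
         call. = FALSE)
  }
  structure(list(
    hosts = hosts, parasitoids = parasitoids, temperatures = sort(temperatures),
    ambient = ambient, replicates_per_cell = replicates_per_cell,
    controls_per_cell = controls_per_cell, eggs_per_vial = eggs_per_vial
  ), class = "experiment_design")
}

#' Ground-truth parameters for the synthetic experiment
#'
#' Parameters of the generating model, which deliberately shares its linear
#' predictor with the inference model so that parameter recovery is
#' well-posed. On the logit scale, the probability that a surviving host
#' larva in a parasitized vial yields an adult parasitoid is
#' `beta_temp[t] + a_host + b_host_t + c_par + d_par_t + g_host`, where
#' `a, b, c, d` are independent normal random intercepts/temperature slopes
#' and `g` is a host effect correlated by the phylogeny
#' (`g ~ MVN(0, phylo_sd^2 * C)` with `C` the depth-normalized tree
#' correlation).
#'
#' Default effect sizes reproduce the magnitudes reported for this system:
#' strong loss of parasitoid developmental success under warming
#' (log odds ratio `log(0.037)` vs ambient), mild loss under cooling
#' (`log(0.828)`); host egg-to-adult survival 0.75 at ambient, shifted by
#' `log(0.928)` (log-odds) under cooling, and under warming reduced
#' heterogeneously across hosts — shifts spread evenly from 0 down to
#' `2*log(0.198)`, averaging the overall `log(0.198)` — so that some hosts
#' crash under warming while others are barely affected, which is what makes
#' available host diversity itself drop with warming.
#'
#' @param design An [experiment_design()].
#' @param beta_temp Named numeric: parasitism fixed effect (logit) per
#'   temperature.
#' @param host_sd,parasitoid_sd Standard deviations of host/parasitoid
#'   random intercepts.
#' @param slope_sds Standard deviation of the categorical temperature random
#'   slopes (hosts and parasitoids alike).
#' @param phylo_sd Scale of the tree-correlated host effect.
#' @param survival_probs Host x temperature matrix of egg-to-adult survival
#'   probabilities (dimnames required); default built as described above.
#' @param escape_prob Conditional probability that an attacked surviving
#'   larva which does not yield a parasitoid emerges as an adult host (fly
#'   immune win); otherwise both die.
#' @return A list of class `"true_params"`.
#' @export
true_params <- function(design = experiment_design(),
                        beta_temp = NULL,
                        host_sd = 0.5,
                        parasitoid_sd = 0.5,
                        slope_sds = 0.3,
                        phylo_sd = 0.5,
                        survival_probs = NULL,
                        escape_prob = 0.15) {
  temps <- design$temperatures
  if (is.null(beta_temp)) {
    beta_temp <- stats::setNames(rep(-0.5, length(temps)), temps)
    beta_temp[as.character(20)] <- -0.5 + log(0.828)
    beta_temp[as.character(28)] <- -0.5 + log(0.037)
    beta_temp <- beta_temp[as.character(temps)]
  }
  if (is.null(names(beta_temp)) || !setequal(names(beta_temp), as.character(temps))) {
    stop("beta_temp must be named by temperature", call. = FALSE)
  }
  if (is.null(survival_probs)) {
    nh <- length(design$hosts)
    base <- stats::setNames(rep(stats::qlogis(0.75), length(temps)), temps)
    base[as.character(20)] <- base[as.character(20)] + log(0.928)
    host_off <- seq(-0.4, 0.4, length.out = nh)
    survival_probs <- stats::plogis(outer(host_off, base[as.character(temps)], `+`))
    dimnames(survival_probs) <- list(design$hosts, temps)
    # hosts respond heterogeneously to warming (some crash, some barely
    # affected), averaging to the overall warming log-odds shift log(0.198)
    if ("28" %in% colnames(survival_probs)) {
      warm_shift <- seq(0, 2 * log(0.198), length.out = nh)
      survival_probs[, "28"] <- stats::plogis(
        stats::qlogis(survival_probs[, "28"]) + warm_shift)
    }
  }
  stopifnot(all(survival_probs >= 0 & survival_probs <= 1),
            host_sd >= 0, parasitoid_sd >= 0, slope_sds >= 0, phylo_sd >= 0,
            escape_prob >= 0, escape_prob <= 1)
  structure(list(
    beta_temp = beta_temp, host_sd = host_sd, parasitoid_sd = parasitoid_sd,
    slope_sds = slope_sds, phylo_sd = phylo_sd,
    survival_probs = survival_probs, escape_prob = escape_prob
  ), class = "true_params")
}

# deterministic 31-bit stream id for one vial, so adding cells to a design
# never perturbs the draws of existing cells
vial_seed <- function(master, host, parasitoid, temperature, replicate) {
  s <- paste(host, parasitoid, temperature, replicate, sep = "\r")
  h <- as.double(master %% 2147483647L)
  for (v in utf8ToInt(s)) h <- (h * 31 + v) %% 2147483647
  as.integer(h)
}

#' Simulate a vial-level rearing experiment
#'
#' Control vials: `H ~ Binomial(eggs, survival)`. Parasitized vials: the
#' number of surviving larvae `n ~ Binomial(eggs, survival)`, then each
#' survivor independently yields an adult parasitoid (probability `pi`,
#' assembled from the model linear predictor) or, failing that, escapes as an
#' adult host (conditional probability `eta = escape_prob`) or dies, giving
#' `(P, H, dead) ~ Multinomial(n; pi, (1-pi) eta, (1-pi)(1-eta))`. This
#' three-outcome attack model guarantees `H + P <= eggs` and is well defined
#' for every value of the linear predictor.
#'
#' All randomness derives from `seed`: dataset-level random effects from the
#' master stream, each vial from its own counter-derived stream.
#'
#' @param design An [experiment_design()].
#' @param params A [true_params()].
#' @param tree Host phylogeny covering `design$hosts` (used for the
#'   correlated host effect); may be `NULL` when `phylo_sd = 0`.
#' @param seed Integer master seed.
#' @return A data frame of vial records with columns
#'   `host, parasitoid, temperature, replicate, eggs, H, P`;
#'   `parasitoid == "CONTROL"` marks unparasitized vials.
#' @export
simulate_experiment <- function(design, params, tree = NULL, seed = 1L) {
  stopifnot(inherits(design, "experiment_design"), inherits(params, "true_params"))
  hosts <- design$hosts; pars <- names(design$parasitoids)
  temps <- design$temperatures
  if (params$phylo_sd > 0 && is.null(tree)) {
    stop("a tree is required when phylo_sd > 0", call. = FALSE)
  }

  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))

  set.seed(seed)
  a <- stats::setNames(stats::rnorm(length(hosts), 0, params$host_sd), hosts)
  b <- matrix(stats::rnorm(length(hosts) * length(temps), 0, params$slope_sds),
              length(hosts), dimnames = list(hosts, temps))
  cc <- stats::setNames(stats::rnorm(length(pars), 0, params$parasitoid_sd), pars)
  d <- matrix(stats::rnorm(length(pars) * length(temps), 0, params$slope_sds),
              length(pars), dimnames = list(pars, temps))
  if (params$phylo_sd > 0) {
    check_tree_covers(tree, hosts)
    C <- phylo_correlation(tree)[hosts, hosts]
    L <- chol(C + diag(1e-10, length(hosts)))
    g <- stats::setNames(params$phylo_sd * drop(crossprod(L, stats::rnorm(length(hosts)))),
                         hosts)
  } else {
    g <- stats::setNames(numeric(length(hosts)), hosts)
  }

  rows <- vector("list", 0L)
  k <- 0L
  add <- function(row) { k <<- k + 1L; rows[[k]] <<- row }
  rows <- vector("list",
                 length(hosts) * length(temps) *
                   (length(pars) * design$replicates_per_cell + design$controls_per_cell))

  for (h in hosts) {
    for (tt in as.character(temps)) {
      surv <- params$survival_probs[h, tt]
      for (r in seq_len(design$controls_per_cell)) {
        set.seed(vial_seed(seed, h, "CONTROL", tt, r))
        H <- stats::rbinom(1, design$eggs_per_vial, surv)
        add(data.frame(host = h, parasitoid = "CONTROL",
                       temperature = as.numeric(tt), replicate = r,
                       eggs = design$eggs_per_vial, H = H, P = 0L))
      }
      for (p in pars) {
        pi_cell <- stats::plogis(params$beta_temp[[tt]] + a[[h]] + b[h, tt] +
                                   cc[[p]] + d[p, tt] + g[[h]])
        for (r in seq_len(design$replicates_per_cell)) {
          set.seed(vial_seed(seed, h, p, tt, r))
          n <- stats::rbinom(1, design$eggs_per_vial, surv)
          eta <- params$escape_prob
          out <- stats::rmultinom(1, n, c(pi_cell, (1 - pi_cell) * eta,
                                          (1 - pi_cell) * (1 - eta)))
          add(data.frame(host = h, parasitoid = p,
                         temperature = as.numeric(tt), replicate = r,
                         eggs = design$eggs_per_vial,
                         H = out[2, 1], P = out[1, 1]))
        }
      }
    }
  }
  vials <- do.call(rbind, rows[seq_len(k)])
  rownames(vials) <- NULL
  vials <- validate_vials(vials)
  # realized random effects, so recovery tests can target the realized
  # (not population) margins
  attr(vials, "true_effects") <- list(a = a, b = b, c = cc, d = d, g = g)
  vials
}

#' Validate a vial-record table
#'
#' Checks the schema (`host, parasitoid, temperature, replicate, eggs, H, P`)
#' and the count invariants `0 <= H`, `0 <= P`, `H + P <= eggs`, and `P = 0`
#' in control vials. Errors list the offending rows.
#'
#' @param vials A data frame of vial records.
#' @return The validated data frame, invisibly usable in a pipe.
#' @export
validate_vials <- function(vials) {
  need <- c("host", "parasitoid", "temperature", "replicate", "eggs", "H", "P")
  miss <- setdiff(need, names(vials))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "), call. = FALSE)
  vials$host <- trimws(as.character(vials$host))
  vials$parasitoid <- trimws(as.character(vials$parasitoid))
  bad <- which(vials$H < 0 | vials$P < 0 | vials$eggs <= 0 |
                 vials$H + vials$P > vials$eggs |
                 (vials$parasitoid == "CONTROL" & vials$P > 0))
  if (length(bad)) {
    stop("invalid vial records in rows: ", paste(utils::head(bad, 20), collapse = ", "),
         if (length(bad) > 20) " ..." else "", call. = FALSE)
  }
  vials
}

#' Write / read vial records as CSV
#'
#' The CSV schema is `host,parasitoid,temperature,replicate,eggs,H,P` with
#' `parasitoid = "CONTROL"` for unparasitized vials. Unknown extra columns
#' are preserved. `read_vials(write_vials(x))` returns `x`.
#'
#' @param vials A data frame of vial records.
#' @param path File path.
#' @return `write_vials` returns `path` invisibly; `read_vials` returns the
#'   validated data frame.
#' @export
write_vials <- function(vials, path) {
  if (nrow(vials) > 0) validate_vials(vials)
  utils::write.csv(vials, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_vials
#' @export
read_vials <- function(path) {
  vials <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(vials) == 0) {
    need <- c("host", "parasitoid", "temperature", "replicate", "eggs", "H", "P")
    miss <- setdiff(need, names(vials))
    if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "), call. = FALSE)
    return(vials)
  }
  validate_vials(vials)
}
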