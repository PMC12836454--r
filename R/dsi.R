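#' Distance-based phylogenetic specialization index (DSI*)
#'
#' Compares the abundance-weighted mean pairwise phylogenetic distance (MPD)
#' of the hosts a parasitoid was reared from against a Monte Carlo null in
#' which the same number of interaction records is resampled from host
#' availability. The standardized index lies in \[-1, 1\]: 0 means the diet
#' is random with respect to availability, 1 maximal specialization (all
#' records on one host, MPD 0), negative values a diet more phylogenetically
#' overdispersed than availability predicts.
#'
#' Observed MPD is \eqn{\sum_{i<j} u_i u_j d_{ij} / \sum_{i<j} u_i u_j} over
#' hosts with use counts `u` and patristic distances `d`. The null draws
#' `sum(u)` records from `availability` weights (multinomial) `n_null` times.
#' Scaling: for `obs <= null_mean`, `(null_mean - obs) / (null_mean -
#' mpd_min)` with `mpd_min = 0` (a single-host diet); for `obs > null_mean`,
#' `(null_mean - obs) / (mpd_max - null_mean)` where `mpd_max` is the largest
#' patristic distance among available hosts (an abundance-weighted MPD is a
#' convex combination of pairwise distances, so this maximum is attained by
#' an even two-host diet at maximal distance).
#'
#' @param uses Named numeric vector: interaction records (reared parasitoid
#'   adults) per host.
#' @param availability Named nonnegative weights: host availability (e.g.
#'   surviving hosts in unparasitized controls at the same temperature).
#' @param tree Host phylogeny covering used and available hosts.
#' @param n_null Number of null resamples (default 999).
#' @param seed Integer seed; fixing it fixes the null exactly.
#' @return List of class `"dsi_result"`: `observed_mpd, null_mean, null_sd,
#'   dsi_star, n_null, n_records, flag` (`"ok"` or a reason the index is
#'   undefined, in which case `dsi_star` is `NA`).
#' @export
dsi_star <- function(uses, availability, tree, n_null = 999, seed = 1L) {
  stopifnot(!is.null(names(uses)), !is.null(names(availability)),
            all(uses >= 0), all(availability >= 0))
  n_rec <- sum(uses)
  res <- function(flag, obs = NA_real_, nm = NA_real_, nsd = NA_real_, d = NA_real_)
    structure(list(observed_mpd = obs, null_mean = nm, null_sd = nsd,
                   dsi_star = d, n_null = n_null, n_records = n_rec, flag = flag),
              class = "dsi_result")
  if (n_rec < 2) return(res("fewer than 2 interaction records"))
  avail <- availability[availability > 0]
  if (length(avail) < 2) return(res("availability concentrated on fewer than 2 hosts"))
  check_tree_covers(tree, union(names(uses)[uses > 0], names(avail)))
  D <- patristic_distances(tree)

  mpd <- function(u) {
    h <- names(u)[u > 0]
    if (length(h) < 2) return(0)
    ui <- u[h]
    d <- D[h, h, drop = FALSE]
    w <- outer(ui, ui)
    lt <- lower.tri(w)
    sum(w[lt] * d[lt]) / sum(w[lt])
  }

  obs <- mpd(uses[uses > 0])
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  nulls <- vapply(seq_len(n_null), function(i) {
    draw <- stats::rmultinom(1, n_rec, avail / sum(avail))[, 1]
    mpd(stats::setNames(draw, names(avail)))
  }, 0)
  null_mean <- mean(nulls); null_sd <- stats::sd(nulls)
  mpd_max <- max(D[names(avail), names(avail)])
  if (null_mean <= 0) return(res("degenerate null (all resamples monophagous)",
                                 obs, null_mean, null_sd))
  d <- if (obs <= null_mean) {
    (null_mean - obs) / null_mean            # mpd_min = 0
  } else {
    if (mpd_max <= null_mean) -1 else (null_mean - obs) / (mpd_max - null_mean)
  }
  res("ok", obs, null_mean, null_sd, max(-1, min(1, d)))
}

#' DSI* panel: one index per parasitoid x temperature
#'
#' Uses are the reared-parasitoid counts (`P`) per host, pooled over the
#' parasitized vials of the cell; availability is the surviving-host counts
#' (`H`) in the control vials at the same temperature. Cells with fewer than
#' 2 records are reported with a flag, never imputed (0 would claim "random
#' diet", a different statement).
#'
#' @param vials A vial-record data frame with control vials.
#' @param tree Host phylogeny.
#' @param n_null Null resamples per cell.
#' @param seed Integer seed (advanced per cell deterministically).
#' @return Data frame `parasitoid, temperature, observed_mpd, null_mean,
#'   null_sd, dsi_star, n_records, flag`.
#' @export
dsi_panel <- function(vials, tree, n_null = 999, seed = 1L) {
  vials <- validate_vials(vials)
  trt <- vials[vials$parasitoid != "CONTROL", ]
  ctl <- vials[vials$parasitoid == "CONTROL", ]
  pars <- sort(unique(trt$parasitoid))
  temps <- sort(unique(trt$temperature))
  rows <- list(); k <- 0L
  for (p in pars) for (tt in temps) {
    sub <- trt[trt$parasitoid == p & trt$temperature == tt, ]
    uses <- tapply(sub$P, sub$host, sum)
    uses <- stats::setNames(as.numeric(uses), names(uses))
    csub <- ctl[ctl$temperature == tt, ]
    avail <- tapply(csub$H, csub$host, sum)
    avail <- stats::setNames(as.numeric(avail), names(avail))
    r <- dsi_star(uses, avail, tree, n_null = n_null,
                  seed = vial_seed(seed, "dsi", p, tt, 0L))
    k <- k + 1L
    rows[[k]] <- data.frame(parasitoid = p, temperature = tt,
                            observed_mpd = r$observed_mpd,
                            null_mean = r$null_mean, null_sd = r$null_sd,
                            dsi_star = r$dsi_star, n_records = r$n_records,
                            flag = r$flag)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
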