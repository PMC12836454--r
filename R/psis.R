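# Pareto-smoothed importance sampling and PSIS-LOO.
#
# Importance ratios for leaving out observation j are 1/p(y_j | theta_s);
# their right tail is stabilized by replacing the largest ratios with
# expected order statistics of a generalized Pareto distribution fitted to
# the tail exceedances (profile-likelihood fit of Zhang & Stephens 2009,
# with the usual weakly informative shrinkage of k-hat toward 0.5).

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Generalized Pareto fit to exceedances x > 0. Returns shape k and scale.
gpd_fit <- function(x) {
  x <- sort(x)
  n <- length(x)
  prior <- 3
  m <- 30 + floor(sqrt(n))
  j <- seq_len(m)
  xstar <- x[max(1L, floor(n / 4 + 0.5))]
  theta <- 1 / x[n] + (1 - sqrt(m / (j - 0.5))) / (prior * xstar)
  k_zs <- function(th) -mean(log1p(-th * x))   # Zhang-Stephens shape (= -k)
  lik <- vapply(theta, function(th) {
    kz <- k_zs(th)
    n * (log(th / kz) + kz - 1)
  }, 0)
  w <- 1 / vapply(seq_len(m), function(i) sum(exp(lik - lik[i])), 0)
  theta_hat <- sum(theta * w)
  k <- -k_zs(theta_hat)                        # heavy tail <=> k > 0
  sigma <- -k / theta_hat
  # shrink k-hat toward 0.5 (stabilizes small tails)
  k <- (n * k + 10 * 0.5) / (n + 10)
  list(k = k, sigma = sigma)
}

gpd_quantile <- function(p, k, sigma) {
  if (abs(k) < 1e-12) -sigma * log1p(-p) else sigma * expm1(-k * log1p(-p)) / k
}

# Smooth one vector of log importance ratios. Returns normalized log weights
# and the Pareto k diagnostic.
psis_smooth <- function(lr) {
  S <- length(lr)
  lr <- lr - max(lr)
  tail_len <- ceiling(min(0.2 * S, 3 * sqrt(S)))
  khat <- NA_real_
  if (tail_len >= 5) {
    ord <- order(lr)
    tail_ids <- ord[(S - tail_len + 1):S]
    cut <- exp(lr[ord[S - tail_len]])
    exceed <- exp(lr[tail_ids]) - cut
    if (max(exceed) > 0) {
      fit <- gpd_fit(exceed[exceed > 0])
      khat <- fit$k
      if (is.finite(khat)) {
        p <- (seq_len(tail_len) - 0.5) / tail_len
        smoothed <- log(cut + gpd_quantile(p, fit$k, fit$sigma))
        lr[tail_ids] <- pmin(smoothed, 0)   # tail_ids already ascending in lr
      }
    } else {
      khat <- -Inf
    }
  }
  list(log_weights = lr - logsumexp(lr), k = khat)
}

#' PSIS leave-one-out cross-validation from a pointwise log-likelihood matrix
#'
#' @param log_lik Matrix of pointwise log-likelihoods, draws x observations.
#' @return List of class `"psis_loo"`: `elpd_loo`, `se_elpd_loo`, `pointwise`
#'   (per-observation elpd), `pareto_k` (tail-shape diagnostics; values above
#'   0.7 flag unreliable points), `n_bad_k`.
#' @export
psis_loo <- function(log_lik) {
  stopifnot(is.matrix(log_lik), nrow(log_lik) > 1)
  n <- ncol(log_lik)
  pointwise <- numeric(n)
  k <- numeric(n)
  for (j in seq_len(n)) {
    ll <- log_lik[, j]
    sm <- psis_smooth(-ll)
    pointwise[j] <- logsumexp(sm$log_weights + ll)
    k[j] <- sm$k
  }
  n_bad <- sum(is.finite(k) & k > 0.7)
  if (n_bad > 0.1 * n) {
    warning(n_bad, " of ", n, " observations have Pareto k > 0.7; ",
            "PSIS-LOO may be unreliable", call. = FALSE)
  }
  structure(list(elpd_loo = sum(pointwise),
                 se_elpd_loo = sqrt(n * stats::var(pointwise)),
                 pointwise = pointwise, pareto_k = k, n_bad_k = n_bad),
            class = "psis_loo")
}

#' Compare two model fits by PSIS-LOO
#'
#' Both fits must be on the identical observation rows. The expected log
#' pointwise predictive density (elpd) difference is `fit1 - fit2`; its
#' standard error comes from the pointwise differences. Following common
#' practice, the models are judged "not significantly different" when
#' `|elpd_diff| < 2 * se_diff`.
#'
#' @param fit1,fit2 Objects of class `"pg_fit"` (see [fit_glmm()]) or
#'   matrices of pointwise log-likelihood.
#' @return List of class `"loo_compare"`: `elpd` (per model), `elpd_diff`,
#'   `se_diff`, `significant`, and the two `"psis_loo"` objects.
#' @export
compare_loo <- function(fit1, fit2) {
  ll1 <- if (inherits(fit1, "pg_fit")) log_lik_matrix(fit1) else fit1
  ll2 <- if (inherits(fit2, "pg_fit")) log_lik_matrix(fit2) else fit2
  if (ncol(ll1) != ncol(ll2)) {
    stop("fits have different numbers of observations", call. = FALSE)
  }
  l1 <- psis_loo(ll1); l2 <- psis_loo(ll2)
  d <- l1$pointwise - l2$pointwise
  se <- sqrt(length(d) * stats::var(d))
  structure(list(
    elpd = c(fit1 = l1$elpd_loo, fit2 = l2$elpd_loo),
    elpd_diff = sum(d), se_diff = se,
    significant = is.finite(se) && se > 0 && abs(sum(d)) >= 2 * se,
    loo1 = l1, loo2 = l2
  ), class = "loo_compare")
}
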