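#' Beta-Binomial log likelihood of one brood
#'
#' The per-hermaphrodite viability model: the hatch probability p of one
#' brood is drawn from Beta(lambda * phi, lambda * (1 - phi)) — phi the group
#' mean viability, lambda the shape-parameter sum controlling
#' inter-hermaphrodite overdispersion — and hatched ~ Binomial(brood size, p).
#' Marginalizing p gives the beta-binomial mass
#' C(n,k) B(k + alpha, n - k + beta) / B(alpha, beta), computed in log space.
#'
#' @param k Hatched progeny (vectorized).
#' @param n Brood size (hatched + dead eggs); `k <= n`.
#' @param phi Mean viability in (0, 1).
#' @param lambda Shape-parameter sum, > 0.
#' @return Log probability; 0 for an empty brood (k = n = 0).
#' @export
#' @examples
#' betabinom_loglik(3, 9, 0.5, 2)  # log(1/10): alpha = beta = 1 is uniform
betabinom_loglik <- function(k, n, phi, lambda) {
  check_count(k, "k")
  check_count(n, "n")
  if (any(k > n)) abort("`k` must not exceed `n`.")
  if (!is.finite(phi) || phi <= 0 || phi >= 1) abort("`phi` must lie in (0, 1).")
  if (!is.finite(lambda) || lambda <= 0) abort("`lambda` must be > 0.")
  a <- lambda * phi
  b <- lambda * (1 - phi)
  lchoose(n, k) + lbeta(k + a, n - k + b) - lbeta(a, b)
}

#' Prior configuration for the brood viability model
#'
#' Defaults: phi ~ Uniform(0, 1); lambda ~ Exponential(rate 1/1000), weakly
#' informative with support for heavy overdispersion (small lambda) as well
#' as near-binomial groups (large lambda). A half-normal lambda prior is
#' available for sensitivity analysis.
#'
#' @param lambda_prior `"exponential"` or `"half-normal"`.
#' @param lambda_rate Rate of the exponential prior (default 1/1000).
#' @param lambda_sigma Scale of the half-normal prior (default 500).
#' @return A list of class `brood_priors`.
#' @export
brood_priors <- function(lambda_prior = c("exponential", "half-normal"),
                         lambda_rate = 1 / 1000, lambda_sigma = 500) {
  lambda_prior <- match.arg(lambda_prior)
  structure(list(lambda_prior = lambda_prior, lambda_rate = lambda_rate,
                 lambda_sigma = lambda_sigma), class = "brood_priors")
}

#' MCMC control settings for the bundled sampler
#'
#' The bundled sampler is an adaptive random-walk Metropolis on
#' (logit phi, log lambda), run independently per group (groups are
#' conditionally independent given their own parameters). Proposal scales
#' adapt during warmup toward an acceptance rate in the 0.3--0.45 band.
#'
#' @param chains Number of chains (default 4).
#' @param warmup Warmup iterations per chain (default 2000; discarded).
#' @param iter Sampling iterations per chain (default 2000).
#' @param seed Integer seed; identical seed + data + config gives
#'   bit-identical draws.
#' @return A list of class `mcmc_control`.
#' @export
mcmc_control <- function(chains = 4, warmup = 2000, iter = 2000, seed = 1) {
  stopifnot(chains >= 1, warmup >= 100, iter >= 100)
  structure(list(chains = chains, warmup = warmup, iter = iter,
                 seed = as.integer(seed)), class = "mcmc_control")
}

# log posterior in the unconstrained parameterization theta = (logit phi,
# log lambda), including Jacobians. Uniform(0,1) on phi contributes only its
# logit Jacobian log(phi (1 - phi)).
bb_log_post <- function(theta, k, n, priors) {
  phi <- plogis(theta[1])
  lambda <- exp(theta[2])
  if (!is.finite(lambda) || lambda <= 0 || phi <= 0 || phi >= 1) return(-Inf)
  a <- lambda * phi
  b <- lambda * (1 - phi)
  ll <- sum(lbeta(k + a, n - k + b)) - length(k) * lbeta(a, b)
  lp_lambda <- if (priors$lambda_prior == "exponential") {
    -priors$lambda_rate * lambda
  } else {
    -lambda^2 / (2 * priors$lambda_sigma^2)
  }
  ll + lp_lambda + log(phi) + log1p(-phi) + theta[2]
}

# One chain of component-wise adaptive random-walk Metropolis: each
# coordinate of (logit phi, log lambda) is updated in turn with its own
# proposal scale, adapted during warmup toward the 0.3--0.45 acceptance
# band. Returns an iters x 2 matrix of (phi, lambda) draws plus the realized
# post-warmup acceptance rate (averaged over coordinates).
bb_chain <- function(k, n, priors, warmup, iter, seed, init) {
  set.seed(seed)
  theta <- init + rnorm(2, 0, 0.1)
  lp <- bb_log_post(theta, k, n, priors)
  prop_sd <- c(0.5, 0.5)
  total <- warmup + iter
  draws <- matrix(NA_real_, nrow = iter, ncol = 2)
  acc_window <- c(0L, 0L)
  acc_sample <- 0L
  for (s in seq_len(total)) {
    for (j in 1:2) {
      cand <- theta
      cand[j] <- cand[j] + rnorm(1, 0, prop_sd[j])
      lp_cand <- bb_log_post(cand, k, n, priors)
      if (is.finite(lp_cand) && log(runif(1)) < lp_cand - lp) {
        theta <- cand
        lp <- lp_cand
        acc_window[j] <- acc_window[j] + 1L
        if (s > warmup) acc_sample <- acc_sample + 1L
      }
    }
    if (s <= warmup && s %% 50 == 0) {
      rate <- acc_window / 50
      prop_sd <- ifelse(rate > 0.45, prop_sd * 1.15,
                        ifelse(rate < 0.30, prop_sd * 0.85, prop_sd))
      acc_window <- c(0L, 0L)
    }
    if (s > warmup) draws[s - warmup, ] <- c(plogis(theta[1]), exp(theta[2]))
  }
  list(draws = draws, accept_rate = acc_sample / (2 * iter))
}

# split R-hat on a iters x chains matrix (each chain halved)
split_rhat <- function(x) {
  n <- nrow(x)
  half <- floor(n / 2)
  halves <- cbind(x[seq_len(half), , drop = FALSE],
                  x[(n - half + 1):n, , drop = FALSE])
  m <- ncol(halves)
  means <- colMeans(halves)
  vars <- apply(halves, 2, var)
  w <- mean(vars)
  b <- half * var(means)
  var_plus <- (half - 1) / half * w + b / half
  if (w <= 0) return(1)
  sqrt(var_plus / w)
}

# effective sample size: Geyer initial-positive-sequence truncation on the
# chain-averaged autocorrelation (computed per chain then combined)
ess_geyer <- function(x) {
  n <- nrow(x)
  m <- ncol(x)
  max_lag <- min(n - 1, 200)
  rho <- rowMeans(vapply(seq_len(m), function(j) {
    a <- acf(x[, j], lag.max = max_lag, plot = FALSE, demean = TRUE)$acf[, 1, 1]
    a
  }, numeric(max_lag + 1)))
  # sum consecutive lag pairs while positive
  tau <- 1
  t <- 1
  while (t + 1 <= max_lag) {
    pair <- rho[t + 1] + rho[t + 2]
    if (!is.finite(pair) || pair <= 0) break
    tau <- tau + 2 * pair
    t <- t + 2
  }
  max(1, m * n / tau)
}

#' Fit the hierarchical Beta-Binomial brood viability model
#'
#' Fits, per group (genotype x window x dose, plus `mated` when present),
#' the marginal beta-binomial likelihood over individual hermaphrodite
#' broods, by MCMC with the bundled adaptive random-walk Metropolis sampler.
#' Groups are conditionally independent, so each is fit with its own
#' deterministic seed stream derived from the group key: the posterior for a
#' group is identical whether it is fit alone or alongside others.
#'
#' Zero-brood hermaphrodites (brood size 0) contribute no likelihood term
#' (their viability is undefined) but are counted in the returned summary.
#'
#' @param broods A brood table, validated via [validate_broods()]; must have
#'   `genotype`, `window`, `dose_rads`, `hatched`, `dead_eggs`.
#' @param priors A [brood_priors()] configuration.
#' @param control A [mcmc_control()] configuration.
#' @return An object of class `brood_fit` with elements `draws` (tibble:
#'   group keys, `chain`, `iter`, `phi`, `lambda`), `diagnostics` (split
#'   R-hat, bulk ESS, acceptance rate per group x parameter), `groups`,
#'   `data`, `priors`, `control`, `converged`. Methods: [tidy()],
#'   [glance()], [autoplot()].
#' @export
#' @examples
#' \donttest{
#' broods <- sim_brood(tibble::tibble(
#'   genotype = "wt", window = "T22_34", dose_rads = 0,
#'   phi = 0.9, lambda = 50, mean_brood = 200, n_herm = 15), seed = 1)
#' fit <- fit_brood_model(broods, control = mcmc_control(warmup = 500, iter = 500))
#' tidy(fit)
#' }
fit_brood_model <- function(broods, priors = brood_priors(),
                            control = mcmc_control()) {
  broods <- validate_broods(broods)
  key_cols <- intersect(c("genotype", "mated", "window", "dose_rads"),
                        names(broods))
  groups <- distinct(broods, across(all_of(key_cols)))
  if (nrow(groups) == 0) abort("no groups to fit.")

  fit_one <- function(grp) {
    sub <- left_join(grp, broods, by = key_cols)
    n_zero <- sum(sub$brood_size == 0)
    sub <- filter(sub, .data$brood_size > 0)
    if (nrow(sub) == 0) abort("a group has no hermaphrodite with brood size > 0.")
    k <- sub$hatched
    n <- sub$brood_size
    key_str <- paste(vapply(grp, as.character, character(1)), collapse = "|")
    base_seed <- derive_seed(control$seed, paste0("brood_fit|", key_str))
    phi0 <- (sum(k) + 1) / (sum(n) + 2)
    init <- c(qlogis(phi0), log(10))
    chains <- lapply(seq_len(control$chains), function(c_id) {
      bb_chain(k, n, priors, control$warmup, control$iter,
               seed = (base_seed + c_id) %% 2147483647L, init = init)
    })
    phi_mat <- vapply(chains, function(ch) ch$draws[, 1],
                      numeric(control$iter))
    lam_mat <- vapply(chains, function(ch) ch$draws[, 2],
                      numeric(control$iter))
    draws <- tibble(
      grp[rep(1, control$chains * control$iter), , drop = FALSE],
      chain = rep(seq_len(control$chains), each = control$iter),
      iter = rep(seq_len(control$iter), times = control$chains),
      phi = as.vector(phi_mat),
      lambda = as.vector(lam_mat)
    )
    diag <- tibble(
      grp[rep(1, 2), , drop = FALSE],
      parameter = c("phi", "lambda"),
      rhat = c(split_rhat(phi_mat), split_rhat(lam_mat)),
      ess_bulk = c(ess_geyer(phi_mat), ess_geyer(lam_mat)),
      accept_rate = mean(vapply(chains, `[[`, numeric(1), "accept_rate")),
      n_hermaphrodites = nrow(sub),
      n_zero_brood = n_zero
    )
    list(draws = draws, diag = diag)
  }

  pieces <- lapply(seq_len(nrow(groups)),
                   function(i) fit_one(groups[i, , drop = FALSE]))
  draws <- bind_rows(lapply(pieces, `[[`, "draws"))
  diagnostics <- bind_rows(lapply(pieces, `[[`, "diag"))
  converged <- all(diagnostics$rhat <= 1.01)
  if (!converged) {
    warn(sprintf("possible non-convergence: max split R-hat = %.3f",
                 max(diagnostics$rhat)))
  }
  structure(
    list(draws = draws, diagnostics = diagnostics, groups = groups,
         key_cols = key_cols, data = broods, priors = priors,
         control = control, converged = converged),
    class = "brood_fit"
  )
}

#' @export
print.brood_fit <- function(x, ...) {
  cat(sprintf(
    "Beta-Binomial brood viability fit: %d group(s), %d chains x %d draws\n",
    nrow(x$groups), x$control$chains, x$control$iter))
  cat(sprintf("  max split R-hat %.3f, min bulk ESS %.0f%s\n",
              max(x$diagnostics$rhat), min(x$diagnostics$ess_bulk),
              if (x$converged) "" else "  [NOT CONVERGED]"))
  print(tidy(x))
  invisible(x)
}

#' Posterior summaries of a brood viability fit
#'
#' @param x A `brood_fit` object.
#' @param conf_level Credible mass for the central interval, default 0.95.
#' @param ... Unused.
#' @return A tibble: group keys, `parameter` (phi / lambda), posterior
#'   `median`, `conf_low`, `conf_high`, `rhat`, `ess_bulk`.
#' @method tidy brood_fit
#' @export
tidy.brood_fit <- function(x, conf_level = 0.95, ...) {
  alpha <- (1 - conf_level) / 2
  x$draws %>%
    tidyr::pivot_longer(c("phi", "lambda"), names_to = "parameter",
                        values_to = "value") %>%
    group_by(across(all_of(c(x$key_cols, "parameter")))) %>%
    summarise(
      median = stats::median(.data$value),
      conf_low = stats::quantile(.data$value, alpha, names = FALSE),
      conf_high = stats::quantile(.data$value, 1 - alpha, names = FALSE),
      .groups = "drop"
    ) %>%
    left_join(select(x$diagnostics, all_of(c(x$key_cols, "parameter")),
                     "rhat", "ess_bulk"),
              by = c(x$key_cols, "parameter"))
}

#' One-line model fit summary
#'
#' @param x A `brood_fit` object.
#' @param ... Unused.
#' @return A one-row tibble: `n_groups`, `n_hermaphrodites`, `n_zero_brood`,
#'   `chains`, `iter`, `max_rhat`, `min_ess`, `converged`.
#' @method glance brood_fit
#' @export
glance.brood_fit <- function(x, ...) {
  per_group <- distinct(x$diagnostics,
                        across(all_of(x$key_cols)),
                        .data$n_hermaphrodites, .data$n_zero_brood)
  tibble(
    n_groups = nrow(x$groups),
    n_hermaphrodites = sum(per_group$n_hermaphrodites),
    n_zero_brood = sum(per_group$n_zero_brood),
    chains = x$control$chains,
    iter = x$control$iter,
    max_rhat = max(x$diagnostics$rhat),
    min_ess = min(x$diagnostics$ess_bulk),
    converged = x$converged
  )
}
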