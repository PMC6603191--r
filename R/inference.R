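FIT_PARS <- c("alpha0", "alpha_b", "beta_b", "delta")

#' Truncated-normal prior specification for the fitted parameters
#'
#' Independent normal priors, truncated at 0, for theta = (alpha0, alpha_b,
#' beta_b, delta). The default standard deviation of 10x the mean makes the
#' prior weakly informative around an initial guess.
#'
#' @param mean named numeric vector of prior means (names `alpha0`,
#'   `alpha_b`, `beta_b`, `delta`), all > 0.
#' @param sd named numeric vector of prior standard deviations (> 0).
#' @return Object of class `prior_spec`.
#' @export
prior_spec <- function(mean = c(alpha0 = 0.3, alpha_b = 0.3,
                                beta_b = 0.03, delta = 0.5),
                       sd = 10 * mean) {
  mean <- mean[FIT_PARS]; sd <- sd[FIT_PARS]
  if (anyNA(mean) || anyNA(sd))
    stop("prior mean and sd must be named vectors covering: ",
         paste(FIT_PARS, collapse = ", "))
  if (any(sd <= 0)) stop("prior sd must be > 0")
  if (any(mean < 0)) stop("prior means must be >= 0")
  structure(list(mean = mean, sd = sd), class = "prior_spec")
}

# -ln S predicted for acute single-dose records, vectorized over records.
# theta: named c(alpha0, alpha_b, beta_b, delta); fixed: list(beta0, a_plus_c).
model_neglog_s <- function(theta, fixed, field, dose, region) {
  of <- region == "out_of_field"
  gamma_te <- ifelse(of, field$gamma_of, field$gamma_if)
  d_te <- ifelse(of, field$scatter_fraction * dose, dose)
  w_t <- (theta[["alpha0"]] + gamma_te * fixed$beta0) * d_te +
    fixed$beta0 * d_te^2
  ab <- theta[["alpha_b"]]; bb <- theta[["beta_b"]]
  g_if <- pmin((ab + field$gamma_if * bb) * dose + bb * dose^2, 700)
  g_r <- pmin((ab + gamma_te * bb) * d_te + bb * d_te^2, 700)
  w_nt <- theta[["delta"]] * (-expm1(-g_if)) * exp(-g_r)
  w_t + w_nt
}

#' Model survival for single-dose exposures at given parameters
#'
#' Evaluates the combined TE + NTE surviving fraction for acute single-dose
#' records, with beta0 and a_plus_c held fixed (split-dose estimates) and
#' theta supplying the remaining parameters. This is the curve the MCMC fit
#' and the predictive bands are built on.
#'
#' @param theta named numeric vector `alpha0`, `alpha_b`, `beta_b`, `delta`.
#' @param fixed list with elements `beta0` (Gy^-2) and `a_plus_c` (h^-1).
#' @param field a [field_config()].
#' @param dose in-field dose(s), Gy.
#' @param region region label(s), recycled against `dose`.
#' @return Surviving fraction(s) in (0, 1].
#' @export
predict_survival <- function(theta, fixed, field, dose, region) {
  region <- check_region(region)
  n <- max(length(dose), length(region))
  dose <- rep_len(dose, n); region <- rep_len(region, n)
  exp(-pmin(model_neglog_s(theta, fixed, field, dose, region), 700))
}

#' Gaussian log-likelihood on the -ln S scale
#'
#' The measurement error of -ln S is modelled as normal with per-record
#' standard deviation `data$sd` (falling back to `fixed$sd`, default 0.1,
#' where missing). Records from all regions contribute as one sum.
#'
#' @param theta named numeric vector `alpha0`, `alpha_b`, `beta_b`, `delta`
#'   (all >= 0).
#' @param fixed list with `beta0`, `a_plus_c` and optionally `sd`.
#' @param data data.frame with columns `region`, `dose_Gy`,
#'   `surviving_fraction` and optionally `sd` (standard deviation of -ln S).
#' @param field a [field_config()].
#' @return Log-likelihood (0 for an empty dataset).
#' @export
log_likelihood <- function(theta, fixed, data, field) {
  if (nrow(data) == 0) return(0)
  sf <- data$surviving_fraction
  if (any(!is.finite(sf)) || any(sf <= 0) || any(sf > 1))
    stop("surviving fractions must be in (0, 1]")
  sd <- data$sd
  if (is.null(sd)) sd <- rep(NA_real_, nrow(data))
  fallback <- if (!is.null(fixed$sd)) fixed$sd else 0.1
  sd <- ifelse(is.na(sd) | sd <= 0, fallback, sd)
  w_obs <- -log(sf)
  w_mod <- model_neglog_s(theta, fixed, field, data$dose_Gy,
                          check_region(data$region))
  sum(stats::dnorm(w_obs, w_mod, sd, log = TRUE))
}

#' Random-walk Metropolis sampling of theta = (alpha0, alpha_b, beta_b, delta)
#'
#' Component-wise Gaussian random-walk Metropolis with reflection at zero
#' (keeping the proposal symmetric on the non-negative half-line) under
#' truncated-normal priors. Proposal scales are adapted in blocks of 100
#' iterations during burn-in towards a 20-50% acceptance rate and then
#' frozen, so chains are reproducible functions of `seed`. The caller's RNG
#' state is restored on exit.
#'
#' @param data survival dataset (see [log_likelihood()]).
#' @param fixed list with `beta0`, `a_plus_c` and optionally `sd`.
#' @param field a [field_config()].
#' @param priors a [prior_spec()].
#' @param n_draws total chain length (default 20000).
#' @param n_burn burn-in iterations discarded (default 5000).
#' @param proposal_sd optional named vector of initial proposal scales.
#' @param seed integer RNG seed (required).
#' @param n_thin keep every n_thin-th post-burn draw.
#' @return Object of class `imk_posterior`: `draws` (matrix, one column per
#'   parameter), `log_posterior`, `acceptance_rate` (per parameter,
#'   post-burn), `proposal_sd` (final), `seed`, `n_burn`, `n_thin`.
#' @export
run_mcmc <- function(data, fixed, field, priors = prior_spec(),
                     n_draws = 20000, n_burn = 5000, proposal_sd = NULL,
                     seed, n_thin = 1) {
  stopifnot(inherits(priors, "prior_spec"), n_draws > n_burn, n_burn >= 0,
            n_thin >= 1)
  if (missing(seed)) stop("seed is required for a reproducible chain")
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)

  log_post <- function(th) {
    lp <- sum(stats::dnorm(th, priors$mean, priors$sd, log = TRUE))
    lp + log_likelihood(th, fixed, data, field)
  }

  cur <- pmax(priors$mean, 1e-6)
  names(cur) <- FIT_PARS
  ps <- if (is.null(proposal_sd)) 0.25 * pmax(cur, 0.01) else proposal_sd[FIT_PARS]
  lp_cur <- log_post(cur)
  if (!is.finite(lp_cur)) stop("log-posterior not finite at the initial value")

  keep_idx <- seq(n_burn + 1, n_draws, by = n_thin)
  draws <- matrix(NA_real_, length(keep_idx), 4,
                  dimnames = list(NULL, FIT_PARS))
  lp_keep <- numeric(length(keep_idx))
  acc_post <- integer(4); n_post <- 0L
  acc_block <- integer(4); block <- 0L
  k <- 1L

  for (i in seq_len(n_draws)) {
    for (j in 1:4) {
      prop <- cur
      prop[j] <- abs(cur[j] + stats::rnorm(1, 0, ps[j]))  # reflect at 0
      lp_prop <- log_post(prop)
      if (is.finite(lp_prop) && log(stats::runif(1)) < lp_prop - lp_cur) {
        cur <- prop; lp_cur <- lp_prop
        if (i <= n_burn) acc_block[j] <- acc_block[j] + 1L
        else acc_post[j] <- acc_post[j] + 1L
      }
    }
    if (i <= n_burn) {
      block <- block + 1L
      if (block == 100L) {
        rate <- acc_block / 100
        ps <- ps * ifelse(rate < 0.2, 0.7, ifelse(rate > 0.5, 1.4, 1))
        acc_block[] <- 0L; block <- 0L
      }
    } else n_post <- n_post + 1L
    if (k <= length(keep_idx) && i == keep_idx[k]) {
      draws[k, ] <- cur; lp_keep[k] <- lp_cur; k <- k + 1L
    }
  }
  acceptance <- acc_post / n_post
  if (all(acceptance == 0))
    stop("chain rejected every post-burn-in proposal; ",
         "check the data scale or supply smaller proposal_sd")
  structure(list(draws = draws, log_posterior = lp_keep,
                 acceptance_rate = acceptance, proposal_sd = ps,
                 seed = seed, n_burn = n_burn, n_thin = n_thin),
            class = "imk_posterior")
}

#' @export
print.imk_posterior <- function(x, ...) {
  cat(sprintf("<imk_posterior: %d draws, acceptance %s>\n", nrow(x$draws),
              paste(sprintf("%s=%.2f", colnames(x$draws),
                            x$acceptance_rate), collapse = " ")))
  print(round(rbind(mean = colMeans(x$draws),
                    sd = apply(x$draws, 2, stats::sd)), 5))
  invisible(x)
}

#' Posterior summaries, goodness of fit and 95.4% predictive band
#'
#' Parameter means and standard deviations, a pointwise predictive band
#' (default 95.4%, the +-2 sigma convention: 2.3% and 97.7% quantiles of the
#' survival curves evaluated over the retained draws), and R^2 / chi^2 of the
#' posterior-mean curve against the data on the survival scale (survival-
#' scale sigma obtained from the -ln S sd by the delta method).
#'
#' @param samples an `imk_posterior` from [run_mcmc()].
#' @param data the fitted dataset.
#' @param fixed,field as passed to [run_mcmc()].
#' @param dose_grid doses (Gy) at which to evaluate the band.
#' @param level band coverage (default 0.954).
#' @param max_curves cap on the number of draws used for the band.
#' @return List of class `imk_fit_summary`: `params` (data.frame with mean,
#'   sd), `band` (data.frame region/dose_Gy/mean/lower/upper), `r_squared`,
#'   `chi_squared`.
#' @export
posterior_summary <- function(samples, data, fixed, field,
                              dose_grid = seq(0, 10, by = 0.5),
                              level = 0.954, max_curves = 400) {
  stopifnot(inherits(samples, "imk_posterior"))
  nd <- nrow(samples$draws)
  if (nd < 100) stop("need at least 100 post-burn-in draws for summaries")
  params <- data.frame(
    parameter = colnames(samples$draws),
    mean = colMeans(samples$draws),
    sd = apply(samples$draws, 2, stats::sd),
    row.names = NULL)

  regions <- unique(as.character(data$region))
  pick <- unique(round(seq(1, nd, length.out = min(max_curves, nd))))
  qs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  band <- do.call(rbind, lapply(regions, function(rg) {
    curves <- vapply(pick, function(i)
      predict_survival(samples$draws[i, ], fixed, field, dose_grid, rg),
      numeric(length(dose_grid)))
    data.frame(region = rg, dose_Gy = dose_grid,
               mean = rowMeans(curves),
               lower = apply(curves, 1, stats::quantile, probs = qs[1]),
               upper = apply(curves, 1, stats::quantile, probs = qs[2]))
  }))
  rownames(band) <- NULL

  theta_hat <- stats::setNames(params$mean, params$parameter)
  cal <- predict_survival(theta_hat, fixed, field, data$dose_Gy,
                          as.character(data$region))
  obs <- data$surviving_fraction
  sd_lnS <- data$sd
  if (is.null(sd_lnS)) sd_lnS <- rep(NA_real_, nrow(data))
  fallback <- if (!is.null(fixed$sd)) fixed$sd else 0.1
  sd_lnS <- ifelse(is.na(sd_lnS) | sd_lnS <= 0, fallback, sd_lnS)
  structure(list(params = params, band = band,
                 r_squared = r_squared(obs, cal),
                 chi_squared = chi_squared(obs, cal, obs * sd_lnS)),
            class = "imk_fit_summary")
}

#' @export
print.imk_fit_summary <- function(x, ...) {
  cat("IMK fit summary\n")
  print(transform(x$params, mean = round(mean, 5), sd = round(sd, 5)))
  cat(sprintf("R^2 = %.4f, chi^2 = %.4f\n", x$r_squared, x$chi_squared))
  invisible(x)
}

#' Coefficient of determination
#'
#' R^2 = 1 - sum((obs - cal)^2) / sum((obs - mean(obs))^2), computed on the
#' survival scale by default or on -ln S with `scale = "neglog"`.
#'
#' @param observed,calculated numeric vectors of equal length (>= 2).
#' @param scale `"survival"` or `"neglog"`.
#' @return R^2 <= 1.
#' @export
r_squared <- function(observed, calculated, scale = c("survival", "neglog")) {
  scale <- match.arg(scale)
  stopifnot(length(observed) == length(calculated), length(observed) >= 2)
  if (scale == "neglog") {
    observed <- -log(observed); calculated <- -log(calculated)
  }
  ss_tot <- sum((observed - mean(observed))^2)
  if (ss_tot == 0) stop("observed values have zero variance")
  1 - sum((observed - calculated)^2) / ss_tot
}

#' Reduced chi-squared of a fit
#'
#' chi^2 = (1/n) sum((obs_i - cal_i)^2 / sigma_i^2). Points with zero or
#' missing sigma are excluded with a warning and n adjusted accordingly.
#'
#' @param observed,calculated numeric vectors of equal length.
#' @param sd per-point standard deviations of `observed`.
#' @return Mean squared standardized residual.
#' @export
chi_squared <- function(observed, calculated, sd) {
  stopifnot(length(observed) == length(calculated),
            length(observed) == length(sd))
  ok <- is.finite(sd) & sd > 0
  if (!any(ok)) stop("all standard deviations are zero or missing")
  if (!all(ok))
    warning(sum(!ok), " point(s) with sd = 0 excluded from chi-squared")
  mean(((observed[ok] - calculated[ok]) / sd[ok])^2)
}
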