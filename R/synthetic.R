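# Run fn with a seed, restoring the caller's RNG state afterwards.
with_seed <- function(seed, fn) {
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)
  fn()
}

default_regions <- function(field) {
  if (field$a_if >= 1) "uniform" else c("in_field", "out_of_field")
}

theta_of <- function(te, nte) {
  c(alpha0 = te$alpha0, alpha_b = nte$alpha_b, beta_b = nte$beta_b,
    delta = nte$delta)
}

# Additive Gaussian noise on -ln S, truncated below at 0 so recorded survival
# never exceeds the unirradiated control; zero-dose records stay exactly at
# S = 1 (they define the normalization). Matches the likelihood's error model.
add_lnS_noise <- function(w_true, noise_sd) {
  if (noise_sd == 0) return(w_true)
  eps <- stats::rnorm(length(w_true), 0, noise_sd)
  ifelse(w_true > 0, pmax(w_true + eps, 0), w_true)
}

survival_record <- function(experiment_id, schedule_label, region, dose,
                            w_obs, noise_sd, n_replicates) {
  data.frame(experiment_id = experiment_id, schedule_label = schedule_label,
             region = region, dose_Gy = dose,
             surviving_fraction = exp(-pmin(w_obs, 700)),
             sd = noise_sd, n_replicates = n_replicates,
             stringsAsFactors = FALSE)
}

check_gen_seed <- function(noise_sd, seed) {
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (noise_sd > 0 && (missing(seed) || is.null(seed)))
    stop("seed is mandatory when noise_sd > 0")
}

#' Generate a synthetic single-dose dose-response dataset
#'
#' Emulates a clonogenic dose-response experiment: for every dose and region
#' the model's expected -ln S (acute exposure) receives additive Gaussian
#' noise of standard deviation `noise_sd` — the uncertainty of the reported
#' mean over `n_replicates` replicate flasks — and the record stores the
#' noisy surviving fraction together with `sd = noise_sd` on the -ln S scale.
#' Zero-dose controls are reported as exactly 1.
#'
#' @param te a [te_params()] set used for all targeted-effect regions.
#' @param nte an [nte_params()] set.
#' @param field a [field_config()]; the default regions follow its geometry
#'   (`a_if < 1`: in-field + out-of-field, `a_if = 1`: uniform).
#' @param doses dose grid in Gy.
#' @param regions region labels to generate (default from `field`).
#' @param noise_sd Gaussian sd on -ln S (default 0.1; 0 for noiseless).
#' @param n_replicates replicate count recorded with each point.
#' @param seed RNG seed; mandatory when `noise_sd > 0`.
#' @param experiment_id label stored in the records.
#' @return data.frame with columns `experiment_id`, `schedule_label`,
#'   `region`, `dose_Gy`, `surviving_fraction`, `sd`, `n_replicates`.
#' @export
generate_dose_response <- function(te, nte, field = field_config(),
                                   doses = c(0, 0.5, 1, 2, 4, 6, 8, 10),
                                   regions = default_regions(field),
                                   noise_sd = 0.1, n_replicates = 3,
                                   seed = NULL, experiment_id = "dose_response") {
  stopifnot(inherits(te, "te_params"), inherits(nte, "nte_params"))
  if (any(doses < 0)) stop("doses must be >= 0")
  check_gen_seed(noise_sd, seed)
  regions <- check_region(regions)
  gen <- function() {
    do.call(rbind, lapply(regions, function(rg) {
      w <- model_neglog_s(theta_of(te, nte), list(beta0 = te$beta0), field,
                          doses, rep_len(rg, length(doses)))
      survival_record(experiment_id, "acute", rg, doses,
                      add_lnS_noise(w, noise_sd), noise_sd, n_replicates)
    }))
  }
  if (noise_sd > 0) with_seed(seed, gen) else gen()
}

#' Generate a synthetic split-dose recovery curve
#'
#' Two equal (or unequal) acute fractions separated by each inter-fraction
#' time in `taus`. `method = "discretized"` evaluates the full discretized
#' lethal-lesion sum through [imk_survival()]; `"closed_form"` uses the exact
#' two-impulse limit w_T = w(d1) + w(d2) + 2 beta0 d1 d2 exp(-(a+c) tau)
#' (valid because the fractions are acute), which is much faster and agrees
#' with the discretized route to the solver tolerance. Non-targeted killing
#' depends only on the cumulative dose, so it shifts the whole curve by a
#' constant factor.
#'
#' @param te,nte,field model parameter sets (see [imk_survival()]).
#' @param region exposed region of the recorded cells.
#' @param d1,d2 fraction doses (Gy).
#' @param taus inter-fraction times (hours, strictly increasing).
#' @param noise_sd Gaussian sd on -ln S (0 for a noiseless model curve).
#' @param n_replicates replicate count recorded with each point.
#' @param seed RNG seed; mandatory when `noise_sd > 0`.
#' @param method `"discretized"` or `"closed_form"`.
#' @param epsilon acute fraction duration (h) for the discretized route.
#' @param rel_tol convergence tolerance for the discretized route.
#' @return A [recovery_curve()]; the noiseless model curve when
#'   `noise_sd = 0`.
#' @export
generate_recovery_curve <- function(te, nte, field = field_config(),
                                    region = "uniform", d1 = 2, d2 = 2,
                                    taus = c(0, 0.25, 0.5, 1, 2, 4, 24, 48),
                                    noise_sd = 0, n_replicates = 3,
                                    seed = NULL,
                                    method = c("discretized", "closed_form"),
                                    epsilon = 1e-6, rel_tol = 1e-10) {
  method <- match.arg(method)
  region <- check_region(region)
  check_gen_seed(noise_sd, seed)
  d_total <- d1 + d2
  if (method == "closed_form") {
    gamma_te <- if (region == "out_of_field") field$gamma_of else field$gamma_if
    scatter <- if (region == "out_of_field") field$scatter_fraction else 1
    e1 <- scatter * d1; e2 <- scatter * d2
    w_t <- (te$alpha0 + gamma_te * te$beta0) * (e1 + e2) +
      te$beta0 * (e1^2 + e2^2) +
      2 * te$beta0 * e1 * e2 * exp(-pmin(te$a_plus_c * taus, 700))
    w <- w_t + w_nte(nte, field, d_total, region)
  } else {
    w <- vapply(taus, function(tau) {
      sched <- make_split(d1, d2, tau, "acute", epsilon = epsilon)
      -log(imk_survival(te, nte, field, sched, region, rel_tol = rel_tol))
    }, numeric(1))
  }
  gen <- function() {
    w_obs <- add_lnS_noise(w, noise_sd)
    recovery_curve(taus, exp(-pmin(w_obs, 700)),
                   sd = rep(if (noise_sd > 0) noise_sd else NA_real_,
                            length(taus)),
                   d1 = d1, d2 = d2)
  }
  if (noise_sd > 0) with_seed(seed, gen) else gen()
}

#' Generate a synthetic dose-rate-regimen dataset
#'
#' One record per delivery regimen and region, each regimen delivering the
#' same total dose over a different temporal pattern (see
#' [dose_rate_regimens()]). With `a_plus_c = 0` the noiseless survival is
#' identical across regimens; with repair active, survival rises as the
#' average dose rate falls.
#'
#' @param te,nte,field model parameter sets.
#' @param regimens named list of [delivery_schedule()]s.
#' @param regions region labels to generate (default from `field`).
#' @param noise_sd Gaussian sd on -ln S.
#' @param n_replicates replicate count recorded with each point.
#' @param seed RNG seed; mandatory when `noise_sd > 0`.
#' @param rel_tol convergence tolerance passed to [imk_survival()].
#' @return data.frame in the same layout as [generate_dose_response()].
#' @export
generate_doserate_regimens <- function(te, nte, field = field_config(),
                                       regimens = dose_rate_regimens(),
                                       regions = default_regions(field),
                                       noise_sd = 0.1, n_replicates = 3,
                                       seed = NULL, rel_tol = 1e-8) {
  stopifnot(is.list(regimens), length(regimens) >= 1)
  check_gen_seed(noise_sd, seed)
  regions <- check_region(regions)
  gen <- function() {
    do.call(rbind, lapply(names(regimens), function(nm) {
      sched <- regimens[[nm]]
      do.call(rbind, lapply(regions, function(rg) {
        w <- -log(imk_survival(te, nte, field, sched, rg, rel_tol = rel_tol))
        survival_record("dose_rate_regimens", nm, rg, total_dose(sched),
                        add_lnS_noise(w, noise_sd), noise_sd, n_replicates)
      }))
    }))
  }
  if (noise_sd > 0) with_seed(seed, gen) else gen()
}
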