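#' Probability that a cell carries an activated signal-releasing target
#'
#' f_h(D) = 1 - exp(-((alpha_b + gamma beta_b) D + beta_b D^2)): the Poisson
#' probability that at least one micron-scale target triggering intercellular
#' signal release is activated after cumulative dose D. Depends on cumulative
#' dose only, never on how the dose was fractionated in time. The non-hit
#' fraction is f_b(D) = 1 - f_h(D).
#'
#' @param nte an [nte_params()] set.
#' @param gamma microdosimetric constant (Gy) of the region receiving `dose`.
#' @param dose cumulative absorbed dose in Gy (>= 0); vectorized.
#' @return f_h in [0, 1).
#' @export
hit_fraction <- function(nte, gamma, dose) {
  stopifnot(inherits(nte, "nte_params"))
  if (any(!is.finite(dose)) || any(dose < 0)) stop("dose must be >= 0")
  g <- pmin((nte$alpha_b + gamma * nte$beta_b) * dose + nte$beta_b * dose^2, 700)
  -expm1(-g)
}

#' Signal-mediated (non-targeted) lethal lesions per cell
#'
#' w_NT = delta * f_h(D_IF; gamma_IF) * f_b(D_region; gamma_region): lethal
#' lesions induced in non-hit cells by signals emitted from hit in-field
#' cells. The recipient dose D_region equals the in-field dose for in-field
#' and uniform exposures, and `scatter_fraction * d_if` out-of-field. Since
#' both factors are probabilities, w_NT is bounded by delta.
#'
#' @param nte an [nte_params()] set.
#' @param field a [field_config()].
#' @param d_if dose delivered to the in-field region (Gy, >= 0); vectorized.
#' @param region `"in_field"`, `"out_of_field"` or `"uniform"`.
#' @return w_NT in [0, delta].
#' @export
w_nte <- function(nte, field, d_if, region) {
  stopifnot(inherits(nte, "nte_params"), inherits(field, "field_config"))
  region <- check_region(region)
  stopifnot(length(region) == 1)
  if (any(!is.finite(d_if)) || any(d_if < 0)) stop("d_if must be >= 0")
  fh_if <- hit_fraction(nte, field$gamma_if, d_if)
  if (region == "out_of_field") {
    d_r <- field$scatter_fraction * d_if
    g_r <- field$gamma_of
  } else {
    d_r <- d_if
    g_r <- field$gamma_if
  }
  nte$delta * fh_if * (1 - hit_fraction(nte, g_r, d_r))
}

#' Surviving fraction under the combined TE + NTE model
#'
#' S = exp(-(w_T + w_NT)): survival factorizes exactly into a targeted and a
#' non-targeted component because lesion counts are Poisson and the two lesion
#' classes do not interact. The targeted dose seen by out-of-field cells is
#' the schedule scaled by `field$scatter_fraction` (0 by default: all
#' out-of-field killing is signal-mediated); non-targeted killing everywhere
#' depends only on the cumulative in-field dose.
#'
#' @param te a [te_params()] set for the exposed region.
#' @param nte an [nte_params()] set.
#' @param field a [field_config()].
#' @param schedule a [delivery_schedule()] describing the in-field delivery.
#' @param region `"in_field"`, `"out_of_field"` or `"uniform"`.
#' @param rel_tol convergence tolerance passed to [w_te()].
#' @return Surviving fraction in (0, 1].
#' @export
imk_survival <- function(te, nte, field, schedule, region = "uniform",
                         rel_tol = 1e-6) {
  stopifnot(inherits(schedule, "delivery_schedule"))
  region <- check_region(region)
  d_if <- total_dose(schedule)
  if (region == "out_of_field") {
    w_t <- if (field$scatter_fraction > 0)
      as.numeric(w_te(te, field$gamma_of,
                      scale_schedule(schedule, field$scatter_fraction),
                      rel_tol = rel_tol))
    else 0
  } else {
    w_t <- as.numeric(w_te(te, field$gamma_if, schedule, rel_tol = rel_tol))
  }
  w_nt <- w_nte(nte, field, d_if, region)
  exp(-pmin(w_t + w_nt, 700))
}

#' Survival of a mixed in-field population with post-irradiation migration
#'
#' S = (1 - f_move) S_IF + f_move S_M: a fraction `f_move` of the cells scored
#' in the in-field region migrated there from the shielded region during
#' incubation and survive with probability `s_m` (default 1). With `s_m = 1`
#' the measured survival plateaus at `f_move` at high dose.
#'
#' @param s_if surviving fraction of the resident in-field cells, in (0, 1];
#'   vectorized.
#' @param f_move migrating fraction in [0, 1].
#' @param s_m surviving fraction of the migrants.
#' @return Mixed surviving fraction.
#' @export
migration_adjusted_survival <- function(s_if, f_move, s_m = 1.0) {
  if (!is.numeric(f_move) || length(f_move) != 1 || is.na(f_move) ||
      f_move < 0 || f_move > 1)
    stop("f_move must be in [0, 1]")
  if (any(!is.finite(s_if)) || any(s_if <= 0) || any(s_if > 1))
    stop("s_if must be in (0, 1]")
  stopifnot(s_m >= 0, s_m <= 1)
  (1 - f_move) * s_if + f_move * s_m
}

#' Rescale targeted-effect coefficients for a changed initial damage yield
#'
#' In the kinetic model alpha0 = a k / c and beta0 = b k^2 / (2 c), with k the
#' initial yield of potentially lethal lesions per Gy. Changing k by a factor
#' `k_ratio` (e.g. the measured half-field / uniform-field DNA damage-yield
#' ratio, 0.642) therefore scales alpha0 by `k_ratio` and beta0 by
#' `k_ratio^2`, with the rate constants (and hence `a_plus_c`) unchanged.
#'
#' @param te a [te_params()] set.
#' @param k_ratio damage-yield ratio (> 0).
#' @return A rescaled [te_params()] set.
#' @export
scale_by_damage_yield <- function(te, k_ratio) {
  stopifnot(inherits(te, "te_params"))
  if (!is.numeric(k_ratio) || length(k_ratio) != 1 || !is.finite(k_ratio) ||
      k_ratio <= 0)
    stop("k_ratio must be > 0")
  te_params(te$alpha0 * k_ratio, te$beta0 * k_ratio^2, te$a_plus_c)
}
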