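#' Temporal dose-delivery schedules
#'
#' A `delivery_schedule` is an ordered set of non-overlapping beam-on segments,
#' each with a start time (h), a duration (h) and a constant dose rate (Gy/h).
#' Beam-off gaps are simply the spaces between segments. All of the package's
#' survival calculations consume this one representation, so acute, split,
#' constant-rate and pulsed multi-fraction exposures share a single code path.
#'
#' @param segments data.frame with columns `start_h`, `duration_h` and
#'   `dose_rate_Gy_per_h`; rows must be time-ordered and non-overlapping.
#' @param label short text label for the schedule.
#' @return An object of class `delivery_schedule`.
#' @seealso [make_acute()], [make_split()], [make_constant_rate()],
#'   [dose_rate_regimens()], [discretize()]
#' @export
delivery_schedule <- function(segments, label = "schedule") {
  stopifnot(is.data.frame(segments))
  req <- c("start_h", "duration_h", "dose_rate_Gy_per_h")
  if (!all(req %in% names(segments)))
    stop("segments must have columns: ", paste(req, collapse = ", "))
  segments <- segments[req]
  for (col in req) {
    v <- segments[[col]]
    if (!is.numeric(v) || anyNA(v) || any(!is.finite(v)))
      stop("segment column '", col, "' must be finite numeric")
  }
  if (any(segments$start_h < 0)) stop("segment start times must be >= 0")
  if (any(segments$duration_h <= 0)) stop("segment durations must be > 0")
  if (any(segments$dose_rate_Gy_per_h < 0)) stop("dose rates must be >= 0")
  if (nrow(segments) > 1) {
    o <- order(segments$start_h)
    segments <- segments[o, , drop = FALSE]
    ends <- segments$start_h + segments$duration_h
    if (any(segments$start_h[-1] < ends[-nrow(segments)] - 1e-12))
      stop("segments overlap in time")
  }
  rownames(segments) <- NULL
  structure(list(segments = segments, label = label),
            class = "delivery_schedule")
}

#' @export
print.delivery_schedule <- function(x, ...) {
  cat(sprintf("<delivery_schedule '%s': %d segment(s), %.6g Gy over %.6g h>\n",
              x$label, nrow(x$segments), total_dose(x), total_time(x)))
  invisible(x)
}

#' Total dose and total exposure time of a schedule
#'
#' `total_dose()` integrates dose rate over all segments; `total_time()` is the
#' span from the start of the first segment to the end of the last (beam-off
#' gaps included).
#'
#' @param schedule a [delivery_schedule()].
#' @return A single numeric value (Gy, or hours).
#' @export
total_dose <- function(schedule) {
  stopifnot(inherits(schedule, "delivery_schedule"))
  with(schedule$segments, sum(duration_h * dose_rate_Gy_per_h))
}

#' @rdname total_dose
#' @export
total_time <- function(schedule) {
  stopifnot(inherits(schedule, "delivery_schedule"))
  s <- schedule$segments
  max(s$start_h + s$duration_h) - min(s$start_h)
}

#' Effectively instantaneous ("acute") exposure
#'
#' True instantaneity is represented by a single segment of very short finite
#' duration (`epsilon`, default 1e-6 h) so every exposure flows through the
#' same schedule machinery. At this duration the dose-protraction factor is
#' indistinguishable from 1 for any realistic repair rate.
#'
#' @param dose absorbed dose in Gy (>= 0).
#' @param epsilon segment duration in hours.
#' @param label schedule label.
#' @return A [delivery_schedule()].
#' @export
make_acute <- function(dose, epsilon = 1e-6, label = sprintf("acute %g Gy", dose)) {
  if (!is.numeric(dose) || length(dose) != 1 || is.na(dose) || dose < 0)
    stop("dose must be a single non-negative number")
  stopifnot(epsilon > 0)
  delivery_schedule(
    data.frame(start_h = 0, duration_h = epsilon,
               dose_rate_Gy_per_h = dose / epsilon),
    label = label)
}

#' Split-dose exposure (two fractions separated by an incubation gap)
#'
#' @param d1,d2 first and second fraction doses (Gy, >= 0).
#' @param tau inter-fraction time in hours, measured from the end of the first
#'   fraction to the start of the second.
#' @param fraction_rate either the string `"acute"` (each fraction delivered in
#'   `epsilon` hours) or a dose rate in Gy/h applied to both fractions.
#' @param epsilon acute fraction duration in hours.
#' @return A [delivery_schedule()].
#' @export
make_split <- function(d1, d2, tau, fraction_rate = "acute", epsilon = 1e-6) {
  if (!is.numeric(d1) || d1 < 0 || !is.numeric(d2) || d2 < 0)
    stop("fraction doses must be non-negative")
  if (!is.numeric(tau) || length(tau) != 1 || is.na(tau) || tau < 0)
    stop("tau must be a single non-negative number of hours")
  if (identical(fraction_rate, "acute")) {
    dur1 <- epsilon; dur2 <- epsilon
    r1 <- d1 / dur1; r2 <- d2 / dur2
  } else {
    stopifnot(is.numeric(fraction_rate), fraction_rate > 0)
    dur1 <- d1 / fraction_rate; dur2 <- d2 / fraction_rate
    if (dur1 <= 0) dur1 <- epsilon
    if (dur2 <= 0) dur2 <- epsilon
    r1 <- d1 / dur1; r2 <- d2 / dur2
  }
  delivery_schedule(
    data.frame(start_h = c(0, dur1 + tau),
               duration_h = c(dur1, dur2),
               dose_rate_Gy_per_h = c(r1, r2)),
    label = sprintf("split %g+%g Gy, tau=%g h", d1, d2, tau))
}

#' Continuous constant-dose-rate exposure
#'
#' @param dose total dose in Gy (>= 0).
#' @param rate dose rate in Gy/h (> 0).
#' @return A [delivery_schedule()] with one segment of duration `dose/rate`.
#' @export
make_constant_rate <- function(dose, rate) {
  if (!is.numeric(dose) || dose < 0) stop("dose must be >= 0")
  if (!is.numeric(rate) || length(rate) != 1 || is.na(rate) || rate <= 0)
    stop("rate must be > 0")
  dur <- if (dose > 0) dose / rate else 1e-6
  delivery_schedule(
    data.frame(start_h = 0, duration_h = dur, dose_rate_Gy_per_h = dose / dur),
    label = sprintf("%g Gy at %g Gy/h", dose, rate))
}

#' Pulsed regimen reaching a prescribed average dose rate
#'
#' Emulates a dose plan in which the beam runs at its native output
#' (`beam_rate_Gy_per_min`, default 0.59 Gy/min) in `n_pulses` equal pulses,
#' with equal beam-off gaps sized so the whole delivery averages
#' `avg_rate_Gy_per_min`. When the requested average equals the beam output a
#' single continuous segment is returned. The pulse structure is a configurable
#' approximation to machine-specific delivery logs, not a measured timeline.
#'
#' @param avg_rate_Gy_per_min average dose rate over the full delivery (Gy/min).
#' @param total_dose_Gy total dose (Gy), default 4.
#' @param beam_rate_Gy_per_min instantaneous beam-on dose rate (Gy/min).
#' @param n_pulses number of beam-on pulses used to stretch the delivery.
#' @return A [delivery_schedule()].
#' @export
make_regimen <- function(avg_rate_Gy_per_min, total_dose_Gy = 4,
                         beam_rate_Gy_per_min = 0.59, n_pulses = 8) {
  stopifnot(avg_rate_Gy_per_min > 0, total_dose_Gy >= 0,
            beam_rate_Gy_per_min > 0, n_pulses >= 1)
  if (avg_rate_Gy_per_min > beam_rate_Gy_per_min + 1e-12)
    stop("average rate cannot exceed the beam-on rate")
  lab <- sprintf("%g Gy avg %g Gy/min", total_dose_Gy, avg_rate_Gy_per_min)
  beam_h <- beam_rate_Gy_per_min * 60
  t_total <- total_dose_Gy / (avg_rate_Gy_per_min * 60)
  t_on <- total_dose_Gy / beam_h
  if (abs(avg_rate_Gy_per_min - beam_rate_Gy_per_min) < 1e-9 || n_pulses == 1)
    return(make_constant_rate(total_dose_Gy, beam_h))
  pulse <- t_on / n_pulses
  gap <- (t_total - t_on) / (n_pulses - 1)
  starts <- (seq_len(n_pulses) - 1) * (pulse + gap)
  delivery_schedule(
    data.frame(start_h = starts, duration_h = pulse,
               dose_rate_Gy_per_h = beam_h),
    label = lab)
}

#' Preset pulsed regimens: 4 Gy at four average dose rates
#'
#' The four deliveries average 0.59, 0.2, 0.1 and 0.05 Gy/min for a total dose
#' of 4 Gy, built with [make_regimen()] (beam-on at 0.59 Gy/min). These are
#' data, not code: pass your own schedules anywhere a preset is accepted.
#'
#' @param total_dose_Gy total dose per regimen (Gy).
#' @param avg_rates_Gy_per_min average rates defining the regimens.
#' @return Named list of [delivery_schedule()] objects.
#' @export
dose_rate_regimens <- function(total_dose_Gy = 4,
                               avg_rates_Gy_per_min = c(0.59, 0.2, 0.1, 0.05)) {
  out <- lapply(avg_rates_Gy_per_min, make_regimen,
                total_dose_Gy = total_dose_Gy)
  names(out) <- sprintf("%g_Gy_per_min", avg_rates_Gy_per_min)
  out
}

#' Discretize a schedule onto a uniform time grid
#'
#' Splits the schedule's total time span into `n_steps` equal sub-sections of
#' width `delta_t` and integrates the dose rate over each, so the sub-section
#' doses sum exactly to the schedule's total dose (to ~1e-9 relative).
#'
#' @param schedule a [delivery_schedule()].
#' @param n_steps number of sub-sections (>= 1).
#' @return An object of class `discretized_schedule` with fields `delta_t`
#'   (h), `segment_doses` (Gy per sub-section), `n_steps` and `t0` (absolute
#'   start time, h).
#' @export
discretize <- function(schedule, n_steps) {
  stopifnot(inherits(schedule, "delivery_schedule"))
  if (!is.numeric(n_steps) || length(n_steps) != 1 || is.na(n_steps) || n_steps < 1)
    stop("n_steps must be >= 1")
  n_steps <- as.integer(n_steps)
  s <- schedule$segments
  t0 <- min(s$start_h)
  tt <- total_time(schedule)
  dt <- tt / n_steps
  doses <- numeric(n_steps)
  edges_lo <- t0 + (seq_len(n_steps) - 1) * dt
  edges_hi <- edges_lo + dt
  for (i in seq_len(nrow(s))) {
    a <- s$start_h[i]; b <- a + s$duration_h[i]; r <- s$dose_rate_Gy_per_h[i]
    if (r == 0) next
    lo <- max(1L, min(n_steps, 1L + floor((a - t0) / dt)))
    hi <- max(1L, min(n_steps, 1L + floor((b - t0) / dt - 1e-15)))
    idx <- lo:hi
    ov <- pmin(edges_hi[idx], b) - pmax(edges_lo[idx], a)
    ov[ov < 0] <- 0
    doses[idx] <- doses[idx] + r * ov
  }
  structure(list(delta_t = dt, segment_doses = doses, n_steps = n_steps, t0 = t0),
            class = "discretized_schedule")
}

#' @export
print.discretized_schedule <- function(x, ...) {
  cat(sprintf("<discretized_schedule: %d steps of %.6g h, %.6g Gy total>\n",
              x$n_steps, x$delta_t, sum(x$segment_doses)))
  invisible(x)
}

# Scale every dose rate in a schedule by a constant (used for out-of-field
# scattered dose). Zero factor gives a valid zero-dose schedule.
scale_schedule <- function(schedule, factor) {
  stopifnot(inherits(schedule, "delivery_schedule"), factor >= 0)
  s <- schedule$segments
  s$dose_rate_Gy_per_h <- s$dose_rate_Gy_per_h * factor
  delivery_schedule(s, label = sprintf("%s x%g", schedule$label, factor))
}
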