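#' Parametric volume-outcome mortality curve
#'
#' Constructs a monotone-decreasing curve mapping a hospital's annual
#' procedure volume to its 30-day risk-adjusted mortality rate, together with
#' a proportional deviation band. Two functional forms are supported:
#'
#' * `"exponential"`: `m(x) = m_floor + m_scale * exp(-decay * x)`
#' * `"power"`: `m(x) = m_floor + m_scale * (x + 1)^(-decay)`
#'
#' Both decline steeply at low volumes and plateau at `m_floor`, the shape
#' reported for procedure-level volume-outcome associations (e.g. the Italian
#' national outcome evaluation programme for colon surgery). The deviation
#' band `dev(x) = dev_fraction * m(x)` bounds how far an individual hospital's
#' performance may credibly sit from the curve at that volume.
#'
#' @param form `"exponential"` or `"power"`.
#' @param m_floor Asymptotic mortality rate at high volume, in `[0, 1]`.
#' @param m_scale Excess mortality at volume 0 (exponential form) or the
#'   power-law scale; `m_floor + m_scale` must not exceed 1.
#' @param decay Positive decay rate (per intervention) or power exponent.
#' @param dev_fraction Deviation band as a fraction of `m(x)`, in `[0, 1]`.
#' @return An object of class `mortality_curve`.
#' @examples
#' cv <- mortality_curve("exponential", m_floor = 0.02, m_scale = 0.08,
#'                       decay = 0.02, dev_fraction = 0.3)
#' mortality_rate(cv, c(0, 50, 500))
#' @export
mortality_curve <- function(form = c("exponential", "power"),
                            m_floor = 0.02, m_scale = 0.08, decay = 0.02,
                            dev_fraction = 0.3) {
  form <- match.arg(form)
  if (!is.numeric(m_floor) || length(m_floor) != 1L || m_floor < 0 || m_floor > 1)
    stop("'m_floor' must be a rate in [0, 1]", call. = FALSE)
  if (!is.numeric(m_scale) || length(m_scale) != 1L || m_scale < 0)
    stop("'m_scale' must be a non-negative rate", call. = FALSE)
  if (m_floor + m_scale > 1)
    stop("'m_floor' + 'm_scale' must not exceed 1 (mortality at volume 0)",
         call. = FALSE)
  if (!is.numeric(decay) || length(decay) != 1L || decay <= 0)
    stop("'decay' must be a positive real", call. = FALSE)
  if (!is.numeric(dev_fraction) || length(dev_fraction) != 1L ||
      dev_fraction < 0 || dev_fraction > 1)
    stop("'dev_fraction' must lie in [0, 1]", call. = FALSE)
  structure(
    list(form = form, m_floor = m_floor, m_scale = m_scale,
         decay = decay, dev_fraction = dev_fraction),
    class = "mortality_curve"
  )
}

#' @export
print.mortality_curve <- function(x, ...) {
  cat(sprintf("<mortality_curve> %s: m(x) = %.4g + %.4g * %s, dev(x) = %.3g * m(x)\n",
              x$form, x$m_floor, x$m_scale,
              if (x$form == "exponential")
                sprintf("exp(-%.4g x)", x$decay)
              else
                sprintf("(x+1)^-%.4g", x$decay),
              x$dev_fraction))
  invisible(x)
}

stopifnot_curve <- function(curve) {
  if (!inherits(curve, "mortality_curve"))
    stop("expected a 'mortality_curve' object", call. = FALSE)
}

#' Adjusted mortality rate at a given volume
#'
#' Evaluates the volume-outcome curve. Vectorised over `volume`; the result is
#' clamped to `[0, 1]`.
#'
#' @param curve A [mortality_curve()].
#' @param volume Non-negative volume(s) of interventions per year.
#' @return Mortality rate(s) in `[0, 1]`.
#' @export
mortality_rate <- function(curve, volume) {
  stopifnot_curve(curve)
  if (any(!is.finite(volume)) || any(volume < 0))
    stop("'volume' must be finite and non-negative", call. = FALSE)
  m <- switch(curve$form,
    exponential = curve$m_floor + curve$m_scale * exp(-curve$decay * volume),
    power       = curve$m_floor + curve$m_scale * (volume + 1)^(-curve$decay)
  )
  pmin(pmax(m, 0), 1)
}

#' Deviation band of the mortality curve
#'
#' The average deviation from the curve at a given volume: the maximum
#' performance-related change in mortality a hospital can exhibit. Modelled
#' proportionally, `dev(x) = dev_fraction * m(x)`, so that
#' `m(x) - dev(x) >= 0` for any admissible fraction.
#'
#' @inheritParams mortality_rate
#' @return Non-negative rate(s).
#' @export
deviation_band <- function(curve, volume) {
  curve$dev_fraction * mortality_rate(curve, volume)
}

#' Hospital performance coefficient
#'
#' Compares a hospital's observed adjusted mortality in the previous year with
#' the value the curve predicts for its previous-year volume, normalised by
#' the deviation band and clamped to `[-1, +1]`: -1 marks a hospital a full
#' band better than the curve, +1 a full band worse. A hospital with no
#' history (missing observed rate) gets 0, i.e. it is assumed to perform
#' exactly as the curve predicts.
#'
#' @param curve A [mortality_curve()].
#' @param prev_volume Previous-year volume (non-negative integer).
#' @param prev_observed_rate Observed adjusted mortality rate in `[0, 1]`, or
#'   `NA` when no history is available.
#' @return A value in `[-1, +1]`. Vectorised over both record arguments.
#' @export
performance_coefficient <- function(curve, prev_volume, prev_observed_rate) {
  stopifnot_curve(curve)
  n <- max(length(prev_volume), length(prev_observed_rate))
  prev_volume <- rep_len(prev_volume, n)
  prev_observed_rate <- rep_len(prev_observed_rate, n)
  if (any(prev_volume < 0))
    stop("'prev_volume' must be non-negative", call. = FALSE)
  ok <- is.na(prev_observed_rate) |
    (prev_observed_rate >= 0 & prev_observed_rate <= 1)
  if (!all(ok))
    stop("'prev_observed_rate' must lie in [0, 1] (or be NA)", call. = FALSE)
  out <- numeric(n)
  has <- !is.na(prev_observed_rate)
  if (any(has)) {
    num <- prev_observed_rate[has] - mortality_rate(curve, prev_volume[has])
    den <- deviation_band(curve, prev_volume[has])
    v <- ifelse(den > 0, num / den, sign(num))  # zero band: saturate at the sign
    out[has] <- pmin(pmax(v, -1), 1)
  }
  out
}

#' Expected deaths at a hospital
#'
#' The objective contribution of one hospital: volume times the curve
#' mortality, plus a performance adjustment `volume * v * dev(volume)` that
#' raises or lowers the toll for hospitals known to under- or over-perform.
#' Fractional volumes are accepted (operational solutions are sums of choice
#' probabilities).
#'
#' @param curve A [mortality_curve()].
#' @param volume Non-negative volume(s); may be fractional.
#' @param v Performance coefficient(s) in `[-1, +1]` (default 0).
#' @return Expected number of deaths (non-negative).
#' @export
expected_deaths <- function(curve, volume, v = 0) {
  stopifnot_curve(curve)
  if (any(volume < 0)) stop("'volume' must be non-negative", call. = FALSE)
  if (any(v < -1 | v > 1)) stop("'v' must lie in [-1, +1]", call. = FALSE)
  volume * mortality_rate(curve, volume) +
    volume * v * deviation_band(curve, volume)
}

#' Total expected mortality of a volume allocation
#'
#' Sums [expected_deaths()] over hospitals for a named vector of (possibly
#' fractional) volumes, using each hospital's performance coefficient.
#'
#' @param volumes Named numeric vector, names are hospital ids.
#' @param hospitals Hospital table (data frame with columns `id` and
#'   `perf_coeff`; see [as_hospital_table()]).
#' @param curve A [mortality_curve()].
#' @return Total expected deaths.
#' @export
total_mortality <- function(volumes, hospitals, curve) {
  if (length(volumes) == 0L) return(0)
  if (is.null(names(volumes)))
    stop("'volumes' must be named by hospital id", call. = FALSE)
  idx <- match(names(volumes), hospitals$id)
  if (anyNA(idx))
    stop("unknown hospital id(s): ",
         paste(names(volumes)[is.na(idx)], collapse = ", "), call. = FALSE)
  sum(expected_deaths(curve, unname(volumes), hospitals$perf_coeff[idx]))
}
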