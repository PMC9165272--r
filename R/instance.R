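#' Validate a hospital table and attach performance coefficients
#'
#' Checks the columns and ranges of a hospital table (one row per hospital)
#' and computes the `perf_coeff` column from previous-year history via
#' [performance_coefficient()]. Required columns: `id`, `province`,
#' `capacity`, `prev_volume`, `prev_observed_rate` (`NA` allowed),
#' `unit_cost`; optional `x_coord`, `y_coord` (planar km, synthetic regions).
#'
#' @param hospitals A data frame.
#' @param curve A [mortality_curve()] used to score past performance.
#' @return The same data frame, ordered by `id`, with a `perf_coeff` column.
#' @export
as_hospital_table <- function(hospitals, curve) {
  req <- c("id", "province", "capacity", "prev_volume",
           "prev_observed_rate", "unit_cost")
  miss <- setdiff(req, names(hospitals))
  if (length(miss))
    stop("hospital table is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  hospitals$id <- as.character(hospitals$id)
  hospitals$province <- as.character(hospitals$province)
  if (anyDuplicated(hospitals$id))
    stop("duplicated hospital id(s)", call. = FALSE)
  for (col in c("capacity", "prev_volume")) {
    bad <- which(!is.finite(hospitals[[col]]) | hospitals[[col]] < 0)
    if (length(bad))
      stop(sprintf("hospital row %d: '%s' must be a non-negative number",
                   bad[1L], col), call. = FALSE)
  }
  hospitals <- hospitals[order(hospitals$id), , drop = FALSE]
  rownames(hospitals) <- NULL
  hospitals$perf_coeff <- performance_coefficient(
    curve, hospitals$prev_volume, hospitals$prev_observed_rate)
  hospitals
}

#' Build an allocation problem instance
#'
#' Assembles the strategic allocation problem: hospitals grouped by province,
#' provincial demand, the guideline volume threshold `T`, per-province
#' hospitality thresholds `delta`, and an optional budget. Case-study style
#' flags reshape the bounds:
#'
#' * `capacity_twice_prev`: capacity is replaced by twice the previous-year
#'   volume (a hospital can at most double its activity in one planning step).
#' * `halve_threshold_outside_capital`: the volume lower bound is `ceil(T/2)`
#'   everywhere except `capital_province`, where it stays `T`.
#' * `force_open_above_T`: hospitals that performed more than `T`
#'   interventions in the previous year may not be closed.
#'
#' Hospitals whose capacity falls below their applicable lower bound can never
#' host an admissible volume and are dropped with a warning, concentrating
#' demand in wards with sufficient experience.
#'
#' @param hospitals Hospital table (see [as_hospital_table()]); passed through
#'   that validator if `perf_coeff` is absent.
#' @param demand Named positive integer vector of patients per province
#'   (`I_n`).
#' @param threshold Guideline minimum annual volume `T` (e.g. 50 for colon
#'   surgery).
#' @param curve A [mortality_curve()].
#' @param delta Hospitality threshold(s) in `[0, 1]`: scalar or named by
#'   province. 0 means each province treats exactly its own patients.
#' @param budget Total regional funding; `Inf` for unconstrained.
#' @param capital_province Province exempt from threshold halving.
#' @param capacity_twice_prev,halve_threshold_outside_capital,force_open_above_T
#'   Logical flags, see Details.
#' @return An object of class `allocation_instance`.
#' @export
allocation_instance <- function(hospitals, demand, threshold, curve,
                                delta = 0, budget = Inf,
                                capital_province = NULL,
                                capacity_twice_prev = FALSE,
                                halve_threshold_outside_capital = FALSE,
                                force_open_above_T = FALSE) {
  if (is.null(hospitals$perf_coeff))
    hospitals <- as_hospital_table(hospitals, curve)
  if (is.null(names(demand)) || anyDuplicated(names(demand)))
    stop("'demand' must be uniquely named by province", call. = FALSE)
  if (any(demand < 0) || sum(demand) <= 0)
    stop("'demand' must be non-negative with a positive total", call. = FALSE)
  provinces <- sort(names(demand))
  demand <- demand[provinces]
  unknown <- setdiff(hospitals$province, provinces)
  if (length(unknown))
    stop("hospital province(s) not in 'demand': ",
         paste(unique(unknown), collapse = ", "), call. = FALSE)
  if (length(delta) == 1L && is.null(names(delta)))
    delta <- stats::setNames(rep(delta, length(provinces)), provinces)
  delta <- delta[provinces]
  if (anyNA(delta) || any(delta < 0 | delta > 1))
    stop("'delta' must give a rate in [0, 1] for every province", call. = FALSE)
  if (!is.numeric(threshold) || threshold < 1)
    stop("'threshold' must be a positive integer", call. = FALSE)

  if (capacity_twice_prev)
    hospitals$capacity <- 2L * hospitals$prev_volume

  lower <- rep(as.integer(threshold), nrow(hospitals))
  if (halve_threshold_outside_capital) {
    outside <- if (is.null(capital_province)) rep(TRUE, nrow(hospitals))
               else hospitals$province != capital_province
    lower[outside] <- as.integer(ceiling(threshold / 2))
  }
  hospitals$lower_bound <- lower
  hospitals$forced_open <- force_open_above_T & hospitals$prev_volume > threshold

  drop <- hospitals$capacity < hospitals$lower_bound
  if (any(drop)) {
    warning(sprintf("dropping %d hospital(s) with capacity below the volume lower bound: %s",
                    sum(drop), paste(hospitals$id[drop], collapse = ", ")),
            call. = FALSE)
    hospitals <- hospitals[!drop, , drop = FALSE]
    rownames(hospitals) <- NULL
  }

  structure(
    list(hospitals = hospitals, demand = demand, delta = delta,
         threshold = as.integer(threshold), budget = budget,
         capital_province = capital_province, curve = curve,
         flags = list(capacity_twice_prev = capacity_twice_prev,
                      halve_threshold_outside_capital = halve_threshold_outside_capital,
                      force_open_above_T = force_open_above_T)),
    class = "allocation_instance"
  )
}

#' @export
print.allocation_instance <- function(x, ...) {
  cat(sprintf("<allocation_instance> %d hospitals, %d provinces, %d patients, T = %d%s\n",
              nrow(x$hospitals), length(x$demand), sum(x$demand), x$threshold,
              if (is.finite(x$budget)) sprintf(", budget %.4g", x$budget) else ""))
  invisible(x)
}

#' Volume bounds for one hospital
#'
#' The lower/upper bounds of the volume an open hospital may perform: the
#' (possibly halved) guideline threshold and the (possibly doubled) capacity,
#' as set up by [allocation_instance()].
#'
#' @param instance An [allocation_instance()].
#' @param hospital_id A hospital id present in the instance.
#' @return Integer vector `c(lower, upper)`.
#' @export
effective_bounds <- function(instance, hospital_id) {
  i <- match(hospital_id, instance$hospitals$id)
  if (is.na(i)) stop("unknown hospital id: ", hospital_id, call. = FALSE)
  c(lower = instance$hospitals$lower_bound[i],
    upper = as.integer(instance$hospitals$capacity[i]))
}

# Admissible volume levels for a hospital (0 = closed unless forced open).
hospital_levels <- function(instance, i) {
  lo <- instance$hospitals$lower_bound[i]
  hi <- as.integer(instance$hospitals$capacity[i])
  lev <- if (hi >= lo) lo:hi else integer(0)
  if (!instance$hospitals$forced_open[i]) lev <- c(0L, lev)
  lev
}

# Provincial subtotal window from the hospitality constraints (literal
# implementation of the printed inequality: the lower side subtracts the other
# provinces' delta-weighted populations, which is kept as printed even though
# the prose describes an own-outflow cap; see the methods vignette).
province_window <- function(instance, province) {
  I_n <- instance$demand[[province]]
  others <- setdiff(names(instance$demand), province)
  lo <- I_n - sum(instance$delta[others] * instance$demand[others])
  hi <- I_n + instance$delta[[province]] * I_n
  c(lower = max(0L, as.integer(ceiling(lo - 1e-9))),
    upper = as.integer(floor(hi + 1e-9)))
}
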