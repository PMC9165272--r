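# Synthetic multi-province regions: scattered right-skewed hospital volumes,
# a decreasing volume-mortality curve, and patients whose choices trade off
# distance disutility against volume-as-quality attraction. Everything is a
# deterministic function of the configured seed, so the whole pipeline is
# testable without access to real discharge records.

#' Configuration of a synthetic region
#'
#' Defaults emulate a region of the case-study type: eight provinces, a few
#' dozen hospitals with right-skewed (lognormal) previous-year volumes scaled
#' to provincial demand so that roughly 30% of hospitals clear the guideline
#' threshold of 50, capacity at twice the previous volume, observed mortality
#' scattered within the deviation band around the curve, and planar Euclidean
#' geography.
#'
#' @param n_provinces,hospitals_per_province,patients_per_province Region
#'   shape.
#' @param threshold Guideline volume threshold `T`.
#' @param curve A [mortality_curve()].
#' @param coeffs True [choice_coefficients()] driving simulated behaviour.
#' @param volume_sdlog Lognormal sd of the hospital volume weights (skew).
#' @param cap_factor Capacity as a multiple of previous-year volume.
#' @param box_km Side of the square region, km.
#' @param spread_km Scatter of hospitals/patients around province centres.
#' @param p_sex,p_rural,p_urgent,p_comorbid Bernoulli rates of the binary
#'   patient characteristics (age is standardised normal).
#' @param seed Integer seed; fully determines the generated region.
#' @return A list of class `region_config`.
#' @export
region_config <- function(n_provinces = 8L, hospitals_per_province = 6L,
                          patients_per_province = 270L, threshold = 50L,
                          curve = mortality_curve(),
                          coeffs = choice_coefficients(
                            beta_d = -0.1, beta_q = 0.01,
                            alpha_d = c(-0.02, 0, 0, 0, 0)),
                          volume_sdlog = 0.6, cap_factor = 2,
                          box_km = 220, spread_km = 12,
                          p_sex = 0.5, p_rural = 0.3, p_urgent = 0.35,
                          p_comorbid = 0.25, seed = 1L) {
  structure(as.list(environment()), class = "region_config")
}

# Round a positive vector to integers preserving its (integer) sum.
round_preserving_sum <- function(x, total) {
  fl <- floor(x)
  need <- as.integer(round(total - sum(fl)))
  if (need > 0) {
    extra <- order(x - fl, decreasing = TRUE)[seq_len(need)]
    fl[extra] <- fl[extra] + 1
  }
  as.integer(fl)
}

#' Generate a synthetic region
#'
#' Draws hospitals, patients, geography and history per the configuration.
#' Hospital previous-year volumes are lognormal weights scaled to provincial
#' demand; observed previous-year mortality sits within +/- 0.95 of the
#' deviation band around the curve (so performance coefficients span
#' `[-1, 1]` without clipping pathologies). Errors at generation time if any
#' province could never serve its demand or has no hospital reaching the
#' guideline threshold.
#'
#' @param config A [region_config()].
#' @return A list of class `synthetic_region`: `hospitals`, `demand`,
#'   `patients`, `distances`, plus the `curve`, `coeffs`, `threshold` and
#'   `config` used.
#' @export
generate_region <- function(config = region_config()) {
  stopifnot(inherits(config, "region_config"))
  with_seed(config$seed, {
    provs <- sprintf("P%02d", seq_len(config$n_provinces))
    demand <- stats::setNames(rep(as.integer(config$patients_per_province),
                                  config$n_provinces), provs)
    # province centres on a jittered grid inside the box
    g <- ceiling(sqrt(config$n_provinces))
    cx <- config$box_km * ((seq_len(config$n_provinces) - 1) %% g + 0.5) / g
    cy <- config$box_km * ((seq_len(config$n_provinces) - 1) %/% g + 0.5) / g
    cx <- cx + stats::runif(config$n_provinces, -10, 10)
    cy <- cy + stats::runif(config$n_provinces, -10, 10)

    hospitals <- do.call(rbind, lapply(seq_along(provs), function(n) {
      J <- config$hospitals_per_province
      w <- stats::rlnorm(J, 0, config$volume_sdlog)
      prev <- round_preserving_sum(demand[n] * w / sum(w), demand[n])
      cap <- as.integer(round(config$cap_factor * prev))
      m <- mortality_rate(config$curve, prev)
      dv <- deviation_band(config$curve, prev)
      obs <- pmin(pmax(m + stats::runif(J, -0.95, 0.95) * dv, 0), 1)
      data.frame(
        id = sprintf("%s-H%02d", provs[n], seq_len(J)),
        province = provs[n],
        capacity = cap, prev_volume = prev, prev_observed_rate = obs,
        unit_cost = round(stats::runif(J, 8000, 12000)),
        x_coord = cx[n] + stats::rnorm(J, 0, config$spread_km),
        y_coord = cy[n] + stats::rnorm(J, 0, config$spread_km))
    }))
    for (n in seq_along(provs)) {
      sub <- hospitals[hospitals$province == provs[n], ]
      if (sum(sub$capacity) < demand[n])
        stop(sprintf("province %s can never serve its demand (capacity %d < %d)",
                     provs[n], sum(sub$capacity), demand[n]), call. = FALSE)
      if (!any(sub$capacity >= config$threshold))
        stop(sprintf("province %s has no hospital with capacity >= threshold %d",
                     provs[n], config$threshold), call. = FALSE)
    }
    patients <- do.call(rbind, lapply(seq_along(provs), function(n) {
      I <- demand[n]
      data.frame(
        id = sprintf("%s-I%04d", provs[n], seq_len(I)),
        province = provs[n],
        age = stats::rnorm(I),
        sex = stats::rbinom(I, 1, config$p_sex),
        rurality = stats::rbinom(I, 1, config$p_rural),
        admission_type = stats::rbinom(I, 1, config$p_urgent),
        comorbidity = stats::rbinom(I, 1, config$p_comorbid),
        x_coord = cx[n] + stats::rnorm(I, 0, config$spread_km),
        y_coord = cy[n] + stats::rnorm(I, 0, config$spread_km))
    }))
    hospitals <- as_hospital_table(hospitals, config$curve)
    distances <- euclidean_distances(patients, hospitals)
    structure(list(hospitals = hospitals, demand = demand, patients = patients,
                   distances = distances, curve = config$curve,
                   coeffs = config$coeffs, threshold = config$threshold,
                   config = config),
              class = "synthetic_region")
  })
}

#' Patient-hospital Euclidean distance matrix
#'
#' @param patients,hospitals Tables with `x_coord`, `y_coord` columns.
#' @return Matrix (patients x hospitals, km) with hospital-id column names.
#' @export
euclidean_distances <- function(patients, hospitals) {
  D <- sqrt(outer(patients$x_coord, hospitals$x_coord, "-")^2 +
              outer(patients$y_coord, hospitals$y_coord, "-")^2)
  dimnames(D) <- list(patients$id, hospitals$id)
  D
}

#' @export
print.synthetic_region <- function(x, ...) {
  cat(sprintf("<synthetic_region> %d provinces, %d hospitals, %d patients, T = %d\n",
              length(x$demand), nrow(x$hospitals), nrow(x$patients),
              as.integer(x$threshold)))
  invisible(x)
}

#' A deterministic Piedmont-like region
#'
#' A fixed 8-province instance (provinces AL, AT, BI, CN, NO, TO, VB, VC)
#' with 53 hospitals and 1405 patients whose combinatorial structure matches
#' the published provincial summary for colon surgery planning at threshold
#' 50: eligible hospital counts `H = (5, 1, 1, 5, 2, 8, 2, 2)` (26 in total)
#' and minimum open counts `r = (2, 1, 1, 2, 2, 4, 1, 1)`. Capacities,
#' volumes, geography and per-province patient counts are synthetic: real
#' capacities and discharge records are not public, so capacities are
#' invented but constrained to reproduce those counts, and the 1405 patients
#' are split across provinces proportionally to hospital numbers.
#'
#' @param curve A [mortality_curve()] used for history scoring.
#' @param coeffs True [choice_coefficients()] attached to the region.
#' @return A `synthetic_region` list (see [generate_region()]).
#' @export
piedmont_like_fixture <- function(curve = mortality_curve(),
                                  coeffs = choice_coefficients(
                                    beta_d = -0.1, beta_q = 0.01,
                                    alpha_d = c(-0.02, 0, 0, 0, 0))) {
  provs <- c("AL", "AT", "BI", "CN", "NO", "TO", "VB", "VC")
  caps <- list(
    AL = c(160, 120, 90, 70, 60, 46, 40, 34),
    AT = c(140, 44, 38, 30),
    BI = c(140, 44, 38, 30),
    CN = c(180, 130, 90, 70, 60, 46, 40, 34, 28),
    NO = c(90, 70, 44, 38, 30),
    TO = c(120, 110, 100, 90, 80, 70, 60, 56, 48, 44, 40, 36, 32, 28, 26),
    VB = c(130, 60, 40, 30),
    VC = c(130, 60, 40, 30))
  demand <- c(AL = 212L, AT = 106L, BI = 106L, CN = 239L,
              NO = 133L, TO = 397L, VB = 106L, VC = 106L)  # sums to 1405
  centres <- rbind(AL = c(120, 40), AT = c(85, 55), BI = c(75, 115),
                   CN = c(60, 10), NO = c(135, 105), TO = c(55, 70),
                   VB = c(140, 140), VC = c(100, 95))
  with_seed(20140L, {
    hospitals <- do.call(rbind, lapply(provs, function(p) {
      cp <- caps[[p]]
      prev <- as.integer(cp / 2)
      m <- mortality_rate(curve, prev)
      dv <- deviation_band(curve, prev)
      obs <- pmin(pmax(m + stats::runif(length(cp), -0.95, 0.95) * dv, 0), 1)
      data.frame(
        id = sprintf("%s-H%02d", p, seq_along(cp)),
        province = p, capacity = as.integer(cp), prev_volume = prev,
        prev_observed_rate = obs,
        unit_cost = round(stats::runif(length(cp), 8000, 12000)),
        x_coord = centres[p, 1] + stats::rnorm(length(cp), 0, 10),
        y_coord = centres[p, 2] + stats::rnorm(length(cp), 0, 10))
    }))
    patients <- do.call(rbind, lapply(provs, function(p) {
      I <- demand[[p]]
      data.frame(
        id = sprintf("%s-I%04d", p, seq_len(I)),
        province = p,
        age = stats::rnorm(I),
        sex = stats::rbinom(I, 1, 0.5),
        rurality = stats::rbinom(I, 1, 0.3),
        admission_type = stats::rbinom(I, 1, 0.35),
        comorbidity = stats::rbinom(I, 1, 0.25),
        x_coord = centres[p, 1] + stats::rnorm(I, 0, 10),
        y_coord = centres[p, 2] + stats::rnorm(I, 0, 10))
    }))
    hospitals <- as_hospital_table(hospitals, curve)
    structure(list(hospitals = hospitals, demand = demand, patients = patients,
                   distances = euclidean_distances(patients, hospitals),
                   curve = curve, coeffs = coeffs, threshold = 50L,
                   config = NULL),
              class = "synthetic_region")
  })
}

#' Simulate multi-year choice histories for estimation
#'
#' For each year, every patient chooses among all of the region's hospitals
#' under the conditional logit with the previous year's volumes as the
#' quality signal; realised counts become the next year's lag. Emits
#' long-format records (one row per decision x alternative) directly usable
#' by [fit_choice_model()].
#'
#' @param region A `synthetic_region`.
#' @param n_years Number of simulated years.
#' @param seed Integer seed.
#' @return Data frame of choice records (empty for `n_years = 0`).
#' @export
generate_choice_history <- function(region, n_years, seed = 1L) {
  cols <- c("year", "decision_id", "hospital_id", "chosen", "distance",
            "lagged_volume", CHARACTERISTICS)
  if (n_years == 0L) {
    out <- as.data.frame(stats::setNames(
      rep(list(numeric(0)), length(cols)), cols))
    out$decision_id <- character(0)
    out$hospital_id <- character(0)
    return(out)
  }
  hosp <- region$hospitals
  ids <- hosp$id
  J <- length(ids)
  I <- nrow(region$patients)
  lag <- stats::setNames(hosp$prev_volume, ids)
  G <- region$patients[, CHARACTERISTICS]
  out <- vector("list", n_years)
  for (y in seq_len(n_years)) {
    chosen <- simulate_choices(region$coeffs, region$patients,
                               region$distances, lag, ids,
                               seed = seed + y - 1L)
    rec <- data.frame(
      year = rep(y, I * J),
      decision_id = rep(sprintf("y%02d-%s", y, region$patients$id), each = J),
      hospital_id = rep(ids, times = I),
      chosen = as.integer(rep(chosen, each = J) == rep(ids, times = I)),
      distance = as.vector(t(region$distances)),
      lagged_volume = rep(unname(lag), times = I))
    rec <- cbind(rec, G[rep(seq_len(I), each = J), , drop = FALSE])
    rownames(rec) <- NULL
    out[[y]] <- rec
    counts <- table(factor(chosen, levels = ids))
    lag <- stats::setNames(as.numeric(counts), ids)
  }
  do.call(rbind, out)
}
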