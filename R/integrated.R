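# Three-phase integrated planner: enumerate admissible choice sets, predict
# patient response to each, keep the near-best by the theta-rule, and skim to
# a single integrated solution.

#' Hospitals eligible for a patient choice set
#'
#' Phase 1 eligibility: the hospitals a planner may put in front of patients.
#' The default criterion keeps hospitals whose capacity reaches the guideline
#' threshold `T`; `criterion = "prev_volume"` instead requires the threshold
#' volume to have been performed in the previous year.
#'
#' @param hospitals Hospital table.
#' @param threshold Guideline volume threshold `T`.
#' @param criterion `"capacity"` (default) or `"prev_volume"`.
#' @return Named list: province -> character vector of eligible hospital ids
#'   (provinces sorted; empty provinces flagged with a warning).
#' @export
eligible_hospitals <- function(hospitals, threshold,
                               criterion = c("capacity", "prev_volume")) {
  criterion <- match.arg(criterion)
  val <- if (criterion == "capacity") hospitals$capacity else hospitals$prev_volume
  keep <- val >= threshold
  provs <- sort(unique(hospitals$province))
  out <- lapply(provs, function(p)
    sort(hospitals$id[keep & hospitals$province == p]))
  names(out) <- provs
  empty <- provs[lengths(out) == 0L]
  if (length(empty))
    warning("province(s) with no eligible hospital: ",
            paste(empty, collapse = ", "), call. = FALSE)
  out
}

#' Minimum number of hospitals a province must keep open
#'
#' Sorts the eligible capacities in decreasing order and returns the length of
#' the shortest prefix whose capacity covers the provincial demand. A province
#' with zero demand still requires one open facility (with zero hospitality
#' thresholds every province must serve its own patients somewhere).
#'
#' @param capacities Capacities of the province's eligible hospitals.
#' @param demand Provincial patient count `I_n`.
#' @return Integer minimum count.
#' @export
min_required_open <- function(capacities, demand) {
  if (length(capacities) == 0L)
    stop("no eligible hospitals: province can never be served", call. = FALSE)
  if (demand <= 0) return(1L)
  cum <- cumsum(sort(capacities, decreasing = TRUE))
  if (cum[length(cum)] < demand)
    stop("total eligible capacity below provincial demand", call. = FALSE)
  which(cum >= demand)[1L]
}

#' Closed-form count of regional choice sets
#'
#' Number of open/closed combinations across the region before capacity
#' filtering: the product over provinces of the number of subsets of the
#' `H_n` eligible hospitals with size between the required minimum `r_n` and
#' `H_n`.
#'
#' @param H Integer vector of per-province eligible counts.
#' @param r_min Integer vector of per-province minimum open counts.
#' @return Exact count (double holding an exact integer).
#' @export
count_choice_sets <- function(H, r_min) {
  if (length(H) != length(r_min))
    stop("'H' and 'r_min' must have equal length", call. = FALSE)
  if (any(r_min < 1) || any(r_min > H))
    stop("each r_min must satisfy 1 <= r_min <= H", call. = FALSE)
  per <- vapply(seq_along(H), function(n)
    sum(choose(H[n], r_min[n]:H[n])), numeric(1))
  prod(per)
}

#' Enumerate admissible hospital choice sets
#'
#' Phase 1: per province, generates every subset of eligible hospitals with
#' size between the required minimum and `H_n`, then drops subsets whose
#' total capacity cannot cover the provincial demand. Regional choice sets
#' are the cross product of the per-province survivors; they are not
#' materialised here but addressed lazily by index (see [get_choice_set()]),
#' in deterministic lexicographic order.
#'
#' @param instance An [allocation_instance()].
#' @param criterion Eligibility criterion, see [eligible_hospitals()].
#' @return An object of class `choice_set_enum` with per-province eligible
#'   ids, minimum open counts, admissible subsets, the closed-form pre-filter
#'   count `n_prefilter` and the admissible count `n_admissible`.
#' @export
enumerate_choice_sets <- function(instance, criterion = "capacity") {
  hosp <- instance$hospitals
  elig <- eligible_hospitals(hosp, instance$threshold, criterion)
  provs <- names(elig)
  H <- lengths(elig)
  if (any(H == 0L))
    stop("no admissible choice set: some province has no eligible hospital",
         call. = FALSE)
  caps <- lapply(provs, function(p)
    stats::setNames(hosp$capacity[match(elig[[p]], hosp$id)], elig[[p]]))
  names(caps) <- provs
  r_min <- vapply(provs, function(p)
    min_required_open(caps[[p]], instance$demand[[p]]), integer(1))
  subsets <- lapply(provs, function(p) {
    ids <- elig[[p]]
    acc <- list()
    for (r in r_min[[p]]:length(ids)) {
      combos <- utils::combn(ids, r, simplify = FALSE)
      ok <- vapply(combos, function(s)
        sum(caps[[p]][s]) >= instance$demand[[p]], logical(1))
      acc <- c(acc, combos[ok])
    }
    acc
  })
  names(subsets) <- provs
  if (any(lengths(subsets) == 0L))
    stop("no admissible choice set: provincial capacity filter left a province empty",
         call. = FALSE)
  structure(
    list(provinces = provs, eligible = elig, H = H, r_min = r_min,
         subsets = subsets,
         n_prefilter = count_choice_sets(H, r_min),
         n_admissible = prod(lengths(subsets))),
    class = "choice_set_enum"
  )
}

#' @export
print.choice_set_enum <- function(x, ...) {
  cat(sprintf("<choice_set_enum> %d provinces: H = (%s), r_min = (%s)\n",
              length(x$provinces), paste(x$H, collapse = ", "),
              paste(x$r_min, collapse = ", ")))
  cat(sprintf("  %s choice sets before capacity filtering, %s admissible\n",
              format(x$n_prefilter, big.mark = ","),
              format(x$n_admissible, big.mark = ",")))
  invisible(x)
}

#' Extract the k-th admissible regional choice set
#'
#' Mixed-radix indexing of the lazy cross product over per-province subsets,
#' `k` in `1..n_admissible`; the last province varies fastest.
#'
#' @param enum A `choice_set_enum`.
#' @param k Index.
#' @return Character vector of open hospital ids.
#' @export
get_choice_set <- function(enum, k) {
  if (k < 1 || k > enum$n_admissible) stop("index out of range", call. = FALSE)
  sizes <- lengths(enum$subsets)
  k0 <- k - 1
  pick <- integer(length(sizes))
  for (n in rev(seq_along(sizes))) {
    pick[n] <- k0 %% sizes[n] + 1
    k0 <- k0 %/% sizes[n]
  }
  unlist(lapply(seq_along(sizes), function(n) enum$subsets[[n]][[pick[n]]]),
         use.names = FALSE)
}

#' Materialise all admissible choice sets
#'
#' @param enum A `choice_set_enum`.
#' @param max_sets Guard: refuse eager materialisation above this count.
#' @return List of character vectors.
#' @export
materialize_choice_sets <- function(enum, max_sets = 1e5) {
  if (enum$n_admissible > max_sets)
    stop(sprintf("refusing to materialise %g choice sets (> %g); iterate with get_choice_set()",
                 enum$n_admissible, max_sets), call. = FALSE)
  lapply(seq_len(enum$n_admissible), function(k) get_choice_set(enum, k))
}

#' Predict patient response to one choice set and its mortality
#'
#' Phase 2 evaluation: patients see the open hospitals with their
#' previous-year volumes as the quality signal; predicted volumes are the
#' aggregated choice probabilities and the associated mortality is the total
#' expected deaths at those (fractional) volumes including each hospital's
#' performance coefficient. Predicted volumes below the guideline threshold
#' or above capacity are recorded as violations.
#'
#' @param choice_set Character vector of open hospital ids.
#' @param coeffs [choice_coefficients()].
#' @param patients Patient table.
#' @param distances Patient x hospital distance matrix.
#' @param hospitals Hospital table (with `perf_coeff`).
#' @param curve A [mortality_curve()].
#' @param threshold Guideline threshold `T`.
#' @return An object of class `operational_evaluation`: `choice_set`,
#'   `volumes`, `deaths`, `below_threshold`, `over_capacity`.
#' @export
evaluate_choice_set <- function(choice_set, coeffs, patients, distances,
                                hospitals, curve, threshold) {
  idx <- match(choice_set, hospitals$id)
  if (anyNA(idx))
    stop("choice set references unknown hospital(s)", call. = FALSE)
  lag <- stats::setNames(hospitals$prev_volume, hospitals$id)
  vol <- predict_volumes(coeffs, patients, distances, lag, choice_set)
  structure(
    list(choice_set = sort(choice_set),
         volumes = vol,
         deaths = total_mortality(vol, hospitals, curve),
         below_threshold = names(vol)[vol < threshold - 1e-9],
         over_capacity = names(vol)[vol > hospitals$capacity[idx] + 1e-9]),
    class = "operational_evaluation"
  )
}

#' @export
print.operational_evaluation <- function(x, ...) {
  cat(sprintf("<operational_evaluation> %d open hospitals, %.3f expected deaths\n",
              length(x$choice_set), x$deaths))
  if (length(x$below_threshold))
    cat("  below threshold:", paste(x$below_threshold, collapse = ", "), "\n")
  invisible(x)
}

#' Theta-rule candidate selection
#'
#' Phase 2 selection: mortality values are grouped on their nearest-integer
#' value. Every evaluation in the lowest group is kept; evaluations in the
#' second and third lowest groups are kept only if their group value does not
#' exceed the lowest by more than `theta` percent. Output is sorted by
#' mortality, then lexicographically by choice set.
#'
#' @param evaluations List of `operational_evaluation`s.
#' @param theta Percentage tolerance (e.g. 10).
#' @return Sublist of candidate evaluations.
#' @export
select_candidates <- function(evaluations, theta) {
  if (length(evaluations) == 0L)
    stop("no evaluations to select from", call. = FALSE)
  if (theta < 0) stop("'theta' must be non-negative", call. = FALSE)
  deaths <- vapply(evaluations, function(e) e$deaths, numeric(1))
  grp <- round(deaths)
  lev <- sort(unique(grp))
  keep_lev <- lev[1L]
  for (l in lev[-1L][seq_len(min(2L, length(lev) - 1L))])
    if (l <= (1 + theta / 100) * lev[1L]) keep_lev <- c(keep_lev, l)
  keep <- grp %in% keep_lev
  out <- evaluations[keep]
  key <- vapply(out, function(e) paste(e$choice_set, collapse = "|"), "")
  out[order(vapply(out, function(e) e$deaths, numeric(1)), key)]
}

#' Phase-3 skim to the integrated solution
#'
#' Reduces the candidate operational solutions to one. The `"structural"`
#' criterion re-solves the strategic allocation with each candidate's open
#' hospitals fixed and picks the candidate whose predicted volumes are
#' closest (L1) to that strategic solution - the configuration hospitals can
#' best prepare for. The `"utility"` criterion picks the candidate minimising
#' the total absolute gap between each open hospital's expected deaths at its
#' previous-year volume and at its predicted volume, a proxy for the
#' past-versus-realised performance gap patients would experience. Ties are
#' lexicographic; candidates whose restricted strategic model is infeasible
#' are excluded with a warning.
#'
#' @param candidates List of `operational_evaluation`s.
#' @param instance An [allocation_instance()].
#' @param criterion `"structural"` or `"utility"`.
#' @return List: the chosen `evaluation`, its `criterion_value`, and for the
#'   structural criterion the candidate's `strategic_plan`.
#' @export
skim_candidates <- function(candidates, instance,
                            criterion = c("structural", "utility")) {
  criterion <- match.arg(criterion)
  if (length(candidates) == 0L)
    stop("no candidates to skim", call. = FALSE)
  score <- rep(NA_real_, length(candidates))
  plans <- vector("list", length(candidates))
  for (c_i in seq_along(candidates)) {
    ev <- candidates[[c_i]]
    if (criterion == "structural") {
      sub <- restrict_instance(instance, ev$choice_set)
      pl <- solve_region(sub)
      if (pl$status != "optimal") {
        warning("candidate excluded: strategic sub-model infeasible for its choice set",
                call. = FALSE)
        next
      }
      plans[[c_i]] <- pl
      score[c_i] <- sum(abs(ev$volumes[names(pl$volumes)] - pl$volumes))
    } else {
      idx <- match(names(ev$volumes), instance$hospitals$id)
      prev <- instance$hospitals$prev_volume[idx]
      v <- instance$hospitals$perf_coeff[idx]
      score[c_i] <- sum(abs(expected_deaths(instance$curve, prev, v) -
                              expected_deaths(instance$curve, ev$volumes, v)))
    }
  }
  if (all(is.na(score)))
    stop("all candidates excluded during the skim", call. = FALSE)
  key <- vapply(candidates, function(e) paste(e$choice_set, collapse = "|"), "")
  best <- order(score, key, na.last = TRUE)[1L]
  list(evaluation = candidates[[best]], criterion = criterion,
       criterion_value = score[best], strategic_plan = plans[[best]])
}

# Restrict an instance to a choice set, forcing its hospitals open.
restrict_instance <- function(instance, choice_set) {
  out <- instance
  out$hospitals <- instance$hospitals[instance$hospitals$id %in% choice_set, ,
                                      drop = FALSE]
  rownames(out$hospitals) <- NULL
  out$hospitals$forced_open <- TRUE
  out
}

#' Run the full integrated planning algorithm
#'
#' Executes the three phases over the whole instance and, for comparison,
#' also computes: the pure strategic solution (full patient adherence
#' assumed), the operational response to that strategic choice set (what
#' patients would actually do), and the actual baseline mortality at the
#' previous-year volumes. The integrated solution's mortality always lies
#' within `theta` percent (on integer-rounded mortality groups) of the best
#' admissible operational mortality.
#'
#' @param instance An [allocation_instance()].
#' @param coeffs [choice_coefficients()].
#' @param patients Patient table (province + five characteristics).
#' @param distances Patient x hospital distance matrix (all instance
#'   hospitals as columns).
#' @param theta Phase-2 tolerance, percent (default 10).
#' @param criterion Phase-3 skim criterion (default `"structural"`).
#' @param eligibility Phase-1 eligibility criterion.
#' @param strict_threshold If `TRUE`, operational solutions leaving any open
#'   hospital below the guideline threshold are disqualified in Phase 2
#'   rather than merely reported.
#' @param max_sets Guard on the number of admissible sets evaluated.
#' @return An object of class `integrated_report`.
#' @export
run_integrated <- function(instance, coeffs, patients, distances,
                           theta = 10, criterion = "structural",
                           eligibility = "capacity",
                           strict_threshold = FALSE, max_sets = 1e4) {
  enum <- enumerate_choice_sets(instance, eligibility)
  if (enum$n_admissible > max_sets)
    stop(sprintf("%g admissible choice sets exceed the evaluation guard (%g)",
                 enum$n_admissible, max_sets), call. = FALSE)
  hosp <- instance$hospitals
  evals <- lapply(seq_len(enum$n_admissible), function(k)
    evaluate_choice_set(get_choice_set(enum, k), coeffs, patients, distances,
                        hosp, instance$curve, instance$threshold))
  n_evaluated <- length(evals)
  if (strict_threshold) {
    ok <- vapply(evals, function(e) length(e$below_threshold) == 0L, logical(1))
    if (!any(ok))
      stop("strict threshold filter removed every operational solution",
           call. = FALSE)
    evals <- evals[ok]
  }
  candidates <- select_candidates(evals, theta)
  skim <- skim_candidates(candidates, instance, criterion)

  strategic <- solve_region(instance)
  strategic_set <- if (strategic$status == "optimal")
    sort(names(strategic$volumes)[strategic$volumes > 0]) else character(0)
  operational <- if (length(strategic_set))
    evaluate_choice_set(strategic_set, coeffs, patients, distances,
                        hosp, instance$curve, instance$threshold) else NULL
  actual_vol <- stats::setNames(hosp$prev_volume, hosp$id)

  op_deaths <- vapply(evals, function(e) e$deaths, numeric(1))
  structure(
    list(enumeration = enum,
         n_evaluated = n_evaluated,
         n_candidates = length(candidates),
         candidates = candidates,
         integrated = skim$evaluation,
         skim = skim,
         strategic = strategic,
         strategic_choice_set = strategic_set,
         operational_of_strategic = operational,
         min_operational_deaths = min(op_deaths),
         mortality = c(
           actual = total_mortality(actual_vol, hosp, instance$curve),
           strategic = strategic$objective,
           operational = if (is.null(operational)) NA_real_ else operational$deaths,
           integrated = skim$evaluation$deaths),
         theta = theta, criterion = criterion),
    class = "integrated_report"
  )
}

#' @export
print.integrated_report <- function(x, ...) {
  cat("<integrated_report>\n")
  cat(sprintf("  Phase 1: %s pre-filter sets, %s admissible\n",
              format(x$enumeration$n_prefilter, big.mark = ","),
              format(x$enumeration$n_admissible, big.mark = ",")))
  cat(sprintf("  Phase 2: %d evaluated, %d candidate(s) within theta = %g%%\n",
              x$n_evaluated, x$n_candidates, x$theta))
  cat(sprintf("  Phase 3: criterion '%s' -> %d open hospitals\n",
              x$criterion, length(x$integrated$choice_set)))
  cat("  Expected deaths:\n")
  for (nm in names(x$mortality))
    cat(sprintf("    %-12s %8.3f\n", nm, x$mortality[[nm]]))
  invisible(x)
}
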