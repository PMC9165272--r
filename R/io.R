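# CSV/YAML input validation and report generation. All formats are small
# plain-text administrative-style tables; every run is a pure function of
# (input files, config, seed).

#' Read a YAML run configuration
#'
#' Expected keys: a `curve:` section (`form`, `m_floor`, `m_scale`, `decay`,
#' `dev_fraction`), `threshold`, optional `delta` (scalar; per-province
#' values live in the province table), `budget`, `capital_province`, a
#' `flags:` section (`capacity_twice_prev`,
#' `halve_threshold_outside_capital`, `force_open_above_T`), and optional
#' `theta` / `criterion` for the integrated run. Missing keys fall back to
#' defaults.
#'
#' @param path YAML file path.
#' @return Named list with a `curve` entry of class `mortality_curve`.
#' @export
load_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  cv <- cfg$curve
  cfg$curve <- mortality_curve(
    form = cv$form %||% "exponential",
    m_floor = cv$m_floor %||% 0.02, m_scale = cv$m_scale %||% 0.08,
    decay = cv$decay %||% 0.02, dev_fraction = cv$dev_fraction %||% 0.3)
  cfg$threshold <- cfg$threshold %||% 50
  cfg$budget <- cfg$budget %||% Inf
  cfg$flags <- utils::modifyList(
    list(capacity_twice_prev = FALSE, halve_threshold_outside_capital = FALSE,
         force_open_above_T = FALSE), cfg$flags %||% list())
  cfg$theta <- cfg$theta %||% 10
  cfg$criterion <- cfg$criterion %||% "structural"
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Load and validate an allocation instance from CSV files
#'
#' @param hospitals_csv CSV with columns `id`, `province`, `capacity`,
#'   `prev_volume`, `prev_observed_rate` (blank allowed), `unit_cost` and
#'   optional coordinates.
#' @param provinces_csv CSV with columns `province`, `demand` and optional
#'   `delta`.
#' @param config Configuration list from [load_config()].
#' @return An [allocation_instance()]. Hospitals below the applicable volume
#'   lower bound are dropped with a warning.
#' @export
load_instance <- function(hospitals_csv, provinces_csv, config) {
  hospitals <- utils::read.csv(hospitals_csv, stringsAsFactors = FALSE)
  prov <- utils::read.csv(provinces_csv, stringsAsFactors = FALSE)
  for (col in c("province", "demand"))
    if (!col %in% names(prov))
      stop("province table is missing column '", col, "'", call. = FALSE)
  demand <- stats::setNames(as.integer(prov$demand), prov$province)
  delta <- if ("delta" %in% names(prov))
    stats::setNames(prov$delta, prov$province)
  else config$delta %||% 0
  allocation_instance(
    hospitals, demand, threshold = config$threshold, curve = config$curve,
    delta = delta, budget = config$budget,
    capital_province = config$capital_province,
    capacity_twice_prev = isTRUE(config$flags$capacity_twice_prev),
    halve_threshold_outside_capital =
      isTRUE(config$flags$halve_threshold_outside_capital),
    force_open_above_T = isTRUE(config$flags$force_open_above_T))
}

#' Load a patient table from CSV
#'
#' Requires `id`, `province` and the five characteristic columns.
#'
#' @param path CSV path.
#' @return Validated data frame.
#' @export
load_patients <- function(path) {
  patients <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("id", "province", CHARACTERISTICS), names(patients))
  if (length(miss))
    stop("patient table is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  patients
}

#' Load a patient-by-hospital distance matrix from CSV
#'
#' First column `patient_id`, remaining columns one per hospital id. When a
#' hospital table is supplied, referential integrity is checked both ways.
#'
#' @param path CSV path.
#' @param hospitals Optional hospital table to validate against.
#' @return Numeric matrix with patient rows and hospital-id columns.
#' @export
load_distances <- function(path, hospitals = NULL) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1L] != "patient_id")
    stop("distance matrix must have 'patient_id' as its first column",
         call. = FALSE)
  D <- as.matrix(df[, -1L, drop = FALSE])
  rownames(D) <- df$patient_id
  if (any(!is.finite(D)) || any(D < 0))
    stop("distances must be finite and non-negative", call. = FALSE)
  if (!is.null(hospitals)) {
    miss <- setdiff(hospitals$id, colnames(D))
    if (length(miss))
      stop("distance matrix missing hospital column(s): ",
           paste(miss, collapse = ", "), call. = FALSE)
  }
  D
}

#' Write a synthetic region as the four pipeline CSVs
#'
#' Emits `hospitals.csv`, `provinces.csv`, `patients.csv`, `distances.csv`
#' into `dir` in the formats the loaders expect.
#'
#' @param region A `synthetic_region`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_region <- function(region, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  h <- region$hospitals
  h$perf_coeff <- NULL
  utils::write.csv(h, file.path(dir, "hospitals.csv"), row.names = FALSE)
  utils::write.csv(
    data.frame(province = names(region$demand),
               demand = as.integer(region$demand),
               delta = 0),
    file.path(dir, "provinces.csv"), row.names = FALSE)
  utils::write.csv(region$patients, file.path(dir, "patients.csv"),
                   row.names = FALSE)
  utils::write.csv(
    data.frame(patient_id = rownames(region$distances),
               region$distances, check.names = FALSE),
    file.path(dir, "distances.csv"), row.names = FALSE)
  invisible(dir)
}

#' Write an integrated run report
#'
#' Emits per-solution volume tables (`volumes_<solution>.csv` with columns
#' `hospital_id`, `volume`, `expected_deaths`), a `mortality.csv` comparison
#' of the four solutions, `candidates.csv`, `counts.csv` with the per-phase
#' counts, and a plain-text `summary.txt`. The stored mortality figures are
#' recomputable from the volume tables and the curve.
#'
#' @param report An `integrated_report` from [run_integrated()].
#' @param out_dir Output directory (created if needed).
#' @param instance The [allocation_instance()] the report was computed from.
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(report, out_dir, instance) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  hosp <- instance$hospitals
  vol_table <- function(volumes) {
    idx <- match(names(volumes), hosp$id)
    data.frame(hospital_id = names(volumes),
               volume = unname(volumes),
               expected_deaths = unname(expected_deaths(
                 instance$curve, volumes, hosp$perf_coeff[idx])))
  }
  sols <- list(
    actual = stats::setNames(hosp$prev_volume, hosp$id),
    strategic = if (report$strategic$status == "optimal")
      report$strategic$volumes else NULL,
    operational = if (!is.null(report$operational_of_strategic))
      report$operational_of_strategic$volumes else NULL,
    integrated = report$integrated$volumes)
  for (nm in names(sols))
    if (!is.null(sols[[nm]]))
      utils::write.csv(vol_table(sols[[nm]]),
                       file.path(out_dir, paste0("volumes_", nm, ".csv")),
                       row.names = FALSE)
  utils::write.csv(
    data.frame(solution = names(report$mortality),
               expected_deaths = unname(report$mortality)),
    file.path(out_dir, "mortality.csv"), row.names = FALSE)
  utils::write.csv(
    data.frame(
      candidate = seq_along(report$candidates),
      expected_deaths = vapply(report$candidates, function(e) e$deaths,
                               numeric(1)),
      choice_set = vapply(report$candidates, function(e)
        paste(e$choice_set, collapse = "|"), "")),
    file.path(out_dir, "candidates.csv"), row.names = FALSE)
  utils::write.csv(
    data.frame(quantity = c("eligible_hospitals", "choice_sets_prefilter",
                            "choice_sets_admissible", "evaluated",
                            "candidates"),
               value = c(sum(report$enumeration$H),
                         report$enumeration$n_prefilter,
                         report$enumeration$n_admissible,
                         report$n_evaluated, report$n_candidates)),
    file.path(out_dir, "counts.csv"), row.names = FALSE)

  lines <- c(
    "Integrated hospital volume planning report",
    "==========================================",
    sprintf("Provinces: %s", paste(report$enumeration$provinces, collapse = ", ")),
    sprintf("Eligible hospitals per province: %s (total %d)",
            paste(report$enumeration$H, collapse = ", "),
            sum(report$enumeration$H)),
    sprintf("Choice sets: %s before capacity filter, %s admissible, %d evaluated",
            format(report$enumeration$n_prefilter, big.mark = ","),
            format(report$enumeration$n_admissible, big.mark = ","),
            report$n_evaluated),
    sprintf("Candidates within theta = %g%%: %d", report$theta,
            report$n_candidates),
    if (report$n_candidates == 0L)
      "No integrated solution: candidate list is empty."
    else
      sprintf("Integrated solution (criterion '%s'): %d open hospitals",
              report$criterion, length(report$integrated$choice_set)),
    "",
    "Expected deaths by solution:",
    sprintf("  %-12s %10.4f", names(report$mortality), report$mortality),
    "",
    if (length(report$integrated$below_threshold))
      sprintf("Predicted volume below threshold at: %s",
              paste(report$integrated$below_threshold, collapse = ", "))
    else "No open hospital predicted below the guideline threshold.")
  writeLines(lines, file.path(out_dir, "summary.txt"))
  invisible(out_dir)
}
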