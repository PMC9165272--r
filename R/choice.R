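# Conditional-logit model of individual hospital choice.
#
# A patient's utility for a hospital is linear in travel distance and in the
# hospital's lagged annual volume (volume as a quality signal), with both
# slopes shifted by K = 5 personal characteristics: age (standardised), sex,
# rurality, admission type (urgent vs elective) and comorbidity, all measured
# from administrative discharge data.

CHARACTERISTICS <- c("age", "sex", "rurality", "admission_type", "comorbidity")

#' Conditional-logit choice coefficients
#'
#' @param beta_d Utility change per additional km travelled (typically
#'   negative: distance is a disutility).
#' @param beta_q Utility change per additional lagged intervention at the
#'   hospital (typically positive: volume signals quality).
#' @param alpha_d,alpha_q Length-5 numeric vectors of interaction shifts of
#'   `beta_d` / `beta_q` per patient characteristic, in the order
#'   `age, sex, rurality, admission_type, comorbidity`.
#' @return An object of class `choice_coefficients`.
#' @export
choice_coefficients <- function(beta_d, beta_q,
                                alpha_d = numeric(5), alpha_q = numeric(5)) {
  if (length(alpha_d) != 5L || length(alpha_q) != 5L)
    stop("'alpha_d' and 'alpha_q' must have length 5", call. = FALSE)
  structure(
    list(beta_d = as.numeric(beta_d), beta_q = as.numeric(beta_q),
         alpha_d = stats::setNames(as.numeric(alpha_d), CHARACTERISTICS),
         alpha_q = stats::setNames(as.numeric(alpha_q), CHARACTERISTICS)),
    class = "choice_coefficients"
  )
}

#' @export
print.choice_coefficients <- function(x, ...) {
  cat(sprintf("<choice_coefficients> beta_d = %.4g /km, beta_q = %.4g /intervention\n",
              x$beta_d, x$beta_q))
  cat("  alpha_d:", paste(sprintf("%s=%.3g", names(x$alpha_d), x$alpha_d),
                          collapse = " "), "\n")
  cat("  alpha_q:", paste(sprintf("%s=%.3g", names(x$alpha_q), x$alpha_q),
                          collapse = " "), "\n")
  invisible(x)
}

patient_char_matrix <- function(patients) {
  miss <- setdiff(CHARACTERISTICS, names(patients))
  if (length(miss))
    stop("patient table is missing characteristic(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  as.matrix(patients[, CHARACTERISTICS, drop = FALSE])
}

#' Patient utilities over a set of hospitals
#'
#' `U[i, j] = (beta_d + sum_k alpha_dk g_ik) d[i, j] +
#' (beta_q + sum_k alpha_qk g_ik) x_lag[j]`: quality always refers to the
#' previous year's volume, the information patients actually hold at choice
#' time (one-year information lag).
#'
#' @param coeffs [choice_coefficients()].
#' @param patients Data frame with the five characteristic columns.
#' @param distances Matrix (patients x hospitals, km) with hospital-id
#'   column names.
#' @param volumes_lag Named vector of previous-year volumes, one per hospital
#'   column of `distances`.
#' @return Utility matrix, patients x hospitals.
#' @export
choice_utilities <- function(coeffs, patients, distances, volumes_lag) {
  G <- patient_char_matrix(patients)
  ids <- colnames(distances)
  if (is.null(ids) || anyNA(match(ids, names(volumes_lag))))
    stop("'distances' columns must be hospital ids with lagged volumes",
         call. = FALSE)
  if (nrow(G) != nrow(distances))
    stop("patients and distance matrix disagree on patient count", call. = FALSE)
  if (any(distances < 0)) stop("distances must be non-negative", call. = FALSE)
  bd <- coeffs$beta_d + as.vector(G %*% coeffs$alpha_d)
  bq <- coeffs$beta_q + as.vector(G %*% coeffs$alpha_q)
  U <- bd * distances + outer(bq, as.numeric(volumes_lag[ids]))
  dimnames(U) <- list(NULL, ids)
  U
}

#' Choice probabilities over an open choice set
#'
#' Converts utilities to per-patient probabilities over the open hospitals.
#' The default `"softmax"` convention is the conditional logit
#' `p_ij = exp(U_ij) / sum_j' exp(U_ij')`, computed with log-sum-exp
#' stabilisation. The `"literal-ratio"` convention computes `p_ij =
#' U_ij / sum_j' U_ij'` directly; it is only well defined when every utility
#' is strictly positive and refuses otherwise.
#'
#' @inheritParams choice_utilities
#' @param choice_set Character vector of open hospital ids (columns of
#'   `distances`); default all.
#' @param convention `"softmax"` (default) or `"literal-ratio"`.
#' @return Probability matrix, patients x open hospitals; rows sum to 1.
#' @export
choice_probabilities <- function(coeffs, patients, distances, volumes_lag,
                                 choice_set = colnames(distances),
                                 convention = c("softmax", "literal-ratio")) {
  convention <- match.arg(convention)
  if (length(choice_set) == 0L)
    stop("empty choice set: at least one hospital must be open", call. = FALSE)
  if (anyNA(match(choice_set, colnames(distances))))
    stop("choice set contains hospitals absent from the distance matrix",
         call. = FALSE)
  U <- choice_utilities(coeffs, patients, distances, volumes_lag)
  U <- U[, choice_set, drop = FALSE]
  if (convention == "softmax") {
    mx <- apply(U, 1L, max)
    E <- exp(U - mx)
    P <- E / rowSums(E)
  } else {
    if (any(U <= 0))
      stop(paste("literal-ratio convention requires strictly positive",
                 "utilities; use convention = \"softmax\""), call. = FALSE)
    P <- U / rowSums(U)
  }
  dimnames(P) <- list(NULL, choice_set)
  P
}

#' Predicted hospital volumes from aggregated choice probabilities
#'
#' The operational solution: each open hospital's predicted volume is the sum
#' over patients of their probability of choosing it, so the volumes sum
#' exactly to the patient count.
#'
#' @inheritParams choice_probabilities
#' @return Named numeric vector of (fractional) predicted volumes.
#' @export
predict_volumes <- function(coeffs, patients, distances, volumes_lag,
                            choice_set = colnames(distances),
                            convention = "softmax") {
  P <- choice_probabilities(coeffs, patients, distances, volumes_lag,
                            choice_set, convention)
  colSums(P)
}

# Run code with a reproducible, caller-isolated RNG state.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Simulate one realised hospital choice per patient
#'
#' Draws each patient's hospital independently from their conditional-logit
#' probability vector; reproducible under a fixed seed and isolated from the
#' caller's RNG state.
#'
#' @inheritParams choice_probabilities
#' @param seed Integer seed (or `NULL` to use the current RNG state).
#' @return Character vector of chosen hospital ids, one per patient.
#' @export
simulate_choices <- function(coeffs, patients, distances, volumes_lag,
                             choice_set = colnames(distances), seed = NULL,
                             convention = "softmax") {
  P <- choice_probabilities(coeffs, patients, distances, volumes_lag,
                            choice_set, convention)
  with_seed(seed, {
    u <- stats::runif(nrow(P))
    cum <- P %*% upper.tri(diag(ncol(P)), diag = TRUE)
    pick <- rowSums(u > cum) + 1L  # u > cumulative share => later column
    colnames(P)[pmin(pick, ncol(P))]
  })
}

#' Divergence of patient choices from a provincial plan
#'
#' Fraction of patients whose (simulated or modal) hospital choice falls
#' outside the set of hospitals planned for their own province. The paper's
#' two information regimes are obtained by the caller feeding either lagged
#' volumes (what patients actually know) or planned strategic volumes (full
#' information about the plan) into the choice model before calling this.
#'
#' @param patients Data frame with a `province` column.
#' @param chosen Character vector of chosen hospital ids, one per patient.
#' @param planned_sets Named list: province -> character vector of the
#'   hospitals planned to serve that province.
#' @return Divergence rate in `[0, 1]`.
#' @export
adherence_divergence <- function(patients, chosen, planned_sets) {
  if (length(chosen) != nrow(patients))
    stop("'chosen' must have one entry per patient", call. = FALSE)
  outside <- vapply(seq_len(nrow(patients)), function(i) {
    planned <- planned_sets[[patients$province[i]]]
    !(chosen[i] %in% planned)
  }, logical(1))
  mean(outside)
}
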