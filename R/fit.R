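# Maximum-likelihood estimation of the conditional-logit choice model.
#
# The utility is linear in theta = (beta_d, beta_q, alpha_d[5], alpha_q[5])
# through the feature vector z = (d, x, d*g, x*g), so the log-likelihood
# sum_i [ z_chosen' theta - log sum_j exp(z_j' theta) ] is concave and is
# maximised by damped Newton-Raphson from a zero start, on internally
# standardised features for conditioning.

clogit_design <- function(records) {
  req <- c("decision_id", "hospital_id", "chosen", "distance", "lagged_volume",
           CHARACTERISTICS)
  miss <- setdiff(req, names(records))
  if (length(miss))
    stop("choice records are missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  G <- as.matrix(records[, CHARACTERISTICS, drop = FALSE])
  d <- records$distance
  x <- records$lagged_volume
  Z <- cbind(d, x, d * G, x * G)
  colnames(Z) <- c("beta_d", "beta_q",
                   paste0("alpha_d.", CHARACTERISTICS),
                   paste0("alpha_q.", CHARACTERISTICS))
  grp <- factor(records$decision_id, levels = unique(records$decision_id))
  y <- as.numeric(records$chosen)
  if (!all(tapply(y, grp, sum) == 1))
    stop("every decision must have exactly one chosen alternative", call. = FALSE)
  list(Z = Z, grp = grp, y = y)
}

clogit_nll <- function(theta, Z, grp, y) {
  eta <- as.vector(Z %*% theta)
  mg <- as.vector(tapply(eta, grp, max))  # aligned: both in levels order
  E <- exp(eta - mg[as.integer(grp)])
  den <- rowsum(E, grp)[, 1L]
  p <- E / den[as.integer(grp)]
  nll <- -(sum(y * eta) - sum(log(den) + mg))
  grad <- as.vector(crossprod(Z, p - y))
  Zbar <- rowsum(p * Z, grp)
  H <- crossprod(Z, p * Z) - crossprod(Zbar)
  list(nll = nll, grad = grad, H = H)
}

#' Fit conditional-logit choice coefficients from choice histories
#'
#' Estimates `(beta_d, beta_q, alpha_d, alpha_q)` by maximum likelihood from
#' long-format records: one row per (decision, alternative) with the
#' alternative's distance and lagged volume, the chooser's five
#' characteristics, and a 0/1 `chosen` indicator (exactly one per decision).
#' Standard errors come from the observed information at the optimum. The
#' problem is convex, so the fit is deterministic given the data.
#'
#' Non-identified designs (e.g. only single-alternative choice sets, or a
#' characteristic constant across all patients) are flagged through
#' `converged = FALSE` with `NA` standard errors rather than an error.
#'
#' @param records Data frame of choice records (see Details).
#' @param max_iter Newton iteration cap.
#' @param grad_tol Convergence tolerance on the max absolute gradient of the
#'   standardised problem.
#' @return An object of class `choice_fit`: estimates, standard errors,
#'   covariance, log-likelihood, convergence flag.
#' @export
fit_choice_model <- function(records, max_iter = 100L, grad_tol = 1e-8) {
  ds <- clogit_design(records)
  Z <- ds$Z
  scale <- apply(Z, 2L, function(col) {
    s <- stats::sd(col)
    if (!is.finite(s) || s < 1e-12) 1 else s
  })
  Zs <- sweep(Z, 2L, scale, "/")
  p <- ncol(Zs)
  theta <- numeric(p)
  cur <- clogit_nll(theta, Zs, ds$grp, ds$y)
  converged <- FALSE
  msg <- "ok"
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    if (max(abs(cur$grad)) < grad_tol * max(1, abs(cur$nll))) {
      converged <- TRUE
      break
    }
    step <- tryCatch(solve(cur$H, cur$grad), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step))) {
      msg <- "observed information is singular: model not identified on these records"
      break
    }
    lam <- 1
    repeat {
      cand <- theta - lam * step
      new <- clogit_nll(cand, Zs, ds$grp, ds$y)
      if (is.finite(new$nll) && new$nll <= cur$nll + 1e-12) break
      lam <- lam / 2
      if (lam < 1e-10) break
    }
    if (lam < 1e-10) {
      msg <- "line search failed"
      break
    }
    theta <- theta - lam * step
    cur <- new
  }
  if (!converged && msg == "ok") msg <- "iteration cap reached"
  vcov_s <- tryCatch(solve(cur$H), error = function(e) NULL)
  identified <- !is.null(vcov_s) && all(is.finite(diag(vcov_s))) &&
    all(diag(vcov_s) > 0)
  if (!identified && converged) {
    converged <- FALSE
    msg <- "observed information is singular: model not identified on these records"
  }
  est <- stats::setNames(theta / scale, colnames(Z))
  if (identified) {
    vc <- vcov_s / tcrossprod(scale)
    se <- stats::setNames(sqrt(diag(vc)), colnames(Z))
  } else {
    vc <- matrix(NA_real_, p, p, dimnames = list(colnames(Z), colnames(Z)))
    se <- stats::setNames(rep(NA_real_, p), colnames(Z))
  }
  structure(
    list(coefficients = est, se = se, vcov = vc, loglik = -cur$nll,
         converged = converged, message = msg, iterations = iter,
         n_decisions = nlevels(ds$grp)),
    class = "choice_fit"
  )
}

#' @export
coef.choice_fit <- function(object, ...) object$coefficients

#' @export
logLik.choice_fit <- function(object, ...) {
  structure(object$loglik, df = length(object$coefficients), class = "logLik")
}

#' @export
print.choice_fit <- function(x, ...) {
  cat(sprintf("<choice_fit> %d decisions, logLik %.3f, %s (%d Newton iterations)\n",
              x$n_decisions, x$loglik,
              if (x$converged) "converged" else paste0("NOT converged: ", x$message),
              x$iterations))
  print(data.frame(estimate = x$coefficients, se = x$se))
  invisible(x)
}

#' Extract fitted values as a coefficient object
#'
#' @param fit A `choice_fit`.
#' @return A [choice_coefficients()] usable in prediction and simulation.
#' @export
as_choice_coefficients <- function(fit) {
  stopifnot(inherits(fit, "choice_fit"))
  cf <- fit$coefficients
  choice_coefficients(cf[["beta_d"]], cf[["beta_q"]],
                      cf[paste0("alpha_d.", CHARACTERISTICS)],
                      cf[paste0("alpha_q.", CHARACTERISTICS)])
}
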