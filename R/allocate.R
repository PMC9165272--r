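# Exact solvers for the strategic allocation model.
#
# The objective x * m(x) + x * v * dev(x) is nonlinear in the integer volume
# x, but every hospital's admissible volume set {0} U [lower, cap] is small,
# so the objective is tabulated per level and the optimum found by dynamic
# programming over cumulative volume. When a finite budget couples provinces
# through intervention costs, the DP states carry Pareto frontiers of
# (deaths, cost) pairs instead of scalars; both paths are exact.

# ---- scalar DP (budget unbounded) -----------------------------------------

# Suffix value table: B[i, s+1] = min cost of serving exactly s with items
# i..M, items having admissible 'levels' and per-level 'costs'.
dp_suffix <- function(levels, costs, S) {
  M <- length(levels)
  B <- matrix(Inf, M + 1L, S + 1L)
  B[M + 1L, 1L] <- 0
  for (i in rev(seq_len(M))) {
    lv <- levels[[i]]
    cs <- costs[[i]]
    for (k in seq_along(lv)) {
      x <- lv[k]
      if (x > S) next
      tgt <- (x + 1L):(S + 1L)
      B[i, tgt] <- pmin(B[i, tgt], B[i + 1L, seq_len(S - x + 1L)] + cs[k])
    }
  }
  B
}

# Reconstruct one optimal level per item, preferring the smallest admissible
# level at each step (levels are ascending, with 0 first where closure is
# allowed): ties therefore resolve to the lexicographically smallest
# open-pattern and volume vector in item order.
dp_reconstruct <- function(B, levels, costs, target, tol = 1e-9) {
  M <- length(levels)
  out <- integer(M)
  s <- target
  for (i in seq_len(M)) {
    lv <- levels[[i]]
    cs <- costs[[i]]
    picked <- FALSE
    for (k in seq_along(lv)) {
      x <- lv[k]
      if (x > s) next
      rest <- B[i + 1L, s - x + 1L]
      if (is.finite(rest) && cs[k] + rest <= B[i, s + 1L] + tol) {
        out[i] <- x
        s <- s - x
        picked <- TRUE
        break
      }
    }
    if (!picked) stop("internal error: DP reconstruction failed", call. = FALSE)
  }
  out
}

province_tables <- function(instance, province) {
  idx <- which(instance$hospitals$province == province)  # id-sorted already
  levels <- lapply(idx, function(i) hospital_levels(instance, i))
  costs <- lapply(seq_along(idx), function(j) {
    i <- idx[j]
    expected_deaths(instance$curve, levels[[j]], instance$hospitals$perf_coeff[i])
  })
  money <- lapply(seq_along(idx), function(j)
    levels[[j]] * instance$hospitals$unit_cost[idx[j]])
  list(idx = idx, ids = instance$hospitals$id[idx],
       levels = levels, costs = costs, money = money)
}

new_allocation_plan <- function(instance, volumes, status,
                                restricted_to = NULL) {
  if (status != "optimal") {
    return(structure(list(open = NULL, volumes = NULL, objective = NA_real_,
                          cost = NA_real_, status = status),
                     class = "allocation_plan"))
  }
  hosp <- instance$hospitals
  if (!is.null(restricted_to)) hosp <- hosp[hosp$id %in% restricted_to, ]
  volumes <- volumes[hosp$id]
  cost <- sum(volumes * hosp$unit_cost)
  structure(
    list(open = stats::setNames(volumes > 0, names(volumes)),
         volumes = volumes,
         objective = total_mortality(volumes, hosp, instance$curve),
         cost = cost, status = "optimal"),
    class = "allocation_plan"
  )
}

#' @export
print.allocation_plan <- function(x, ...) {
  if (x$status != "optimal") {
    cat(sprintf("<allocation_plan> status: %s\n", x$status))
  } else {
    cat(sprintf("<allocation_plan> optimal: %d/%d hospitals open, %d patients, %.3f expected deaths\n",
                sum(x$open), length(x$open), sum(x$volumes), x$objective))
  }
  invisible(x)
}

#' Exact volume allocation within one province
#'
#' Solves the strategic model restricted to a single province (valid when the
#' hospitality thresholds are zero and the budget is unbounded, in which case
#' the regional model decomposes province by province): minimise total
#' expected deaths subject to exact provincial demand coverage, per-hospital
#' volume bounds and forced-open rules. Solved exactly by dynamic programming
#' over cumulative volume; ties go to the lexicographically smallest
#' open-pattern / volume vector in hospital-id order.
#'
#' @param instance An [allocation_instance()].
#' @param province Province name.
#' @return An `allocation_plan` restricted to the province's hospitals.
#' @export
solve_province <- function(instance, province) {
  if (!province %in% names(instance$demand))
    stop("unknown province: ", province, call. = FALSE)
  tb <- province_tables(instance, province)
  S <- as.integer(instance$demand[[province]])
  if (length(tb$idx) == 0L) {
    if (S == 0L) return(new_allocation_plan(instance, stats::setNames(integer(0), character(0)), "optimal", restricted_to = character(0)))
    return(new_allocation_plan(instance, NULL, "infeasible"))
  }
  B <- dp_suffix(tb$levels, tb$costs, S)
  if (!is.finite(B[1L, S + 1L]))
    return(new_allocation_plan(instance, NULL, "infeasible"))
  x <- dp_reconstruct(B, tb$levels, tb$costs, S)
  new_allocation_plan(instance, stats::setNames(x, tb$ids), "optimal",
                      restricted_to = tb$ids)
}

#' Exact regional volume allocation
#'
#' Solves the full strategic model: minimise total expected deaths across the
#' region subject to per-hospital volume bounds (open hospitals between the
#' guideline threshold and capacity), provincial demand windows widened by the
#' hospitality thresholds, exact conservation of the regional patient total,
#' and (optionally) a regional budget. With all hospitality thresholds at zero
#' and an unbounded budget the model decomposes and is solved province by
#' province; otherwise a two-level dynamic program over provincial subtotals
#' is used, carrying (deaths, cost) Pareto frontiers when the budget binds.
#' Both paths return the exact integer optimum.
#'
#' @param instance An [allocation_instance()].
#' @return An `allocation_plan` with `status` `"optimal"` or `"infeasible"`.
#' @export
solve_region <- function(instance) {
  provinces <- names(instance$demand)
  if (all(instance$delta == 0) && !is.finite(instance$budget)) {
    plans <- lapply(provinces, function(p) solve_province(instance, p))
    if (any(vapply(plans, function(p) p$status, "") != "optimal"))
      return(new_allocation_plan(instance, NULL, "infeasible"))
    vol <- do.call(c, lapply(plans, function(p) p$volumes))
    return(new_allocation_plan(instance, vol, "optimal"))
  }
  if (!is.finite(instance$budget)) solve_region_windows(instance)
  else solve_region_budget(instance)
}

# delta > 0 somewhere, no budget: per-province DP profiles over subtotals,
# then a DP across provinces picking one subtotal per province.
solve_region_windows <- function(instance) {
  provinces <- names(instance$demand)
  S <- as.integer(sum(instance$demand))
  tabs <- lapply(provinces, function(p) province_tables(instance, p))
  names(tabs) <- provinces
  prof <- vector("list", length(provinces))
  subtot_levels <- vector("list", length(provinces))
  subtot_costs <- vector("list", length(provinces))
  for (n in seq_along(provinces)) {
    win <- province_window(instance, provinces[n])
    cap_total <- sum(vapply(tabs[[n]]$levels, max, 0L))
    smax <- min(win[["upper"]], cap_total, S)
    B <- dp_suffix(tabs[[n]]$levels, tabs[[n]]$costs, max(smax, 0L))
    prof[[n]] <- B
    feas <- which(is.finite(B[1L, seq_len(smax + 1L)])) - 1L
    feas <- feas[feas >= win[["lower"]]]
    if (length(feas) == 0L)
      return(new_allocation_plan(instance, NULL, "infeasible"))
    subtot_levels[[n]] <- as.integer(feas)
    subtot_costs[[n]] <- B[1L, feas + 1L]
  }
  BR <- dp_suffix(subtot_levels, subtot_costs, S)
  if (!is.finite(BR[1L, S + 1L]))
    return(new_allocation_plan(instance, NULL, "infeasible"))
  subtot <- dp_reconstruct(BR, subtot_levels, subtot_costs, S)
  vol <- numeric(0)
  for (n in seq_along(provinces)) {
    x <- dp_reconstruct(prof[[n]], tabs[[n]]$levels, tabs[[n]]$costs, subtot[n])
    vol <- c(vol, stats::setNames(x, tabs[[n]]$ids))
  }
  new_allocation_plan(instance, vol, "optimal")
}

# ---- Pareto-frontier DP (finite budget) -----------------------------------

# Frontier: matrix with columns (deaths, cost), sorted by deaths, strictly
# decreasing cost, all rows within budget. NULL = infeasible state.
fr_prune <- function(m, budget) {
  if (is.null(m) || nrow(m) == 0L) return(NULL)
  m <- m[m[, 2L] <= budget + 1e-9, , drop = FALSE]
  if (nrow(m) == 0L) return(NULL)
  m <- m[order(m[, 1L], m[, 2L]), , drop = FALSE]
  best <- Inf
  keep <- logical(nrow(m))
  for (r in seq_len(nrow(m))) {
    if (m[r, 2L] < best - 1e-12) {
      keep[r] <- TRUE
      best <- m[r, 2L]
    }
  }
  m[keep, , drop = FALSE]
}

fr_cross <- function(a, b) {
  # all pairwise sums of two frontiers
  ia <- rep(seq_len(nrow(a)), each = nrow(b))
  ib <- rep(seq_len(nrow(b)), times = nrow(a))
  cbind(a[ia, 1L] + b[ib, 1L], a[ia, 2L] + b[ib, 2L])
}

# Suffix frontiers over items with per-level single (deaths, money) points.
fr_suffix <- function(levels, costs, money, S, budget) {
  M <- length(levels)
  FR <- vector("list", M + 1L)
  FR[[M + 1L]] <- c(list(matrix(c(0, 0), 1L)), rep(list(NULL), S))
  for (i in rev(seq_len(M))) {
    cur <- vector("list", S + 1L)
    for (s in 0:S) {
      acc <- NULL
      for (k in seq_along(levels[[i]])) {
        x <- levels[[i]][k]
        if (x > s) next
        nxt <- FR[[i + 1L]][[s - x + 1L]]
        if (is.null(nxt)) next
        acc <- rbind(acc, cbind(nxt[, 1L] + costs[[i]][k],
                                nxt[, 2L] + money[[i]][k]))
      }
      cur[s + 1L] <- list(fr_prune(acc, budget))  # [[<- would drop NULLs
    }
    FR[[i]] <- cur
  }
  FR
}

# Reconstruct levels hitting an exact (deaths, cost-bound) target.
fr_reconstruct <- function(FR, levels, costs, money, s, d_target, c_budget,
                           tol = 1e-9) {
  M <- length(levels)
  out <- integer(M)
  d0 <- 0; c0 <- 0
  for (i in seq_len(M)) {
    picked <- FALSE
    for (k in seq_along(levels[[i]])) {
      x <- levels[[i]][k]
      if (x > s) next
      nxt <- FR[[i + 1L]][[s - x + 1L]]
      if (is.null(nxt)) next
      need_d <- d_target - d0 - costs[[i]][k]
      need_c <- c_budget - c0 - money[[i]][k]
      hit <- abs(nxt[, 1L] - need_d) <= tol & nxt[, 2L] <= need_c + tol
      if (any(hit)) {
        out[i] <- x
        s <- s - x
        d0 <- d0 + costs[[i]][k]
        c0 <- c0 + money[[i]][k]
        picked <- TRUE
        break
      }
    }
    if (!picked) stop("internal error: frontier reconstruction failed", call. = FALSE)
  }
  out
}

solve_region_budget <- function(instance) {
  provinces <- names(instance$demand)
  S <- as.integer(sum(instance$demand))
  b <- instance$budget
  tabs <- lapply(provinces, function(p) province_tables(instance, p))
  hosp_FR <- vector("list", length(provinces))
  sub_levels <- vector("list", length(provinces))
  sub_frontiers <- vector("list", length(provinces))
  for (n in seq_along(provinces)) {
    win <- province_window(instance, provinces[n])
    cap_total <- sum(vapply(tabs[[n]]$levels, max, 0L))
    smax <- min(win[["upper"]], cap_total, S)
    if (smax < win[["lower"]])
      return(new_allocation_plan(instance, NULL, "infeasible"))
    FRn <- fr_suffix(tabs[[n]]$levels, tabs[[n]]$costs, tabs[[n]]$money,
                     smax, b)
    hosp_FR[[n]] <- FRn
    feas <- Filter(function(s) !is.null(FRn[[1L]][[s + 1L]]),
                   seq.int(win[["lower"]], smax))
    if (length(feas) == 0L)
      return(new_allocation_plan(instance, NULL, "infeasible"))
    sub_levels[[n]] <- as.integer(feas)
    sub_frontiers[[n]] <- lapply(feas, function(s) FRn[[1L]][[s + 1L]])
  }
  # DP across provinces with frontier-valued levels
  N <- length(provinces)
  REG <- vector("list", N + 1L)
  REG[[N + 1L]] <- c(list(matrix(c(0, 0), 1L)), rep(list(NULL), S))
  for (n in rev(seq_len(N))) {
    cur <- vector("list", S + 1L)
    for (s in 0:S) {
      acc <- NULL
      for (k in seq_along(sub_levels[[n]])) {
        t <- sub_levels[[n]][k]
        if (t > s) next
        nxt <- REG[[n + 1L]][[s - t + 1L]]
        if (is.null(nxt)) next
        acc <- rbind(acc, fr_cross(sub_frontiers[[n]][[k]], nxt))
      }
      cur[s + 1L] <- list(fr_prune(acc, b))
    }
    REG[[n]] <- cur
  }
  top <- REG[[1L]][[S + 1L]]
  if (is.null(top))
    return(new_allocation_plan(instance, NULL, "infeasible"))
  Z <- top[1L, 1L]  # min deaths within budget
  # walk provinces: smallest subtotal first, then jointly pick the realizable
  # (province frontier point, regional suffix point) pair
  vol <- numeric(0)
  s <- S; d0 <- 0; c0 <- 0
  for (n in seq_len(N)) {
    done <- FALSE
    for (k in seq_along(sub_levels[[n]])) {
      t <- sub_levels[[n]][k]
      if (t > s) next
      nxt <- REG[[n + 1L]][[s - t + 1L]]
      if (is.null(nxt)) next
      pf <- sub_frontiers[[n]][[k]]
      for (r in seq_len(nrow(pf))) {
        need_d <- Z - d0 - pf[r, 1L]
        need_c <- b - c0 - pf[r, 2L]
        hit <- abs(nxt[, 1L] - need_d) <= 1e-9 & nxt[, 2L] <= need_c + 1e-9
        if (any(hit)) {
          x <- fr_reconstruct(hosp_FR[[n]], tabs[[n]]$levels, tabs[[n]]$costs,
                              tabs[[n]]$money, t, pf[r, 1L], pf[r, 2L])
          vol <- c(vol, stats::setNames(x, tabs[[n]]$ids))
          s <- s - t; d0 <- d0 + pf[r, 1L]; c0 <- c0 + pf[r, 2L]
          done <- TRUE
          break
        }
      }
      if (done) break
    }
    if (!done) stop("internal error: regional reconstruction failed", call. = FALSE)
  }
  new_allocation_plan(instance, vol, "optimal")
}

# ---- verification and brute-force oracle ----------------------------------

#' Check a plan against every model constraint
#'
#' Audits an allocation against the volume-bound, hospitality-window,
#' conservation and budget constraints of the strategic model. Returns an
#' empty data frame iff the plan is feasible.
#'
#' @param instance An [allocation_instance()].
#' @param plan An `allocation_plan`, or a named volume vector.
#' @return Data frame with columns `constraint`, `unit`, `message`.
#' @export
verify_plan <- function(instance, plan) {
  volumes <- if (inherits(plan, "allocation_plan")) plan$volumes else plan
  viol <- list()
  add <- function(constraint, unit, message)
    viol[[length(viol) + 1L]] <<- data.frame(
      constraint = constraint, unit = unit, message = message)
  hosp <- instance$hospitals
  unknown <- setdiff(names(volumes), hosp$id)
  if (length(unknown))
    stop("plan references unknown hospital(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  x <- stats::setNames(rep(0, nrow(hosp)), hosp$id)
  x[names(volumes)] <- volumes
  for (i in seq_len(nrow(hosp))) {
    id <- hosp$id[i]
    if (x[id] > 0) {
      if (x[id] < hosp$lower_bound[i] || x[id] > hosp$capacity[i])
        add("volume_bounds", id,
            sprintf("open hospital volume %g outside [%d, %d]",
                    x[id], hosp$lower_bound[i], as.integer(hosp$capacity[i])))
    } else if (hosp$forced_open[i]) {
      add("forced_open", id, "hospital above threshold last year must stay open")
    }
  }
  for (p in names(instance$demand)) {
    win <- province_window(instance, p)
    tot <- sum(x[hosp$id[hosp$province == p]])
    if (tot < win[["lower"]] - 1e-9 || tot > win[["upper"]] + 1e-9)
      add("hospitality_window", p,
          sprintf("province subtotal %g outside [%d, %d]",
                  tot, win[["lower"]], win[["upper"]]))
  }
  if (abs(sum(x) - sum(instance$demand)) > 1e-9)
    add("conservation", "region",
        sprintf("total volume %g differs from total demand %d",
                sum(x), as.integer(sum(instance$demand))))
  cost <- sum(x * hosp$unit_cost[match(names(x), hosp$id)])
  if (cost > instance$budget + 1e-9)
    add("budget", "region",
        sprintf("plan cost %g exceeds budget %g", cost, instance$budget))
  if (length(viol)) do.call(rbind, viol)
  else data.frame(constraint = character(0), unit = character(0),
                  message = character(0))
}

#' Brute-force allocation oracle
#'
#' Exhaustively enumerates every feasible integer volume vector and returns
#' the global optimum. Intended as an independent test oracle for tiny
#' instances; refuses instances whose level-combination count exceeds
#' `max_combos`.
#'
#' @param instance An [allocation_instance()].
#' @param max_combos Enumeration guard (default 5e5 combinations).
#' @return An `allocation_plan`.
#' @export
brute_force_allocate <- function(instance, max_combos = 5e5) {
  hosp <- instance$hospitals
  levels <- lapply(seq_len(nrow(hosp)), function(i) hospital_levels(instance, i))
  n_combo <- prod(vapply(levels, length, 1))
  if (n_combo > max_combos)
    stop(sprintf("instance too large for brute force (%g combinations)", n_combo),
         call. = FALSE)
  grid <- as.matrix(do.call(expand.grid, c(levels, KEEP.OUT.ATTRS = FALSE)))
  colnames(grid) <- hosp$id
  keep <- rowSums(grid) == sum(instance$demand)
  for (p in names(instance$demand)) {
    win <- province_window(instance, p)
    sub <- rowSums(grid[, hosp$province == p, drop = FALSE])
    keep <- keep & sub >= win[["lower"]] & sub <= win[["upper"]]
  }
  if (is.finite(instance$budget))
    keep <- keep & as.vector(grid %*% hosp$unit_cost) <= instance$budget + 1e-9
  grid <- grid[keep, , drop = FALSE]
  if (nrow(grid) == 0L)
    return(new_allocation_plan(instance, NULL, "infeasible"))
  g_tab <- lapply(seq_len(nrow(hosp)), function(i)
    stats::setNames(expected_deaths(instance$curve, levels[[i]],
                                    hosp$perf_coeff[i]),
                    as.character(levels[[i]])))
  obj <- numeric(nrow(grid))
  for (j in seq_len(ncol(grid)))
    obj <- obj + unname(g_tab[[j]][as.character(grid[, j])])
  ord <- do.call(order, c(list(obj), lapply(seq_len(ncol(grid)), function(j) grid[, j])))
  best <- grid[ord[1L], ]
  new_allocation_plan(instance, best, "optimal")
}
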