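# Strategic allocation: bounds, province DP, regional solver, verification
# and the brute-force oracle.

test_that("effective bounds follow the threshold and capacity flags", {
  cv <- test_curve()
  hosp <- simple_hospitals(c("C1", "N1"), c("CAP", "OTH"), c(300, 300),
                           prev_volume = c(80, 80))
  inst <- allocation_instance(hosp, c(CAP = 100, OTH = 100), threshold = 50,
                              curve = cv, capital_province = "CAP",
                              halve_threshold_outside_capital = TRUE)
  expect_equal(effective_bounds(inst, "C1"), c(lower = 50, upper = 300))
  expect_equal(effective_bounds(inst, "N1"), c(lower = 25, upper = 300))
  inst2 <- allocation_instance(hosp, c(CAP = 100, OTH = 100), threshold = 50,
                               curve = cv, capacity_twice_prev = TRUE)
  expect_equal(effective_bounds(inst2, "C1"), c(lower = 50, upper = 160))
})

test_that("hospitals below their volume lower bound are dropped with a warning", {
  cv <- test_curve()
  hosp <- simple_hospitals(c("A", "B"), "P1", c(60, 49))
  expect_warning(
    inst <- allocation_instance(hosp, c(P1 = 55), threshold = 50, curve = cv),
    "B")
  expect_equal(inst$hospitals$id, "A")
})

test_that("single-province conservation forces the only feasible volume", {
  cv <- test_curve()
  inst <- allocation_instance(simple_hospitals("A", "P1", 100),
                              c(P1 = 70), threshold = 50, curve = cv)
  plan <- solve_province(inst, "P1")
  expect_equal(plan$status, "optimal")
  expect_equal(plan$volumes, c(A = 70))
  expect_equal(sum(plan$volumes), 70)
})

test_that("identical hospitals concentrate demand on the tie-break winner", {
  cv <- test_curve()
  inst <- allocation_instance(simple_hospitals(c("A", "B"), "P1", c(100, 100)),
                              c(P1 = 90), threshold = 50, curve = cv)
  plan <- solve_province(inst, "P1")
  # exhaustive sweep oracle over all integer splits
  best <- Inf
  for (a in c(0, 50:90)) {
    b <- 90 - a
    if (b != 0 && (b < 50 || b > 100)) next
    best <- min(best, sum(expected_deaths(cv, c(a, b))))
  }
  expect_equal(plan$objective, best, tolerance = 1e-12)
  expect_equal(sum(plan$open), 1)  # concentration: one open hospital
  expect_equal(unname(plan$volumes["B"]), 90)  # smallest open-pattern: A closed
})

test_that("demand exceeding total capacity is infeasible, as is a broken budget", {
  cv <- test_curve()
  inst <- allocation_instance(simple_hospitals(c("A", "B"), "P1", c(60, 60)),
                              c(P1 = 200), threshold = 50, curve = cv)
  expect_equal(solve_province(inst, "P1")$status, "infeasible")
  expect_equal(solve_region(inst)$status, "infeasible")
  instb <- allocation_instance(simple_hospitals("A", "P1", 100, unit_cost = 10),
                               c(P1 = 70), threshold = 50, curve = cv,
                               budget = 100)  # any plan costs 700
  expect_equal(solve_region(instb)$status, "infeasible")
  expect_equal(brute_force_allocate(instb)$status, "infeasible")
})

test_that("regional solve equals the province-wise decomposition when delta is zero", {
  cv <- test_curve()
  set.seed(31)
  hosp <- do.call(rbind, lapply(c("P1", "P2", "P3"), function(p)
    simple_hospitals(paste0(p, "-H", 1:2), p, sample(60:140, 2),
                     prev_observed_rate = runif(2, 0, 0.12))))
  demand <- c(P1 = 80, P2 = 120, P3 = 60)
  inst <- allocation_instance(hosp, demand, threshold = 50, curve = cv)
  joint <- solve_region(inst)
  pieces <- do.call(c, lapply(names(demand), function(p)
    solve_province(inst, p)$volumes))
  expect_identical(joint$volumes[names(pieces)], pieces)
  expect_equal(sum(joint$volumes), sum(demand))
})

test_that("solver matches the brute-force oracle on random small instances", {
  n_checked <- 0
  for (s in 1:25) {
    inst <- random_small_instance(s)
    a <- solve_region(inst)
    b <- brute_force_allocate(inst)
    expect_identical(a$status, b$status)
    if (a$status == "optimal") {
      n_checked <- n_checked + 1
      expect_equal(a$objective, b$objective, tolerance = 1e-9)
      expect_equal(nrow(verify_plan(inst, a)), 0)
      expect_equal(sum(a$volumes), sum(inst$demand))
    }
  }
  expect_gte(n_checked, 10)
})

test_that("hospitality windows admit cross-province allocations a 2-province enumeration confirms", {
  cv <- test_curve()
  hosp <- simple_hospitals(c("P1-H1", "P2-H1", "P2-H2"),
                           c("P1", "P2", "P2"), c(40, 40, 40),
                           prev_volume = c(20, 20, 20),
                           prev_observed_rate = c(0.02, 0.09, 0.09))
  inst <- allocation_instance(hosp, c(P1 = 30, P2 = 30), threshold = 10,
                              curve = cv, delta = 0.2)
  a <- solve_region(inst)
  b <- brute_force_allocate(inst)
  expect_equal(a$status, "optimal")
  expect_equal(a$objective, b$objective, tolerance = 1e-9)
  # the good P1 hospital absorbs foreign patients up to P1's inflow cap
  expect_equal(unname(a$volumes["P1-H1"]), 36)  # 30 + 0.2 * 30
  expect_equal(nrow(verify_plan(inst, a)), 0)
})

test_that("verify_plan names each violated constraint family", {
  cv <- test_curve()
  hosp <- simple_hospitals(c("A", "B"), "P1", c(100, 100))
  inst <- allocation_instance(hosp, c(P1 = 120), threshold = 50, curve = cv)
  plan <- solve_region(inst)
  expect_equal(nrow(verify_plan(inst, plan)), 0)
  v1 <- verify_plan(inst, c(A = 49, B = 71))
  expect_true("volume_bounds" %in% v1$constraint)
  v2 <- verify_plan(inst, c(A = 60, B = 59))
  expect_true("conservation" %in% v2$constraint)
  expect_true("hospitality_window" %in% v2$constraint)
  expect_error(verify_plan(inst, c(Z = 10)), "unknown hospital")
})

test_that("forced-open hospitals stay open even when closing would be better", {
  cv <- test_curve()
  hosp <- simple_hospitals(c("A", "B"), "P1", c(200, 60),
                           prev_volume = c(100, 55),
                           prev_observed_rate = c(0.02, 0.10))
  inst <- allocation_instance(hosp, c(P1 = 160), threshold = 50, curve = cv,
                              force_open_above_T = TRUE)
  plan <- solve_region(inst)
  expect_true(plan$open[["B"]])  # prev 55 > T = 50: may not close
  free <- allocation_instance(hosp, c(P1 = 160), threshold = 50, curve = cv)
  expect_lte(solve_region(free)$objective, plan$objective)
})

test_that("the Piedmont-like fixture solves under the case-study flags", {
  fx <- piedmont_like_fixture()
  expect_warning(
    inst <- allocation_instance(fx$hospitals, fx$demand, threshold = 50,
                                curve = fx$curve, capital_province = "TO",
                                capacity_twice_prev = TRUE,
                                halve_threshold_outside_capital = TRUE,
                                force_open_above_T = TRUE),
    "dropping")  # Torino wards below the unhalved threshold leave the model
  expect_equal(effective_bounds(inst, "TO-H01")[["lower"]], 50)
  expect_equal(effective_bounds(inst, "AL-H01")[["lower"]], 25)
  plan <- solve_region(inst)
  expect_equal(plan$status, "optimal")
  expect_equal(sum(plan$volumes), 1405)
  expect_equal(nrow(verify_plan(inst, plan)), 0)
  # every forced-open hospital (prev volume > T) is indeed open
  forced <- inst$hospitals$id[inst$hospitals$forced_open]
  expect_true(all(plan$open[forced]))
})

test_that("brute force refuses oversized instances", {
  cv <- test_curve()
  hosp <- simple_hospitals(paste0("H", 1:6), rep("P1", 6), rep(400, 6))
  inst <- allocation_instance(hosp, c(P1 = 900), threshold = 50, curve = cv)
  expect_error(brute_force_allocate(inst), "too large")
})
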