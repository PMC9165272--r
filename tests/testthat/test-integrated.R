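# Choice-set enumeration, theta-rule selection, skim and the full
# three-phase run.

test_that("eligibility splits hospitals by province under both criteria", {
  cv <- test_curve()
  hosp <- as_hospital_table(simple_hospitals(
    c("A1", "A2", "B1"), c("PA", "PA", "PB"), capacity = c(60, 40, 70),
    prev_volume = c(55, 20, 30)), cv)
  el <- eligible_hospitals(hosp, 50)
  expect_equal(el, list(PA = "A1", PB = "B1"))
  expect_warning(el2 <- eligible_hospitals(hosp, 50, criterion = "prev_volume"),
                 "no eligible")
  expect_equal(el2$PA, "A1")
  expect_equal(el2$PB, character(0))
})

test_that("minimum open count is the shortest capacity prefix covering demand", {
  expect_equal(min_required_open(c(100, 80), 90), 1)
  expect_equal(min_required_open(c(100, 80), 150), 2)
  expect_equal(min_required_open(c(80, 100, 60), 150), 2)  # order-free
  expect_equal(min_required_open(c(100, 80), 0), 1)  # one facility stays open
  expect_error(min_required_open(c(100, 80), 500), "capacity below")
  expect_error(min_required_open(numeric(0), 10), "never be served")
})

test_that("closed-form choice-set count equals explicit subset enumeration", {
  expect_equal(count_choice_sets(2, 1), 3)
  expect_equal(count_choice_sets(c(3, 5), c(3, 5)), 1)
  set.seed(77)
  for (rep in 1:40) {
    np <- sample(1:4, 1)
    H <- sample(1:8, np, replace = TRUE)
    r <- vapply(H, function(h) sample(seq_len(h), 1), integer(1))
    expect_equal(count_choice_sets(H, r), count_sets_by_enumeration(H, r))
  }
  expect_error(count_choice_sets(3, 4), "r_min")
})

test_that("enumeration respects both phase-1 constraints and indexes lazily", {
  cv <- test_curve()
  hosp <- simple_hospitals(
    c("A1", "A2", "B1", "B2"), c("PA", "PA", "PB", "PB"),
    capacity = c(100, 60, 100, 60), prev_volume = c(50, 30, 50, 30))
  inst <- allocation_instance(hosp, c(PA = 80, PB = 120), threshold = 50,
                              curve = cv)
  enum <- enumerate_choice_sets(inst)
  # PA: demand 80 -> {A1}, {A1,A2} admissible; {A2} fails capacity
  expect_equal(enum$subsets$PA, list("A1", c("A1", "A2")))
  # PB: demand 120 -> only {B1,B2}
  expect_equal(enum$subsets$PB, list(c("B1", "B2")))
  expect_equal(enum$n_admissible, 2)
  expect_equal(enum$n_prefilter, count_choice_sets(c(2, 2), c(1, 2)))
  sets <- materialize_choice_sets(enum)
  expect_equal(sets, lapply(1:2, function(k) get_choice_set(enum, k)))
  expect_error(materialize_choice_sets(enum, max_sets = 1), "refusing")
  # every admissible set covers provincial demand with eligible hospitals
  for (s in sets)
    for (p in c("PA", "PB")) {
      own <- intersect(s, hosp$id[hosp$province == p])
      expect_gte(sum(hosp$capacity[match(own, hosp$id)]), inst$demand[[p]])
    }
})

test_that("evaluating a choice set conserves patients and records violations", {
  region <- small_choice_region(seed = 3L)
  inst <- allocation_instance(region$hospitals, region$demand,
                              threshold = region$threshold,
                              curve = region$curve)
  D <- region$distances[, inst$hospitals$id, drop = FALSE]
  ev <- evaluate_choice_set(inst$hospitals$id, region$coeffs, region$patients,
                            D, inst$hospitals, region$curve, region$threshold)
  expect_equal(sum(ev$volumes), nrow(region$patients), tolerance = 1e-9)
  expect_equal(ev$deaths,
               total_mortality(ev$volumes, inst$hospitals, region$curve),
               tolerance = 1e-12)
  # a singleton regional choice set takes all the volume mass
  one <- evaluate_choice_set(inst$hospitals$id[1], region$coeffs,
                             region$patients, D, inst$hospitals,
                             region$curve, region$threshold)
  expect_equal(unname(one$volumes), nrow(region$patients))
  expect_true(length(one$over_capacity) >= 0)
})

test_that("theta-rule keeps the lowest rounded-mortality groups within tolerance", {
  mk_eval <- function(deaths, id) structure(
    list(choice_set = id, volumes = NULL, deaths = deaths,
         below_threshold = character(0), over_capacity = character(0)),
    class = "operational_evaluation")
  evals <- list(mk_eval(76, "a"), mk_eval(76.4, "b"),
                mk_eval(77, "c"), mk_eval(90, "d"))
  kept <- select_candidates(evals, theta = 10)
  expect_equal(vapply(kept, function(e) e$deaths, numeric(1)), c(76, 76.4, 77))
  # theta = 0: only ties with the minimum rounded value survive
  kept0 <- select_candidates(evals, theta = 0)
  expect_equal(vapply(kept0, function(e) e$deaths, numeric(1)), c(76, 76.4))
  expect_length(select_candidates(evals[4], theta = 10), 1)
  expect_error(select_candidates(list(), 10), "no evaluations")
  # never returns a group beyond (1 + theta/100) * lowest rounded value
  set.seed(13)
  for (rep in 1:20) {
    ev <- lapply(seq_len(8), function(i)
      mk_eval(runif(1, 20, 40), letters[i]))
    th <- sample(c(0, 5, 10, 25), 1)
    kept <- select_candidates(ev, th)
    lo <- min(round(vapply(ev, function(e) e$deaths, numeric(1))))
    for (k in kept) expect_lte(round(k$deaths), (1 + th / 100) * lo)
  }
})

test_that("structural skim picks the candidate closest to its strategic solution", {
  region <- small_choice_region(seed = 3L)
  inst <- allocation_instance(region$hospitals, region$demand,
                              threshold = region$threshold,
                              curve = region$curve)
  D <- region$distances[, inst$hospitals$id, drop = FALSE]
  enum <- enumerate_choice_sets(inst)
  evals <- lapply(seq_len(enum$n_admissible), function(k)
    evaluate_choice_set(get_choice_set(enum, k), region$coeffs,
                        region$patients, D, inst$hospitals, region$curve,
                        region$threshold))
  picked <- skim_candidates(evals, inst, "structural")
  # hand-computed oracle: recompute every candidate's L1 distance
  l1 <- vapply(evals, function(ev) {
    sub <- solve_region(volalloc:::restrict_instance(inst, ev$choice_set))
    if (sub$status != "optimal") return(NA_real_)
    sum(abs(ev$volumes[names(sub$volumes)] - sub$volumes))
  }, numeric(1))
  expect_equal(picked$criterion_value, min(l1, na.rm = TRUE), tolerance = 1e-9)
  single <- skim_candidates(evals[2], inst, "utility")
  expect_identical(single$evaluation$choice_set, evals[[2]]$choice_set)
})

test_that("the integrated run obeys the theta band and is deterministic", {
  region <- small_choice_region(seed = 3L)
  inst <- allocation_instance(region$hospitals, region$demand,
                              threshold = region$threshold,
                              curve = region$curve)
  D <- region$distances[, inst$hospitals$id, drop = FALSE]
  r1 <- run_integrated(inst, region$coeffs, region$patients, D, theta = 10)
  r2 <- run_integrated(inst, region$coeffs, region$patients, D, theta = 10)
  expect_identical(r1$mortality, r2$mortality)
  expect_identical(r1$integrated$choice_set, r2$integrated$choice_set)
  expect_gte(r1$mortality[["integrated"]], r1$min_operational_deaths - 1e-9)
  expect_lte(round(r1$mortality[["integrated"]]),
             (1 + 10 / 100) * round(r1$min_operational_deaths))
  expect_equal(sum(r1$integrated$volumes), nrow(region$patients),
               tolerance = 1e-9)
  # a region with a single admissible set: integrated == its evaluation
  cv <- test_curve()
  hosp <- simple_hospitals(c("A", "B"), c("PA", "PB"), c(120, 120),
                           prev_volume = c(60, 60))
  inst1 <- allocation_instance(hosp, c(PA = 100, PB = 100), threshold = 50,
                               curve = cv)
  pat <- data.frame(id = paste0("i", 1:8),
                    province = rep(c("PA", "PB"), each = 4),
                    age = 0, sex = 0, rurality = 0, admission_type = 0,
                    comorbidity = 0,
                    x_coord = rep(c(0, 50), each = 4), y_coord = 0)
  hosp$x_coord <- c(0, 50); hosp$y_coord <- 0
  Dm <- euclidean_distances(pat, hosp)
  rep1 <- run_integrated(inst1, region$coeffs, pat, Dm, theta = 10)
  expect_equal(rep1$enumeration$n_admissible, 1)
  expect_equal(rep1$mortality[["integrated"]], rep1$min_operational_deaths)
})
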