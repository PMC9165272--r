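# Conditional-logit choice probabilities, volume prediction and simulation.

two_hospital_setup <- function(n = 4) {
  patients <- data.frame(age = rep(0, n), sex = 0, rurality = 0,
                         admission_type = 0, comorbidity = 0)
  D <- matrix(10, n, 2, dimnames = list(NULL, c("A", "B")))
  list(patients = patients, D = D, lag = c(A = 100, B = 100))
}

test_that("utilities follow the linear distance/quality form", {
  cf <- choice_coefficients(-0.1, 0.01)
  s <- two_hospital_setup(1)
  U <- choice_utilities(cf, s$patients, s$D, s$lag)
  expect_equal(unname(U[1, ]), c(0, 0))  # -0.1*10 + 0.01*100 = 0
  # age interaction shifts the distance slope
  cf2 <- choice_coefficients(-0.1, 0, alpha_d = c(-0.05, 0, 0, 0, 0))
  p2 <- s$patients; p2$age <- 1
  U2 <- choice_utilities(cf2, p2, s$D, c(A = 0, B = 0))
  expect_equal(unname(U2[1, "A"]), -1.5)
  # zero distance, zero volume: zero utility
  expect_equal(unname(choice_utilities(cf, s$patients, s$D * 0,
                                       c(A = 0, B = 0))[1, ]), c(0, 0))
})

test_that("probabilities are normalised, symmetric and match the softmax closed form", {
  cf <- choice_coefficients(-0.1, 0.01)
  s <- two_hospital_setup()
  P <- choice_probabilities(cf, s$patients, s$D, s$lag)
  expect_equal(unname(P), matrix(0.5, 4, 2), tolerance = 1e-15)
  expect_equal(rowSums(P), rep(1, 4), tolerance = 1e-12)
  # singleton choice set
  P1 <- choice_probabilities(cf, s$patients, s$D, s$lag, choice_set = "A")
  expect_equal(unname(P1[, 1]), rep(1, 4))
  # closed form: utilities (0, ln 2, ln 4) -> (1/7, 2/7, 4/7)
  patients <- two_hospital_setup(1)$patients
  D3 <- matrix(0, 1, 3, dimnames = list(NULL, c("A", "B", "C")))
  P3 <- choice_probabilities(choice_coefficients(0, 1), patients, D3,
                             c(A = 0, B = log(2), C = log(4)))
  expect_equal(unname(P3[1, ]), c(1, 2, 4) / 7, tolerance = 1e-12)
  expect_error(choice_probabilities(cf, s$patients, s$D, s$lag,
                                    choice_set = character(0)), "empty")
})

test_that("literal-ratio convention works for positive utilities and refuses otherwise", {
  patients <- two_hospital_setup(1)$patients
  D <- matrix(0, 1, 2, dimnames = list(NULL, c("A", "B")))
  P <- choice_probabilities(choice_coefficients(0, 1), patients, D,
                            c(A = 30, B = 10), convention = "literal-ratio")
  expect_equal(unname(P[1, ]), c(0.75, 0.25))
  expect_error(
    choice_probabilities(choice_coefficients(-0.1, 0), patients,
                         D + 10, c(A = 0, B = 0),
                         convention = "literal-ratio"),
    "strictly positive")
})

test_that("probability normalisation and volume conservation hold on 1000 random patients", {
  region <- generate_region(region_config(n_provinces = 4L,
                                          hospitals_per_province = 3L,
                                          patients_per_province = 250L,
                                          seed = 9L))
  lag <- setNames(region$hospitals$prev_volume, region$hospitals$id)
  P <- choice_probabilities(region$coeffs, region$patients, region$distances, lag)
  expect_equal(nrow(P), 1000L)
  expect_true(max(abs(rowSums(P) - 1)) < 1e-12)
  vol <- predict_volumes(region$coeffs, region$patients, region$distances, lag)
  expect_equal(sum(vol), 1000, tolerance = 1e-9)
  # conservation also on a strict subset of open hospitals
  sub <- region$hospitals$id[seq(1, 12, by = 2)]
  vol_sub <- predict_volumes(region$coeffs, region$patients, region$distances,
                             lag, choice_set = sub)
  expect_equal(sum(vol_sub), 1000, tolerance = 1e-9)
})

test_that("softmax probabilities are invariant to a per-patient utility translation", {
  region <- small_choice_region(seed = 5L)
  lag <- setNames(region$hospitals$prev_volume, region$hospitals$id)
  P1 <- choice_probabilities(region$coeffs, region$patients, region$distances, lag)
  # adding a constant to every lagged volume shifts each patient's utilities
  # by a row constant, which must leave the softmax unchanged
  P2 <- choice_probabilities(region$coeffs, region$patients, region$distances,
                             lag + 500)
  expect_equal(P1, P2, tolerance = 1e-12)
})

test_that("probabilities move with own distance and own lagged volume as signed", {
  cf <- choice_coefficients(-0.1, 0.01)
  patients <- two_hospital_setup(1)$patients
  base <- matrix(c(10, 10), 1, 2, dimnames = list(NULL, c("A", "B")))
  lag <- c(A = 100, B = 100)
  p0 <- choice_probabilities(cf, patients, base, lag)[1, "A"]
  further <- base; further[1, 1] <- 20
  expect_lt(choice_probabilities(cf, patients, further, lag)[1, "A"], p0)
  expect_gt(choice_probabilities(cf, patients, base,
                                 c(A = 150, B = 100))[1, "A"], p0)
})

test_that("simulated choices are reproducible and match the binomial oracle", {
  s <- two_hospital_setup(10000)
  cf <- choice_coefficients(-0.1, 0.01)
  c1 <- simulate_choices(cf, s$patients, s$D, s$lag, seed = 42)
  c2 <- simulate_choices(cf, s$patients, s$D, s$lag, seed = 42)
  expect_identical(c1, c2)
  share <- mean(c1 == "A")
  expect_lt(abs(share - 0.5), 3 * sqrt(0.25 / 10000))
  # degenerate probabilities: overwhelming quality gap
  det <- simulate_choices(choice_coefficients(0, 1), s$patients[1:50, ],
                          s$D[1:50, ], c(A = 0, B = 100), seed = 1)
  expect_true(all(det == "B"))
})

test_that("divergence from a provincial plan counts out-of-plan choices", {
  patients <- data.frame(province = c("P1", "P1", "P2"))
  planned <- list(P1 = c("A"), P2 = c("B"))
  expect_equal(adherence_divergence(patients, c("A", "A", "B"), planned), 0)
  expect_equal(adherence_divergence(patients, c("B", "B", "A"), planned), 1)
  expect_equal(adherence_divergence(patients, c("A", "B", "B"), planned), 1 / 3)
})
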