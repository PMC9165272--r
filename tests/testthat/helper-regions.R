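# Shared builders for small test instances. Everything is generated in code;
# seeds are fixed where randomness is used.

test_curve <- function(dev_fraction = 0.3)
  mortality_curve("exponential", m_floor = 0.02, m_scale = 0.08,
                  decay = 0.02, dev_fraction = dev_fraction)

# A flat curve (mortality independent of volume) for arithmetic checks.
flat_curve <- function(rate = 0.05, dev_fraction = 0) {
  cv <- mortality_curve("exponential", m_floor = rate, m_scale = 0,
                        decay = 1, dev_fraction = dev_fraction)
  cv
}

simple_hospitals <- function(ids, provinces, capacity, prev_volume = capacity %/% 2,
                             prev_observed_rate = NA_real_, unit_cost = 10) {
  data.frame(id = ids, province = provinces, capacity = capacity,
             prev_volume = prev_volume, prev_observed_rate = prev_observed_rate,
             unit_cost = unit_cost)
}

# Random tiny instance small enough for the brute-force oracle: at most
# 3 hospitals per province, at most 4 hospitals overall, demand <= 30.
random_small_instance <- function(seed, curve = test_curve()) {
  set.seed(seed)
  np <- sample(1:2, 1)
  provs <- paste0("P", seq_len(np))
  sizes <- sample(1:3, np, replace = TRUE)
  while (sum(sizes) > 4) sizes <- sample(1:3, np, replace = TRUE)
  hosp <- do.call(rbind, lapply(seq_len(np), function(n) {
    J <- sizes[n]
    prev <- sample(4:10, J, replace = TRUE)
    simple_hospitals(paste0(provs[n], "-H", seq_len(J)), provs[n],
                     capacity = prev * 2L, prev_volume = prev,
                     prev_observed_rate = runif(J, 0, 0.15),
                     unit_cost = round(runif(J, 5, 15)))
  }))
  demand <- stats::setNames(vapply(seq_len(np), function(n) {
    cap_n <- sum(hosp$capacity[hosp$province == provs[n]])
    sample(6:min(30L, cap_n), 1L)
  }, integer(1)), provs)
  delta <- if (runif(1) < 0.5) 0 else round(runif(1, 0.05, 0.3), 2)
  budget <- if (runif(1) < 0.3) sum(demand) * 11 else Inf
  suppressWarnings(allocation_instance(
    hosp, demand, threshold = 8, curve = curve, delta = delta,
    budget = budget, force_open_above_T = runif(1) < 0.3))
}

# Independent per-province subset-enumeration oracle for the choice-set count.
count_sets_by_enumeration <- function(H, r_min) {
  per <- vapply(seq_along(H), function(n) {
    tot <- 0L
    for (k in r_min[n]:H[n])
      tot <- tot + ncol(utils::combn(seq_len(H[n]), k))
    tot
  }, integer(1))
  prod(per)
}

small_choice_region <- function(seed = 3L, n_provinces = 3L,
                                hospitals_per_province = 2L,
                                patients_per_province = 100L,
                                threshold = 50L)
  generate_region(region_config(
    n_provinces = n_provinces,
    hospitals_per_province = hospitals_per_province,
    patients_per_province = patients_per_province,
    threshold = threshold, seed = seed))
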