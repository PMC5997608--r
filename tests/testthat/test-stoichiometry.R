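test_that("Cmol masses reproduce the standard biomass and PHB constants", {
  expect_equal(round(cmol_mass(biomass_formula()), 1), 24.6)
  expect_equal(round(cmol_mass(phb_formula()), 1), 21.5)
  expect_equal(cmol_mass(biomass_formula()), 24.6263, tolerance = 1e-6)
  expect_equal(cmol_mass(phb_formula()), 21.5225, tolerance = 1e-6)
  expect_equal(cmol_mass(elemental_formula(C = 1)), 12.011)
  # normalisation: C4H6O2 scales to CH1.5O0.5
  f <- elemental_formula(C = 4, H = 6, O = 2)
  expect_equal(unclass(f)[["C"]], 1)
  expect_equal(unclass(f)[["H"]], 1.5)
})

test_that("cmol_mass agrees with an independent per-element summation", {
  w <- c(C = 12.011, H = 1.008, O = 15.999, N = 14.007)
  set.seed(11)
  for (i in 1:1000) {
    f <- random_formula()
    oracle <- sum(unclass(f) * w[names(unclass(f))])
    expect_equal(cmol_mass(f), oracle, tolerance = 1e-12)
  }
})

test_that("invalid formulas and masses are rejected", {
  expect_error(elemental_formula(C = 1, H = -0.1), "negative")
  expect_error(elemental_formula(C = 0, H = 2), "carbon")
  expect_error(mass_to_cmol(1, 0), "positive")
  expect_error(mass_to_cmol(-1, 21.5), "non-negative")
})

test_that("degree of reduction matches hand-computed values and is linear", {
  expect_identical(degree_of_reduction(acetate_formula()), 4)
  expect_equal(degree_of_reduction(phb_formula()), 4.5)
  expect_equal(degree_of_reduction(biomass_formula()), 4.2)
  # linearity in each coefficient
  set.seed(12)
  for (i in 1:50) {
    a <- random_formula(); b <- random_formula()
    ga <- degree_of_reduction(a); gb <- degree_of_reduction(b)
    mix <- elemental_formula(C = 1,
                             H = (unclass(a)[["H"]] + unclass(b)[["H"]]) / 2,
                             O = (unclass(a)[["O"]] + unclass(b)[["O"]]) / 2,
                             N = (unclass(a)[["N"]] + unclass(b)[["N"]]) / 2)
    expect_equal(degree_of_reduction(mix), (ga + gb) / 2, tolerance = 1e-12)
  }
})

test_that("mass/Cmol conversions round-trip and match worked values", {
  expect_identical(mass_to_cmol(0, 21.5), 0)
  expect_equal(mass_to_cmol(21.5, 21.5), 1000)
  expect_equal(mass_to_cmol(3.182, 21.5), 148, tolerance = 5e-4)
  set.seed(13)
  x <- runif(200, 0, 50)
  m <- runif(200, 10, 40)
  for (i in 1:200)
    expect_equal(cmol_to_mass(mass_to_cmol(x[i], m[i]), m[i]), x[i],
                 tolerance = 1e-12)
})

test_that("active biomass is VSS minus PHB with consistency guards", {
  expect_equal(active_biomass(2, 0), 2)
  expect_equal(active_biomass(2, 2), 0)
  expect_equal(active_biomass(3.945, 3.182), 0.763)
  expect_equal(active_biomass(2, phb_fraction = 0.5), 1)
  expect_error(active_biomass(2, 2.1), "exceeds")
  expect_error(active_biomass(2, phb_fraction = 1.2), "0, 1")
})
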