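# Single-curve analysis: depth correction, Hertz model/fit, contact point,
# drop detection, segmentation. Ground truth from the seeded generator is
# the oracle throughout.

test_that("indentation depth subtracts the cantilever deflection", {
  # d = F/k = 2 nN / 0.02 N/m = 100 nm, so 1000 nm travel -> 900 nm depth
  expect_equal(indentation_depth(2000, 2, 0.02, 1000), 900)
  # rigid-cantilever limit: deflection ~ 0
  expect_equal(indentation_depth(2000, 2, 1e6, 1000), 1000, tolerance = 1e-5)
  expect_equal(indentation_depth(1500, 0, 0.02, 1000), 500)
  expect_equal(indentation_depth(900, 0.5, 0.02, 1000), 0)  # floored
  expect_error(indentation_depth(2000, 2, -1, 1000),
               class = "afm_invalid_argument")
  expect_error(indentation_depth(numeric(0), numeric(0), 0.02, 0),
               class = "afm_invalid_argument")
})

test_that("hertz_force matches independent arithmetic and is linear in E", {
  expect_identical(hertz_force(1000, 2.25, 0.5, 0), 0)
  # frozen via numpy: 4*sqrt(2.25e-6)*1000/(3*0.75)*(500e-9)^1.5 * 1e9
  expect_equal(hertz_force(1000, 2.25, 0.5, 500), 0.9428090415820632,
               tolerance = 1e-12)
  expect_equal(hertz_force(2000, 2.25, 0.5, 500),
               2 * hertz_force(1000, 2.25, 0.5, 500))
  expect_error(hertz_force(1000, 2.25, 1, 500),
               class = "afm_invalid_argument")
  expect_error(hertz_force(-5, 2.25, 0.5, 500),
               class = "afm_invalid_argument")
})

test_that("contact point is found to one sample on noiseless curves", {
  cv <- generate_curve(pyramid_params(seed = 4))
  zA <- detect_contact_point(cv)
  dz <- median(diff(cv$piezo_z))
  expect_lte(abs(as.numeric(zA) - cv$ground_truth$contact_z), dz)
})

test_that("contact point is within 20 nm at noise_sd = 0.01", {
  for (seed in 1:8) {
    cv <- generate_curve(pyramid_params(seed = seed, membrane_slope = 5,
                                        noise_sd = 0.01,
                                        penetration_probability = 0))
    zA <- detect_contact_point(cv)
    expect_lte(abs(as.numeric(zA) - cv$ground_truth$contact_z), 20)
  }
})

test_that("a flat trace raises a no-contact error", {
  flat <- force_curve(seq(0, 1998, by = 2), rep(0, 1000),
                      spring_constant = 0.02, approach_speed = 1,
                      trigger_force = 12, tip_kind = "pyramid",
                      tip_radius = 0.01)
  expect_error(detect_contact_point(flat), class = "afm_no_contact")
})

test_that("fit_hertz recovers noiseless moduli essentially exactly", {
  for (E in c(423, 1862)) {
    fit <- fit_hertz(generate_curve(sphere_params(E = E, seed = 5)))
    expect_lt(abs(fit$modulus - E) / E, 1e-3)
    expect_lt(abs(fit$contact_point - 1000), 1)
    expect_identical(fit$poisson_ratio, 0.5)
  }
})

test_that("fit_hertz is unbiased under noise and rejects pyramid tips", {
  Es <- vapply(1:20, function(i)
    fit_hertz(generate_curve(sphere_params(E = 1000, seed = i,
                                           noise_sd = 0.05)))$modulus,
    numeric(1))
  expect_lt(abs(mean(Es) - 1000) / 1000, 0.05)
  expect_error(fit_hertz(generate_curve(pyramid_params(seed = 1))),
               class = "afm_fit_error")
})

test_that("drop-free curves give an empty event list", {
  cv <- generate_curve(pyramid_params(seed = 6, penetration_probability = 0,
                                      noise_sd = 0.05))
  expect_identical(nrow(detect_force_drops(cv)), 0L)
})

test_that("planted drops are recovered with index, force and magnitude", {
  # noiseless: exact index, exact insertion force
  cv <- generate_curve(pyramid_params(seed = 7))
  gt <- cv$ground_truth$events
  ev <- detect_force_drops(cv)
  expect_identical(nrow(ev), 1L)
  expect_lte(abs(ev$index - gt$index), 2L)
  expect_equal(ev$insertion_force, gt$force, tolerance = 1e-9)
  expect_equal(ev$drop_magnitude, gt$drop, tolerance = 0.05)
  # two planted drops, ranked membrane then nucleus
  cv2 <- generate_curve(pyramid_params(seed = 11, noise_sd = 0.05,
                                       membrane_slope = 1.6667,
                                       second_drop_probability = 1))
  gt2 <- cv2$ground_truth$events
  ev2 <- detect_force_drops(cv2)
  expect_identical(nrow(ev2), 2L)
  expect_identical(ev2$rank, c("membrane_first", "nucleus_second"))
  expect_lt(max(abs(ev2$index - gt2$index)), 6)
})

test_that("round-trip recovery holds over a seeded noisy batch", {
  p <- pyramid_params(seed = 21, noise_sd = 0.05,
                      penetration_probability = 1)
  set <- generate_condition_set(p, 25)
  errs <- c()
  for (cv in set) {
    ev <- detect_force_drops(cv)
    gt <- cv$ground_truth$events
    expect_identical(nrow(ev), nrow(gt))
    expect_lt(max(abs(ev$index - gt$index)), 8)
    errs <- c(errs, ev$insertion_force - gt$force)
    # displacement consistency: time * speed = displacement, exactly
    expect_equal(ev$insertion_time * cv$approach_speed,
                 ev$insertion_displacement, tolerance = 1e-12)
  }
  expect_lt(mean(abs(errs)), 3 * 0.05)
})

test_that("segmentation fits the A-B slope on corrected depth", {
  cv <- generate_curve(pyramid_params(seed = 9, membrane_slope = 3))
  # exact line when measured from the true contact point
  seg_true <- segment_curve(cv, z_A = cv$ground_truth$contact_z)
  expect_equal(seg_true$ab_slope, 3, tolerance = 1e-6)
  # detected contact point is one sample off at most, slope still tight
  seg <- segment_curve(cv)
  expect_equal(seg$ab_slope, 3, tolerance = 1e-4)
  expect_gt(seg$ab_slope_r2, 1 - 1e-6)
  expect_identical(seg$first_drop_index,
                   detect_force_drops(cv)$index[1])
  # no-drop curve: B absent, slope fitted A -> C
  cv0 <- generate_curve(pyramid_params(seed = 10,
                                       penetration_probability = 0,
                                       substrate_onset_depth = 10,
                                       z_max_um = 10))
  seg0 <- segment_curve(cv0)
  expect_true(is.na(seg0$first_drop_index))
  expect_equal(seg0$ab_slope, 3, tolerance = 1e-6)
})

test_that("degenerate A-B segments are rejected", {
  cv <- generate_curve(pyramid_params(seed = 12))
  zA <- detect_contact_point(cv)
  fake <- detect_force_drops(cv)
  fake$index[1] <- attr(zA, "index") + 2L
  expect_error(segment_curve(cv, events = fake, z_A = zA),
               class = "afm_segmentation_degenerate")
})

test_that("stiffer generated membranes yield larger fitted slopes", {
  slope_of <- function(s, seed) {
    set <- generate_condition_set(
      pyramid_params(seed = seed, membrane_slope = s, noise_sd = 0.05,
                     penetration_probability = 1), 8)
    mean(vapply(set, function(cv) segment_curve(cv)$ab_slope, numeric(1)))
  }
  expect_lt(slope_of(2, 31), slope_of(6, 32))
})

test_that("detector false-positive rate is <= 1% on drop-free noisy curves", {
  # scaled-down version of the 1000-curve acceptance property (n = 120)
  p <- pyramid_params(seed = 41, penetration_probability = 0,
                      noise_sd = 0.05)
  set <- generate_condition_set(p, 120)
  fp <- sum(vapply(set, function(cv) nrow(detect_force_drops(cv)) > 0,
                   logical(1)))
  expect_lte(fp / length(set), 0.01)
})
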