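# Generator: four-stage morphology, seeded determinism, ground-truth labels.

test_that("parameter invariants are enforced", {
  expect_error(curve_gen_params(penetration_probability = 1.2),
               class = "afm_invalid_params")
  expect_error(curve_gen_params(noise_sd = -1), class = "afm_invalid_params")
  expect_error(curve_gen_params(trigger_force = 0),
               class = "afm_invalid_params")
  expect_error(curve_gen_params(insertion_force_mean = 15,
                                trigger_force = 12),
               class = "afm_invalid_params")
  expect_error(curve_gen_params(post_drop_softening = 0),
               class = "afm_invalid_params")
})

test_that("no-penetration curves carry an empty ground-truth event list", {
  cv <- generate_curve(pyramid_params(seed = 3, penetration_probability = 0))
  expect_identical(nrow(cv$ground_truth$events), 0L)
})

test_that("noiseless spherical curves equal the Hertz forward model", {
  p <- sphere_params(E = 1000, seed = 3)
  cv <- generate_curve(p)
  post <- cv$piezo_z > cv$ground_truth$contact_z
  d <- indentation_depth(cv$piezo_z, cv$force, cv$spring_constant,
                         cv$ground_truth$contact_z)
  expect_lt(max(abs(cv$force[post] -
                      hertz_force(1000, 2.25, 0.5, d[post]))), 1e-9)
})

test_that("curves stop at the trigger force and respect its tolerance", {
  for (seed in 1:5) {
    cv <- generate_curve(pyramid_params(seed = seed, noise_sd = 0.05))
    n <- length(cv$force)
    expect_gte(cv$force[n], cv$trigger_force)
    expect_true(all(cv$force[-n] < cv$trigger_force))
    expect_lte(max(cv$force), cv$trigger_force * 1.1)
  }
})

test_that("the trigger must be reachable within the piezo range", {
  expect_error(
    generate_curve(pyramid_params(seed = 1, contact_z = 1, z_max_um = 1.2,
                                  penetration_probability = 0)),
    class = "afm_trigger_unreachable")
})

test_that("identical params and seed give bit-identical output", {
  p <- pyramid_params(seed = 17, noise_sd = 0.05,
                      second_drop_probability = 0.5)
  expect_identical(generate_curve(p), generate_curve(p))
  set_a <- generate_condition_set(p, 12)
  set_b <- generate_condition_set(p, 12)
  expect_identical(set_a, set_b)
  # and the generator does not disturb the caller's RNG stream
  set.seed(99); before <- .Random.seed
  invisible(generate_curve(p))
  expect_identical(before, .Random.seed)
})

test_that("exact-count mode realises the configured penetration count", {
  p <- pyramid_params(seed = 5, penetration_probability = 37 / 60,
                      noise_sd = 0.05)
  set <- generate_condition_set(p, 60, exact_count = TRUE)
  n_pen <- sum(vapply(set, function(cv) nrow(cv$ground_truth$events) > 0,
                      logical(1)))
  expect_identical(n_pen, 37L)
  single <- generate_condition_set(pyramid_params(seed = 2), 1)
  expect_gte(nrow(single[[1]]$ground_truth$events), 1)
})

test_that("ground-truth labels are consistent with the trace", {
  # every labelled event must coincide with a negative step > 5 x noise_sd
  for (seed in 1:10) {
    p <- pyramid_params(seed = seed, noise_sd = 0.05,
                        second_drop_probability = 0.5)
    cv <- generate_curve(p)
    ev <- cv$ground_truth$events
    for (i in seq_len(nrow(ev))) {
      step <- cv$force[ev$index[i] + 1L] - cv$force[ev$index[i]]
      expect_lt(step, -5 * p$noise_sd)
    }
  }
})

test_that("pre-contact segment is zero-mean noise", {
  p <- pyramid_params(seed = 8, noise_sd = 0.05)
  cv <- generate_curve(p)
  pre <- cv$force[cv$piezo_z < cv$ground_truth$contact_z - 10]
  expect_gt(length(pre), 400)
  expect_lt(abs(mean(pre)), 4 * 0.05 / sqrt(length(pre)))
  expect_equal(sd(pre), 0.05, tolerance = 0.15)
})

test_that("second drops appear only after a first drop and before trigger", {
  found <- 0L
  for (seed in 1:20) {
    cv <- generate_curve(pyramid_params(seed = seed, noise_sd = 0.02,
                                        second_drop_probability = 1))
    ev <- cv$ground_truth$events
    if (nrow(ev) == 2) {
      found <- found + 1L
      expect_identical(ev$rank, c("membrane_first", "nucleus_second"))
      expect_gt(ev$index[2], ev$index[1])
      expect_lt(ev$index[2], length(cv$force))
    }
  }
  expect_gt(found, 10L)
})
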