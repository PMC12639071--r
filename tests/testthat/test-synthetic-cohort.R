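test_that("generated gradient basis is orthonormal, unipolar-first, ordered", {
  b <- generate_gradient_basis(n_regions = 4, n_gradients = 2, seed = 1)
  expect_equal(dim(b$vectors), c(4L, 2L))
  expect_lt(abs(sum(b$vectors[, 1] * b$vectors[, 2])), 1e-12)

  for (seed in c(1, 7, 99)) {
    b <- generate_gradient_basis(40, 6, seed = seed)
    expect_true(all(b$vectors[, 1] > 0))
    # bipolar later components
    expect_true(all(apply(b$vectors[, -1], 2, min) < 0))
    expect_true(all(apply(b$vectors[, -1], 2, max) > 0))
    # orthonormal columns, weight norms strictly decreasing
    expect_lt(max(abs(crossprod(b$vectors) - diag(6))), 1e-10)
    expect_true(all(diff(sqrt(colSums(b$weights^2))) < 0))
  }
  expect_identical(generate_gradient_basis(30, 5, seed = 3)$vectors,
                   generate_gradient_basis(30, 5, seed = 3)$vectors)
  expect_error(generate_gradient_basis(4, 5, seed = 1), "exceed")
})

test_that("coupling matrix eigenvalues match the damped-oscillator closed form", {
  m <- build_coupling_matrix(0.2, 0, tr_seconds = 1)
  ev <- eigen(companion_matrix(m))$values
  expect_equal(sort(Im(ev)), c(-0.2, 0.2), tolerance = 1e-12)
  expect_equal(Re(ev), c(0, 0), tolerance = 1e-12)

  m <- build_coupling_matrix(1.0, 0.2, tr_seconds = 1)
  ev <- eigen(companion_matrix(m))$values
  expect_equal(Re(ev), c(-0.1, -0.1), tolerance = 1e-10)
  expect_equal(max(Im(ev)), sqrt(0.99), tolerance = 1e-10)

  expect_error(build_coupling_matrix(0.1, 0.3), "overdamped")
})

test_that("cross-coupling terms alter only the targeted equation", {
  base <- build_coupling_matrix(c(0.2, 0.3), c(0.02, 0.02))
  cc <- data.frame(from = 2, to = 1, type = "position", value = 0.01)
  m <- build_coupling_matrix(c(0.2, 0.3), c(0.02, 0.02), cc)
  diffs <- m$coefficients - base$coefficients
  expect_equal(sum(diffs != 0), 1L)
  expect_equal(diffs[1, "g2"], 0.01)
})

test_that("noise-free simulation matches analytic oscillator solutions", {
  # G(0) = 0, G'(0) = omega gives sin(omega t)
  m <- build_coupling_matrix(0.2, 0)
  g <- simulate_gradient_timeseries(m, 400, forcing_sd = 0,
                                    init = c(0, 0.2))
  tt <- 0:399
  expect_lt(sqrt(mean((g$values[, 1] - sin(0.2 * tt))^2)), 1e-3)

  # damping c = 0.2: envelope decays as exp(-0.1 t)
  m <- build_coupling_matrix(1, 0.2)
  g <- simulate_gradient_timeseries(m, 200, forcing_sd = 0, init = c(1, 0))
  env <- exp(-0.1 * (0:199))
  expect_true(all(abs(g$values[, 1]) <= env * 1.01 + 1e-12))
  # amplitude at peaks tracks the envelope
  expect_equal(unname(abs(g$values[64, 1]) / env[64]), 1, tolerance = 0.1)
})

test_that("forced simulations are reproducible and stationary", {
  m <- default_coupling_model(4, tr_seconds = 2,
                              frequencies = c(0.12, 0.2, 0.28, 0.36),
                              dampings = rep(0.05, 4),
                              calibrate_pairs = list())
  g1 <- simulate_gradient_timeseries(m, 500, forcing_sd = 0.05, seed = 11)
  g2 <- simulate_gradient_timeseries(m, 500, forcing_sd = 0.05, seed = 11)
  expect_identical(g1$values, g2$values)

  g <- simulate_gradient_timeseries(m, 4000, forcing_sd = 0.05, seed = 5)
  v1 <- apply(g$values[1:2000, ], 2, var)
  v2 <- apply(g$values[2001:4000, ], 2, var)
  expect_true(all(v1 / v2 > 0.8 & v1 / v2 < 1.25))
})

test_that("unstable systems trigger a warning", {
  m <- coupling_model(matrix(c(0, 0.04, 0.01), 1), tr_seconds = 1)
  expect_warning(simulate_gradient_timeseries(m, 50, forcing_sd = 0),
                 "unstable")
})

test_that("rendered BOLD round-trips through projection and is reproducible", {
  basis <- generate_gradient_basis(15, 4, seed = 2)
  model <- build_coupling_matrix(seq(0.15, 0.3, length.out = 4),
                                 rep(0.04, 4))
  g <- simulate_gradient_timeseries(model, 200, forcing_sd = 0.05, seed = 3)
  scan <- render_bold(g, basis, region_noise_sd = 0)
  back <- project_to_gradients(scan, basis, center = FALSE)
  expect_lt(max(abs(back$values - g$values)), 1e-10)

  s1 <- render_bold(g, basis, region_noise_sd = 0.1, seed = 9)
  s2 <- render_bold(g, basis, region_noise_sd = 0.1, seed = 9)
  expect_identical(s1$values, s2$values)

  # unipolar-only rendering: all regions positively correlated
  gu <- gradient_timeseries(cbind(sin(0.2 * (1:300)), 0, 0, 0))
  su <- render_bold(gu, basis, region_noise_sd = 0.01, seed = 1)
  expect_true(all(cor(su$values) > 0))

  bad <- gradient_timeseries(matrix(rnorm(100 * 3), 100, 3))
  expect_error(render_bold(bad, basis), "does not match")
})

test_that("atrophy cohort is built from planted components and recoverable", {
  cfg <- cohort_config(n_subjects = 200, n_normals = 20, n_regions = 40,
                       noise_sds = list(atrophy = 0.1, bold = 0.1),
                       batch_shift = c(trio = 0, prisma = 0),
                       batch_scale = c(trio = 1, prisma = 1),
                       seed = 42)
  co <- generate_atrophy_cohort(cfg)
  expect_equal(dim(co$atrophy), c(220L, 40L))
  # normals have exactly zero scores
  expect_true(all(co$scores[co$group == "normal", ] == 0))
  # least-squares recovery of the planted scores
  shat <- t(qr.coef(qr(co$patterns), t(co$atrophy)))
  for (k in 1:3) {
    r2 <- summary(lm(co$scores[, k] ~ shat[, k]))$r.squared
    expect_gt(r2, 0.95)
  }
  # noise-free construction is exact (unit atrophy scale)
  cfg0 <- cohort_config(n_subjects = 5, n_regions = 40, atrophy_scale = 1,
                        noise_sds = list(atrophy = 0, bold = 0), seed = 1)
  co0 <- generate_atrophy_cohort(cfg0)
  expect_equal(unname(co0$atrophy), co0$scores %*% t(co0$patterns),
               tolerance = 1e-12)
  # the configured scale multiplies the planted mix
  cfg8 <- cohort_config(n_subjects = 5, n_regions = 40, atrophy_scale = 8,
                        noise_sds = list(atrophy = 0, bold = 0), seed = 1)
  co8 <- generate_atrophy_cohort(cfg8)
  expect_equal(co8$atrophy, 8 * co0$atrophy, tolerance = 1e-12)
})

test_that("structure-function link shifts amplitudes and angles as planted", {
  base <- default_coupling_model(6, tr_seconds = 2)
  link <- link_coefficients(amp_jitter_sd = 0, angle_jitter_sd = 0)
  sc <- rbind(c(0, 0, 0), c(1.5, 0, 0), c(-1.5, 0, 0), c(0, 1, 0),
              c(0, 0, 1))
  subj <- apply_structure_function_link(sc, link, base, forcing_sd = 0.05)

  # zero scores: base model unchanged
  expect_equal(subj[[1]]$model$coefficients, base$coefficients)
  expect_equal(unname(subj[[1]]$forcing_sd), rep(0.05, 6))

  # planted angles are realized in the eigenmode measurement
  for (i in 2:5) {
    pa <- pair_phase_angle(eigenmodes_of(subj[[i]]$model))
    a14 <- pa$angle_deg[pa$g1 == 1 & pa$g2 == 4]
    a12 <- pa$angle_deg[pa$g1 == 1 & pa$g2 == 2]
    expect_lt(abs(a14 - subj[[i]]$angle_targets["g1-g4"]), 6)
    expect_lt(abs(a12 - subj[[i]]$angle_targets["g1-g2"]), 6)
  }
  # s1 high: angle below 90, G1 forcing reduced
  expect_lt(subj[[2]]$angle_targets["g1-g4"], 90)
  expect_lt(subj[[2]]$forcing_sd[1], subj[[1]]$forcing_sd[1])

  # monotone link: higher s1 never increases expected G1 variance
  grid <- c(-1, 0, 1, 2)
  sg <- cbind(grid, 0, 0)
  sj <- apply_structure_function_link(sg, link, base, forcing_sd = 0.05)
  mean_var <- sapply(seq_along(grid), function(i) {
    mean(sapply(1:20, function(r) {
      g <- simulate_gradient_timeseries(sj[[i]]$model, 400,
                                        forcing_sd = sj[[i]]$forcing_sd,
                                        seed = 100 * r + i)
      var(g$values[, 1])
    }))
  })
  expect_true(all(diff(mean_var) < 0))
})

test_that("simulated G1 variance falls and G1-G4 angle collapses with s1", {
  base <- default_coupling_model(6, tr_seconds = 2)
  link <- link_coefficients(amp_jitter_sd = 0, angle_jitter_sd = 0)
  s_low <- qnorm(0.2, 0.8, 0.8); s_high <- qnorm(0.8, 0.8, 0.8)
  subj <- apply_structure_function_link(rbind(c(s_low, 0, 0),
                                              c(s_high, 0, 0)),
                                        link, base, forcing_sd = 0.05)
  v <- sapply(1:2, function(i) {
    g <- simulate_gradient_timeseries(subj[[i]]$model, 3000,
                                      forcing_sd = subj[[i]]$forcing_sd,
                                      seed = 77)
    var(g$values[, 1])
  })
  expect_lt(v[2] / v[1], 1)
  pa <- pair_phase_angle(eigenmodes_of(subj[[2]]$model))
  expect_lt(pa$angle_deg[pa$g1 == 1 & pa$g2 == 4], 90)
})

test_that("angle targets outside (0, 180) are rejected", {
  base <- default_coupling_model(4, tr_seconds = 2,
                                 calibrate_pairs = list(c(1L, 2L)))
  cal <- calibrate_pair_angle(base, 1, 2)
  expect_error(lookup_angle_stiffness(cal, 0), "0, 180")
  expect_error(lookup_angle_stiffness(cal, 185), "0, 180")
})

test_that("cognition generator follows the specified coefficients", {
  s <- data.frame(S1 = rnorm(50), S2 = rnorm(50), S3 = rnorm(50))
  specs <- list(
    pure_noise = list(coef = c(S1 = 0)),
    copy_s1 = list(coef = c(S1 = 1)),
    quad = list(coef = c(S1 = 0.5), quadratic = c(S3 = 1)),
    masked = list(coef = c(S2 = 1), missing_rate = 0.3)
  )
  cg0 <- generate_cognition(s, specs, noise_sd = 0, seed = 4)
  expect_equal(cg0$copy_s1, s$S1, tolerance = 1e-12)
  expect_equal(cg0$quad, 0.5 * s$S1 + (s$S3 - mean(s$S3))^2,
               tolerance = 1e-12)
  expect_true(all(cg0$pure_noise == 0))
  expect_gt(sum(is.na(cg0$masked)), 0)

  cg1 <- generate_cognition(s, specs, noise_sd = 0.5, seed = 4)
  cg2 <- generate_cognition(s, specs, noise_sd = 0.5, seed = 4)
  expect_identical(cg1, cg2)
  expect_gt(sd(cg1$pure_noise), 0)

  expect_error(generate_cognition(s, list(bad = list(coef = c(F9 = 1)))),
               "unknown predictor")
})

test_that("normative reference volumes follow the linear covariate model", {
  ref <- generate_normative_reference(60, n_regions = 8, seed = 5)
  expect_equal(dim(ref$volumes), c(60L, 8L))
  # zero residual SD makes volumes exactly linear in covariates
  re0 <- ref$region_effects
  re0$residual_sd <- rep(0, 8)
  ref0 <- generate_normative_reference(60, n_regions = 8,
                                       region_effects = re0, seed = 5)
  D <- cbind(1, as.matrix(ref0$covariates))
  expect_equal(unname(ref0$volumes), unname(D %*% re0$coefficients),
               tolerance = 1e-10)
  expect_identical(generate_normative_reference(40, n_regions = 4,
                                                seed = 9)$volumes,
                   generate_normative_reference(40, n_regions = 4,
                                                seed = 9)$volumes)
  expect_error(generate_normative_reference(10), "n >= 30")
})

test_that("full cohort simulation is deterministic in the seed", {
  cfg <- cohort_config(n_subjects = 3, n_normals = 1, n_regions = 15,
                       n_gradients = 4, n_timepoints = 80, seed = 8)
  base <- default_coupling_model(4, tr_seconds = 2,
                                 calibrate_pairs = list(c(1L, 2L)))
  a <- simulate_cohort(cfg, base_model = base)
  b <- simulate_cohort(cfg, base_model = base)
  expect_identical(a$atrophy, b$atrophy)
  expect_identical(a$scans[[2]]$values, b$scans[[2]]$values)
  expect_identical(a$ground_truth$scores, b$ground_truth$scores)
})
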