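test_that("finite differences match polynomial and trigonometric oracles", {
  n <- 50
  ramp <- gradient_timeseries(cbind(seq_len(n)))
  d <- finite_difference(ramp)
  expect_equal(unname(d$first[, 1]), rep(1, n), tolerance = 1e-12)
  expect_equal(unname(d$second[2:(n - 1), 1]), rep(0, n - 2),
               tolerance = 1e-12)

  quad <- gradient_timeseries(cbind((seq_len(n))^2))
  dq <- finite_difference(quad)
  expect_equal(unname(dq$second[3:(n - 2), 1]), rep(2, n - 4),
               tolerance = 1e-10)

  tt <- seq_len(400)
  sine <- gradient_timeseries(cbind(sin(0.2 * tt)))
  ds <- finite_difference(sine)
  err <- abs(ds$first[2:399, 1] - 0.2 * cos(0.2 * tt[2:399]))
  expect_lt(max(err), 0.2^3 / 6 + 1e-12)

  expect_error(finite_difference(gradient_timeseries(matrix(1:2, 2, 1))),
               "3 timepoints")
})

test_that("coupling fit recovers a noise-free oscillator to the bias bound", {
  m <- build_coupling_matrix(0.2, 0)
  g <- simulate_gradient_timeseries(m, 2000, forcing_sd = 0,
                                    init = c(1, 0))
  fit <- fit_coupling(g)
  expect_lt(abs(fit$coefficients[1, "g1"] + 0.2^2), 1e-3)
  expect_lt(abs(fit$coefficients[1, "intercept"]), 1e-4)

  const <- gradient_timeseries(cbind(sin(0.1 * 1:100), sin(0.1 * 1:100)))
  expect_error(fit_coupling(const), "collinear")
})

test_that("coupling fit recovers a planted cross term from forced data", {
  freqs <- c(0.12, 0.17, 0.22, 0.27)
  cross <- data.frame(from = 2, to = 1, type = "position", value = 0.012)
  m <- build_coupling_matrix(freqs, rep(0.02, 4), cross, tr_seconds = 2)
  ests <- sapply(1:3, function(s) {
    g <- simulate_gradient_timeseries(m, 8000, forcing_sd = 0.05, seed = s)
    fit_coupling(g)$coefficients[1, "g2"]
  })
  expect_lt(abs(median(ests) - 0.012) / 0.012, 0.1)
})

test_that("eigenmodes match closed forms, ordering, and Hz conversion", {
  m <- coupling_model(matrix(c(0, -0.04, 0), 1), tr_seconds = 1)
  em <- eigenmodes_of(m)
  expect_equal(nrow(em$modes), 1L)
  expect_equal(em$modes$beta, 0.2, tolerance = 1e-12)
  expect_equal(em$modes$alpha, 0, tolerance = 1e-12)

  m2 <- build_coupling_matrix(1, 0.2)
  em2 <- eigenmodes_of(m2)
  expect_equal(em2$modes$alpha, -0.1, tolerance = 1e-10)
  expect_equal(em2$modes$beta, sqrt(0.99), tolerance = 1e-10)

  m3 <- build_coupling_matrix(0.2, 0, tr_seconds = 2)
  em3 <- eigenmodes_of(m3)
  expect_equal(em3$modes$frequency_hz, 0.2 / (2 * pi * 2),
               tolerance = 1e-12)

  # multi-oscillator: modes ordered by ascending frequency
  m4 <- build_coupling_matrix(c(0.3, 0.1, 0.2), rep(0.02, 3))
  em4 <- eigenmodes_of(m4)
  expect_false(is.unsorted(em4$modes$beta))
  expect_equal(em4$modes$beta,
               sort(sqrt(c(0.3, 0.1, 0.2)^2 - 0.0001)), tolerance = 1e-10)
})

test_that("conjugate eigenvalues pair up before reduction", {
  m <- default_coupling_model(4, tr_seconds = 2,
                              calibrate_pairs = list(c(1L, 2L)))
  ev <- eigen(companion_matrix(m))$values
  for (l in ev[Im(ev) > 1e-10]) {
    expect_true(any(abs(ev - Conj(l)) < 1e-10))
  }
})

test_that("defective companion matrices are rejected with diagnostics", {
  # a critically damped oscillator: repeated real eigenvalue, rank-1
  # eigenvector space
  m <- coupling_model(matrix(c(0, -0.01, -0.2), 1), tr_seconds = 1)
  expect_error(eigenmodes_of(m), "condition")
})

test_that("cumulative amplitude follows the mode-sum formula", {
  fake <- structure(list(
    modes = data.frame(mode = 1, alpha = 0, beta = 0.2,
                       frequency_hz = 0.2 / (2 * pi), oscillatory = TRUE),
    components = matrix(c(1 + 0i, 0 + 0i), 2, 1), K = 2, tr_seconds = 1),
    class = "eigenmode_set")
  amp <- cumulative_amplitude(fake)
  expect_equal(unname(amp), c(sqrt(2), 0), tolerance = 1e-12)

  fake$components <- matrix(c(1 + 0i, 0 + 1i), 1, 2)
  fake$modes <- fake$modes[c(1, 1), ]
  fake$K <- 1L
  # two modes with (a,b) = (1,0) and (0,1): sqrt(2) + sqrt(2)
  expect_equal(unname(cumulative_amplitude(fake)), 2 * sqrt(2),
               tolerance = 1e-12)
})

test_that("pair angles use weighted circular means folded into (0, 180]", {
  one_mode <- structure(list(
    modes = data.frame(mode = 1, alpha = 0, beta = 0.2,
                       frequency_hz = 0.2 / (2 * pi), oscillatory = TRUE),
    components = matrix(c(1 + 0i, 0 + 1i), 2, 1), K = 2, tr_seconds = 1),
    class = "eigenmode_set")
  pa <- pair_phase_angle(one_mode)
  expect_equal(pa$angle_deg, 90, tolerance = 1e-10)

  # two modes with identical components: same angle as one
  two_same <- one_mode
  two_same$components <- cbind(one_mode$components, one_mode$components)
  two_same$modes <- one_mode$modes[c(1, 1), ]
  expect_equal(pair_phase_angle(two_same)$angle_deg, 90, tolerance = 1e-10)

  # modes at +80 and +100 degrees with equal weights average to 90
  c80 <- complex(argument = c(0, -80 * pi / 180), modulus = 1)
  c100 <- complex(argument = c(0, -100 * pi / 180), modulus = 1)
  mixed <- one_mode
  mixed$components <- cbind(c80, c100)
  mixed$modes <- one_mode$modes[c(1, 1), ]
  expect_equal(pair_phase_angle(mixed)$angle_deg, 90, tolerance = 1e-10)

  # zero shared weight: NaN, not an error
  disjoint <- one_mode
  disjoint$components <- matrix(c(1 + 0i, 0 + 0i), 2, 1)
  expect_true(is.nan(pair_phase_angle(disjoint)$angle_deg))
})

test_that("mode simulation reproduces analytic envelopes", {
  m <- build_coupling_matrix(0.2, 0)
  g <- simulate_from_model(m, 300, damping_policy = "fitted")
  # constant-amplitude sinusoid at beta: the (cos, sin) pair at 0.2
  # rad/sample captures all of the signal energy
  tt <- 0:299
  y <- g$values[, 1]
  res <- resid(lm(y ~ cos(0.2 * tt) + sin(0.2 * tt)))
  expect_lt(sum(res^2) / sum((y - mean(y))^2), 1e-10)
  amp_first <- max(abs(g$values[1:40, 1]))
  amp_last <- max(abs(g$values[260:300, 1]))
  expect_equal(amp_last / amp_first, 1, tolerance = 0.05)

  # damped mode: amplitude at t = 10 is e^{-1} of initial within 1%
  md <- coupling_model(matrix(c(0, -(0.9^2 + 0.01), -0.2), 1),
                       tr_seconds = 1)
  expect_equal(eigenmodes_of(md)$modes$alpha, -0.1, tolerance = 1e-10)
  gd <- simulate_from_model(md, 60, damping_policy = "fitted")
  env <- sqrt(gd$values[, 1]^2 +
                (finite_difference(gd)$first[, 1] / 0.9)^2)
  # log-envelope regression over interior points averages out the small
  # oscillatory modulation of the envelope estimator
  tt2 <- 5:55
  slope <- coef(lm(log(env[tt2]) ~ tt2))[2]
  expect_equal(unname(slope), -0.1, tolerance = 0.01)
  expect_equal(unname(exp(10 * slope)), exp(-1), tolerance = 0.01)

  # zeroed policy removes decay
  gz <- simulate_from_model(md, 200, damping_policy = "zeroed")
  expect_gt(max(abs(gz$values[150:200, 1])), 0.5 * max(abs(gz$values[1:50, 1])))
})

test_that("fit-then-simulate reproduces a subject's gradient covariance", {
  base <- default_coupling_model(6, tr_seconds = 2)
  g <- simulate_gradient_timeseries(base, 4000, forcing_sd = 0.05, seed = 21)
  fit <- fit_coupling(g)
  w <- estimate_mode_weights(fit, g)
  sim <- simulate_from_model(fit, 3000, damping_policy = "zeroed",
                             mode_weights = w)
  Ce <- cov(g$values); Cs <- cov(sim$values)
  # elementwise agreement of the gradient covariance structure
  expect_gt(cor(Ce[lower.tri(Ce, diag = TRUE)],
                Cs[lower.tri(Cs, diag = TRUE)]), 0.8)
  expect_gt(cor(diag(Ce), diag(Cs)), 0.8)
})

test_that("eigenmode FC differences track amplitude-only manipulations", {
  basis <- generate_gradient_basis(20, 4, seed = 31)
  m <- default_coupling_model(4, tr_seconds = 2,
                              calibrate_pairs = list(c(1L, 2L)))
  fc1 <- eigenmode_fc(m, basis, n_timepoints = 1500)
  expect_equal(unname(diag(fc1)), rep(1, 20))

  # identical models give a zero difference matrix
  both <- eigenmode_fc(list(m, m), basis, n_timepoints = 1500)
  expect_lt(max(abs(both$difference)), 1e-12)
})

test_that("amplitude/angle features correspond to variance/covariance", {
  # small cohort: amplitude and angle jitter only (no atrophy links)
  base <- default_coupling_model(6, tr_seconds = 2)
  link <- link_coefficients(amp_g1_s1 = 0, amp_g2_s3 = 0,
                            angle_g14_s1 = 0, angle_g12_s2 = 0,
                            angle_g12_s3 = 0,
                            amp_jitter_sd = 0.3, angle_jitter_sd = 0.1)
  n <- 40
  subj <- apply_structure_function_link(matrix(0, n, 3), link, base,
                                        forcing_sd = 0.05, seed = 3)
  eig <- dyn <- NULL
  for (i in seq_len(n)) {
    g <- simulate_gradient_timeseries(subj[[i]]$model, 600,
                                      forcing_sd = subj[[i]]$forcing_sd,
                                      seed = 300 + i)
    fit <- fit_coupling(g)
    eig <- rbind(eig, eigenmode_features(eigenmodes_of(fit)))
    dyn <- rbind(dyn, gradient_dynamics_features(g))
  }
  res <- amplitude_angle_correspondence(eig, dyn)
  expect_gt(res$median_corresponding, res$median_noncorresponding)
  expect_equal(dim(res$correlation), c(21L, 21L))

  expect_warning(amplitude_angle_correspondence(eig[1:5, ], dyn[1:5, ]),
                 "fewer than 10")
})
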