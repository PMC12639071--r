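#' Configuration for a synthetic structure-function cohort
#'
#' Collects every knob of the generative model: planted atrophy components,
#' oscillator base dynamics, the links from atrophy scores to oscillator
#' amplitude/phase parameters, observation noise, and the two-scanner batch
#' structure. A fixed seed makes the whole cohort a pure function of the
#' configuration.
#'
#' @param n_subjects number of patients (score-carrying subjects).
#' @param n_normals number of cognitively normal subjects, generated as
#'   score-zero members of the same model.
#' @param n_regions number of brain regions (default 246).
#' @param n_gradients number of gradients K (default 6).
#' @param n_timepoints samples per scan (default 400).
#' @param tr_seconds sampling interval (default 2).
#' @param atrophy_patterns optional region x 3 matrix of unit-norm planted
#'   atrophy components (component 1 unipolar); generated from the seed when
#'   omitted.
#' @param severity_mean,severity_sd length-3 mean and SD of the patients'
#'   component score distributions. Defaults centre component 1 at 0.8
#'   (patients atrophied on average) with spreads decreasing over
#'   components, so component 1 dominates the atrophy variance.
#' @param atrophy_scale multiplier applied to the planted component mix
#'   when building atrophy maps. Component scores stay on a unit scale
#'   (they parameterize the oscillator links); the patterns are unit-norm,
#'   so this factor carries the W-score units and sets how strongly the
#'   peak regions atrophy (default 8, giving peak W-scores of 2-3 in
#'   severely affected subjects).
#' @param link link coefficients, see [link_coefficients()].
#' @param noise_sds named list: `atrophy` (regional atrophy noise SD),
#'   `bold` (regional BOLD noise SD).
#' @param forcing_sd baseline per-step oscillator forcing SD.
#' @param batch_probs named probabilities of scanner assignment.
#' @param batch_shift,batch_scale per-batch additive/multiplicative effects
#'   applied to the atrophy features (same order as `batch_probs`).
#' @param seed integer master seed.
#'
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects, n_normals = 0L, n_regions = 246L,
                          n_gradients = 6L, n_timepoints = 400L,
                          tr_seconds = 2,
                          atrophy_patterns = NULL,
                          severity_mean = c(0.8, 0, 0),
                          severity_sd = c(1.2, 1, 0.8),
                          atrophy_scale = 8,
                          link = link_coefficients(),
                          noise_sds = list(atrophy = 0.1, bold = 0.1),
                          forcing_sd = 0.05,
                          batch_probs = c(trio = 0.5, prisma = 0.5),
                          batch_shift = c(trio = 0, prisma = 0.3),
                          batch_scale = c(trio = 1, prisma = 1.15),
                          seed = 1L) {
  stopifnot(n_subjects >= 1, n_normals >= 0,
            n_gradients >= 2, n_gradients <= n_regions,
            length(severity_mean) == 3L, length(severity_sd) == 3L,
            all(severity_sd >= 0), all(unlist(noise_sds) >= 0),
            forcing_sd >= 0, atrophy_scale > 0,
            abs(sum(batch_probs) - 1) < 1e-8)
  if (!is.null(atrophy_patterns)) {
    atrophy_patterns <- check_matrix(atrophy_patterns)
    stopifnot(nrow(atrophy_patterns) == n_regions,
              ncol(atrophy_patterns) == 3L)
    nrm <- sqrt(colSums(atrophy_patterns^2))
    if (max(abs(nrm - 1)) > 1e-6)
      stop("atrophy patterns must be unit-normalized", call. = FALSE)
  }
  structure(list(
    n_subjects = as.integer(n_subjects), n_normals = as.integer(n_normals),
    n_regions = as.integer(n_regions), n_gradients = as.integer(n_gradients),
    n_timepoints = as.integer(n_timepoints), tr_seconds = tr_seconds,
    atrophy_patterns = atrophy_patterns,
    severity_mean = severity_mean, severity_sd = severity_sd,
    atrophy_scale = atrophy_scale,
    link = link, noise_sds = noise_sds, forcing_sd = forcing_sd,
    batch_probs = batch_probs, batch_shift = batch_shift,
    batch_scale = batch_scale, seed = as.integer(seed)
  ), class = "cohort_config")
}

#' Link coefficients from atrophy scores to oscillator parameters
#'
#' Encodes how planted atrophy component scores shift the oscillator
#' parameters of each subject: higher overall atrophy (s1) multiplies the
#' gradient-1 forcing amplitude by `exp(-amp_g1_s1 * s1)` and lowers the
#' gradient 1-4 phase-angle target by `angle_g14_s1` degrees per unit s1;
#' s2 and s3 move the gradient 1-2 angle target in opposite directions, and
#' s3 raises the gradient-2 amplitude. Per-subject lognormal amplitude
#' jitter (all gradients) and Gaussian stiffness jitter (all pairs) give
#' every amplitude and angle idiosyncratic variation.
#'
#' @param amp_g1_s1 amplitude-reduction rate for gradient 1 per unit s1.
#' @param amp_g2_s3 amplitude-increase rate for gradient 2 per unit s3.
#' @param angle_g14_s1 degrees subtracted from the gradient 1-4 angle per
#'   unit s1.
#' @param angle_g12_s2,angle_g12_s3 degrees added/subtracted to the
#'   gradient 1-2 angle per unit s2 / s3.
#' @param amp_jitter_sd SD of log amplitude multipliers (all gradients).
#' @param angle_jitter_sd SD of random stiffness perturbations, as a
#'   fraction of omega_i * omega_j, applied to every gradient pair.
#' @return A list of class `link_coefficients`.
#' @export
link_coefficients <- function(amp_g1_s1 = 0.35, amp_g2_s3 = 0.25,
                              angle_g14_s1 = 15, angle_g12_s2 = 10,
                              angle_g12_s3 = 10,
                              amp_jitter_sd = 0.2, angle_jitter_sd = 0.08) {
  structure(list(amp_g1_s1 = amp_g1_s1, amp_g2_s3 = amp_g2_s3,
                 angle_g14_s1 = angle_g14_s1, angle_g12_s2 = angle_g12_s2,
                 angle_g12_s3 = angle_g12_s3,
                 amp_jitter_sd = amp_jitter_sd,
                 angle_jitter_sd = angle_jitter_sd),
            class = "link_coefficients")
}

#' Default base oscillator model for synthetic cohorts
#'
#' K damped oscillators with distinct natural frequencies spanning the slow
#' BOLD band, antisymmetric velocity (gyroscopic) coupling between all
#' pairs so that every gradient participates in every mode, and baseline
#' symmetric stiffness on the linked pairs calibrated by grid search to a
#' target measured phase angle. The gradient 1-4 baseline sits at 90
#' degrees (temporal orthogonality); pairs whose target is `NA` are
#' calibrated to the midpoint of their achievable angle range, which for
#' strongly mixed adjacent-frequency pairs lies below 90 degrees.
#'
#' @param K number of gradients.
#' @param tr_seconds sampling interval.
#' @param frequencies optional natural frequencies (rad/sample).
#' @param dampings optional damping coefficients.
#' @param gyro antisymmetric velocity coupling strength.
#' @param calibrate_pairs list of gradient index pairs whose baseline angle
#'   is calibrated.
#' @param target_deg baseline angle targets in degrees, recycled over
#'   `calibrate_pairs`; `NA` calibrates to the midpoint of the achievable
#'   range.
#' @return A [coupling_model()].
#' @export
default_coupling_model <- function(K = 6L, tr_seconds = 2,
                                   frequencies = NULL, dampings = NULL,
                                   gyro = 0.04,
                                   calibrate_pairs = list(c(1L, 4L),
                                                          c(1L, 2L)),
                                   target_deg = c(90, NA)) {
  frequencies <- frequencies %||% seq(0.15, 0.30, length.out = K)
  dampings <- dampings %||% rep(0.06, K)
  idx <- pair_index(K)
  cc <- data.frame(
    from = c(idx[, 2L], idx[, 1L]),
    to = c(idx[, 1L], idx[, 2L]),
    type = "velocity",
    value = c(rep(gyro, nrow(idx)), rep(-gyro, nrow(idx)))
  )
  base <- build_coupling_matrix(frequencies, dampings, cc,
                                tr_seconds = tr_seconds)
  if (length(calibrate_pairs) == 0L) return(base)
  target_deg <- rep_len(target_deg, length(calibrate_pairs))
  # calibrating one pair perturbs the others slightly; a few rounds converge
  for (round in 1:3) {
    for (p in seq_along(calibrate_pairs)) {
      pr <- calibrate_pairs[[p]]
      cal <- calibrate_pair_angle(base, pr[1L], pr[2L])
      tgt <- if (is.na(target_deg[p]))
        (min(cal$angle_deg) + max(cal$angle_deg)) / 2 else target_deg[p]
      b <- lookup_angle_stiffness(cal, tgt)
      base <- add_pair_stiffness(base, pr[1L], pr[2L], b)
    }
  }
  base
}

#' Add symmetric stiffness coupling between two gradients
#'
#' Adds `value * G_j` to the equation for `G_i''` and `value * G_i` to the
#' equation for `G_j''`; only those two coefficient entries change.
#'
#' @param model a [coupling_model()].
#' @param i,j gradient indices.
#' @param value stiffness coefficient.
#' @return The modified [coupling_model()].
#' @export
add_pair_stiffness <- function(model, i, j, value) {
  stopifnot(inherits(model, "coupling_model"))
  B <- model$coefficients
  B[i, 1L + j] <- B[i, 1L + j] + value
  B[j, 1L + i] <- B[j, 1L + i] + value
  coupling_model(B, tr_seconds = model$tr_seconds)
}

#' Calibration curve from pair stiffness to measured phase angle
#'
#' Numerically maps symmetric stiffness values to the eigenmode phase angle
#' measured by [pair_phase_angle()], by evaluating a grid of stiffness
#' perturbations of the base model. The returned table is restricted to the
#' maximal strictly monotone stretch around zero stiffness, so inverse
#' lookups are well defined.
#'
#' @param model base [coupling_model()].
#' @param i,j gradient pair.
#' @param span grid half-width as a fraction of `omega_i * omega_j`.
#' @param n_grid number of grid points.
#' @return Data frame with columns `stiffness`, `angle_deg`.
#' @export
calibrate_pair_angle <- function(model, i, j, span = 0.9, n_grid = 61L) {
  stopifnot(inherits(model, "coupling_model"))
  wi <- sqrt(abs(model$coefficients[i, 1L + i]))
  wj <- sqrt(abs(model$coefficients[j, 1L + j]))
  grid <- seq(-span, span, length.out = n_grid) * wi * wj
  ang <- vapply(grid, function(b) {
    m <- add_pair_stiffness(model, i, j, b)
    A <- companion_matrix(m)
    if (max(Re(eigen(A, only.values = TRUE)$values)) > 1e-8)
      return(NA_real_)  # destabilizing stiffness: outside usable range
    pa <- pair_phase_angle(eigenmodes_of(m))
    pa$angle_deg[pa$g1 == min(i, j) & pa$g2 == max(i, j)]
  }, numeric(1L))
  ok <- is.finite(ang)
  grid <- grid[ok]; ang <- ang[ok]
  # keep the maximal monotone run containing stiffness 0
  dir <- sign(diff(ang))
  mono <- dir == dir[which.min(abs(grid))[1L]] & dir != 0
  z <- which.min(abs(grid))
  lo <- z; while (lo > 1L && mono[lo - 1L]) lo <- lo - 1L
  hi <- z; while (hi < length(grid) && mono[hi]) hi <- hi + 1L
  data.frame(stiffness = grid[lo:hi], angle_deg = ang[lo:hi])
}

#' Invert an angle calibration curve
#'
#' Linear interpolation of the calibration table; targets outside the
#' achievable range are clamped to the nearest endpoint. Targets outside
#' (0, 180) degrees are rejected.
#'
#' @param calibration data frame from [calibrate_pair_angle()].
#' @param target_deg desired measured angle in degrees.
#' @return Stiffness value.
#' @export
lookup_angle_stiffness <- function(calibration, target_deg) {
  if (!is.finite(target_deg) || target_deg <= 0 || target_deg >= 180)
    stop("angle target must lie strictly inside (0, 180) degrees",
         call. = FALSE)
  a <- calibration$angle_deg; s <- calibration$stiffness
  o <- order(a)
  target <- min(max(target_deg, min(a)), max(a))
  stats::approx(a[o], s[o], xout = target, ties = mean)$y
}

#' Generate planted atrophy patterns
#'
#' Three unit-norm, mutually orthogonal regional patterns: component 1 is
#' unipolar (overall mean atrophy), components 2 and 3 are bipolar
#' (syndrome-contrast patterns).
#'
#' @param n_regions number of regions.
#' @param seed integer seed.
#' @return region x 3 matrix with unit-norm columns.
#' @export
generate_atrophy_patterns <- function(n_regions, seed = NULL) {
  b <- generate_gradient_basis(n_regions, 3L, seed = seed)
  unname(b$vectors)
}

#' Generate a cohort of atrophy maps from planted components
#'
#' Subject i's atrophy map is `atrophy_scale * sum_k s_ik pattern_k +
#' noise`; patients draw scores from the configured severity distributions
#' and cognitively normal subjects have all scores exactly zero, placing
#' them at the centre of the spectrum.
#'
#' @param config a [cohort_config()].
#' @return List with `atrophy` (subject x region matrix), `scores`
#'   (subject x 3 true component scores), `patterns` (region x 3), `group`
#'   (factor patient/normal), `batch` (factor scanner label).
#' @export
generate_atrophy_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  with_seed(child_seed(config$seed, 101L), {
    patterns <- config$atrophy_patterns %||%
      generate_atrophy_patterns(config$n_regions,
                                seed = child_seed(config$seed, 7L))
    n_pat <- config$n_subjects; n_all <- n_pat + config$n_normals
    scores <- matrix(0, n_all, 3L,
                     dimnames = list(NULL, paste0("s", 1:3)))
    for (k in 1:3)
      scores[seq_len(n_pat), k] <- rnorm(n_pat, config$severity_mean[k],
                                         config$severity_sd[k])
    atrophy <- config$atrophy_scale * scores %*% t(patterns)
    if (config$noise_sds$atrophy > 0)
      atrophy <- atrophy + matrix(rnorm(length(atrophy), 0,
                                        config$noise_sds$atrophy),
                                  n_all, config$n_regions)
    colnames(atrophy) <- paste0("r", seq_len(config$n_regions))
    rownames(atrophy) <- sprintf("sub%03d", seq_len(n_all))
    batch <- factor(sample(names(config$batch_probs), n_all, replace = TRUE,
                           prob = config$batch_probs),
                    levels = names(config$batch_probs))
    list(atrophy = atrophy, scores = scores, patterns = patterns,
         group = factor(rep(c("patient", "normal"),
                            c(n_pat, config$n_normals))),
         batch = batch)
  })
}

#' Subject-specific oscillator models from atrophy scores
#'
#' Applies the structure-function link: each subject's component scores set
#' per-gradient forcing amplitude multipliers and phase-angle targets for
#' the linked gradient pairs (hit by inverting a numeric calibration curve
#' of stiffness versus measured angle), plus optional per-subject jitter on
#' all amplitudes and pair stiffnesses. With all scores zero and jitter
#' disabled the base model is returned unchanged.
#'
#' @param scores subject x 3 matrix of atrophy component scores.
#' @param link a [link_coefficients()].
#' @param base_model base [coupling_model()] (angles of the linked pairs
#'   should sit at their zero-atrophy baseline, see
#'   [default_coupling_model()]).
#' @param forcing_sd baseline forcing SD (scalar).
#' @param seed seed for the per-subject jitter.
#'
#' @return List per subject: `model` (a [coupling_model()]), `forcing_sd`
#'   (length-K vector), `angle_targets` (named vector, degrees).
#' @export
apply_structure_function_link <- function(scores, link, base_model,
                                          forcing_sd = 0.05, seed = NULL) {
  stopifnot(inherits(link, "link_coefficients"),
            inherits(base_model, "coupling_model"))
  scores <- as.matrix(scores)
  stopifnot(ncol(scores) == 3L)
  K <- base_model$K
  base_pa <- pair_phase_angle(eigenmodes_of(base_model))
  base_angle <- function(i, j)
    base_pa$angle_deg[base_pa$g1 == i & base_pa$g2 == j]
  cal14 <- calibrate_pair_angle(base_model, 1L, 4L)
  cal12 <- calibrate_pair_angle(base_model, 1L, 2L)
  idx <- pair_index(K)
  omega <- sqrt(abs(diag(base_model$coefficients[, 2L:(K + 1L)])))
  n <- nrow(scores)
  with_seed(seed, {
    amp_jit <- matrix(rnorm(n * K, 0, link$amp_jitter_sd), n, K)
    stiff_jit <- matrix(rnorm(n * nrow(idx), 0, link$angle_jitter_sd),
                        n, nrow(idx))
    lapply(seq_len(n), function(i) {
      s <- scores[i, ]
      t14 <- clamp_angle(base_angle(1L, 4L) - link$angle_g14_s1 * s[1L])
      t12 <- clamp_angle(base_angle(1L, 2L) + link$angle_g12_s2 * s[2L] -
                           link$angle_g12_s3 * s[3L])
      b14 <- lookup_angle_stiffness(cal14, t14)
      b12 <- lookup_angle_stiffness(cal12, t12)
      # the two targeted terms are calibrated in isolation; jointly they
      # can destabilize the system, so shrink both until stable
      repeat {
        m <- base_model
        if (abs(b14) > 0) m <- add_pair_stiffness(m, 1L, 4L, b14)
        if (abs(b12) > 0) m <- add_pair_stiffness(m, 1L, 2L, b12)
        stable <- max(Re(eigen(companion_matrix(m),
                               only.values = TRUE)$values)) <= 1e-8
        if (stable || (abs(b14) < 1e-12 && abs(b12) < 1e-12)) break
        b14 <- b14 * 0.7; b12 <- b12 * 0.7
      }
      if (link$angle_jitter_sd > 0) {
        # jitter can destabilize the system; shrink it until stable
        shrink <- 1
        repeat {
          mj <- m
          for (r in seq_len(nrow(idx))) {
            mj <- add_pair_stiffness(mj, idx[r, 1L], idx[r, 2L],
                                     shrink * stiff_jit[i, r] *
                                       omega[idx[r, 1L]] *
                                       omega[idx[r, 2L]])
          }
          Aj <- companion_matrix(mj)
          if (max(Re(eigen(Aj, only.values = TRUE)$values)) <= 1e-8) {
            m <- mj; break
          }
          shrink <- shrink / 2
          if (shrink < 1 / 64) break
        }
      }
      fs <- rep(forcing_sd, K)
      fs[1L] <- fs[1L] * exp(-link$amp_g1_s1 * s[1L])
      fs[2L] <- fs[2L] * exp(link$amp_g2_s3 * s[3L])
      if (link$amp_jitter_sd > 0) fs <- fs * exp(amp_jit[i, ])
      list(model = m, forcing_sd = fs,
           angle_targets = c(`g1-g4` = t14, `g1-g2` = t12))
    })
  })
}

clamp_angle <- function(x, lo = 5, hi = 175) min(max(x, lo), hi)

#' Generate cognitive test scores from component scores
#'
#' Each test is a linear combination of the supplied predictors (for
#' example S1..S3, F1..F3) plus optional quadratic terms and Gaussian
#' noise; a missing-data mask can be applied per test.
#'
#' @param scores data frame or matrix of predictor columns.
#' @param test_specs named list; each element is a list with `coef` (named
#'   numeric vector over predictor columns), optional `quadratic` (named
#'   numeric vector; coefficient on the squared, centered predictor),
#'   optional `missing_rate`.
#' @param noise_sd Gaussian noise SD added to every test.
#' @param seed integer seed.
#' @return Data frame of test columns (NA where masked).
#' @export
generate_cognition <- function(scores, test_specs, noise_sd = 0.5,
                               seed = NULL) {
  S <- as.data.frame(scores)
  n <- nrow(S)
  with_seed(seed, {
    out <- lapply(names(test_specs), function(nm) {
      spec <- test_specs[[nm]]
      bad <- setdiff(c(names(spec$coef), names(spec$quadratic)),
                     names(S))
      if (length(bad) > 0L)
        stop_dims("unknown predictor(s) in test '%s': %s", nm,
                  paste(bad, collapse = ", "))
      y <- rep(0, n)
      for (p in names(spec$coef)) y <- y + spec$coef[[p]] * S[[p]]
      for (p in names(spec$quadratic))
        y <- y + spec$quadratic[[p]] * (S[[p]] - mean(S[[p]]))^2
      y <- y + rnorm(n, 0, noise_sd)
      mr <- spec$missing_rate %||% 0
      if (mr > 0) y[runif(n) < mr] <- NA_real_
      y
    })
    names(out) <- names(test_specs)
    as.data.frame(out)
  })
}

#' Generate a normative reference cohort
#'
#' Regional volumes are exact linear functions of the covariates (age, sex,
#' total intracranial volume proxy by default) plus Gaussian residuals with
#' known per-region SD — the data-generating process assumed by the
#' normative W-score model.
#'
#' @param n number of subjects (>= 30).
#' @param n_regions number of regions.
#' @param region_effects optional list with `coefficients`
#'   ((p + 1) x region matrix, intercept row first) and `residual_sd`
#'   (length n_regions); generated from the seed when omitted.
#' @param seed integer seed.
#' @return List with `volumes` (n x region), `covariates` (data frame with
#'   age, sex, tiv), `region_effects` (the generating coefficients).
#' @export
generate_normative_reference <- function(n, n_regions = 246L,
                                         region_effects = NULL,
                                         seed = NULL) {
  if (n < 30L) stop("normative cohorts need n >= 30", call. = FALSE)
  with_seed(seed, {
    covs <- data.frame(
      age = runif(n, 45, 85),
      sex = rbinom(n, 1L, 0.5),
      tiv = rnorm(n, 1500, 120)
    )
    if (is.null(region_effects)) {
      region_effects <- list(
        coefficients = rbind(
          intercept = runif(n_regions, 4, 8),
          age = runif(n_regions, -0.04, -0.01),
          sex = runif(n_regions, -0.3, 0.3),
          tiv = runif(n_regions, 0.0005, 0.002)
        ),
        residual_sd = runif(n_regions, 0.2, 0.6)
      )
    }
    D <- cbind(1, as.matrix(covs))
    vol <- D %*% region_effects$coefficients
    if (any(region_effects$residual_sd > 0))
      vol <- vol + matrix(rnorm(length(vol), 0,
                                rep(region_effects$residual_sd,
                                    each = n)),
                          n, n_regions)
    colnames(vol) <- paste0("r", seq_len(n_regions))
    list(volumes = vol, covariates = covs,
         region_effects = region_effects)
  })
}

#' Simulate a complete synthetic cohort
#'
#' End-to-end generator: planted atrophy maps, subject-specific oscillator
#' models via the structure-function link, simulated gradient timeseries,
#' rendered regional BOLD scans, and scanner batch effects on the atrophy
#' features. The returned ground truth carries everything downstream stages
#' are expected to recover.
#'
#' @param config a [cohort_config()].
#' @param basis optional [gradient_basis()]; generated from the seed when
#'   omitted.
#' @param base_model optional base [coupling_model()]; defaults to
#'   [default_coupling_model()].
#' @param simulate_bold render regional scans (set FALSE to keep only
#'   gradient timeseries, which is cheaper).
#'
#' @return List with `atrophy` (subject x region, batch effects applied),
#'   `scans` (list of [regional_timeseries()] or NULL), `gradient_ts`
#'   (list of [gradient_timeseries()]), `batch`, `group`, and
#'   `ground_truth` (scores, patterns, basis, base_model, subject_models,
#'   angle targets).
#' @export
simulate_cohort <- function(config, basis = NULL, base_model = NULL,
                            simulate_bold = TRUE) {
  stopifnot(inherits(config, "cohort_config"))
  basis <- basis %||% generate_gradient_basis(config$n_regions,
                                              config$n_gradients,
                                              seed = child_seed(config$seed,
                                                                11L))
  base_model <- base_model %||%
    default_coupling_model(config$n_gradients,
                           tr_seconds = config$tr_seconds)
  co <- generate_atrophy_cohort(config)
  subj <- apply_structure_function_link(
    co$scores, config$link, base_model,
    forcing_sd = config$forcing_sd,
    seed = child_seed(config$seed, 23L))
  n_all <- nrow(co$scores)
  gts <- vector("list", n_all)
  scans <- if (simulate_bold) vector("list", n_all) else NULL
  for (i in seq_len(n_all)) {
    gts[[i]] <- simulate_gradient_timeseries(
      subj[[i]]$model, config$n_timepoints,
      forcing_sd = subj[[i]]$forcing_sd,
      seed = child_seed(config$seed, 1000L + i))
    if (simulate_bold)
      scans[[i]] <- render_bold(gts[[i]], basis,
                                region_noise_sd = config$noise_sds$bold,
                                seed = child_seed(config$seed, 5000L + i))
  }
  atrophy <- co$atrophy
  for (b in names(config$batch_probs)) {
    i <- which(co$batch == b)
    atrophy[i, ] <- atrophy[i, ] * config$batch_scale[[b]] +
      config$batch_shift[[b]]
  }
  list(atrophy = atrophy, scans = scans, gradient_ts = gts,
       batch = co$batch, group = co$group,
       ground_truth = list(scores = co$scores, patterns = co$patterns,
                           basis = basis, base_model = base_model,
                           subject_models = subj,
                           atrophy_clean = co$atrophy))
}
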