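#' Finite differences with the standard numerical gradient stencil
#'
#' Central differences in the interior, one-sided at the ends (unit sample
#' step). Applying it twice yields the second derivative used by
#' [fit_coupling()].
#'
#' @param gts a [gradient_timeseries()] or a numeric matrix (time x series).
#' @return A list with `first` and `second` derivative matrices of the same
#'   dimension as the input values.
#' @export
finite_difference <- function(gts) {
  X <- if (inherits(gts, "gradient_timeseries")) gts$values else
    check_matrix(gts)
  if (nrow(X) < 3L)
    stop("at least 3 timepoints are required for finite differences",
         call. = FALSE)
  d1 <- apply(X, 2L, pracma::gradient)
  d2 <- apply(d1, 2L, pracma::gradient)
  list(first = d1, second = d2)
}

#' Fit the coupled-oscillator model to gradient timeseries
#'
#' For each gradient, ordinary least squares estimates its second derivative
#' (by finite differencing) as a linear function of all K gradients' levels
#' and first derivatives, plus an intercept: K independent regressions with
#' 2K + 1 coefficients each.
#'
#' @param gts a [gradient_timeseries()].
#' @return A [coupling_model()] with per-equation R^2 in `$r_squared`.
#' @export
fit_coupling <- function(gts) {
  stopifnot(inherits(gts, "gradient_timeseries"))
  G <- gts$values
  K <- ncol(G)
  if (nrow(G) <= 2L * K + 1L)
    stop("need more timepoints than coefficients (2K + 1)", call. = FALSE)
  d <- finite_difference(gts)
  Xmat <- cbind(1, G, d$first)
  qrX <- qr(Xmat)
  if (qrX$rank < ncol(Xmat)) {
    keep <- qrX$pivot[seq_len(qrX$rank)]
    bad <- setdiff(seq_len(ncol(Xmat)), keep)
    labels <- c("intercept", paste0("g", seq_len(K)),
                paste0("dg", seq_len(K)))
    stop_dims("collinear regressors in coupling fit: %s",
              paste(labels[bad], collapse = ", "))
  }
  coefs <- matrix(0, K, 2L * K + 1L)
  r2 <- numeric(K)
  for (g in seq_len(K)) {
    y <- d$second[, g]
    beta <- qr.coef(qrX, y)
    coefs[g, ] <- beta
    res <- y - Xmat %*% beta
    r2[g] <- 1 - sum(res^2) / sum((y - mean(y))^2)
  }
  coupling_model(coefs, tr_seconds = gts$tr_seconds, r_squared = r2)
}

#' Eigenmode decomposition of a coupling model
#'
#' Eigendecomposes the 2K x 2K companion matrix. Complex eigenvalues come in
#' conjugate pairs; one representative per pair is kept (the member with
#' positive imaginary part), giving up to K oscillatory modes ordered by
#' ascending angular frequency. Each mode carries: `alpha` (damping, per
#' sample), `beta` (angular frequency, rad per sample), `frequency_hz`
#' (= beta / (2 pi TR)), and the complex per-gradient components `a + ib`
#' read from the position block of the eigenvector. Real eigenvalues yield
#' zero-frequency (non-oscillatory) modes, which are retained and flagged
#' via `oscillatory = FALSE`; they are excluded from phase-angle statistics.
#'
#' @param model a [coupling_model()].
#' @return An object of class `eigenmode_set`: a list with `modes` (a data
#'   frame of alpha, beta, frequency_hz, oscillatory), `components` (complex
#'   K x n_modes matrix: gradient components per mode), `K`, `tr_seconds`.
#' @export
eigenmodes_of <- function(model) {
  stopifnot(inherits(model, "coupling_model"))
  K <- model$K
  A <- companion_matrix(model)
  e <- eigen(A)
  kap <- cond_complex(e$vectors)
  if (!is.finite(kap) || kap > 1e8)
    stop(sprintf(paste0(
      "defective or near-defective companion matrix: eigenvector condition ",
      "number %.3g (repeated eigenvalues give deficient eigenvectors)"), kap),
      call. = FALSE)
  tol <- 1e-10 * max(1, max(abs(e$values)))
  osc <- which(Im(e$values) > tol)
  real_ev <- which(abs(Im(e$values)) <= tol)
  idx <- c(osc, real_ev)
  beta <- ifelse(abs(Im(e$values[idx])) <= tol, 0, Im(e$values[idx]))
  ord <- order(beta)
  idx <- idx[ord]; beta <- beta[ord]
  comp <- e$vectors[seq_len(K), idx, drop = FALSE]
  modes <- data.frame(
    mode = seq_along(idx),
    alpha = Re(e$values[idx]),
    beta = beta,
    frequency_hz = beta / (2 * pi * model$tr_seconds),
    oscillatory = beta > 0
  )
  structure(list(modes = modes, components = comp, K = K,
                 tr_seconds = model$tr_seconds),
            class = "eigenmode_set")
}

#' @export
print.eigenmode_set <- function(x, ...) {
  cat(sprintf("<eigenmode_set> %d modes over %d gradients\n",
              nrow(x$modes), x$K))
  print(x$modes, row.names = FALSE)
  invisible(x)
}

#' Cumulative gradient amplitude across eigenmodes
#'
#' For each gradient, sums `sqrt((-a + b)^2 + (a + b)^2)` over modes, where
#' `a + ib` is the gradient's complex component on the mode. The summand
#' equals `sqrt(2) * |a + ib|`, so the cumulative amplitude is proportional
#' to the gradient's total participation across modes.
#'
#' @param modes an `eigenmode_set` from [eigenmodes_of()].
#' @return Numeric vector of length K (non-negative).
#' @export
cumulative_amplitude <- function(modes) {
  stopifnot(inherits(modes, "eigenmode_set"))
  if (nrow(modes$modes) == 0L) stop("no modes present", call. = FALSE)
  a <- Re(modes$components); b <- Im(modes$components)
  amp <- rowSums(sqrt((-a + b)^2 + (a + b)^2))
  setNames(amp, paste0("g", seq_len(modes$K)))
}

#' Weighted circular mean phase angle between gradient pairs
#'
#' On each oscillatory mode, the phase difference between gradients g and h
#' is the difference of the arguments of their complex components; the
#' cumulative pair angle is the circular mean of these differences across
#' modes, weighted per mode by the product of the two gradients' amplitudes
#' (moduli) on that mode. The signed circular mean is folded to a magnitude
#' in (0, 180] degrees, since 90 degrees represents temporal orthogonality
#' and the direction of rotation is not interpreted. Pairs with zero total
#' weight get `NaN` (flagged, not an error). Non-oscillatory modes are
#' excluded.
#'
#' @param modes an `eigenmode_set` from [eigenmodes_of()].
#' @return A data frame with columns `g1`, `g2`, `pair`, `angle_deg`,
#'   `total_weight`, one row per gradient pair (i < j, row-major order).
#' @export
pair_phase_angle <- function(modes) {
  stopifnot(inherits(modes, "eigenmode_set"))
  K <- modes$K
  osc <- which(modes$modes$oscillatory)
  idx <- pair_index(K)
  out <- data.frame(g1 = idx[, 1L], g2 = idx[, 2L],
                    pair = pair_names(K),
                    angle_deg = NA_real_, total_weight = 0)
  comp <- modes$components
  for (r in seq_len(nrow(idx))) {
    i <- idx[r, 1L]; j <- idx[r, 2L]
    if (length(osc) == 0L) { out$angle_deg[r] <- NaN; next }
    dang <- Arg(comp[i, osc]) - Arg(comp[j, osc])
    w <- Mod(comp[i, osc]) * Mod(comp[j, osc])
    tw <- sum(w)
    out$total_weight[r] <- tw
    out$angle_deg[r] <- if (tw == 0) NaN else
      abs(rad2deg(atan2(sum(w * sin(dang)), sum(w * cos(dang)))))
  }
  out
}

#' Summarize an eigenmode set into amplitudes and pair angles
#'
#' @param modes an `eigenmode_set`.
#' @return List with `amplitude` (length-K vector from
#'   [cumulative_amplitude()]) and `angles` (data frame from
#'   [pair_phase_angle()]).
#' @export
eigenmode_summary <- function(modes) {
  list(amplitude = cumulative_amplitude(modes),
       angles = pair_phase_angle(modes))
}

#' Simulate gradient timeseries from eigenmodes
#'
#' Reconstructs trajectories as the analytic superposition of eigenmodes:
#' `Y(t) = Re(V exp(Lambda t) k)`, with the constants `k` solved from the
#' initial conditions by a linear system against the eigenvectors at t = 0.
#' By default every mode receives unit weight (`k = 1` on each member of
#' each conjugate pair), superposing all modes with equal energy. Under the
#' `"zeroed"` damping policy the real parts of the eigenvalues are set to
#' zero before simulation, so modes neither decay nor grow and long-horizon
#' covariance is non-degenerate; `"fitted"` keeps the estimated dampings.
#'
#' @param model a [coupling_model()] (its companion matrix is
#'   eigendecomposed internally).
#' @param n_timepoints number of samples.
#' @param damping_policy `"zeroed"` (default) or `"fitted"`.
#' @param init optional length-2K initial state (positions then velocities);
#'   when supplied, `k = V^{-1} init`.
#' @param mode_weights optional length-2K non-negative weights setting each
#'   mode's constant `|k|` directly (e.g. from [estimate_mode_weights()]),
#'   so the simulated covariance reflects the empirical excitation of each
#'   mode. Overrides `init`.
#'
#' @return A [gradient_timeseries()] with attribute `damping_policy`.
#' @export
simulate_from_model <- function(model, n_timepoints,
                                damping_policy = c("zeroed", "fitted"),
                                init = NULL, mode_weights = NULL) {
  stopifnot(inherits(model, "coupling_model"), n_timepoints >= 1)
  damping_policy <- match.arg(damping_policy)
  K <- model$K
  A <- companion_matrix(model)
  e <- eigen(A)
  if (!is.finite(cond_complex(e$vectors)) ||
      cond_complex(e$vectors) > 1e8)
    stop("ill-conditioned eigenvector matrix; modes are not well separated",
         call. = FALSE)
  lambda <- e$values
  if (damping_policy == "zeroed") lambda <- complex(real = 0,
                                                    imaginary = Im(lambda))
  k <- if (!is.null(mode_weights)) {
    stopifnot(length(mode_weights) == 2L * K, all(mode_weights >= 0))
    as.complex(mode_weights)
  } else if (is.null(init)) rep(1 + 0i, 2L * K) else {
    stopifnot(length(init) == 2L * K)
    solve(e$vectors, as.complex(init))
  }
  tt <- seq_len(n_timepoints) - 1
  # (2K x T) mode activations
  act <- exp(outer(lambda, tt)) * k
  Y <- Re(e$vectors[seq_len(K), , drop = FALSE] %*% act)
  gts <- gradient_timeseries(t(Y), tr_seconds = model$tr_seconds)
  attr(gts, "damping_policy") <- damping_policy
  gts
}

#' Estimate per-mode excitation weights from observed gradient timeseries
#'
#' Projects the observed state (gradient levels and finite-difference
#' velocities) onto the eigenvector basis of the model's companion matrix
#' and returns the root-mean-square modulus of each modal coordinate. Used
#' as `mode_weights` in [simulate_from_model()], these weights make the
#' simulated gradient covariance mirror how strongly each mode is excited
#' in the data.
#'
#' @param model a [coupling_model()].
#' @param gts the observed [gradient_timeseries()] the model was fitted to.
#' @return Numeric vector of length 2K (one weight per eigenvalue).
#' @export
estimate_mode_weights <- function(model, gts) {
  stopifnot(inherits(model, "coupling_model"),
            inherits(gts, "gradient_timeseries"))
  A <- companion_matrix(model)
  e <- eigen(A)
  d <- finite_difference(gts)
  state <- cbind(gts$values, d$first)
  z <- solve(e$vectors, t(state))
  sqrt(rowMeans(Mod(z)^2))
}

#' Eigenmode-based functional connectivity
#'
#' Simulates gradient timeseries from a coupling model (via
#' [simulate_from_model()]), renders regional BOLD through a gradient basis,
#' and computes the Pearson FC matrix. When two models are supplied (e.g.
#' fitted to a low- and a high-atrophy group), the FC difference matrix
#' (second minus first) is also returned.
#'
#' @param model a [coupling_model()] or list of two coupling models.
#' @param basis a [gradient_basis()] whose column count matches K.
#' @param n_timepoints simulation length (default 2000).
#' @param damping_policy passed to [simulate_from_model()].
#' @param gts optional observed [gradient_timeseries()] (or list of two,
#'   matching `model`) used to weight mode excitation via
#'   [estimate_mode_weights()].
#'
#' @return For one model, a region x region FC matrix; for two, a list with
#'   `fc` (list of both matrices) and `difference`.
#' @export
eigenmode_fc <- function(model, basis, n_timepoints = 2000,
                         damping_policy = "zeroed", gts = NULL) {
  one <- function(m, g) {
    w <- if (is.null(g)) NULL else estimate_mode_weights(m, g)
    sim <- simulate_from_model(m, n_timepoints,
                               damping_policy = damping_policy,
                               mode_weights = w)
    cor(render_bold(sim, basis)$values)
  }
  if (inherits(model, "coupling_model")) return(one(model, gts))
  stopifnot(is.list(model), length(model) == 2L)
  fc <- lapply(seq_len(2L), function(i)
    one(model[[i]], if (is.null(gts)) NULL else gts[[i]]))
  list(fc = fc, difference = fc[[2L]] - fc[[1L]])
}

#' Gradient variance/covariance feature vector of one scan
#'
#' The 21-dimensional (for K = 6) dynamics feature vector used throughout
#' the structure-function analyses: K temporal variances followed by the
#' K(K-1)/2 pairwise covariances in row-major pair order.
#'
#' @param gts a [gradient_timeseries()] or a `gradient_covariance` matrix.
#' @return Named numeric vector (`var_g1..`, `cov_g1-g2..`).
#' @export
gradient_dynamics_features <- function(gts) {
  C <- if (inherits(gts, "gradient_timeseries")) gradient_covariance(gts)
       else unclass(gts)
  K <- ncol(C)
  idx <- pair_index(K)
  c(setNames(diag(C), paste0("var_g", seq_len(K))),
    setNames(C[idx], paste0("cov_", pair_names(K))))
}

#' Eigenmode amplitude/angle feature vector of one model
#'
#' Companion to [gradient_dynamics_features()]: K cumulative amplitudes
#' followed by the pair angles in the same row-major pair order.
#'
#' @param modes an `eigenmode_set`.
#' @return Named numeric vector (`amp_g1..`, `angle_g1-g2..`).
#' @export
eigenmode_features <- function(modes) {
  s <- eigenmode_summary(modes)
  c(setNames(as.numeric(s$amplitude), paste0("amp_g", seq_len(modes$K))),
    setNames(s$angles$angle_deg, paste0("angle_", s$angles$pair)))
}

#' Correspondence between eigenmode and covariance descriptions
#'
#' Correlates, across subjects, the eigenmode-derived features (K cumulative
#' amplitudes, K(K-1)/2 pair angles) with the gradient temporal features
#' (K variances, matching covariances). "Corresponding" cells are the
#' diagonal pairs amplitude_g <-> var_g and angle_gh <-> cov_gh; all other
#' cells are non-corresponding. If the two descriptions capture the same
#' dynamics, corresponding correlations should dominate.
#'
#' @param eig_features subject x 2K+K(K-1)/2... matrix of eigenmode features
#'   (rows = subjects), as from [eigenmode_features()].
#' @param dyn_features subject x same-dimension matrix of variance/covariance
#'   features, as from [gradient_dynamics_features()].
#'
#' @return List with `correlation` (feature x feature matrix),
#'   `median_corresponding`, `median_noncorresponding` (medians of |r|), and
#'   `corresponding` (logical mask).
#' @export
amplitude_angle_correspondence <- function(eig_features, dyn_features) {
  eig_features <- check_na_ok_matrix(eig_features)
  dyn_features <- check_na_ok_matrix(dyn_features)
  stopifnot(nrow(eig_features) == nrow(dyn_features),
            ncol(eig_features) == ncol(dyn_features))
  if (nrow(eig_features) < 10L)
    warning("fewer than 10 subjects; correspondence correlations are unstable")
  sds <- c(apply(eig_features, 2L, sd, na.rm = TRUE),
           apply(dyn_features, 2L, sd, na.rm = TRUE))
  if (any(sds == 0 | is.na(sds)))
    warning("constant feature columns; their correlations are undefined")
  R <- suppressWarnings(cor(eig_features, dyn_features,
                            use = "pairwise.complete.obs"))
  corresponding <- diag(ncol(R)) == 1
  list(correlation = R,
       median_corresponding = median(abs(R[corresponding]), na.rm = TRUE),
       median_noncorresponding = median(abs(R[!corresponding]), na.rm = TRUE),
       corresponding = corresponding)
}

#' Condition number of a (possibly complex) matrix via singular values
#' @noRd
cond_complex <- function(M) {
  s <- svd(M, nu = 0, nv = 0)$d
  if (min(s) == 0) return(Inf)
  max(s) / min(s)
}

check_na_ok_matrix <- function(x) {
  x <- as.matrix(x)
  if (!is.numeric(x)) stop("features must be numeric", call. = FALSE)
  x
}
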