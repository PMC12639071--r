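#' Coupled damped harmonic oscillator models for gradient dynamics
#'
#' A coupling model stores, for each of K gradients, the coefficients of a
#' linear second-order equation: the gradient's acceleration G'' is an
#' intercept plus linear terms in all gradients' levels G and velocities G'.
#' The coefficient matrix is K x (2K + 1), columns ordered
#' (intercept, G_1..G_K, G'_1..G'_K), with time measured in samples.
#'
#' @param coefficients K x (2K + 1) numeric matrix.
#' @param tr_seconds sampling interval of the underlying timeseries, used
#'   only to convert angular frequencies to hertz.
#' @param r_squared optional per-equation R^2 from a regression fit.
#'
#' @return An object of class `coupling_model`.
#' @export
coupling_model <- function(coefficients, tr_seconds = 1, r_squared = NULL) {
  coefficients <- check_matrix(coefficients)
  K <- nrow(coefficients)
  if (ncol(coefficients) != 2L * K + 1L)
    stop_dims("coefficient matrix must be K x (2K+1); got %d x %d",
              K, ncol(coefficients))
  gn <- paste0("g", seq_len(K))
  dimnames(coefficients) <- list(gn, c("intercept", gn, paste0("d", gn)))
  structure(list(coefficients = coefficients, K = K,
                 tr_seconds = tr_seconds, r_squared = r_squared),
            class = "coupling_model")
}

#' @export
print.coupling_model <- function(x, ...) {
  cat(sprintf("<coupling_model> K = %d gradients, TR = %g s\n", x$K,
              x$tr_seconds))
  if (!is.null(x$r_squared))
    cat("per-equation R^2:", paste(sprintf("%.3f", x$r_squared),
                                   collapse = " "), "\n")
  invisible(x)
}

#' Build a coupling model from oscillator parameters
#'
#' Constructs the second-order system in which gradient g obeys
#' `G'' = -omega_g^2 G - c_g G'` plus optional cross-coupling terms. With no
#' cross terms the companion-matrix eigenvalues equal the closed form
#' `lambda = (-c +/- sqrt(c^2 - 4 omega^2)) / 2` for each gradient.
#'
#' @param frequencies natural angular frequencies, rad per sample, > 0.
#' @param dampings per-gradient damping coefficients c (per sample). Each
#'   diagonal oscillator must be underdamped: `c^2 < 4 omega^2`.
#' @param cross_couplings optional data frame with columns `from`, `to`,
#'   `type` ("position" or "velocity") and `value`: adds `value * G_from`
#'   (or `value * G'_from`) to the equation for `G_to''`. Only the row for
#'   `G_to''` is altered.
#' @param tr_seconds sampling interval in seconds.
#'
#' @return A [coupling_model()].
#' @export
build_coupling_matrix <- function(frequencies, dampings,
                                  cross_couplings = NULL, tr_seconds = 1) {
  K <- length(frequencies)
  stopifnot(length(dampings) == K)
  if (any(frequencies <= 0)) stop("frequencies must be > 0", call. = FALSE)
  over <- dampings^2 >= 4 * frequencies^2
  if (any(over))
    stop(sprintf(
      "overdamped oscillator spec (c^2 >= 4 omega^2) for gradient(s) %s",
      paste(which(over), collapse = ", ")), call. = FALSE)
  coefs <- matrix(0, K, 2L * K + 1L)
  for (g in seq_len(K)) {
    coefs[g, 1L + g] <- -frequencies[g]^2
    coefs[g, 1L + K + g] <- -dampings[g]
  }
  if (!is.null(cross_couplings) && nrow(cross_couplings) > 0L) {
    stopifnot(all(c("from", "to", "type", "value") %in%
                    names(cross_couplings)))
    for (r in seq_len(nrow(cross_couplings))) {
      cc <- cross_couplings[r, ]
      col <- if (cc$type == "position") 1L + cc$from else 1L + K + cc$from
      coefs[cc$to, col] <- coefs[cc$to, col] + cc$value
    }
  }
  coupling_model(coefs, tr_seconds = tr_seconds)
}

#' First-order companion form of a coupling model
#'
#' Rewrites the K second-order equations as `dY/dt = A Y` with the 2K state
#' vector blocked as all positions then all velocities:
#' `Y = (G_1..G_K, G'_1..G'_K)`. The intercept terms are omitted (they shift
#' the equilibrium, which is zero for centered gradient timeseries).
#'
#' @param model a [coupling_model()].
#' @return A 2K x 2K numeric matrix.
#' @export
companion_matrix <- function(model) {
  stopifnot(inherits(model, "coupling_model"))
  K <- model$K
  B <- model$coefficients
  A <- rbind(cbind(matrix(0, K, K), diag(K)),
             cbind(B[, 2L:(K + 1L), drop = FALSE],
                   B[, (K + 2L):(2L * K + 1L), drop = FALSE]))
  dimnames(A) <- NULL
  A
}

#' Gradient timeseries container
#'
#' @param values time x gradient numeric matrix.
#' @param tr_seconds sampling interval in seconds.
#' @return An object of class `gradient_timeseries`.
#' @export
gradient_timeseries <- function(values, tr_seconds = 1) {
  values <- check_matrix(values)
  colnames(values) <- colnames(values) %||% paste0("g", seq_len(ncol(values)))
  structure(list(values = values, tr_seconds = tr_seconds),
            class = "gradient_timeseries")
}

#' @export
print.gradient_timeseries <- function(x, ...) {
  cat(sprintf("<gradient_timeseries> %d timepoints x %d gradients, TR = %g s\n",
              nrow(x$values), ncol(x$values), x$tr_seconds))
  invisible(x)
}

#' Simulate gradient timeseries from a coupling model
#'
#' Integrates the companion system exactly over each sampling step using the
#' matrix exponential of the companion matrix (one step = one sample), with
#' additive Gaussian forcing injected into the velocity block after every
#' step. This avoids the instability of explicit Euler schemes and makes
#' noise-free trajectories match the analytic mode solution to machine
#' precision.
#'
#' @param model a [coupling_model()].
#' @param n_timepoints number of samples to return.
#' @param forcing_sd scalar or length-K vector of per-step forcing standard
#'   deviations (applied to velocities). Zero gives a deterministic
#'   trajectory from `init`.
#' @param seed integer seed for the forcing realization.
#' @param init optional length-2K initial state (positions then velocities).
#'   Defaults to zero.
#' @param burn_in samples discarded before recording; defaults to 200 when
#'   forcing is present and 0 otherwise, so that forced simulations start
#'   near stationarity.
#'
#' @return A [gradient_timeseries()]; row t is the state after t - 1 steps
#'   (so row 1 reproduces `init` when `burn_in = 0`).
#' @export
simulate_gradient_timeseries <- function(model, n_timepoints, forcing_sd = 0,
                                         seed = NULL, init = NULL,
                                         burn_in = NULL) {
  stopifnot(inherits(model, "coupling_model"), n_timepoints >= 1)
  K <- model$K
  forcing_sd <- rep_len(forcing_sd, K)
  stopifnot(all(forcing_sd >= 0))
  A <- companion_matrix(model)
  re <- max(Re(eigen(A, only.values = TRUE)$values))
  if (re > 1e-8)
    warning(sprintf(
      "companion system is unstable (max Re(lambda) = %.3g); trajectories may diverge",
      re))
  burn_in <- burn_in %||% (if (any(forcing_sd > 0)) 200L else 0L)
  P <- as.matrix(Matrix::expm(A))
  y <- if (is.null(init)) rep(0, 2L * K) else {
    stopifnot(length(init) == 2L * K)
    as.numeric(init)
  }
  # states: s_0 = init, s_t = P s_{t-1} + forcing_t; rows are
  # s_{burn_in} .. s_{burn_in + n_timepoints - 1}
  out <- matrix(0, n_timepoints, K)
  vel <- (K + 1L):(2L * K)
  forced <- any(forcing_sd > 0)
  nsteps <- burn_in + n_timepoints - 1L
  with_seed(seed, {
    noise <- if (forced && nsteps > 0L)
      matrix(rnorm(nsteps * K, 0, rep(forcing_sd, each = nsteps)),
             nsteps, K)
    else NULL
    if (burn_in == 0L) out[1L, ] <- y[seq_len(K)]
    for (t in seq_len(nsteps)) {
      y <- P %*% y
      if (forced) y[vel] <- y[vel] + noise[t, ]
      idx <- t - burn_in + 1L
      if (idx >= 1L) out[idx, ] <- y[seq_len(K)]
    }
    NULL
  })
  if (anyNA(out) || any(!is.finite(out)))
    stop("simulation produced non-finite values", call. = FALSE)
  gradient_timeseries(out, tr_seconds = model$tr_seconds)
}

#' Render regional BOLD timeseries from gradient timeseries
#'
#' The forward (rendering) counterpart of gradient projection: regional
#' signal equals the gradient timeseries mixed through the orthonormal basis
#' vectors, plus independent Gaussian observation noise per region. With
#' zero noise, projecting the rendered data back through the same basis
#' recovers the (column-centered) gradient timeseries exactly.
#'
#' @param gradients a [gradient_timeseries()].
#' @param basis a [gradient_basis()] whose column count matches the gradient
#'   count.
#' @param region_noise_sd standard deviation of additive regional noise.
#' @param seed integer seed for the noise realization.
#'
#' @return A [regional_timeseries()] (time x region).
#' @export
render_bold <- function(gradients, basis, region_noise_sd = 0, seed = NULL) {
  stopifnot(inherits(gradients, "gradient_timeseries"),
            inherits(basis, "gradient_basis"))
  G <- gradients$values
  if (ncol(G) != ncol(basis$vectors))
    stop_dims("gradient count (%d) does not match basis columns (%d)",
              ncol(G), ncol(basis$vectors))
  X <- G %*% t(basis$vectors)
  if (region_noise_sd > 0) {
    X <- X + with_seed(seed,
      matrix(rnorm(length(X), 0, region_noise_sd), nrow(X), ncol(X)))
  }
  regional_timeseries(X, tr_seconds = gradients$tr_seconds,
                      region_ids = basis$region_ids)
}
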