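#' Regional BOLD timeseries container
#'
#' @param values time x region numeric matrix.
#' @param tr_seconds sampling interval in seconds.
#' @param region_ids character vector of region identifiers (defaults to
#'   `r1..rR`).
#' @param mean_fd optional mean framewise displacement (mm) for the scan.
#' @param scan_id optional scan identifier.
#' @return An object of class `regional_timeseries`.
#' @export
regional_timeseries <- function(values, tr_seconds = 1, region_ids = NULL,
                                mean_fd = NA_real_, scan_id = NULL) {
  values <- check_matrix(values)
  region_ids <- region_ids %||% paste0("r", seq_len(ncol(values)))
  stopifnot(length(region_ids) == ncol(values))
  colnames(values) <- region_ids
  structure(list(values = values, tr_seconds = tr_seconds,
                 region_ids = region_ids, mean_fd = mean_fd,
                 scan_id = scan_id),
            class = "regional_timeseries")
}

#' @export
print.regional_timeseries <- function(x, ...) {
  cat(sprintf("<regional_timeseries> %d timepoints x %d regions, TR = %g s",
              nrow(x$values), ncol(x$values), x$tr_seconds))
  if (!is.na(x$mean_fd)) cat(sprintf(", mean FD = %.3f mm", x$mean_fd))
  cat("\n")
  invisible(x)
}

#' Two-stage scan quality control
#'
#' Stage 1 excludes scans whose mean framewise displacement strictly exceeds
#' `fd_threshold` (a scan at exactly the threshold is retained). Stage 2
#' computes Pearson FC matrices for the survivors, vectorizes their upper
#' triangles, runs a PCA across scans, and excludes scans whose first
#' principal component score lies strictly above mean + `pc_sd_threshold`
#' standard deviations. PC1 is oriented so that the largest-magnitude score
#' is positive, putting outliers on the upper tail. Stage order is fixed:
#' motion first, then the PCA outlier screen.
#'
#' @param scans list of [regional_timeseries()].
#' @param fd_threshold mean-FD exclusion threshold in mm.
#' @param pc_sd_threshold PC1 exclusion threshold in standard deviations.
#'
#' @return A list with `included` and `excluded` integer indices into
#'   `scans`, plus a `report` data frame (scan, mean_fd, stage1_pass,
#'   pc1_score, stage2_pass).
#' @export
qc_filter_scans <- function(scans, fd_threshold = 0.55, pc_sd_threshold = 1.0) {
  stopifnot(is.list(scans), length(scans) > 0L, fd_threshold > 0)
  fd <- vapply(scans, function(s) s$mean_fd, numeric(1L))
  stage1 <- is.na(fd) | fd <= fd_threshold
  survivors <- which(stage1)
  pc1 <- rep(NA_real_, length(scans))
  stage2 <- stage1
  if (length(survivors) < 3L) {
    warning("fewer than 3 scans after motion exclusion; PCA outlier stage skipped")
  } else {
    edges <- t(vapply(survivors, function(i) {
      vectorize_fc(cor(scans[[i]]$values))
    }, numeric(choose(ncol(scans[[1L]]$values), 2L))))
    pc <- prcomp(edges, center = TRUE, scale. = FALSE)
    s1 <- pc$x[, 1L]
    if (s1[which.max(abs(s1))] < 0) s1 <- -s1
    pc1[survivors] <- s1
    cut <- mean(s1) + pc_sd_threshold * sd(s1)
    stage2[survivors] <- s1 <= cut
  }
  report <- data.frame(
    scan = seq_along(scans),
    mean_fd = fd,
    stage1_pass = stage1,
    pc1_score = pc1,
    stage2_pass = stage2
  )
  list(included = which(stage1 & stage2),
       excluded = which(!(stage1 & stage2)),
       report = report)
}

#' Derive a gradient basis by PCA of concatenated regional timeseries
#'
#' Region columns are mean-centered per scan, scans are temporally
#' concatenated, and a covariance PCA (no per-region variance scaling) is
#' run. Variance scaling is deliberately avoided so the component loadings
#' preserve amplitude information (the dominant unipolar component's
#' variance tracks global signal amplitude). Component signs are fixed so
#' the largest-magnitude region weight is positive.
#'
#' @param scans list of [regional_timeseries()] from the reference cohort.
#' @param K number of gradients to retain.
#' @param reference optional reference-cohort label stored in the basis.
#'
#' @return A [gradient_basis()]; `sdev` holds the PCA component standard
#'   deviations of the concatenated reference data.
#' @export
derive_gradient_basis <- function(scans, K, reference = NULL) {
  stopifnot(is.list(scans), length(scans) > 0L, K >= 1)
  region_ids <- scans[[1L]]$region_ids
  X <- do.call(rbind, lapply(scans, function(s) {
    stopifnot(identical(s$region_ids, region_ids))
    scale(s$values, center = TRUE, scale = FALSE)
  }))
  if (nrow(X) <= ncol(X))
    stop("total timepoints must exceed the number of regions", call. = FALSE)
  pc <- prcomp(X, center = FALSE, scale. = FALSE)
  if (sum(pc$sdev > max(pc$sdev) * 1e-8) < K)
    stop_dims("reference data have rank < K = %d", K)
  V <- pc$rotation[, seq_len(K), drop = FALSE]
  for (k in seq_len(K)) {
    if (V[which.max(abs(V[, k])), k] < 0) V[, k] <- -V[, k]
  }
  rownames(V) <- region_ids
  gradient_basis(V, pc$sdev[seq_len(K)], region_ids = region_ids,
                 reference = reference)
}

#' Project a scan into gradient space
#'
#' Scores are the (column-centered) regional data multiplied by the basis
#' eigenvectors. Projecting a scan that contributed to basis derivation
#' reproduces its PCA scores exactly.
#'
#' @param scan a [regional_timeseries()].
#' @param basis a [gradient_basis()].
#' @param center center region columns before projection (default TRUE,
#'   matching the derivation convention).
#'
#' @return A [gradient_timeseries()].
#' @export
project_to_gradients <- function(scan, basis, center = TRUE) {
  stopifnot(inherits(scan, "regional_timeseries"),
            inherits(basis, "gradient_basis"))
  if (!identical(scan$region_ids, basis$region_ids)) {
    bad <- union(setdiff(scan$region_ids, basis$region_ids),
                 setdiff(basis$region_ids, scan$region_ids))
    if (length(bad) > 0L)
      stop_dims("region mismatch between scan and basis: %s",
                paste(head(bad, 10L), collapse = ", "))
    stop("regions must appear in the same order as the basis", call. = FALSE)
  }
  X <- scan$values
  if (center) X <- scale(X, center = TRUE, scale = FALSE)
  gradient_timeseries(X %*% basis$vectors, tr_seconds = scan$tr_seconds)
}

#' Gradient covariance matrix of one scan
#'
#' Unbiased temporal covariance of the gradient score columns: variances on
#' the diagonal, covariances off it.
#'
#' @param gts a [gradient_timeseries()].
#' @return A K x K symmetric matrix of class `gradient_covariance` with a
#'   `constant_gradients` attribute flagging zero-variance columns.
#' @export
gradient_covariance <- function(gts) {
  stopifnot(inherits(gts, "gradient_timeseries"))
  if (nrow(gts$values) < 2L)
    stop("at least 2 timepoints are required for a covariance", call. = FALSE)
  C <- cov(gts$values)
  const <- which(diag(C) == 0)
  structure(C, class = c("gradient_covariance", class(C)),
            constant_gradients = const)
}

#' Reconstruct functional connectivity from gradient covariance
#'
#' Region covariance is `V C V'` where `V` holds the basis eigenvectors and
#' `C` the gradient covariance; Pearson FC follows by normalizing to a
#' correlation. With the full component set (K = number of regions) this
#' reproduces the scan's direct Pearson FC exactly; truncated bases give the
#' low-rank approximation carried by the retained gradients.
#'
#' @param cov_g K x K gradient covariance (from [gradient_covariance()]).
#' @param basis a [gradient_basis()] with K columns.
#'
#' @return A region x region correlation matrix. Regions with zero
#'   reconstructed variance get `NaN` rows/columns and are listed in the
#'   `zero_variance` attribute.
#' @export
fc_from_gradient_covariance <- function(cov_g, basis) {
  stopifnot(inherits(basis, "gradient_basis"))
  cov_g <- unclass(cov_g)
  V <- basis$vectors
  if (ncol(V) != ncol(cov_g))
    stop_dims("basis has %d components but covariance is %d x %d",
              ncol(V), nrow(cov_g), ncol(cov_g))
  RC <- V %*% cov_g %*% t(V)
  v <- diag(RC)
  zero <- which(v <= 0)
  d <- sqrt(pmax(v, 0))
  FC <- RC / tcrossprod(d)
  FC[zero, ] <- NaN
  FC[, zero] <- NaN
  ok <- setdiff(seq_along(v), zero)
  FC[cbind(ok, ok)] <- 1
  dimnames(FC) <- list(basis$region_ids, basis$region_ids)
  attr(FC, "zero_variance") <- zero
  FC
}

#' Compare two gradient bases component by component
#'
#' Computes the per-component spatial Pearson correlation after choosing the
#' sign flip that makes each correlation non-negative. Useful for checking
#' that bases derived from independent cohorts agree.
#'
#' @param basis_a,basis_b [gradient_basis()] objects over the same regions.
#' @return A data frame with columns `component`, `r` (after sign
#'   alignment), and `flipped`.
#' @export
match_gradient_bases <- function(basis_a, basis_b) {
  stopifnot(inherits(basis_a, "gradient_basis"),
            inherits(basis_b, "gradient_basis"),
            identical(basis_a$region_ids, basis_b$region_ids))
  K <- min(ncol(basis_a$vectors), ncol(basis_b$vectors))
  r <- numeric(K); flipped <- logical(K)
  for (k in seq_len(K)) {
    rho <- cor(basis_a$vectors[, k], basis_b$vectors[, k])
    flipped[k] <- rho < 0
    r[k] <- abs(rho)
  }
  data.frame(component = seq_len(K), r = r, flipped = flipped)
}
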