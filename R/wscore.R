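#' Fit a normative model of regional volumes
#'
#' Per-region ordinary least squares of gray-matter volume on covariates
#' (intercept added automatically). Residual standard deviations use the
#' n - p - 1 denominator, where p is the number of covariates.
#'
#' @param volumes subject x region numeric matrix.
#' @param covariates subject x p data frame or matrix of numeric covariates
#'   (factors must be pre-coded).
#'
#' @return An object of class `normative_model`: `coefficients`
#'   ((p + 1) x region), `residual_sd` (per region), `covariate_names`,
#'   `region_ids`, `degenerate` (regions with zero residual SD).
#' @export
fit_normative_model <- function(volumes, covariates = NULL) {
  volumes <- check_matrix(volumes)
  X <- if (is.null(covariates)) matrix(numeric(0), nrow(volumes), 0L)
       else as.matrix(covariates)
  if (anyNA(X)) stop("covariates contain missing values", call. = FALSE)
  n <- nrow(volumes); p <- ncol(X)
  stopifnot(nrow(X) == n)
  if (n <= p + 2L)
    stop("need more subjects than covariates + 2", call. = FALSE)
  covariate_names <- if (p == 0L) character(0) else
    colnames(X) %||% paste0("x", seq_len(p))
  colnames(X) <- covariate_names
  D <- cbind(`(Intercept)` = 1, X)
  qrD <- qr(D)
  if (qrD$rank < ncol(D)) {
    bad <- colnames(D)[qrD$pivot[-seq_len(qrD$rank)]]
    stop_dims("rank-deficient covariates; collinear columns: %s",
              paste(bad, collapse = ", "))
  }
  beta <- qr.coef(qrD, volumes)
  res <- volumes - D %*% beta
  residual_sd <- sqrt(colSums(res^2) / (n - p - 1L))
  region_ids <- colnames(volumes) %||% paste0("r", seq_len(ncol(volumes)))
  deg_tol <- 1e-8 * pmax(apply(abs(volumes), 2L, max), 1)
  degenerate <- region_ids[residual_sd <= deg_tol]
  if (length(degenerate) > 0L)
    warning(sprintf(
      "degenerate normative fit: zero residual SD in %d region(s)",
      length(degenerate)))
  structure(list(coefficients = beta, residual_sd = residual_sd,
                 covariate_names = covariate_names,
                 region_ids = region_ids, degenerate = degenerate),
            class = "normative_model")
}

#' @export
print.normative_model <- function(x, ...) {
  cat(sprintf("<normative_model> %d regions, covariates: %s\n",
              length(x$region_ids), paste(x$covariate_names, collapse = ", ")))
  invisible(x)
}

#' Compute atrophy W-scores against a normative model
#'
#' The W-score is the deviation of observed regional gray-matter volume from
#' its covariate-adjusted normative prediction, in units of the normative
#' residual standard deviation. Under the default atrophy-positive
#' convention, `W = (predicted - observed) / SD`, so tissue loss gives
#' positive scores and the affected-region rule "W > 1.5" flags atrophy.
#' Set `convention = "deficit-negative"` for the opposite sign.
#'
#' @param volumes subject x region matrix.
#' @param covariates subject x p covariates with names matching the model.
#' @param model a `normative_model` from [fit_normative_model()].
#' @param convention `"atrophy-positive"` (default) or `"deficit-negative"`.
#'
#' @return Subject x region matrix of W-scores with attribute `convention`.
#' @export
compute_w_scores <- function(volumes, covariates, model,
                             convention = c("atrophy-positive",
                                            "deficit-negative")) {
  stopifnot(inherits(model, "normative_model"))
  convention <- match.arg(convention)
  volumes <- check_matrix(volumes)
  region_ids <- colnames(volumes) %||% paste0("r", seq_len(ncol(volumes)))
  if (!identical(region_ids, model$region_ids)) {
    bad <- setdiff(region_ids, model$region_ids)
    stop_dims("unknown or misordered region ids: %s",
              paste(head(bad %||% region_ids, 10L), collapse = ", "))
  }
  X <- if (is.null(covariates)) matrix(numeric(0), nrow(volumes), 0L)
       else as.matrix(covariates)
  cn <- if (ncol(X) == 0L) character(0) else
    colnames(X) %||% paste0("x", seq_len(ncol(X)))
  if (!identical(cn, model$covariate_names))
    stop_dims("covariate names do not match the model (expected: %s)",
              paste(model$covariate_names, collapse = ", "))
  pred <- cbind(1, X) %*% model$coefficients
  W <- sweep(pred - volumes, 2L, model$residual_sd, `/`)
  if (convention == "deficit-negative") W <- -W
  dimnames(W) <- dimnames(volumes)
  attr(W, "convention") <- convention
  W
}

#' Location-scale batch harmonization
#'
#' Removes batch (scanner) additive and multiplicative effects from a
#' feature matrix while preserving variance associated with biological
#' covariates, using the non-empirical-Bayes location/scale estimator: each
#' feature is regressed on the design covariates plus batch indicators,
#' residuals are standardized by the pooled residual SD, per-batch residual
#' means and SDs are removed, and the covariate-predicted part is added
#' back. The same transform applies to W-score vectors and vectorized
#' connectivity/covariance features.
#'
#' @param features subject x feature numeric matrix.
#' @param batch factor or vector of batch labels (>= 2 subjects per batch).
#' @param covariates optional subject x q matrix of biological covariates to
#'   preserve (e.g. patient/control status, age, sex).
#' @param tol convergence tolerance for the fixed-point iteration.
#' @param max_iter maximum number of adjustment passes.
#'
#' @details Each pass fits, per feature, an OLS model with intercept,
#'   covariates, and sum-to-zero batch contrasts; subtracts the estimated
#'   batch location effect; rescales residuals so every batch has the pooled
#'   residual SD; and restores the covariate-predicted part. Passes repeat
#'   until the adjustment is a fixed point, which makes the operator
#'   idempotent: applying it to already-harmonized data returns the input.
#'
#' @return Harmonized matrix of the same dimension.
#' @export
harmonize_location_scale <- function(features, batch, covariates = NULL,
                                     tol = 1e-10, max_iter = 50L) {
  features <- check_matrix(features)
  batch <- as.factor(batch)
  stopifnot(length(batch) == nrow(features))
  if (nlevels(droplevels(batch)) < 2L) {
    warning("single batch; returning features unchanged")
    return(features)
  }
  batch <- droplevels(batch)
  if (any(table(batch) < 2L))
    stop("each batch needs at least 2 subjects", call. = FALSE)
  n <- nrow(features)
  Xcov <- if (is.null(covariates)) matrix(numeric(0), n, 0L) else {
    M <- as.matrix(covariates)
    stopifnot(nrow(M) == n)
    M
  }
  # sum-to-zero batch contrasts so batch effects average out over levels
  B <- model.matrix(~b, data.frame(b = batch),
                    contrasts.arg = list(b = "contr.sum"))[, -1L,
                                                           drop = FALSE]
  D <- cbind(1, Xcov, B)
  qrD <- qr(D)
  if (qrD$rank < ncol(D))
    stop("design (covariates + batch) is rank deficient", call. = FALSE)
  keep <- seq_len(1L + ncol(Xcov))
  scale_val <- max(abs(features), 1)
  cur <- features
  for (it in seq_len(max_iter)) {
    beta <- qr.coef(qr(D), cur)
    resid <- cur - D %*% beta
    bio <- D[, keep, drop = FALSE] %*% beta[keep, , drop = FALSE]
    # pooled scale as the df-weighted mean of within-batch variances, so
    # equal batch scales give delta exactly 1 (a true fixed point)
    bv <- sapply(levels(batch), function(b)
      apply(resid[batch == b, , drop = FALSE], 2L, var))
    dfb <- table(batch)[levels(batch)] - 1L
    pooled_sd <- sqrt(as.matrix(bv) %*% as.numeric(dfb) / sum(dfb))[, 1L]
    pooled_sd[pooled_sd == 0] <- 1
    adj <- resid
    for (b in levels(batch)) {
      i <- which(batch == b)
      delta <- apply(resid[i, , drop = FALSE], 2L, sd) / pooled_sd
      delta[delta == 0 | is.na(delta)] <- 1
      adj[i, ] <- sweep(resid[i, , drop = FALSE], 2L, delta, `/`)
    }
    nxt <- bio + adj
    if (max(abs(nxt - cur)) < tol * scale_val) { cur <- nxt; break }
    cur <- nxt
  }
  dimnames(cur) <- dimnames(features)
  cur
}

#' Flag regions affected by atrophy within a group
#'
#' A region is affected when at least `min_patients` subjects show a W-score
#' strictly greater than `w_threshold` (strict on the score, inclusive on
#' the count).
#'
#' @param w subject x region W-score matrix (atrophy-positive convention).
#' @param w_threshold W-score cut, > 0 (default 1.5).
#' @param min_patients minimum number of supra-threshold subjects
#'   (default 5).
#'
#' @return Named logical vector over regions.
#' @export
flag_affected_regions <- function(w, w_threshold = 1.5, min_patients = 5) {
  stopifnot(w_threshold > 0)
  w <- check_matrix(w)
  if (nrow(w) == 0L) {
    warning("empty cohort; no regions flagged")
    return(setNames(rep(FALSE, ncol(w)),
                    colnames(w) %||% paste0("r", seq_len(ncol(w)))))
  }
  counts <- colSums(w > w_threshold)
  setNames(counts >= min_patients,
           colnames(w) %||% paste0("r", seq_len(ncol(w))))
}

#' Jaccard overlap of affected-region sets between groups
#'
#' `J(A, B) = |A intersect B| / |A union B|`; two empty sets give 0 with a
#' warning. The mean off-diagonal (upper triangle) index summarizes
#' between-group overlap.
#'
#' @param flags_by_group named list of logical vectors (same regions) or of
#'   region-id vectors.
#' @return List with `jaccard` (group x group matrix, unit diagonal) and
#'   `mean_offdiagonal`.
#' @export
jaccard_overlap <- function(flags_by_group) {
  stopifnot(is.list(flags_by_group), length(flags_by_group) >= 2L)
  sets <- lapply(flags_by_group, function(f) {
    if (is.logical(f)) which(f) else f
  })
  g <- length(sets)
  nm <- names(sets) %||% paste0("group", seq_len(g))
  J <- matrix(1, g, g, dimnames = list(nm, nm))
  warned <- FALSE
  for (a in seq_len(g - 1L)) for (b in (a + 1L):g) {
    u <- length(union(sets[[a]], sets[[b]]))
    if (u == 0L) {
      if (!warned) warning("two empty region sets; Jaccard defined as 0")
      warned <- TRUE
      J[a, b] <- J[b, a] <- 0
    } else {
      J[a, b] <- J[b, a] <- length(intersect(sets[[a]], sets[[b]])) / u
    }
  }
  list(jaccard = J, mean_offdiagonal = mean(J[upper.tri(J)]))
}
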