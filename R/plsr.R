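#' Vectorize the upper triangle of a symmetric FC matrix
#'
#' Extracts the strict upper triangle (i < j) in row-major order:
#' (1,2), (1,3), ..., (1,R), (2,3), ... For R regions the edge vector has
#' length R(R-1)/2 (30135 for the 246-region atlas). The ordering is fixed,
#' so edge vectors are comparable across subjects.
#'
#' @param fc square symmetric numeric matrix.
#' @param tol asymmetry tolerance (default 1e-8).
#' @return Numeric edge vector of length R(R-1)/2.
#' @export
vectorize_fc <- function(fc, tol = 1e-8) {
  fc <- check_matrix(fc)
  if (nrow(fc) != ncol(fc)) stop("FC matrix must be square", call. = FALSE)
  if (max(abs(fc - t(fc))) > tol)
    stop("FC matrix is asymmetric beyond tolerance", call. = FALSE)
  fc[pair_index(nrow(fc))]
}

#' Rebuild a symmetric matrix from an edge vector
#'
#' Inverse of [vectorize_fc()]: fills both triangles and sets a unit
#' diagonal (the diagonal of a correlation matrix).
#'
#' @param edges edge vector of length R(R-1)/2.
#' @param diag_value value for the diagonal (default 1).
#' @return R x R symmetric matrix.
#' @export
devectorize_fc <- function(edges, diag_value = 1) {
  m <- length(edges)
  R <- (1 + sqrt(1 + 8 * m)) / 2
  if (R != round(R))
    stop("edge vector length is not R(R-1)/2 for any integer R",
         call. = FALSE)
  R <- as.integer(R)
  M <- matrix(0, R, R)
  idx <- pair_index(R)
  M[idx] <- edges
  M <- M + t(M)
  diag(M) <- diag_value
  M
}

#' Partial least squares regression of FC edges on atrophy
#'
#' NIPALS PLS2 with Y-deflation. X (subject x region atrophy W-scores) is
#' column-centered but not variance-scaled, because regional W-scores share
#' units and the first component should retain its interpretation as overall
#' mean atrophy; Y (subject x FC edges) is column-centered. Component k
#' maximizes the covariance between X-scores and Y-scores subject to
#' deflation of earlier components.
#'
#' Signs are fixed so that component 1's structure scores correlate
#' positively with overall mean atrophy, and for later components the
#' largest-magnitude X-weight region is positive.
#'
#' @param X subject x region atrophy matrix.
#' @param Y subject x edge FC matrix.
#' @param n_components number of components (default 3).
#' @param max_iter,tol NIPALS iteration controls.
#'
#' @return Object of class `plsr_model`: `x_weights` (region x k),
#'   `x_loadings`, `y_loadings` (edge x k), `x_scores` (S, subject x k),
#'   `y_scores` (F, subject x k), `explained_x_variance` (per component, of
#'   total X variance), `score_correlation` (in-sample r(S_k, F_k)),
#'   `x_center`, `y_center`, `n_components`.
#' @export
fit_plsr <- function(X, Y, n_components = 3, max_iter = 500L, tol = 1e-10) {
  X <- check_matrix(X); Y <- check_matrix(Y)
  n <- nrow(X)
  stopifnot(nrow(Y) == n, n > n_components)
  if (all(apply(Y, 2L, var) == 0))
    stop("Y has zero variance", call. = FALSE)
  x_center <- colMeans(X); y_center <- colMeans(Y)
  Xc <- sweep(X, 2L, x_center); Yc <- sweep(Y, 2L, y_center)
  ssx_total <- sum(Xc^2)
  p <- ncol(Xc)
  W <- P <- matrix(0, p, n_components)
  Q <- matrix(0, ncol(Yc), n_components)
  Tm <- U <- matrix(0, n, n_components)
  expl <- rs <- numeric(n_components)
  Xd <- Xc; Yd <- Yc
  for (k in seq_len(n_components)) {
    u <- Yd[, which.max(apply(Yd, 2L, var))]
    if (var(u) == 0) u <- rnorm(n)
    t_old <- rep(Inf, n)
    for (it in seq_len(max_iter)) {
      w <- crossprod(Xd, u)
      w <- w / sqrt(sum(w^2))
      tt <- Xd %*% w
      q <- crossprod(Yd, tt) / sum(tt^2)
      u <- Yd %*% q / sum(q^2)
      if (sqrt(sum((tt - t_old)^2)) < tol * sqrt(sum(tt^2))) break
      t_old <- tt
    }
    pp <- crossprod(Xd, tt) / sum(tt^2)
    W[, k] <- w; P[, k] <- pp; Q[, k] <- q
    Tm[, k] <- tt; U[, k] <- u
    expl[k] <- sum(tt^2) * sum(pp^2) / ssx_total
    Xd <- Xd - tcrossprod(tt, pp)
    Yd <- Yd - tcrossprod(tt, q)
  }
  # sign conventions
  mean_atrophy <- rowMeans(Xc)
  for (k in seq_len(n_components)) {
    flip <- if (k == 1L) cor(Tm[, 1L], mean_atrophy) < 0 else
      W[which.max(abs(W[, k])), k] < 0
    if (isTRUE(flip)) {
      W[, k] <- -W[, k]; P[, k] <- -P[, k]; Q[, k] <- -Q[, k]
      Tm[, k] <- -Tm[, k]; U[, k] <- -U[, k]
    }
    rs[k] <- cor(Tm[, k], U[, k])
  }
  kn <- paste0("c", seq_len(n_components))
  dimnames(W) <- dimnames(P) <- list(colnames(X), kn)
  dimnames(Q) <- list(colnames(Y), kn)
  dimnames(Tm) <- dimnames(U) <- list(rownames(X), kn)
  structure(list(
    x_weights = W, x_loadings = P, y_loadings = Q,
    x_scores = Tm, y_scores = U,
    explained_x_variance = setNames(expl, kn),
    score_correlation = setNames(rs, kn),
    x_center = x_center, y_center = y_center,
    n_components = n_components
  ), class = "plsr_model")
}

#' @export
print.plsr_model <- function(x, ...) {
  cat(sprintf("<plsr_model> %d components, %d regions -> %d edges\n",
              x$n_components, nrow(x$x_weights), nrow(x$y_loadings)))
  cat("X variance explained:",
      paste(sprintf("%.1f%%", 100 * x$explained_x_variance),
            collapse = " "), "\n")
  cat("in-sample r(S_k, F_k):",
      paste(sprintf("%.2f", x$score_correlation), collapse = " "), "\n")
  invisible(x)
}

#' Project new atrophy data onto PLSR structure components
#'
#' Uses the rotation `W (P'W)^{-1}` so that scores of the training data are
#' reproduced exactly despite deflation.
#'
#' @param model a `plsr_model`.
#' @param X new subject x region matrix.
#' @return Subject x k matrix of structure scores.
#' @export
plsr_structure_scores <- function(model, X) {
  stopifnot(inherits(model, "plsr_model"))
  Xc <- sweep(check_matrix(X), 2L, model$x_center)
  R <- model$x_weights %*%
    solve(crossprod(model$x_loadings, model$x_weights))
  Xc %*% R
}

#' Cross-validated function scores via ridge regression
#'
#' For each of `folds` outer folds: a PLSR model is fit on the training
#' subjects; ridge regressions (one per component) predict the training
#' Y-scores from the training FC edges, with the penalty chosen on an inner
#' 3-fold grid; held-out function scores are then predicted from the
#' held-out edges and correlated with the held-out structure scores. The
#' reported statistic per component is the per-fold correlation
#' r(S_heldout, F_heldout_predicted) and its median.
#'
#' @param X subject x region atrophy matrix.
#' @param Y subject x edge FC matrix.
#' @param n_components number of PLSR components.
#' @param folds number of outer folds (default 4).
#' @param lambda ridge penalty grid (default logarithmic 1e-2..1e4).
#' @param seed seed controlling fold assignment.
#'
#' @return List with `fold_r` (fold x component matrix), `median_r` (per
#'   component), `oos_scores` (subject x component out-of-sample function
#'   scores), `fold_id`.
#' @export
crossval_function_scores <- function(X, Y, n_components = 3, folds = 4,
                                     lambda = 10^seq(-2, 4, length.out = 13),
                                     seed = NULL) {
  X <- check_matrix(X); Y <- check_matrix(Y)
  n <- nrow(X)
  stopifnot(folds >= 2, nrow(Y) == n)
  fold_id <- with_seed(seed, sample(rep(seq_len(folds), length.out = n)))
  if (min(table(fold_id)) < 3L)
    stop("each fold needs at least 3 subjects", call. = FALSE)
  fold_r <- matrix(NA_real_, folds, n_components)
  oos <- matrix(NA_real_, n, n_components)
  for (f in seq_len(folds)) {
    tr <- which(fold_id != f); te <- which(fold_id == f)
    fit <- fit_plsr(X[tr, , drop = FALSE], Y[tr, , drop = FALSE],
                    n_components = n_components)
    Ytr <- sweep(Y[tr, , drop = FALSE], 2L, fit$y_center)
    Yte <- sweep(Y[te, , drop = FALSE], 2L, fit$y_center)
    S_te <- plsr_structure_scores(fit, X[te, , drop = FALSE])
    inner <- with_seed(child_seed(seed, f),
                       sample(rep(seq_len(3L), length.out = length(tr))))
    for (k in seq_len(n_components)) {
      u <- fit$y_scores[, k]
      cvm <- numeric(length(lambda))
      for (i in seq_len(3L)) {
        it <- which(inner != i); iv <- which(inner == i)
        g <- glmnet::glmnet(Ytr[it, , drop = FALSE], u[it], alpha = 0,
                            lambda = rev(sort(lambda)),
                            standardize = FALSE, intercept = TRUE)
        pr <- predict(g, Ytr[iv, , drop = FALSE],
                      s = rev(sort(lambda)))
        cvm <- cvm + colMeans((pr - u[iv])^2)
      }
      best <- rev(sort(lambda))[which.min(cvm)]
      g <- glmnet::glmnet(Ytr, u, alpha = 0, lambda = rev(sort(lambda)),
                          standardize = FALSE, intercept = TRUE)
      fhat <- as.numeric(predict(g, Yte, s = best))
      oos[te, k] <- fhat
      fold_r[f, k] <- cor(S_te[, k], fhat)
    }
  }
  list(fold_r = fold_r,
       median_r = apply(fold_r, 2L, median),
       oos_scores = oos,
       fold_id = fold_id)
}

#' Reconstruct FC (difference) matrices from component scores
#'
#' Per subject, the reconstructed edge vector is the sum over components of
#' score times edge loading (`scores %*% t(loadings)`), devectorized to a
#' symmetric matrix with zero diagonal. Applied to function scores and Y
#' loadings this gives the component-based approximation of each subject's
#' (centered) FC pattern.
#'
#' @param scores subject x k score matrix.
#' @param loadings edge x k loading matrix.
#' @return List of symmetric matrices, one per subject (named by row names
#'   when present).
#' @export
reconstruct_fc <- function(scores, loadings) {
  scores <- check_matrix(as.matrix(scores))
  loadings <- check_matrix(as.matrix(loadings))
  if (ncol(scores) != ncol(loadings))
    stop_dims("component mismatch: scores have %d, loadings %d",
              ncol(scores), ncol(loadings))
  E <- tcrossprod(scores, loadings)
  out <- lapply(seq_len(nrow(E)), function(i)
    devectorize_fc(E[i, ], diag_value = 0))
  names(out) <- rownames(scores)
  out
}

#' Syndrome-typical subject subset via linear discriminant analysis
#'
#' Fits LDA on the structure component scores with the syndrome label as the
#' response and retains the subjects whose in-sample predicted label equals
#' their true label: the subjects expressing the "typical" pattern for their
#' syndrome. If the within-class covariance is singular, a small shrinkage
#' ridge is added with a warning.
#'
#' @param S subject x component score matrix.
#' @param labels factor of class labels (>= 2 classes, >= 4 subjects each).
#' @return Integer vector of retained subject indices, with attribute
#'   `predicted` (the full predicted label vector).
#' @export
typical_subset_lda <- function(S, labels) {
  S <- check_matrix(as.matrix(S))
  labels <- as.factor(labels)
  stopifnot(length(labels) == nrow(S))
  if (nlevels(droplevels(labels)) < 2L)
    stop("need at least 2 classes", call. = FALSE)
  if (any(table(labels) < 4L))
    stop("each class needs at least 4 subjects", call. = FALSE)
  fit <- tryCatch(MASS::lda(S, grouping = labels),
                  error = function(e) NULL)
  if (is.null(fit)) {
    warning("singular within-class covariance; applying shrinkage jitter")
    scl <- pmax(apply(S, 2L, sd), 1e-8) * 1e-6
    jit <- with_seed(1L, matrix(rnorm(length(S)), nrow(S))) *
      rep(scl, each = nrow(S))
    S <- S + jit
    fit <- MASS::lda(S, grouping = labels)
  }
  pred <- predict(fit, S)$class
  keep <- which(pred == labels)
  attr(keep, "predicted") <- pred
  keep
}

#' Two-dimensional embedding of structure scores
#'
#' Classical (metric) multidimensional scaling of the Euclidean distances
#' between subjects' structure component scores.
#'
#' @param S subject x component score matrix.
#' @param dim embedding dimension (< number of columns of S).
#' @return List with `coordinates` (subject x dim) and
#'   `distance_correlation` between original and embedded distances.
#' @export
mds_embed <- function(S, dim = 2) {
  S <- check_matrix(as.matrix(S))
  stopifnot(dim < ncol(S))
  d0 <- dist(S)
  coords <- cmdscale(d0, k = dim)
  list(coordinates = coords,
       distance_correlation = cor(as.numeric(d0),
                                  as.numeric(dist(coords))))
}

#' Decompose function-score variance into gradient terms
#'
#' Multiple regression of a function component score on the standardized
#' gradient dynamics features (K temporal variances and K(K-1)/2 pair
#' covariances). Each term's share of statistical variance is its squared
#' semi-partial correlation `t^2 (1 - R^2) / (n - p - 1)`; the total R^2 and
#' the signed t statistic per term are reported. Collinear features trigger
#' a ridge fallback with a warning.
#'
#' @param f numeric vector of function scores (one component).
#' @param features subject x term matrix from
#'   [gradient_dynamics_features()] rows.
#' @return Data frame with `term`, `share` (squared semi-partial
#'   correlation), `t`, `p`; attribute `r_squared` holds the model R^2.
#' @export
explain_fc_by_gradient_terms <- function(f, features) {
  features <- check_matrix(as.matrix(features))
  stopifnot(length(f) == nrow(features))
  n <- nrow(features); p <- ncol(features)
  Z <- scale(features)
  if (any(!is.finite(Z))) stop("constant feature column", call. = FALSE)
  D <- cbind(1, Z)
  qrD <- qr(D)
  if (qrD$rank < ncol(D)) {
    warning("collinear gradient features; using ridge fallback")
    lam <- 1e-6 * n
    beta <- solve(crossprod(D) + diag(c(0, rep(lam, p))), crossprod(D, f))
    fitted <- D %*% beta
    r2 <- 1 - sum((f - fitted)^2) / sum((f - mean(f))^2)
    return(structure(
      data.frame(term = colnames(features) %||% paste0("term", seq_len(p)),
                 share = NA_real_, t = NA_real_, p = NA_real_),
      r_squared = r2))
  }
  fit <- lm.fit(D, f)
  res <- fit$residuals
  df <- n - p - 1L
  sigma2 <- sum(res^2) / df
  XtXinv <- chol2inv(qr.R(qrD))
  se <- sqrt(pmax(diag(XtXinv) * sigma2, .Machine$double.xmin))
  tval <- fit$coefficients / se
  sst <- sum((f - mean(f))^2)
  r2 <- 1 - sum(res^2) / sst
  # squared semi-partial correlation as the R^2 drop from removing the term
  share <- vapply(seq_len(p), function(j) {
    rj <- lm.fit(D[, -(j + 1L), drop = FALSE], f)$residuals
    (sum(rj^2) - sum(res^2)) / sst
  }, numeric(1L))
  tv <- tval[-1L]
  pv <- 2 * pf(tv^2, 1, df, lower.tail = FALSE)
  structure(
    data.frame(term = colnames(features) %||% paste0("term", seq_len(p)),
               share = share, t = as.numeric(tv), p = as.numeric(pv)),
    r_squared = r2,
    r_squared_adj = 1 - (1 - r2) * (n - 1) / df)
}
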