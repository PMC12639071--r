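#' Fit an additive brain-behavior model for one cognitive test
#'
#' Generalized additive model of a cognitive score on brain component
#' scores (by default S1-S3 and F1-F3), each restricted to a small
#' nonlinear basis (dimension 3, cubic regression splines), plus strictly
#' linear covariates. Brain predictors are standardized before fitting.
#' By default the spline terms use their full fixed basis (no penalty), so
#' each term's F statistic is the exact linear-model test and type-I error
#' is controlled at the nominal level; `penalized = TRUE` switches to
#' penalized smooths with the smoothing parameter chosen by `method`,
#' whose approximate term tests run slightly liberal at small basis
#' dimensions. Tests with fewer than `min_n` non-missing responses are
#' skipped (returns NULL with a message). With `basis_dim <= 1` the brain
#' terms enter linearly and the fit reduces to ordinary least squares.
#'
#' @param response numeric vector of test scores (NA allowed).
#' @param scores data frame of brain predictor columns.
#' @param covariates optional data frame of linear covariates.
#' @param basis_dim spline basis dimension per brain term (default 3).
#' @param min_n minimum number of non-missing responses (default 120).
#' @param penalized use penalized smooths instead of fixed-df splines
#'   (default FALSE).
#' @param method smoothing-parameter selection criterion passed to
#'   [mgcv::gam()] when `penalized = TRUE` (default `"GCV.Cp"`).
#'
#' @return Object of class `behavior_result`: `terms` (data frame with
#'   per-term F, p), `r_squared` (adjusted), `dev_explained`, `n`, `fit`
#'   (the mgcv fit), `partial_effects` (per brain term: grid, fit, se), or
#'   NULL if the test is skipped.
#' @export
fit_additive_model <- function(response, scores, covariates = NULL,
                               basis_dim = 3, min_n = 120,
                               penalized = FALSE, method = "GCV.Cp") {
  scores <- as.data.frame(scores)
  ok <- !is.na(response) & complete.cases(scores)
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    ok <- ok & complete.cases(covariates)
  }
  if (sum(ok) < min_n) {
    message(sprintf("skipping test: %d non-missing responses < %d",
                    sum(ok), min_n))
    return(NULL)
  }
  y <- response[ok]
  Z <- as.data.frame(lapply(scores[ok, , drop = FALSE],
                            function(x) as.numeric(scale(x))))
  dat <- cbind(data.frame(.y = y), Z)
  brain <- names(Z)
  if (basis_dim > 1) {
    terms <- sprintf("s(%s, k = %d, bs = 'cr'%s)", brain, basis_dim,
                     if (penalized) "" else ", fx = TRUE")
  } else {
    terms <- brain
  }
  if (!is.null(covariates)) {
    cv <- covariates[ok, , drop = FALSE]
    names(cv) <- make.names(names(cv))
    dat <- cbind(dat, cv)
    terms <- c(terms, names(cv))
  }
  form <- stats::as.formula(paste(".y ~", paste(terms, collapse = " + ")))
  fit <- mgcv::gam(form, data = dat, method = method)
  sm <- summary(fit)
  if (basis_dim > 1) {
    tt <- data.frame(term = brain,
                     F = as.numeric(sm$s.table[, "F"]),
                     p = as.numeric(sm$s.table[, "p-value"]))
  } else {
    pt <- sm$p.table[brain, , drop = FALSE]
    tt <- data.frame(term = brain,
                     F = as.numeric(pt[, "t value"])^2,
                     p = as.numeric(pt[, "Pr(>|t|)"]))
  }
  pe <- lapply(brain, function(b) {
    grid <- dat[rep(1L, 100L), , drop = FALSE]
    for (v in setdiff(names(dat), ".y"))
      grid[[v]] <- if (is.numeric(dat[[v]])) mean(dat[[v]]) else dat[[v]][1L]
    grid[[b]] <- seq(min(dat[[b]]), max(dat[[b]]), length.out = 100L)
    pr <- predict(fit, newdata = grid, type = "terms", se.fit = TRUE)
    cn <- if (basis_dim > 1) sprintf("s(%s)", b) else b
    data.frame(x = grid[[b]],
               fit = as.numeric(pr$fit[, cn]),
               se = as.numeric(pr$se.fit[, cn]))
  })
  names(pe) <- brain
  structure(list(terms = tt, r_squared = sm$r.sq,
                 dev_explained = sm$dev.expl, n = sum(ok), fit = fit,
                 partial_effects = pe),
            class = "behavior_result")
}

#' @export
print.behavior_result <- function(x, ...) {
  cat(sprintf("<behavior_result> n = %d, adj. R^2 = %.3f\n", x$n,
              x$r_squared))
  print(x$terms, row.names = FALSE)
  invisible(x)
}

#' Benjamini-Hochberg FDR correction
#'
#' Step-up FDR control at level `q` over a family of p-values; NaN/NA
#' p-values are excluded from the family and flagged NA in the output.
#'
#' @param p numeric vector of p-values in `[0, 1]` (NA allowed).
#' @param q FDR level (default 0.05).
#' @return Data frame with `p`, `p_adjusted` (BH), `rejected`.
#' @export
fdr_correct <- function(p, q = 0.05) {
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  adj <- rep(NA_real_, length(p))
  ok <- is.finite(p)
  adj[ok] <- p.adjust(p[ok], method = "BH")
  data.frame(p = p, p_adjusted = adj,
             rejected = ifelse(is.na(adj), NA, adj <= q))
}

#' Summarize variance explained across a battery of behavior models
#'
#' @param results named list of `behavior_result` objects (NULL entries,
#'   from skipped tests, are dropped).
#' @return List with `table` (per-test R^2 and top-3 terms by F),
#'   `mean_r_squared`, `sd_r_squared`, `range_r_squared`.
#' @export
variance_explained_summary <- function(results) {
  results <- Filter(Negate(is.null), results)
  if (length(results) == 0L)
    stop("no fitted behavior models to summarize", call. = FALSE)
  tab <- do.call(rbind, lapply(names(results), function(nm) {
    r <- results[[nm]]
    top <- r$terms$term[order(-r$terms$F)][seq_len(min(3L,
                                                       nrow(r$terms)))]
    data.frame(test = nm, r_squared = r$r_squared, n = r$n,
               top_terms = paste(top, collapse = ","))
  }))
  r2 <- tab$r_squared
  list(table = tab, mean_r_squared = mean(r2),
       sd_r_squared = if (length(r2) > 1L) sd(r2) else 0,
       range_r_squared = range(r2))
}
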