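#' Internal helpers
#'
#' Small utilities shared across modules. None are exported.
#' @name gradmodes-utils
#' @keywords internal
NULL

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Run code with a temporary RNG seed, restoring the caller's RNG state
#' @noRd
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}

#' Derive a child seed from a base seed, staying inside 32-bit integer range
#' @noRd
child_seed <- function(seed, offset) {
  if (is.null(seed)) return(NULL)
  as.integer((as.double(seed) * 7919 + offset) %% .Machine$integer.max)
}

stop_dims <- function(msg, ...) stop(sprintf(msg, ...), call. = FALSE)

check_matrix <- function(x, name = deparse(substitute(x))) {
  if (!is.matrix(x) || !is.numeric(x))
    stop_dims("`%s` must be a numeric matrix", name)
  if (anyNA(x)) stop_dims("`%s` contains missing values", name)
  x
}

#' Upper-triangle (i < j) index pairs in row-major order
#' @noRd
pair_index <- function(n) {
  i <- rep(seq_len(n - 1L), times = (n - 1L):1L)
  j <- unlist(lapply(seq_len(n - 1L), function(a) (a + 1L):n))
  cbind(i = i, j = j)
}

#' Names like "g1-g4" for gradient pairs in row-major upper-triangle order
#' @noRd
pair_names <- function(K, prefix = "g") {
  idx <- pair_index(K)
  paste0(prefix, idx[, 1L], "-", prefix, idx[, 2L])
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi
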