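#' Read and write tab-separated matrices and model objects
#'
#' Plain-text interchange for the pipeline's tabular artifacts: W-score and
#' volume tables (subjects x regions, header = region ids), gradient bases
#' (regions x K), and coupling/eigenmode results as JSON.
#'
#' @param x matrix to write.
#' @param path file path.
#' @name gradmodes-io
NULL

#' @rdname gradmodes-io
#' @export
write_matrix_tsv <- function(x, path) {
  df <- data.frame(id = rownames(x) %||% seq_len(nrow(x)), x,
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname gradmodes-io
#' @export
read_matrix_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  m
}

#' Write a normative model as JSON
#' @param model a `normative_model`.
#' @param path file path.
#' @export
write_normative_model <- function(model, path) {
  stopifnot(inherits(model, "normative_model"))
  jsonlite::write_json(list(
    coefficients = model$coefficients,
    residual_sd = model$residual_sd,
    covariate_names = model$covariate_names,
    region_ids = model$region_ids
  ), path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read a normative model from JSON
#' @param path file path.
#' @export
read_normative_model <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(
    coefficients = as.matrix(j$coefficients),
    residual_sd = as.numeric(j$residual_sd),
    covariate_names = j$covariate_names,
    region_ids = j$region_ids,
    degenerate = character(0)
  ), class = "normative_model")
}

#' Serialize an eigenmode set to a plain list (for JSON export)
#' @param modes an `eigenmode_set`.
#' @export
eigenmodes_to_list <- function(modes) {
  stopifnot(inherits(modes, "eigenmode_set"))
  list(modes = modes$modes,
       components_re = Re(modes$components),
       components_im = Im(modes$components),
       K = modes$K, tr_seconds = modes$tr_seconds)
}
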