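#' @importFrom rlang %||% abort warn
#' @importFrom tibble tibble as_tibble
#' @import Matrix
#' @importFrom methods as is
#' @importFrom stats median pnorm pt quantile sd setNames var predict coef
#' @importFrom utils read.table write.table
#' @importFrom Rcpp evalCpp
#' @useDynLib netprior, .registration = TRUE
NULL

# Deterministic TSV writers: all pipeline output goes through these so that
# re-running with the same seed is byte-identical.
write_tsv_plain <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE)
  invisible(path)
}

read_tsv_plain <- function(path, ...) {
  as_tibble(read.table(path, sep = "\t", header = TRUE,
                       stringsAsFactors = FALSE, check.names = FALSE, ...))
}

# All randomness is scoped: callers pass `seed`, nothing touches the global
# RNG state of the session.
with_seed_ <- function(seed, code) {
  if (is.null(seed)) return(code)
  withr::with_seed(as.integer(seed), code)
}

stopifnot_scalar_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0 || x >= 1) {
    abort(sprintf("`%s` must be a single number strictly between 0 and 1.",
                  name))
  }
}
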