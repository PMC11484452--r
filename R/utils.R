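#' Evaluate an expression with a temporary RNG seed
#'
#' Sets the RNG seed for the duration of `expr` and restores the caller's RNG
#' state afterwards, so that library code never clobbers user-level
#' reproducibility.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("'seed' must be a single integer")
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Internal: derive a stream of sub-seeds from a master seed, kept within
# 32-bit integer range.
derive_seeds <- function(seed, n) {
  (as.integer(seed) %% 1000000L) * 1000L + seq_len(n)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

REGIONS <- c("utr5", "cds", "utr3")

stopifnot_names <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop(sprintf("%s is missing required column(s): %s",
                 what, paste(miss, collapse = ", ")))
}
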