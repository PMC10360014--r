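#' Round half away from zero to an integer
#'
#' Device outputs in this pipeline are integers; ties (x.5) round up, unlike
#' [base::round()]'s round-half-to-even.
#'
#' @param x numeric vector.
#' @return integer-valued numeric vector.
#' @examples
#' round_half_up(c(36.5, 37.49, -0.5))
#' @export
round_half_up <- function(x) {
  stopifnot(is.numeric(x))
  sign(x) * floor(abs(x) + 0.5)
}

# Evaluate `code` under a temporary RNG seed, restoring global RNG state.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# stop() with a consistent prefix-less message built via sprintf
abort <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# maximal runs of TRUE in a logical vector; returns data.frame(start, end),
# 1-based inclusive indices
true_runs <- function(mask) {
  r <- rle(mask)
  end <- cumsum(r$lengths)
  start <- end - r$lengths + 1L
  keep <- r$values
  data.frame(start = start[keep], end = end[keep])
}
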