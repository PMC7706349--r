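#' @keywords internal
"_PACKAGE"

#' Derive a reproducible sub-seed for a named operation
#'
#' All generators in the package are pure functions of (config, seed). To
#' avoid accidental stream coupling between operations that share a master
#' seed, each operation draws from a substream whose seed is a stable hash
#' of the operation name combined with the master seed.
#'
#' @param seed master integer seed.
#' @param op character scalar naming the operation.
#' @return an integer seed in [0, 2^31 - 1).
#' @export
derive_seed <- function(seed, op) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(op))
  h <- 0
  for (k in utf8ToInt(op)) h <- (h * 131 + k) %% 2147483647
  as.integer((h + as.numeric(seed) * 2654435761) %% 2147483647)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

stop_param <- function(...) stop(sprintf(...), call. = FALSE)

# shoelace signed area of a closed polygon (positive = counter-clockwise in
# a y-up frame; in the image frame with y down the sign flips)
polygon_area_signed <- function(x, y) {
  n <- length(x)
  i2 <- c(2:n, 1L)
  sum(x * y[i2] - x[i2] * y) / 2
}
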