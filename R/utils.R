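#' @keywords internal
"_PACKAGE"

# Run an expression under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

#' The four cardinal crown-measurement directions
#'
#' Canonical ordering (E, W, S, N) used throughout the package.
#' @export
DIRECTIONS <- c("E", "W", "S", "N")

# Compass bearings (degrees clockwise from north) of the four directions.
DIRECTION_BEARING <- c(E = 90, W = 270, S = 180, N = 0)

#' The uniform relative-crown-height grid
#'
#' The 11 interpolation points from the tree top (RCH 0) to the crown base
#' (RCH 1), spaced by 0.1.
#' @export
RCH_GRID <- seq(0, 1, by = 0.1)

# Number of competition layers (grid points excluding the zero-radius top).
N_LAYERS <- 10L

stopifnot_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
}
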