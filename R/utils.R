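#' Derive child seeds from a master seed
#'
#' Deterministically expands one master seed into `n` child seeds, so that
#' per-participant and per-replicate random streams are reproducible and do
#' not collide in practice. Child seeds are drawn without replacement from
#' the full 31-bit integer range.
#'
#' @param master_seed Integer master seed.
#' @param n Number of child seeds to derive.
#' @return Integer vector of length `n`.
#' @export
derive_seeds <- function(master_seed, n) {
  stopifnot(is.numeric(master_seed), length(master_seed) == 1L, n >= 1)
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(master_seed))
  sample.int(.Machine$integer.max, n)
}

# Set the RNG seed if one is supplied; NULL means "use the current stream".
maybe_seed <- function(seed) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  invisible(NULL)
}

# Snap values to the nearest grid point, clipping to the grid range.
# Exact midpoints between two levels snap to the lower level.
snap_to_grid <- function(x, grid) {
  if (length(grid) < 1L) stop("bet grid is empty", call. = FALSE)
  grid <- sort(grid)
  if (length(grid) == 1L) return(rep(grid, length(x)))
  mids <- (grid[-1] + grid[-length(grid)]) / 2
  grid[findInterval(x, mids, left.open = TRUE) + 1L]
}

# Moment-matched lognormal draws (mean m, sd s on the natural scale),
# floored at `floor_at`.
rlnorm_matched <- function(n, m, s, floor_at = 0.2) {
  sdlog <- sqrt(log1p((s / m)^2))
  meanlog <- log(m) - sdlog^2 / 2
  pmax(floor_at, rlnorm(n, meanlog, sdlog))
}

# Index range of samples with time in [from, to), for a signal whose i-th
# sample (1-based) sits at t0 + (i - 1) / rate.
sample_window <- function(from, to, rate, t0 = 0, n = NULL) {
  i0 <- ceiling((from - t0) * rate - 1e-9) + 1L
  i1 <- ceiling((to - t0) * rate - 1e-9)
  if (i0 < 1L || (!is.null(n) && i1 > n) || i1 < i0) {
    return(NULL)
  }
  c(i0, i1)
}
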