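# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         closed_lower = TRUE, closed_upper = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stopf("`%s` must be a single finite number", name)
  }
  lo_ok <- if (closed_lower) x >= lower else x > lower
  hi_ok <- if (closed_upper) x <= upper else x < upper
  if (!lo_ok || !hi_ok) {
    stopf("`%s` = %g is outside its allowed range", name, x)
  }
  invisible(x)
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

# Range of motion (max - min) per column of a matrix.
channel_rom <- function(m) apply(m, 2L, function(v) max(v) - min(v))

# Flatten a 101 x 4 cycle matrix column-major (LHip samples first).
flatten_cycle <- function(cycle) {
  as.vector(cycle_matrix(cycle))
}

unflatten_cycle <- function(v) {
  matrix(v, nrow = 101L, ncol = 4L, dimnames = list(NULL, gait_channels()))
}

# Accept either a normalized_cycle or a bare 101 x 4 matrix.
cycle_matrix <- function(cycle) {
  m <- if (inherits(cycle, "normalized_cycle")) cycle$angles else cycle
  if (!is.matrix(m) || nrow(m) != 101L || ncol(m) != 4L) {
    stopf("expected a 101 x 4 cycle matrix, got %s x %s",
          NROW(m), NCOL(m))
  }
  m
}
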