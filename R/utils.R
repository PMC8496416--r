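# Internal helpers shared across modules.

#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded to `seed`, restoring the previous
#' RNG state afterwards. With `seed = NULL` the code runs against the ambient
#' RNG stream, so callers can embed seeded generators in a larger seeded run.
#'
#' @param seed integer seed or `NULL`.
#' @param code expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Maximal runs of TRUE in a logical vector (NA counts as FALSE).
# Returns a two-column integer matrix (start, end), zero rows if none.
logical_runs <- function(x) {
  x <- !is.na(x) & x
  n <- length(x)
  if (n == 0L || !any(x)) {
    return(matrix(integer(0), ncol = 2L,
                  dimnames = list(NULL, c("start", "end"))))
  }
  d <- diff(c(FALSE, x, FALSE))
  starts <- which(d == 1L)
  ends <- which(d == -1L) - 1L
  cbind(start = starts, end = ends)
}

# Centered moving average of width k over full symmetric windows only:
# edge samples (and any window touching an NA) yield NA. Truncated edge
# windows are deliberately not used -- they would bias endpoint-slope
# estimates on drifting segments.
moving_average <- function(x, k) {
  n <- length(x)
  if (k <= 1L || n == 0L) return(x)
  half <- (k - 1L) %/% 2L
  out <- rep(NA_real_, n)
  cs <- cumsum(ifelse(is.na(x), 0, x))
  nas <- cumsum(is.na(x))
  for (i in seq_len(n)) {
    lo <- i - half
    hi <- i + half
    if (lo < 1L || hi > n) next
    if ((nas[hi] - (if (lo > 1L) nas[lo - 1L] else 0L)) > 0L) next
    out[i] <- (cs[hi] - (if (lo > 1L) cs[lo - 1L] else 0)) / (hi - lo + 1L)
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_okncs <- function(msg, class, ...) {
  stop(structure(class = c(class, "okncs_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1), ...)))
}
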