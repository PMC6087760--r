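# Internal helpers: classed error conditions and seed scoping.

fa_stop <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "fa_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

stop_invalid <- function(msg, ...) fa_stop("fa_invalid_argument", msg, ...)
stop_infeasible <- function(msg, ...) fa_stop("fa_infeasible", msg, ...)

#' @noRd
is_count <- function(x, min = 0L) {
  length(x) == 1L && is.numeric(x) && !is.na(x) && x == round(x) && x >= min
}

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# random stream.  `seed = NULL` leaves the current stream untouched.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is_count(seed)) stop_invalid("`seed` must be a single non-negative integer")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a reproducible sub-seed for a named substream of a master seed,
# kept below 2^31 so it is always a valid R integer.
sub_seed <- function(seed, stream) {
  if (is.null(seed)) return(NULL)
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.numeric(seed) * 271L + h * 7919) %% 2147483629)
}
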