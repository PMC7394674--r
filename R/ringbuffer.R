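#' Bounded single-producer / single-consumer ring buffer
#'
#' The circular buffer that decouples the template refiller from the waveform
#' consumer in the streaming pipeline. Reads never return uninitialized
#' slots: a pop is limited to the number of values currently held. Under the
#' default `"block"` policy a push stores only as many values as fit and
#' reports how many were taken (the producer is expected to retry); under
#' `"overwrite"` a push always succeeds, silently discarding the oldest
#' values, which emulates real-time dropout.
#'
#' @param capacity Maximum number of values held (>= 1).
#' @param policy `"block"` (lossless, default) or `"overwrite"`.
#' @return A `ring_buffer` object.
#' @examples
#' rb <- ring_buffer(4)
#' rb_push(rb, 1:3)
#' rb_pop(rb, 2)
#' rb_size(rb)
#' @export
ring_buffer <- function(capacity, policy = c("block", "overwrite")) {
  policy <- match.arg(policy)
  if (!is.finite(capacity) || capacity < 1) abort("capacity must be >= 1")
  capacity <- as.integer(capacity)
  env <- new.env(parent = emptyenv())
  env$buf <- numeric(capacity)
  env$capacity <- capacity
  env$head <- 0L   # index of next slot to read (0-based)
  env$count <- 0L
  env$policy <- policy
  env$dropped <- 0L
  class(env) <- "ring_buffer"
  env
}

#' @rdname ring_buffer
#' @param rb A `ring_buffer`.
#' @param x Numeric values to append in order.
#' @return `rb_push()` returns the number of values actually stored.
#' @export
rb_push <- function(rb, x) {
  stopifnot(inherits(rb, "ring_buffer"))
  n <- length(x)
  if (n == 0) return(0L)
  if (rb$policy == "block") {
    k <- min(n, rb$capacity - rb$count)
    if (k == 0) return(0L)
    x <- x[seq_len(k)]
  } else {
    if (n > rb$capacity) {
      rb$dropped <- rb$dropped + (n - rb$capacity)
      x <- x[(n - rb$capacity + 1):n]
      n <- rb$capacity
    }
    overflow <- rb$count + n - rb$capacity
    if (overflow > 0) {
      rb$head <- (rb$head + overflow) %% rb$capacity
      rb$count <- rb$count - overflow
      rb$dropped <- rb$dropped + overflow
    }
    k <- n
  }
  idx <- ((rb$head + rb$count + seq_len(k) - 1L) %% rb$capacity) + 1L
  rb$buf[idx] <- x
  rb$count <- rb$count + as.integer(k)
  as.integer(k)
}

#' @rdname ring_buffer
#' @param n Number of values to pop; must not exceed `rb_size(rb)`.
#' @return `rb_pop()` returns the `n` oldest values in FIFO order.
#' @export
rb_pop <- function(rb, n) {
  stopifnot(inherits(rb, "ring_buffer"))
  n <- as.integer(n)
  if (n > rb$count) {
    abort(sprintf("buffer underrun: requested %d, holds %d", n, rb$count))
  }
  if (n == 0) return(numeric(0))
  idx <- ((rb$head + seq_len(n) - 1L) %% rb$capacity) + 1L
  out <- rb$buf[idx]
  rb$head <- (rb$head + n) %% rb$capacity
  rb$count <- rb$count - n
  out
}

#' @rdname ring_buffer
#' @return `rb_size()` returns the number of values currently held.
#' @export
rb_size <- function(rb) {
  stopifnot(inherits(rb, "ring_buffer"))
  rb$count
}

#' @export
print.ring_buffer <- function(x, ...) {
  cat(sprintf("<ring_buffer> %d/%d values, %s policy, %d dropped\n",
              x$count, x$capacity, x$policy, x$dropped))
  invisible(x)
}
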