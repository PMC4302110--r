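# Interval helpers. All intervals are 1-based inclusive data.frames with
# integer columns `start` and `end`, start <= end, kept sorted by start.

`%||%` <- function(x, y) if (is.null(x)) y else x

iv <- function(start = integer(), end = integer()) {
  stopifnot(length(start) == length(end))
  if (any(end < start)) stop("interval with end < start")
  data.frame(start = as.integer(start), end = as.integer(end))
}

iv_sort <- function(x) x[order(x$start, x$end), , drop = FALSE]

iv_length <- function(x) {
  if (nrow(x) == 0L) return(0L)
  sum(x$end - x$start + 1L)
}

iv_merge <- function(x) {
  if (nrow(x) <= 1L) return(iv_sort(x))
  x <- iv_sort(x)
  out_s <- x$start[1L]; out_e <- x$end[1L]
  res_s <- integer(); res_e <- integer()
  for (i in seq_len(nrow(x))[-1L]) {
    if (x$start[i] <= out_e + 1L) {
      out_e <- max(out_e, x$end[i])
    } else {
      res_s <- c(res_s, out_s); res_e <- c(res_e, out_e)
      out_s <- x$start[i]; out_e <- x$end[i]
    }
  }
  iv(c(res_s, out_s), c(res_e, out_e))
}

# x minus y
iv_subtract <- function(x, y) {
  y <- iv_merge(y)
  res_s <- integer(); res_e <- integer()
  for (i in seq_len(nrow(x))) {
    s <- x$start[i]; e <- x$end[i]
    segs_s <- s; segs_e <- e
    for (j in seq_len(nrow(y))) {
      ys <- y$start[j]; ye <- y$end[j]
      new_s <- integer(); new_e <- integer()
      for (k in seq_along(segs_s)) {
        a <- segs_s[k]; b <- segs_e[k]
        if (ye < a || ys > b) {          # no overlap
          new_s <- c(new_s, a); new_e <- c(new_e, b)
        } else {
          if (ys > a) { new_s <- c(new_s, a); new_e <- c(new_e, ys - 1L) }
          if (ye < b) { new_s <- c(new_s, ye + 1L); new_e <- c(new_e, b) }
        }
      }
      segs_s <- new_s; segs_e <- new_e
      if (length(segs_s) == 0L) break
    }
    res_s <- c(res_s, segs_s); res_e <- c(res_e, segs_e)
  }
  iv_sort(iv(res_s, res_e))
}

iv_intersect <- function(x, y) {
  y <- iv_merge(y)
  res_s <- integer(); res_e <- integer()
  for (i in seq_len(nrow(x))) {
    s <- pmax(x$start[i], y$start)
    e <- pmin(x$end[i], y$end)
    keep <- s <= e
    res_s <- c(res_s, s[keep]); res_e <- c(res_e, e[keep])
  }
  iv_sort(iv(res_s, res_e))
}

# vectorized membership test: is each position inside any interval of x?
iv_contains <- function(x, pos) {
  if (nrow(x) == 0L) return(rep(FALSE, length(pos)))
  x <- iv_sort(x)
  idx <- findInterval(pos, x$start)
  idx > 0L & pos <= x$end[pmax(idx, 1L)]
}

# deterministic sub-stream seed, safe against 32-bit integer overflow
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(k) * 16807) %%
               2147483647)
}

# run a function with a locally-scoped RNG seed (global RNG untouched)
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  withr::with_seed(as.integer(seed), code)
}

tasrdiv_msg <- function(...) message("[tasrdiv] ", ...)
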