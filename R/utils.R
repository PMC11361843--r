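# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

# Deterministic child seeds for per-sample / per-repeat randomness.
# Keeps every derived seed a valid 32-bit integer.
deriveSeed <- function(master, idx) {
  stopifnot(is.numeric(master), length(master) == 1L, is.numeric(idx))
  m <- as.double(master) %% 2147483647
  as.integer((m * 48271 + as.double(idx) * 9973 + 17) %% 2147483629) + 1L
}

# Median rounding used for reference-normal replication counts: half-up,
# i.e. 8.5 -> 9 (never banker's rounding).
roundHalfUp <- function(x) floor(x + 0.5)

.assertScalarNumber <- function(x, name, lo = -Inf, hi = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lo || x > hi)
    stop(sprintf("'%s' must be a single number in [%s, %s]", name,
                 format(lo), format(hi)), call. = FALSE)
  invisible(x)
}

# Normalize a length multiset given as (a) a bare numeric vector of
# lengths, (b) a named count vector (names = lengths), or (c) a
# data.frame with columns length and count.  Returns list(len, count).
.asLengthCounts <- function(x) {
  if (is.data.frame(x)) {
    stopifnot(all(c("length", "count") %in% names(x)))
    len <- as.numeric(x$length); cnt <- as.numeric(x$count)
  } else if (!is.null(names(x))) {
    len <- as.numeric(names(x)); cnt <- as.numeric(x)
  } else {
    tab <- table(x)
    len <- as.numeric(names(tab)); cnt <- as.numeric(tab)
  }
  if (length(len) == 0L || sum(cnt) == 0)
    stop("empty length multiset", call. = FALSE)
  if (any(cnt < 0) || any(cnt != floor(cnt)))
    stop("counts must be non-negative integers", call. = FALSE)
  keep <- cnt > 0
  len <- len[keep]; cnt <- cnt[keep]
  o <- order(len)
  list(len = len[o], count = cnt[o])
}
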