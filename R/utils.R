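# Internal helpers shared across modules.

# round-half-up; R's round() is banker's rounding which would split quota
# ties unpredictably across platforms
round_half_up <- function(x) floor(x + 0.5)

# deterministic branch count for a binary split: child count k, complement n-k
quota_count <- function(n, p) {
  k <- as.integer(round_half_up(n * p))
  max(0L, min(as.integer(n), k))
}

# largest-remainder apportionment of n into length(shares) integer counts
# summing exactly to n; ties broken by index order
largest_remainder <- function(n, shares) {
  stopifnot(n >= 0, all(shares >= 0))
  if (abs(sum(shares) - 1) > 1e-9) {
    stop("shares must sum to 1", call. = FALSE)
  }
  raw <- n * shares
  base <- floor(raw)
  rem <- raw - base
  short <- as.integer(n - sum(base))
  if (short > 0) {
    take <- order(rem, seq_along(rem), decreasing = c(TRUE, FALSE), method = "radix")[seq_len(short)]
    base[take] <- base[take] + 1
  }
  as.integer(base)
}

# completed calendar years between birth and ref (administrative age)
completed_years <- function(birth, ref) {
  b <- as.POSIXlt(birth)
  r <- as.POSIXlt(ref)
  age <- r$year - b$year
  before_birthday <- (r$mon < b$mon) | (r$mon == b$mon & r$mday < b$mday)
  as.integer(age - before_birthday)
}

# sample k elements from x without the length-1 surprise of sample()
sample_from <- function(x, k) {
  if (k <= 0L) return(x[0])
  x[sample.int(length(x), k)]
}

# uniform integer draws on [lo, hi], vectorised over lo/hi
runif_int <- function(n, lo, hi) {
  stopifnot(all(hi >= lo))
  as.integer(lo + floor(stats::runif(n) * (hi - lo + 1)))
}

`%||%` <- function(x, y) if (is.null(x)) y else x
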