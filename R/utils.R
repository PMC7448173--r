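# Internal helpers shared across modules.

#' Round half away from zero
#'
#' Fixed-precision rounding in which ties go up (.005 -> .01), the convention
#' used throughout the package for printed percentages. Base [round()] rounds
#' half to even, which disagrees with hand-computed report tables.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return `x` rounded to `digits` places, half away from zero.
#' @export
#' @examples
#' round_half_up(8.805, 2)  # 8.81
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Percentage of a total, rounded half-up to two decimals
#'
#' All summary tables in the package report shares as
#' `round_half_up(100 * n / total, 2)` with the raw numerator and denominator
#' kept alongside, so every printed percentage is recomputable.
#'
#' @param n numerator count(s).
#' @param total denominator count.
#' @param digits decimal places (default 2).
#' @return numeric vector of percentages; `NA` where `total` is 0.
#' @export
#' @examples
#' share_pct(10017, 44721)  # 22.40
share_pct <- function(n, total, digits = 2) {
  total <- rep_len(total, length(n))
  ifelse(!is.na(total) & total > 0, round_half_up(100 * n / total, digits),
         NA_real_)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# Count pairwise order inversions (i < j with x[i] > x[j]) by merge sort.
# Used for the time-regression diagnostic; equals the brute-force O(n^2) scan.
count_inversions <- function(x) {
  n <- length(x)
  if (n < 2L) return(0)
  rec <- function(v) {
    n <- length(v)
    if (n < 2L) return(list(inv = 0, v = v))
    mid <- n %/% 2L
    l <- rec(v[seq_len(mid)])
    r <- rec(v[(mid + 1L):n])
    a <- l$v; b <- r$v
    out <- numeric(n)
    i <- 1L; j <- 1L; k <- 1L; inv <- l$inv + r$inv
    na <- length(a); nb <- length(b)
    while (i <= na && j <= nb) {
      if (a[i] <= b[j]) {
        out[k] <- a[i]; i <- i + 1L
      } else {
        out[k] <- b[j]; j <- j + 1L
        inv <- inv + (na - i + 1L)
      }
      k <- k + 1L
    }
    if (i <= na) out[k:n] <- a[i:na]
    if (j <= nb) out[k:n] <- b[j:nb]
    list(inv = inv, v = out)
  }
  rec(as.numeric(x))$inv
}

# Run code with a private RNG stream, restoring the caller's .Random.seed.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
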