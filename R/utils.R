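#' @keywords internal
"_PACKAGE"

#' @importFrom methods as is
#' @importFrom Matrix Diagonal readMM writeMM
#' @importFrom stats median rnbinom rlnorm runif cor setNames
#' @importFrom utils read.delim read.csv write.table head
NULL

# Stable 32-bit sub-seed from a base seed and a string key. Keeps every
# derived seed in [0, 2^31-2] so set.seed() never overflows.
derive_seed <- function(seed, key) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- 0
  for (cp in utf8ToInt(as.character(key))) {
    h <- (h * 31 + cp) %% 2147483647
  }
  as.integer((abs(seed) * 1000003 + h) %% 2147483647)
}

# Run `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is restored afterwards. seed = NULL uses the ambient stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

#' Largest-remainder apportionment of fractions into integer counts
#'
#' Rounds a vector of non-negative fractions summing to 1 into integer
#' counts summing exactly to `total`: each fraction is multiplied by
#' `total` and floored, then the remaining units are given to the entries
#' with the largest fractional remainders, ties broken by earliest
#' position.
#'
#' @param fractions named numeric vector, non-negative, summing to 1
#'   (within 1e-9).
#' @param total positive integer, the number of cells to apportion
#'   (default 500, the fixed mixture size).
#' @return integer vector, same names and length as `fractions`, summing
#'   to `total`.
#' @examples
#' fractions_to_counts(c(a = 0.5, b = 0.3, c = 0.2))
#' fractions_to_counts(c(a = 0.333, b = 0.333, c = 0.334))
#' @export
fractions_to_counts <- function(fractions, total = 500L) {
  if (any(fractions < 0)) stop("fractions must be non-negative")
  if (abs(sum(fractions) - 1) > 1e-9) stop("fractions must sum to 1")
  if (total <= 0) stop("total must be positive")
  raw <- fractions * total
  counts <- floor(raw + 1e-12)
  rem <- raw - counts
  short <- as.integer(round(total - sum(counts)))
  if (short > 0) {
    take <- order(-rem, seq_along(rem))[seq_len(short)]
    counts[take] <- counts[take] + 1
  }
  out <- as.integer(counts)
  names(out) <- names(fractions)
  stopifnot(sum(out) == total)
  out
}
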