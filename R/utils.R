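# Internal helpers shared across modules.

#' Round half away from zero
#'
#' Base R `round()` rounds half to even; registry reports conventionally
#' round half up (56.25 -> 56.3), so report formatting uses this variant.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @keywords internal
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Percentage as printed in demographic tables: 100 * num / den, half-up, 1 dp.
pct_1dp <- function(num, den) round_half_up(100 * num / den, 1)

# Derive a stream of child seeds from one user seed, kept inside 32-bit range.
child_seeds <- function(seed, n) {
  (as.integer(seed) + 1013L * seq_len(n)) %% .Machine$integer.max
}

# Evaluate `expr` under a locally-set RNG seed, restoring the caller's RNG.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed) %% .Machine$integer.max)
  expr
}

# Timestamp parsing/formatting: everything internal is POSIXct UTC.
# Unparseable strings become NA (callers report them with row indices).
parse_ts <- function(x) {
  if (inherits(x, "POSIXct")) {
    attr(x, "tzone") <- "UTC"
    return(x)
  }
  x <- as.character(x)
  out <- as.POSIXct(strptime(x, "%Y-%m-%dT%H:%M:%S", tz = "UTC"), tz = "UTC")
  for (fmt in c("%Y-%m-%d %H:%M:%S", "%Y-%m-%d")) {
    miss <- is.na(out) & !is.na(x)
    if (!any(miss)) break
    out[miss] <- as.POSIXct(strptime(x[miss], fmt, tz = "UTC"), tz = "UTC")
  }
  out
}

format_ts <- function(x) format(x, "%Y-%m-%dT%H:%M:%S", tz = "UTC")

stopf <- function(fmt, ...) abort(sprintf(fmt, ...))
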