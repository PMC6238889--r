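#' @keywords internal
"_PACKAGE"

#' @importFrom stats approx dnorm pnorm qnorm qgamma rnorm rt runif pt sd
#' @importFrom utils read.csv write.csv packageVersion
#' @importFrom graphics plot abline axis legend lines mtext par
NULL

# minutes-since-midnight grid the whole package works on: 00:00 .. 23:45
GRID_STEP <- 15
GRID_N <- 96L

#' The fixed 15-minute time grid
#'
#' All curves in the package live on a fixed grid of 96 time points spanning
#' one day: 0, 15, ..., 1425 minutes since midnight.
#'
#' @return Integer vector of 96 minutes-since-midnight values.
#' @export
#' @examples
#' head(glucose_grid())
glucose_grid <- function() {
  seq(0L, 1425L, by = GRID_STEP)
}

stopf <- function(fmt, ..., class = "glywalk_error") {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "error", "condition")))
}

# evaluate `code` under a temporary RNG state seeded with `seed`,
# restoring the caller's .Random.seed afterwards
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# derive a sub-seed from a master seed so each module consumes an
# independent stream; kept below 2^31 - 1
fanout_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + k * 1000003) %% 2147483647)
}

# inverse-CDF sampler for a normal truncated to [lo, hi]
rtruncnorm <- function(n, mean, sd, lo, hi) {
  plo <- pnorm(lo, mean, sd)
  phi <- pnorm(hi, mean, sd)
  qnorm(runif(n, plo, phi), mean, sd)
}

# analytic mean/sd of the truncated normal above (moment targets for tests)
truncnorm_moments <- function(mean, sd, lo, hi) {
  a <- (lo - mean) / sd
  b <- (hi - mean) / sd
  z <- pnorm(b) - pnorm(a)
  d <- (dnorm(a) - dnorm(b)) / z
  m <- mean + sd * d
  v <- sd^2 * (1 + (a * dnorm(a) - b * dnorm(b)) / z - d^2)
  c(mean = m, sd = sqrt(v))
}
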