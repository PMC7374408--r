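#' @keywords internal
"_PACKAGE"

#' @import methods
#' @importFrom stats cor.test prcomp pnorm qnorm rnorm runif sd shapiro.test
#'   t.test wilcox.test dnorm setNames complete.cases
#' @importFrom utils head read.csv write.csv
NULL

# Number of samples per time-normalised gait cycle (0..100% inclusive).
GAIT_SAMPLES <- 101L

#' Deterministic sub-stream seed derived from a master seed and a label
#'
#' Each stochastic component of the cohort generator draws from its own
#' sub-stream so that, e.g., adding a variable to the registry does not
#' perturb the draws of earlier variables. The sub-stream seed is a simple
#' 31-bit hash of the master seed and a component label.
#'
#' @param seed master integer seed.
#' @param label character scalar naming the component.
#' @return an integer seed in `[0, 2^31 - 1)`.
#' @keywords internal
substreamSeed <- function(seed, label) {
  stopifnot(length(seed) == 1L, is.finite(seed))
  h <- as.double(seed %% 2147483647)
  for (code in utf8ToInt(as.character(label))) {
    h <- (h * 131 + code) %% 2147483647
  }
  as.integer(h)
}

# Draws from a normal truncated to [lower, upper] by inverse-CDF sampling.
rtruncnorm <- function(n, mean, sd, lower, upper) {
  if (sd <= 0) {
    return(rep(pmin(pmax(mean, lower), upper), n))
  }
  plo <- pnorm(lower, mean, sd)
  phi <- pnorm(upper, mean, sd)
  qnorm(runif(n, plo, phi), mean, sd)
}

# Variance of a normal(mean, sd) truncated to [lower, upper] (closed form).
truncnormVar <- function(mean, sd, lower, upper) {
  a <- (lower - mean) / sd
  b <- (upper - mean) / sd
  Z <- pnorm(b) - pnorm(a)
  da <- dnorm(a)
  db <- dnorm(b)
  sd^2 * (1 + (a * da - b * db) / Z - ((da - db) / Z)^2)
}

#' Orthonormal smooth mode basis over the gait-cycle grid
#'
#' Low-order cosine shapes `cos(m * pi * t / 100)`, `m = 1..n_modes`,
#' orthonormalised by QR over the 101-point grid so that the columns are
#' exactly orthonormal under the ordinary dot product. Column signs are fixed
#' so the first sample of each mode is positive.
#'
#' @param n_modes number of mode shapes.
#' @return a `101 x n_modes` matrix with orthonormal columns.
#' @export
modeBasis <- function(n_modes = 3L) {
  t <- seq(0, 100, length.out = GAIT_SAMPLES)
  raw <- vapply(seq_len(n_modes), function(m) cos(m * pi * t / 100),
                numeric(GAIT_SAMPLES))
  q <- qr.Q(qr(raw))
  sgn <- ifelse(q[1L, ] >= 0, 1, -1)
  sweep(q, 2L, sgn, `*`)
}

#' Stable hash of a configuration object
#'
#' Serialises the object to canonical JSON and returns its MD5 digest. Used
#' to stamp every artifact written by the pipeline so that models and reports
#' produced under different configurations cannot be silently mixed.
#'
#' @param x an R object (typically a [pipelineConfig()] list).
#' @return a character MD5 hash.
#' @export
configHash <- function(x) {
  if (is.list(x)) x <- lapply(unclass(x), function(el) unclass(el))
  json <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, null = "null")
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  writeLines(as.character(json), tf)
  unname(tools::md5sum(tf))
}
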