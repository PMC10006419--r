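#' @useDynLib aviland, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats AIC coef confint cor cor.test lm logLik median p.adjust
#'   pnorm prcomp predict qnorm quantile rbinom rgamma rnorm runif sd setNames
#'   shapiro.test cmdscale complete.cases
#' @importFrom utils head read.csv write.csv
"_PACKAGE"

# Shannon entropy (nats) of a count or proportion vector; zero-mass classes
# are dropped, as required for 0 * log(0) = 0.
shannon_entropy <- function(p) {
  p <- p[p > 0]
  if (length(p) == 0L) return(NA_real_)
  p <- p / sum(p)
  -sum(p * log(p))
}

# Deterministic per-stage substreams derived from one master seed, so that a
# stage can be regenerated without replaying the whole pipeline. Offsets are
# fixed per stage name; the combination stays within 32-bit integer range.
substream_seed <- function(seed, stage) {
  offsets <- c(landcover = 1L, sea = 2L, npp = 3L, covariates = 4L,
               pool = 5L, occupancy = 6L, report = 7L)
  if (!stage %in% names(offsets)) stop("unknown substream stage: ", stage)
  as.integer((as.numeric(seed) * 48271 + offsets[[stage]] * 7919) %% 2147483629)
}

with_substream <- function(seed, stage, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(substream_seed(seed, stage))
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  force(expr)
}

# Smooth standardized Gaussian random field on an ny x nx lattice, built by
# separable kernel smoothing of white noise.
gaussian_field <- function(ny, nx, range = 3) {
  z <- matrix(rnorm(ny * nx), ny, nx)
  smoother <- function(n) {
    d <- abs(outer(seq_len(n), seq_len(n), "-"))
    K <- exp(-(d^2) / (2 * range^2))
    K / rowSums(K)
  }
  f <- smoother(ny) %*% z %*% t(smoother(nx))
  (f - mean(f)) / stats::sd(as.vector(f))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
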