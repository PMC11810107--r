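# Internal helpers shared across modules.

#' Multiplicative lognormal noise factors with unit mean
#'
#' @param n number of draws
#' @param cv coefficient of variation; `cv <= 0` returns exact ones
#' @return numeric vector of positive factors with E[X] = 1
#' @keywords internal
rlnoise <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  s <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -s^2 / 2, sdlog = s)
}

#' Gamma-distributed phase durations
#'
#' @param n number of draws
#' @param mean_h mean duration (h)
#' @param cv coefficient of variation; `cv <= 0` gives a deterministic timer
#' @keywords internal
rdur <- function(n, mean_h, cv) {
  if (cv <= 0) return(rep(mean_h, n))
  shape <- 1 / cv^2
  stats::rgamma(n, shape = shape, scale = mean_h / shape)
}

# Deterministic 32-bit sub-seed from a base seed and a label, so that every
# simulated arm/well gets its own reproducible stream.
derive_seed <- function(seed, label) {
  codes <- utf8ToInt(as.character(label))
  h <- as.double(seed %% 2147483647L)
  for (c in codes) h <- (h * 31 + c) %% 2147483647
  as.integer(h)
}

# Centered moving average; ends use shrinking symmetric windows.
moving_average <- function(x, window) {
  n <- length(x)
  if (window <= 1 || n < 2) return(x)
  half <- floor(window / 2)
  out <- numeric(n)
  for (i in seq_len(n)) {
    lo <- max(1, i - half)
    hi <- min(n, i + half)
    out[i] <- mean(x[lo:hi])
  }
  out
}

# Central-difference derivative with one-sided differences at the ends.
central_diff <- function(y, x) {
  n <- length(y)
  stopifnot(n == length(x), n >= 2)
  d <- numeric(n)
  d[1] <- (y[2] - y[1]) / (x[2] - x[1])
  d[n] <- (y[n] - y[n - 1]) / (x[n] - x[n - 1])
  if (n > 2) {
    i <- 2:(n - 1)
    d[i] <- (y[i + 1] - y[i - 1]) / (x[i + 1] - x[i - 1])
  }
  d
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_field <- function(msg) stop(msg, call. = FALSE)
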