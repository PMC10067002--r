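# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @keywords internal
#' Derive a reproducible 32-bit substream seed from a master seed and a
#' stage name, so each pipeline stage has its own named random stream.
substream_seed <- function(master, name) {
  stopifnot(is.numeric(master), length(master) == 1L)
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  as.integer((abs(as.numeric(master)) * 1009 + h * 7919) %% 2147483587L)
}

# Inverse-CDF draw from a normal truncated to [lo, hi]; exact, vectorized.
rtruncnorm <- function(n, mean, sd, lo, hi) {
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  u <- stats::runif(n, plo, phi)
  pmin(pmax(stats::qnorm(u, mean, sd), lo), hi)
}

clip01 <- function(x) pmin(pmax(x, 0), 1)

# standardize, degenerating gracefully for tiny or constant inputs
zscale <- function(x) {
  if (length(x) < 2L) return(rep(0, length(x)))
  s <- stats::sd(x)
  if (!is.finite(s) || s < 1e-12) return(rep(0, length(x)))
  (x - mean(x)) / s
}

# Decile label (1..10) from empirical quantile breaks; ties in the break
# vector collapse adjacent bins so the same rule can be shared between the
# generator and the elasticity estimator.
decile_of <- function(x) {
  br <- unique(stats::quantile(x, probs = seq(0, 1, 0.1), type = 1, names = FALSE))
  findInterval(x, br[-c(1L, length(br))]) + 1L
}

stop_hv <- function(...) stop(sprintf(...), call. = FALSE)

assert_fraction <- function(x, name, closed_lo = FALSE, closed_hi = FALSE) {
  lo_ok <- if (closed_lo) x >= 0 else x > 0
  hi_ok <- if (closed_hi) x <= 1 else x < 1
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || !lo_ok || !hi_ok)
    stop_hv("`%s` must be a fraction in %s0,1%s, got %s", name,
            if (closed_lo) "[" else "(", if (closed_hi) "]" else ")",
            format(x))
  invisible(x)
}
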