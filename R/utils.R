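# Internal numerical helpers shared across modules.

# u * log(u) with the convention 0 * log 0 = 0.
xlogx <- function(u) {
  out <- numeric(length(u))
  pos <- u > 0
  out[pos] <- u[pos] * log(u[pos])
  out
}

# atanh written out as 0.5 * log((1 + z) / (1 - z)).
atanh_log <- function(z) 0.5 * log((1 + z) / (1 - z))

# Plain bisection for a continuous f with f(lo), f(hi) of opposite sign.
# Stops when the bracket is narrower than xtol or |f| < ftol.
bisect <- function(f, lo, hi, xtol = 1e-12, ftol = 0, max_iter = 200L) {
  flo <- f(lo)
  fhi <- f(hi)
  if (flo == 0) return(lo)
  if (fhi == 0) return(hi)
  if (sign(flo) == sign(fhi)) {
    stop("bisection requires a sign change on the bracket", call. = FALSE)
  }
  for (i in seq_len(max_iter)) {
    mid <- 0.5 * (lo + hi)
    fmid <- f(mid)
    if (abs(fmid) <= ftol || (hi - lo) / 2 < xtol) return(mid)
    if (sign(fmid) == sign(flo)) {
      lo <- mid
      flo <- fmid
    } else {
      hi <- mid
    }
  }
  0.5 * (lo + hi)
}

# Midpoint-rule mass of values on an equally spaced grid; falls back to the
# trapezoid for grids whose spacing is not uniform.
grid_mass <- function(grid, values) {
  h <- diff(grid)
  if (max(h) - min(h) < 1e-9 * mean(h)) {
    mean(h) * sum(values)
  } else {
    pracma::trapz(grid, values)
  }
}

stopifnot_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  }
  invisible(x)
}
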