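#' Informational energy decomposition
#'
#' Writing the log of the transformed density as
#' log rho = log sin(pi F) - H_B(F) + log f + C with C = log(24/(pi e))
#' splits it into a *modulation energy* E_mod = -log sin(pi F) (the effort
#' to maintain order, diverging at the boundaries) and a *structural
#' energy* E_str = H_B(F) - log f (the disorder component). The total
#' energy E_tot = E_mod + E_str satisfies E_tot = -log rho + C wherever
#' rho > 0.
#'
#' @param dist A `distspec`.
#' @param grid Strictly increasing points interior to the support
#'   (0 < F < 1 required; energies diverge at the boundary).
#' @return An object of class `energy_profile`: list with `grid`,
#'   `modulation`, `structural`, `total`, `constant` (= log(24/(pi e))).
#' @examples
#' ep <- energy_profile(dist_uniform(0, 1), c(0.25, 0.5, 0.75))
#' ep$modulation[2]  # 0: -log sin(pi/2)
#' @export
energy_profile <- function(dist, grid) {
  stopifnot(inherits(dist, "distspec"))
  if (is.unsorted(grid, strictly = TRUE)) {
    stop("grid must be strictly increasing", call. = FALSE)
  }
  Fv <- dist$cdf(grid)
  if (any(Fv <= 0 | Fv >= 1)) {
    stop("energies diverge at the boundary: grid must satisfy 0 < F < 1",
         call. = FALSE)
  }
  fv <- dist$pdf(grid)
  modulation <- -log(sin(pi * Fv))
  structural <- binary_entropy(Fv) - log(fv)
  structure(
    list(grid = grid, modulation = modulation, structural = structural,
         total = modulation + structural, constant = log(DRGT_CONST),
         source = dist),
    class = "energy_profile"
  )
}

#' @export
print.energy_profile <- function(x, ...) {
  cat(sprintf("<energy_profile> %s base, %d points on [%g, %g]\n",
              x$source$name, length(x$grid), x$grid[1L],
              x$grid[length(x$grid)]))
  cat(sprintf("  C = log(24/(pi e)) = %.6f\n", x$constant))
  cat(sprintf("  total energy: min %.4f at x = %.4f\n",
              min(x$total), x$grid[which.min(x$total)]))
  invisible(x)
}

#' @export
as.data.frame.energy_profile <- function(x, ...) {
  data.frame(x = x$grid, modulation = x$modulation,
             structural = x$structural, total = x$total)
}

#' @rdname energy_profile
#' @param x An `energy_profile`.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.energy_profile <- function(x, ...) {
  graphics::matplot(x$grid, cbind(x$total, x$structural, x$modulation),
                    type = "l", lty = c(1, 2, 3), col = 1,
                    xlab = "x", ylab = "energy", ...)
  graphics::legend("top", c("total", "structural", "modulation"),
                   lty = c(1, 2, 3), bty = "n")
  invisible(x)
}

#' Export an energy profile as tab-separated text
#'
#' Four columns (x, modulation, structural, total) with a header row;
#' infinite values are serialised as `inf`.
#'
#' @param profile An `energy_profile`.
#' @param path Output file path.
#' @export
export_energy_profile <- function(profile, path) {
  df <- as.data.frame(profile)
  fmt <- function(v) ifelse(is.infinite(v), ifelse(v > 0, "inf", "-inf"),
                            format(v, digits = 15))
  out <- data.frame(x = fmt(df$x), modulation = fmt(df$modulation),
                    structural = fmt(df$structural), total = fmt(df$total))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Closed-form energy derivatives for the uniform base
#'
#' For the uniform distribution on (0, 1) the total energy is
#' E_tot(x) = -log sin(pi x) + H_B(x), whose derivative is
#' -pi cot(pi x) + 2 atanh(1 - 2x) (antisymmetric about 0.5, with the lone
#' root at the median) and whose second derivative is
#' pi^2 csc^2(pi x) + 1/(x(1-x)) (everywhere positive, diverging at both
#' boundaries, equal to pi^2 + 4 at x = 0.5 -- the equilibrium is an
#' energy minimum).
#'
#' @param x Points in (0, 1).
#' @return Derivative (resp. curvature) values.
#' @export
total_energy_derivative_uniform <- function(x) {
  if (any(!is.finite(x)) || any(x <= 0 | x >= 1)) {
    stop("x must lie strictly inside (0, 1)", call. = FALSE)
  }
  -pi / tan(pi * x) + 2 * atanh_log(1 - 2 * x)
}

#' @rdname total_energy_derivative_uniform
#' @export
total_energy_second_derivative_uniform <- function(x) {
  if (any(!is.finite(x)) || any(x <= 0 | x >= 1)) {
    stop("x must lie strictly inside (0, 1)", call. = FALSE)
  }
  pi^2 / sin(pi * x)^2 + 1 / (x * (1 - x))
}

#' Equilibria of the total informational energy
#'
#' Finds interior stationary points of E_tot for an arbitrary base: the
#' energy is evaluated through -log rho + C on an interior grid, its
#' central-difference derivative is scanned for sign changes, and each
#' bracket is refined by bisection. Equilibria are classified by the sign
#' of the second derivative (closed form for the uniform(0, 1) base,
#' central differences otherwise).
#'
#' @param dist A `distspec`.
#' @param n_points Scan grid size (default 2048).
#' @return A data frame with columns `location`, `first_derivative`,
#'   `second_derivative`, `classification` (`"minimum"` or `"maximum"`);
#'   zero rows when no sign change is found.
#' @export
find_equilibria <- function(dist, n_points = 2048L) {
  stopifnot(inherits(dist, "distspec"))
  grid <- evaluation_grid(dist, n_points)
  h <- diff(grid[1:2])
  is_unif01 <- dist$name == "uniform" &&
    isTRUE(all.equal(unname(dist$params), c(0, 1)))
  etot <- function(x) -log(drgt_eval(dist, x, "sine")) + log(DRGT_CONST)
  dE <- if (is_unif01) {
    total_energy_derivative_uniform
  } else {
    function(x) (etot(x + h) - etot(x - h)) / (2 * h)
  }
  inner <- grid[grid - h > dist$support[1L] & grid + h < dist$support[2L]]
  g <- dE(inner)
  flips <- which(g[-1] * g[-length(g)] < 0)
  if (!length(flips)) {
    return(data.frame(location = numeric(0), first_derivative = numeric(0),
                      second_derivative = numeric(0),
                      classification = character(0)))
  }
  d2E <- if (is_unif01) {
    total_energy_second_derivative_uniform
  } else {
    function(x) (etot(x + h) - 2 * etot(x) + etot(x - h)) / h^2
  }
  rows <- lapply(flips, function(i) {
    x_star <- bisect(dE, inner[i], inner[i + 1L], xtol = 1e-13)
    curv <- d2E(x_star)
    data.frame(location = x_star, first_derivative = dE(x_star),
               second_derivative = curv,
               classification = if (curv > 0) "minimum" else "maximum")
  })
  do.call(rbind, rows)
}
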