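#' Identity suite for the derangetropy transform
#'
#' Recomputes the package's core identities and reports each against its
#' tolerance: the unit-mass quadrature for the five analytic families, the
#' equivalence of the sine, entropy and Gamma forms, the mode-equals-median
#' property for the symmetric families, the normalising integral of
#' sin(pi z) z^z (1-z)^(1-z) against pi e/24, the equilibrium curvature
#' pi^2 + 4 of the uniform total energy, the recovered harmonic
#' coefficients C1 = 24/(pi e), C2 = 0, and the initial slope 24/e.
#'
#' @return A data frame with columns `check`, `value`, `target`,
#'   `tolerance`, `pass`.
#' @export
drgt_validate <- function() {
  fams <- list(
    uniform = dist_uniform(0, 1), normal = dist_normal(0, 1),
    exponential = dist_exponential(1), semicircle = dist_semicircle(1),
    arcsin = dist_arcsine(0, 1))
  rows <- list()
  add <- function(check, value, target, tol) {
    rows[[length(rows) + 1L]] <<- data.frame(
      check = check, value = value, target = target, tolerance = tol,
      pass = abs(value - target) <= tol)
  }
  for (nm in names(fams)) {
    add(paste0("unit_mass_", nm), normalization_check(fams[[nm]]), 1, 1e-6)
  }
  for (nm in names(fams)) {
    grid <- evaluation_grid(fams[[nm]], 2048L)
    a <- drgt(fams[[nm]], grid, "sine")
    b <- drgt(fams[[nm]], grid, "entropy")
    cc <- drgt(fams[[nm]], grid, "gamma")
    rel <- max(abs(a - b) / pmax(a, 1e-300), abs(a - cc) / pmax(a, 1e-300))
    add(paste0("three_form_equivalence_", nm), rel, 0, 1e-10)
  }
  for (nm in c("uniform", "normal", "semicircle")) {
    add(paste0("mode_at_median_", nm),
        mode_of_derangetropy(fams[[nm]]), fams[[nm]]$median, 1e-6)
  }
  kern <- stats::integrate(function(z) sin(pi * z) * z^z * (1 - z)^(1 - z),
                           0, 1, rel.tol = 1e-12)$value
  add("normalising_integral", kern, pi * exp(1) / 24, 1e-8)
  add("equilibrium_curvature",
      total_energy_second_derivative_uniform(0.5), pi^2 + 4, 1e-9)
  rep <- ode_report(dist_uniform(0, 1))
  add("ode_max_residual", rep$max_abs_residual, 0, 1e-8)
  add("C1", rep$C1, DRGT_CONST, 1e-6)
  add("C2", rep$C2, 0, 1e-6)
  add("initial_slope", rep$initial_slope, 24 / exp(1),
      1e-3 * 24 / exp(1))
  do.call(rbind, rows)
}
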