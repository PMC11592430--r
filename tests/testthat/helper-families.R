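# The five analytic families under study, at their reference parameters.
reference_families <- function() {
  list(
    uniform     = dist_uniform(0, 1),
    normal      = dist_normal(0, 1),
    exponential = dist_exponential(1),
    semicircle  = dist_semicircle(1),
    arcsin      = dist_arcsine(0, 1)
  )
}

# Midpoint/trapezoid mass of a fitted curve (equispaced grids).
curve_mass <- function(curve) {
  mean(diff(curve$grid)) * sum(curve$values)
}

# Build a synthetic "curve" object with planted values on an F-grid, for
# testing decompositions independently of the fitting path.
planted_curve <- function(F, values, level = 1L) {
  structure(
    list(grid = F, values = values,
         cdf_values = pmin(pracma::cumtrapz(F, values)[, 1L], 1),
         level = level, source = dist_uniform(0, 1)),
    class = "derangetropy"
  )
}
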