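#' Hertz contact force for a spherical indenter
#'
#' Sphere-on-elastic-half-space contact law
#' `F = (4/3) * E / (1 - nu^2) * sqrt(R) * delta^(3/2)` for indentation
#' `delta >= 0` (zero before contact). Linear in the Young's modulus E.
#'
#' @param delta_um indentation depth(s), micrometres; negative values give 0.
#' @param E_pa Young's modulus, Pa.
#' @param nu Poisson ratio, in `[0, 0.5]`.
#' @param R_um indenter tip radius, micrometres.
#' @return load in newtons.
#' @export
hertz_force <- function(delta_um, E_pa, nu = 0.5, R_um = 25) {
  if (E_pa <= 0 || R_um <= 0) oc_abort("E and R must be > 0", "invalid_input")
  if (nu < 0 || nu > 0.5 + 1e-12)
    oc_abort("`nu` must be in [0, 0.5]", "invalid_input")
  d <- pmax(delta_um, 0) * 1e-6
  (4 / 3) * (E_pa / (1 - nu^2)) * sqrt(R_um * 1e-6) * d^1.5
}

#' Parameters of a synthetic load-indentation curve
#'
#' Defaults mirror the nanoindenter probe used on-chip: ~0.5 N/m cantilever
#' and ~25 um spherical tip. Indentation is the recorded abscissa directly
#' (cantilever compliance is handled upstream by the instrument).
#'
#' @param E_pa true Young's modulus, Pa (> 0).
#' @param nu Poisson ratio.
#' @param R_um tip radius, um.
#' @param cantilever_stiffness N/m (metadata only; not used by the forward
#'   model).
#' @param contact_offset_um position of the contact point along the recorded
#'   axis: samples before it are pre-contact baseline.
#' @param max_indentation_um indentation depth reached past contact; must
#'   exceed the upper fit-window bound.
#' @param step_um sampling step.
#' @param noise_sd_n additive Gaussian load noise, newtons.
#' @return a validated list of class `curve_params`.
#' @export
curve_params <- function(E_pa = 15e3, nu = 0.5, R_um = 25,
                         cantilever_stiffness = 0.5,
                         contact_offset_um = 2, max_indentation_um = 5,
                         step_um = 0.02, noise_sd_n = 0) {
  if (E_pa <= 0) oc_abort("`E_pa` must be > 0", "invalid_input")
  if (nu < 0 || nu > 0.5 + 1e-12)
    oc_abort("`nu` must be in [0, 0.5]", "invalid_input")
  if (R_um <= 0 || step_um <= 0 || max_indentation_um <= 0)
    oc_abort("geometry parameters must be > 0", "invalid_input")
  structure(list(E_pa = E_pa, nu = nu, R_um = R_um,
                 cantilever_stiffness = cantilever_stiffness,
                 contact_offset_um = contact_offset_um,
                 max_indentation_um = max_indentation_um,
                 step_um = step_um, noise_sd_n = noise_sd_n),
            class = c("curve_params", "list"))
}

#' Generate one synthetic load-indentation curve
#'
#' Samples the Hertz forward model from a pre-contact baseline through the
#' maximum indentation, with optional additive Gaussian load noise. The true
#' parameters are attached as an attribute for validation use only.
#'
#' @param c_par a [curve_params()].
#' @param seed RNG seed (only noise is stochastic).
#' @param position optional `(x, y)` um position on the sample.
#' @return an [indentation_curve()] with attribute `truth`.
#' @export
generate_indentation_curve <- function(c_par = curve_params(), seed = 1L,
                                       position = NULL) {
  set.seed(seed)
  pos_um <- seq(0, c_par$contact_offset_um + c_par$max_indentation_um,
                by = c_par$step_um)
  load <- hertz_force(pos_um - c_par$contact_offset_um, c_par$E_pa,
                      c_par$nu, c_par$R_um)
  if (c_par$noise_sd_n > 0)
    load <- load + rnorm(length(load), 0, c_par$noise_sd_n)
  crv <- indentation_curve(pos_um, load, tip_radius_um = c_par$R_um,
                           cantilever_stiffness = c_par$cantilever_stiffness,
                           position = position)
  attr(crv, "truth") <- c_par
  crv
}

#' Generate a spatial array of synthetic indentation curves
#'
#' One curve per entry of `E_grid`, on a regular grid of positions; used to
#' validate elasticity array maps (e.g. a two-level bone/cartilage pattern).
#'
#' @param E_grid matrix of true moduli (Pa); rows index y, columns x.
#' @param spacing_um grid pitch.
#' @param base_params a [curve_params()] supplying everything but `E_pa`.
#' @param seed RNG seed; each curve gets an independent noise draw.
#' @return list of [indentation_curve()]s with positions set.
#' @export
generate_indentation_array <- function(E_grid, spacing_um = 100,
                                       base_params = curve_params(),
                                       seed = 1L) {
  set.seed(seed)
  curves <- vector("list", length(E_grid))
  k <- 0L
  for (i in seq_len(nrow(E_grid)))
    for (j in seq_len(ncol(E_grid))) {
      k <- k + 1L
      cp <- base_params
      cp$E_pa <- E_grid[i, j]
      curves[[k]] <- generate_indentation_curve(
        cp, seed = sample.int(.Machine$integer.max, 1),
        position = c((j - 1) * spacing_um, (i - 1) * spacing_um))
    }
  curves
}
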