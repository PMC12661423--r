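# Component property polynomials (Choi & Okos 1986), temperature in deg C.
# Fibre and sugar share the complex-carbohydrate density polynomial; fibre keeps
# its own specific-heat polynomial.
.choi_okos_density <- list(
  water        = c(997.18, 3.1439e-3, -3.7574e-3),
  protein      = c(1329.9, -0.5184, 0),
  carbohydrate = c(1599.1, -0.31046, 0),
  fibre        = c(1599.1, -0.31046, 0),
  sugar        = c(1599.1, -0.31046, 0),
  ash          = c(2423.8, -0.28063, 0),
  oil          = c(925.59, -0.41757, 0)
)

.choi_okos_cp <- list(
  water        = c(4176.2, -9.0864e-2, 5.4731e-3),
  protein      = c(2008.2, 1.2089, -1.3129e-3),
  carbohydrate = c(1548.8, 1.9625, -5.9399e-3),
  fibre        = c(1845.9, 1.8306, -4.6509e-3),
  sugar        = c(1548.8, 1.9625, -5.9399e-3),
  ash          = c(1092.6, 1.8896, -3.6817e-3),
  oil          = c(1984.2, 1.4733, -4.8008e-3)
)

.component_names <- names(.choi_okos_density)
.hygroscopic_classes <- c("protein", "carbohydrate", "fibre", "sugar", "ash")

.poly2 <- function(coefs, t_c) coefs[1] + coefs[2] * t_c + coefs[3] * t_c^2

.check_temp <- function(T_K, lo = 270, hi = 360, what = "T") {
  if (any(!is.finite(T_K)) || any(T_K < lo) || any(T_K > hi)) {
    abort(sprintf("`%s` must lie in [%g, %g] K.", what, lo, hi))
  }
  invisible(T_K)
}

#' Density of a seed component
#'
#' Evaluates the embedded Choi-Okos temperature polynomials for the density of
#' water, oil and the hygroscopic solid classes (protein, carbohydrate, fibre,
#' sugar, ash). Fibre and sugar are treated with the complex-carbohydrate
#' polynomial.
#'
#' @param component One of `"water"`, `"protein"`, `"carbohydrate"`, `"fibre"`,
#'   `"sugar"`, `"ash"`, `"oil"`.
#' @param T_K Temperature in Kelvin, in \[270, 360\].
#' @return Density in kg m^-3 (vectorised over `T_K`).
#' @examples
#' component_density("water", 293.15)
#' @export
component_density <- function(component, T_K) {
  if (length(component) != 1L || !component %in% .component_names) {
    abort(sprintf(
      "Unknown component '%s'. Valid components: %s.",
      as.character(component)[1], paste(.component_names, collapse = ", ")
    ))
  }
  .check_temp(T_K)
  .poly2(.choi_okos_density[[component]], T_K - 273.15)
}

#' Specific heat capacity of a seed component
#'
#' Choi-Okos temperature polynomials for specific heat, J kg^-1 K^-1.
#'
#' @inheritParams component_density
#' @return Specific heat in J kg^-1 K^-1.
#' @export
component_heat_capacity <- function(component, T_K) {
  if (length(component) != 1L || !component %in% .component_names) {
    abort(sprintf(
      "Unknown component '%s'. Valid components: %s.",
      as.character(component)[1], paste(.component_names, collapse = ", ")
    ))
  }
  .check_temp(T_K)
  .poly2(.choi_okos_cp[[component]], T_K - 273.15)
}

#' Seed composition
#'
#' Builds a validated composition object from a water mass fraction and the
#' mass fractions of the dry-matter classes (which must sum to one). Oil is
#' inert to water sorption; protein, carbohydrate, fibre, sugar and ash form
#' the hygroscopic solid.
#'
#' @param y_w Mass fraction of water (wet basis) in \[0, 1).
#' @param oil,protein,carbohydrate,fibre,sugar,ash Mass fractions of the
#'   dry matter, summing to 1.
#' @return A `seed_composition` object (named list of total-mass fractions).
#' @examples
#' seed_composition(y_w = 0.367, oil = 0.35, protein = 0.28,
#'                  carbohydrate = 0.12, fibre = 0.15, sugar = 0.05, ash = 0.05)
#' @export
seed_composition <- function(y_w = 0, oil = 0, protein = 0, carbohydrate = 0,
                             fibre = 0, sugar = 0, ash = 0) {
  dry <- c(oil = oil, protein = protein, carbohydrate = carbohydrate,
           fibre = fibre, sugar = sugar, ash = ash)
  if (any(dry < 0) || any(dry > 1) || y_w < 0 || y_w >= 1) {
    abort("All mass fractions must lie in [0, 1] and `y_w` in [0, 1).")
  }
  if (abs(sum(dry) - 1) > 1e-9) {
    abort(sprintf("Dry-matter fractions must sum to 1 (got %.12f).", sum(dry)))
  }
  out <- c(list(y_w = y_w), as.list(dry * (1 - y_w)))
  names(out) <- c("y_w", paste0("y_", names(dry)))
  structure(out, dry_fractions = dry, class = "seed_composition")
}

#' @export
print.seed_composition <- function(x, ...) {
  cat("<seed_composition>\n")
  cat(sprintf("  y_w = %.4f; dry matter:", x$y_w))
  d <- attr(x, "dry_fractions")
  cat(paste0(" ", names(d), "=", signif(d, 3), collapse = ","), "\n")
  invisible(x)
}

#' Re-moisturise a composition
#'
#' Keeps the dry-matter recipe of `comp` and sets a new water fraction.
#'
#' @param comp A [seed_composition()].
#' @param y_w New wet-basis water mass fraction.
#' @export
set_moisture <- function(comp, y_w) {
  stopifnot(inherits(comp, "seed_composition"))
  d <- attr(comp, "dry_fractions")
  do.call(seed_composition, c(list(y_w = y_w), as.list(d)))
}

#' Default seed-material compositions
#'
#' Placeholder dry-matter compositions for whole cabbage seed, embryo and coat
#' material. The oil fractions (35 % of dry matter for whole seed/embryo, 15 %
#' for coat) follow the reported measurements; the split of the hygroscopic
#' classes is a documented substitute for unavailable proximate-analysis
#' tables and can be overridden through [seed_composition()].
#'
#' @param material `"whole"`, `"embryo"` or `"coat"`.
#' @param y_w Wet-basis water mass fraction (default: hydrated seed, 36.7 %).
#' @export
default_composition <- function(material = c("whole", "embryo", "coat"),
                                y_w = 0.367) {
  material <- match.arg(material)
  d <- switch(material,
    whole  = c(oil = 0.35, protein = 0.28, carbohydrate = 0.12,
               fibre = 0.15, sugar = 0.05, ash = 0.05),
    embryo = c(oil = 0.38, protein = 0.30, carbohydrate = 0.12,
               fibre = 0.10, sugar = 0.05, ash = 0.05),
    coat   = c(oil = 0.15, protein = 0.12, carbohydrate = 0.20,
               fibre = 0.43, sugar = 0.02, ash = 0.08)
  )
  do.call(seed_composition, c(list(y_w = y_w), as.list(d)))
}

# densities/heat capacities of all components at one temperature, as named
# vectors; the solver caches these because temperature moves slowly
.props_at <- function(T_K) {
  t_c <- T_K - 273.15
  list(
    rho = vapply(.choi_okos_density, .poly2, numeric(1), t_c = t_c),
    cp = vapply(.choi_okos_cp, .poly2, numeric(1), t_c = t_c)
  )
}

# fast internal kernel: volume fraction of water for a dry-matter recipe `d`
# (named vector) at water fractions y_w (vectorised). Oil excluded by default
# (sorption use); oil included gives the total water volume fraction used by
# the thermal closures. `props` short-circuits the polynomial evaluations.
.phi_w <- function(y_w, d, T_K, exclude_oil = TRUE, props = NULL) {
  if (is.null(props)) props <- .props_at(T_K)
  rho <- props$rho
  ys <- 1 - y_w
  num <- y_w / rho[["water"]]
  inv_s <- d[["protein"]] / rho[["protein"]] +
    d[["carbohydrate"]] / rho[["carbohydrate"]] +
    d[["fibre"]] / rho[["fibre"]] + d[["sugar"]] / rho[["sugar"]] +
    d[["ash"]] / rho[["ash"]]
  den <- num + ys * inv_s
  if (!exclude_oil) den <- den + ys * d[["oil"]] / rho[["oil"]]
  phi <- ifelse(den > 0, num / den, 0)
  phi[y_w <= 0] <- 0
  phi
}

#' Volume fraction of water, oil excluded
#'
#' Computes the water volume fraction entering the sorption isotherm. Oil does
#' not take part in water sorption, so it appears neither in the numerator nor
#' the denominator; only water and the hygroscopic solid classes count.
#'
#' @param comp A [seed_composition()].
#' @param T_K Temperature in Kelvin (densities are temperature dependent).
#' @param exclude_oil If `FALSE`, oil volume is included in the denominator,
#'   giving the total water volume fraction of the seed (used by the thermal
#'   closures, not by the isotherm).
#' @return Water volume fraction in \[0, 1\].
#' @export
water_volume_fraction <- function(comp, T_K, exclude_oil = TRUE) {
  stopifnot(inherits(comp, "seed_composition"))
  d <- attr(comp, "dry_fractions")
  if (comp$y_w <= 0) {
    if (sum(d[.hygroscopic_classes]) == 0) {
      inform("Dry matter is all oil and y_w = 0; water volume fraction is 0.")
    }
    return(0)
  }
  .phi_w(comp$y_w, d, T_K, exclude_oil = exclude_oil)
}

#' Physical constants and reference properties
#'
#' Bundles the constants used by the heat balance, the evaporative flux and
#' the isotherm: molar mass of water, gas constant, heat of vaporisation at
#' 0 deg C, vapour/liquid specific heats, enthalpy reference temperature,
#' thermal conductivities of water and dry solids, and the molar volume of
#' water. `lambda_w`/`lambda_s` are documented substitutes (not printed in the
#' source study); `nu_w` defaults to M_w / rho_w(298.15 K).
#'
#' @param M_w Molar mass of water, kg mol^-1.
#' @param R_gas Universal gas constant, J mol^-1 K^-1.
#' @param dH_evap0 Heat of vaporisation of water at 0 deg C, J kg^-1.
#' @param cp_v,cp_w Specific heats of water vapour and liquid water,
#'   J kg^-1 K^-1.
#' @param T0 Enthalpy reference temperature, K.
#' @param lambda_w,lambda_s Thermal conductivities of water and dry solids,
#'   W m^-1 K^-1.
#' @param nu_w Molar volume of water, m^3 mol^-1 (`NULL` computes it from
#'   `M_w` and the water density polynomial at 298.15 K).
#' @return A `material_constants` list.
#' @export
material_constants <- function(M_w = 0.0180153, R_gas = 8.314,
                               dH_evap0 = 2.501e6, cp_v = 1880, cp_w = 4187,
                               T0 = 273.15, lambda_w = 0.60, lambda_s = 0.20,
                               nu_w = NULL) {
  if (is.null(nu_w)) nu_w <- M_w / .poly2(.choi_okos_density$water, 25)
  out <- list(M_w = M_w, R_gas = R_gas, dH_evap0 = dH_evap0, cp_v = cp_v,
              cp_w = cp_w, T0 = T0, lambda_w = lambda_w, lambda_s = lambda_s,
              nu_w = nu_w)
  vals <- unlist(out)
  if (any(vals[setdiff(names(vals), "T0")] <= 0) || out$T0 <= 0) {
    abort("All material constants must be strictly positive.")
  }
  structure(out, class = "material_constants")
}

# internal: effective thermal/caloric mixture properties as a plain list
.eff_thermal <- function(y_w, d, T_K, constants, props = NULL) {
  if (is.null(props)) props <- .props_at(T_K)
  phi_w_tot <- .phi_w(y_w, d, T_K, exclude_oil = FALSE, props = props)
  lambda_eff <- phi_w_tot * constants$lambda_w + (1 - phi_w_tot) * constants$lambda_s
  ys <- 1 - y_w
  cls <- c("oil", .hygroscopic_classes)
  inv_rho <- y_w / props$rho[["water"]] + ys * sum(d[cls] / props$rho[cls])
  cp <- y_w * props$cp[["water"]] + ys * sum(d[cls] * props$cp[cls])
  list(lambda_eff = lambda_eff, rho_eff = 1 / inv_rho, cp_eff = cp,
       phi_w_total = phi_w_tot)
}

#' Effective thermal and caloric properties of the seed mixture
#'
#' Volume-fraction-weighted thermal conductivity (total water volume fraction,
#' oil counted with the solids) and mass-consistent mixture density and
#' specific heat.
#'
#' @inheritParams water_volume_fraction
#' @param constants A [material_constants()] object.
#' @return A tibble with columns `lambda_eff` (W m^-1 K^-1), `rho_eff`
#'   (kg m^-3), `cp_eff` (J kg^-1 K^-1) and `phi_w_total`.
#' @export
effective_thermal <- function(comp, T_K, constants = material_constants()) {
  stopifnot(inherits(comp, "seed_composition"))
  et <- .eff_thermal(comp$y_w, attr(comp, "dry_fractions"), T_K, constants)
  tibble::as_tibble(et)
}

#' Saturation vapour pressure of water
#'
#' Arden Buck correlation over liquid water,
#' `p_sat = 611.21 exp((18.678 - T_C/234.5) T_C/(257.14 + T_C))` Pa,
#' accurate to better than 0.3 % between 0 and 60 deg C and to 0.05 % at the
#' normal boiling point.
#'
#' @param T_K Temperature in Kelvin, in \[270, 375\].
#' @return Saturation pressure in Pa (vectorised).
#' @export
saturation_pressure <- function(T_K) {
  .check_temp(T_K, 270, 375)
  t_c <- T_K - 273.15
  611.21 * exp((18.678 - t_c / 234.5) * (t_c / (257.14 + t_c)))
}

# analytic temperature derivative of the Buck correlation (used by the
# solver's thermal stability cap)
.dpsat_dT <- function(T_K) {
  t_c <- T_K - 273.15
  u <- 18.678 - t_c / 234.5
  v <- t_c / (257.14 + t_c)
  du <- -1 / 234.5
  dv <- 257.14 / (257.14 + t_c)^2
  saturation_pressure(T_K) * (du * v + u * dv)
}

# internal air-side transport properties; linear fits valid 0-80 deg C
# (kinematic viscosity and conductivity from standard dry-air tables, vapour
# diffusivity from the T^1.81 power law referenced to 273.15 K).
.air_props <- function(T_K) {
  t_c <- T_K - 273.15
  nu_air <- 1.33e-5 + 9.2e-8 * t_c
  lambda_air <- 0.0243 + 7.3e-5 * t_c
  alpha_air <- 1.88e-5 + 1.34e-7 * t_c
  D_air <- 2.178e-5 * (T_K / 273.15)^1.81
  list(nu_air = nu_air, D_air = D_air, lambda_air = lambda_air,
       alpha_air = alpha_air, Pr = nu_air / alpha_air)
}

#' Transport properties of humid air
#'
#' Kinematic viscosity, water-vapour diffusivity, thermal conductivity,
#' thermal diffusivity and Prandtl number of air, from low-order polynomial
#' fits valid between 0 and 80 deg C. The Prandtl number is computed as
#' `nu_air / alpha_air`.
#'
#' @param T_K Air (film) temperature in Kelvin.
#' @return A tibble with columns `nu_air`, `D_air`, `lambda_air`, `alpha_air`
#'   (all SI) and `Pr`.
#' @export
air_properties <- function(T_K) {
  .check_temp(T_K, 270, 360, "T_K")
  tibble::as_tibble(.air_props(T_K))
}
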