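# Single-seed drying solver: Lagrangian cell-centred finite volumes on N
# equal-volume shells of a shrinking sphere, lumped heat balance, evaporative
# surface flux, Ranz-Marshall boundary layer.

#' Drying air schedule
#'
#' Either constant air conditions or a time series with linear interpolation
#' (values held constant beyond the last sample).
#'
#' @param temp_C Air temperature, deg C (constant schedule).
#' @param rh Relative humidity as a fraction in \[0, 1\].
#' @param speed Air speed U, m s^-1 (default 0.235, the fluidised-bed value).
#' @param series Optional tibble with columns `time_s`, `temp_air_C`,
#'   `rh_air_pct` and optionally `air_speed_m_s`; when given it overrides the
#'   constant arguments.
#' @return An `air_schedule` object.
#' @export
air_schedule <- function(temp_C = 25, rh = 0.30, speed = 0.235,
                         series = NULL) {
  if (is.null(series)) {
    if (rh < 0 || rh > 1) abort("`rh` must lie in [0, 1].")
    if (speed < 0) abort("`speed` must be >= 0.")
    obj <- list(constant = TRUE, T_air = temp_C + 273.15, RH = rh, U = speed)
  } else {
    series <- tibble::as_tibble(series)
    need <- c("time_s", "temp_air_C", "rh_air_pct")
    if (!all(need %in% names(series))) {
      abort(sprintf("`series` needs columns %s.", paste(need, collapse = ", ")))
    }
    if (is.unsorted(series$time_s, strictly = TRUE)) {
      abort("`series$time_s` must be strictly increasing.")
    }
    if (any(series$rh_air_pct < 0 | series$rh_air_pct > 100)) {
      abort("`rh_air_pct` must lie in [0, 100].")
    }
    u <- if ("air_speed_m_s" %in% names(series)) series$air_speed_m_s
         else rep(speed, nrow(series))
    if (any(u < 0)) abort("Air speed must be >= 0.")
    one <- nrow(series) == 1L
    mkfun <- function(y) {
      if (one) function(t) rep_len(y[1], length(t))
      else approxfun(series$time_s, y, rule = 2)
    }
    obj <- list(constant = FALSE, series = series,
                T_air_fun = mkfun(series$temp_air_C + 273.15),
                RH_fun = mkfun(series$rh_air_pct / 100),
                U_fun = mkfun(u))
  }
  structure(obj, class = "air_schedule")
}

#' Air conditions at a given time
#'
#' @param schedule An [air_schedule()].
#' @param t Time(s) in seconds.
#' @return A tibble with columns `time_s`, `T_air_K`, `RH`, `U`.
#' @export
air_at <- function(schedule, t) {
  a <- .air_now(schedule, t)
  tibble::tibble(time_s = t, T_air_K = a$T_air, RH = a$RH, U = a$U)
}

.air_now <- function(schedule, t) {
  if (schedule$constant) {
    list(T_air = rep_len(schedule$T_air, length(t)),
         RH = rep_len(schedule$RH, length(t)),
         U = rep_len(schedule$U, length(t)))
  } else {
    list(T_air = schedule$T_air_fun(t), RH = schedule$RH_fun(t),
         U = schedule$U_fun(t))
  }
}

#' Average two air schedules
#'
#' Pointwise average of inlet and outlet sensor series (temperature and RH),
#' the recommended driving condition when both are measured.
#'
#' @param inlet,outlet [air_schedule()] objects built from series.
#' @param times Evaluation grid in seconds; defaults to the union of sample
#'   times.
#' @export
average_schedules <- function(inlet, outlet, times = NULL) {
  if (inlet$constant || outlet$constant) {
    abort("Both schedules must be time series to average them.")
  }
  if (is.null(times)) {
    times <- sort(union(inlet$series$time_s, outlet$series$time_s))
  }
  a <- .air_now(inlet, times); b <- .air_now(outlet, times)
  air_schedule(series = tibble::tibble(
    time_s = times,
    temp_air_C = (a$T_air + b$T_air) / 2 - 273.15,
    rh_air_pct = (a$RH + b$RH) / 2 * 100,
    air_speed_m_s = (a$U + b$U) / 2
  ))
}

#' Simulation configuration for the single-seed model
#'
#' Collects geometry, initial state, material parameters and numerical policy
#' for [run_drying()]. The two-material mode assigns the outermost shell the
#' seed-coat isotherm/composition and all inner shells the embryo material;
#' evaporation then uses the coat water activity.
#'
#' @param N Number of equal-volume shells (>= 3; default 10).
#' @param R0 Initial seed radius, m (default 1 mm: seed diameter ca. 2 mm).
#' @param MC0 Initial wet-basis moisture content (default 0.367, hydrated
#'   seed).
#' @param T0_seed Initial seed temperature, K.
#' @param material_mode `"one_material"` or `"two_material"`.
#' @param isotherm Isotherm for the whole seed (one-material mode).
#' @param isotherm_embryo,isotherm_coat Isotherms for the two-material mode.
#' @param diffusivity A [diffusivity_params()] set.
#' @param composition Bulk [seed_composition()] (also used for the thermal
#'   closures).
#' @param composition_embryo,composition_coat Region compositions
#'   (two-material mode).
#' @param constants A [material_constants()] set.
#' @param beta_int_rule Internal transfer coefficient for the water-activity
#'   flux at the embryo/coat interface: `"matched"` (default; reduces to the
#'   concentration-based Fickian flux when the two materials are identical)
#'   or `"gradient"` (the bare `D/dr`).
#' @param sign_convention `"physical"` (convective term `h_eff (T_air - T)`,
#'   default) or `"verbatim"` (`h_eff (T - T_air)` as typeset in the source
#'   heat balance; provided for comparison runs).
#' @param air_psat_at_air_temp If `TRUE`, the air-side partial pressure in
#'   the evaporative flux uses `p_sat(T_air)` instead of `p_sat(T_seed)`
#'   (sensitivity option; default `FALSE`, the verbatim form).
#' @param shrink Ideal shrinkage on/off (off only for verification runs).
#' @param isothermal Hold the seed temperature fixed (verification runs).
#' @param boundary `"evaporative"` (default) or `"dirichlet_zero"` (surface
#'   concentration pinned to zero; used with `D_override` to compare against
#'   the analytic Fickian-sphere series).
#' @param D_override Constant diffusivity overriding the moisture law
#'   (verification runs), m^2 s^-1.
#' @param dt_max Upper bound on the time step, s.
#' @param dt_safety Safety factor on the explicit diffusion stability limit.
#' @param max_frac_loss Largest fraction of a shell's water allowed to leave
#'   in one step.
#' @return A `drying_config` list.
#' @export
drying_config <- function(N = 10, R0 = 1.0e-3, MC0 = 0.367, T0_seed = 298.15,
                          material_mode = c("one_material", "two_material"),
                          isotherm = isotherm_params(model = "FH_LS",
                                                     chi_ws = 1.244),
                          isotherm_embryo = isotherm_params(model = "FH_LS",
                                                            chi_ws = 1.302),
                          isotherm_coat = isotherm_params(model = "FH_LS",
                                                          chi_ws = 0.465),
                          diffusivity = diffusivity_params(),
                          composition = default_composition("whole"),
                          composition_embryo = default_composition("embryo"),
                          composition_coat = default_composition("coat"),
                          constants = material_constants(),
                          beta_int_rule = c("matched", "gradient"),
                          sign_convention = c("physical", "verbatim"),
                          air_psat_at_air_temp = FALSE,
                          shrink = TRUE, isothermal = FALSE,
                          boundary = c("evaporative", "dirichlet_zero"),
                          D_override = NULL,
                          dt_max = 30, dt_safety = 0.25,
                          max_frac_loss = 0.1) {
  material_mode <- match.arg(material_mode)
  if (N < 3) abort("`N` must be >= 3.")
  if (MC0 <= 0 || MC0 >= 1) abort("`MC0` must lie in (0, 1).")
  if (R0 <= 0) abort("`R0` must be positive.")
  structure(
    list(N = as.integer(N), R0 = R0, MC0 = MC0, T0_seed = T0_seed,
         material_mode = material_mode, isotherm = isotherm,
         isotherm_embryo = isotherm_embryo, isotherm_coat = isotherm_coat,
         diffusivity = diffusivity, composition = composition,
         composition_embryo = composition_embryo,
         composition_coat = composition_coat, constants = constants,
         beta_int_rule = match.arg(beta_int_rule),
         sign_convention = match.arg(sign_convention),
         air_psat_at_air_temp = air_psat_at_air_temp,
         shrink = shrink, isothermal = isothermal,
         boundary = match.arg(boundary), D_override = D_override,
         dt_max = dt_max, dt_safety = dt_safety,
         max_frac_loss = max_frac_loss),
    class = "drying_config"
  )
}

# per-shell dry recipes and surface isotherm for a config
.shell_materials <- function(config) {
  N <- config$N
  if (config$material_mode == "one_material") {
    d <- attr(config$composition, "dry_fractions")
    list(d = rep(list(d), N), iso = rep(list(config$isotherm), N),
         d_surface = d, iso_surface = config$isotherm)
  } else {
    de <- attr(config$composition_embryo, "dry_fractions")
    dc <- attr(config$composition_coat, "dry_fractions")
    list(d = c(rep(list(de), N - 1), list(dc)),
         iso = c(rep(list(config$isotherm_embryo), N - 1),
                 list(config$isotherm_coat)),
         d_surface = dc, iso_surface = config$isotherm_coat)
  }
}

.solid_density <- function(d, T_K, props = NULL) {
  if (is.null(props)) props <- .props_at(T_K)
  cls <- c("oil", .hygroscopic_classes)
  1 / sum(d[cls] / props$rho[cls])
}

# per-run context: shell materials plus a temperature-keyed cache of the
# component property vectors (recomputed when T moves by > 0.005 K)
.step_ctx <- function(config) {
  e <- new.env(parent = emptyenv())
  e$T_last <- NA_real_
  list(mat = .shell_materials(config),
       d_bulk = attr(config$composition, "dry_fractions"), cache = e)
}

.ctx_props <- function(ctx, T_K) {
  e <- ctx$cache
  if (is.na(e$T_last) || abs(T_K - e$T_last) > 0.005) {
    e$props <- .props_at(T_K)
    e$T_last <- T_K
  }
  e$props
}

#' Initialise the seed state
#'
#' Builds N equal-volume shells with uniform moisture consistent with `MC0`
#' and the mixture densities at `T0_seed`. Solid shell masses are constant
#' for the whole run (Lagrangian frame).
#'
#' @param config A [drying_config()].
#' @return A `seed_state` list with per-shell solid and water masses, the
#'   seed temperature, the clock and a cumulative-evaporation accumulator.
#' @export
initialize_seed <- function(config) {
  N <- config$N
  mat <- .shell_materials(config)
  V0 <- 4 / 3 * pi * config$R0^3
  Vsh <- rep(V0 / N, N)
  t_c <- config$T0_seed - 273.15
  rho_w <- .poly2(.choi_okos_density$water, t_c)
  m_s <- m_w <- numeric(N)
  for (k in seq_len(N)) {
    rho_s <- .solid_density(mat$d[[k]], config$T0_seed)
    inv_rho_mix <- config$MC0 / rho_w + (1 - config$MC0) / rho_s
    m_tot <- Vsh[k] / inv_rho_mix
    m_w[k] <- config$MC0 * m_tot
    m_s[k] <- m_tot - m_w[k]
    if (m_s[k] <= 0) abort("`MC0` inconsistent with densities (no solid volume).")
  }
  structure(
    list(m_s = m_s, m_w = m_w, T_K = config$T0_seed, t = 0,
         evaporated = 0, V0_shells = Vsh),
    class = "seed_state"
  )
}

#' @export
print.seed_state <- function(x, ...) {
  cat(sprintf("<seed_state> t = %.0f s, T = %.2f K, MC = %.4f (N = %d shells)\n",
              x$t, x$T_K, state_mc(x), length(x$m_w)))
  invisible(x)
}

#' Wet-basis moisture content of a seed state
#' @param state A `seed_state`.
#' @export
state_mc <- function(state) {
  sum(state$m_w) / (sum(state$m_w) + sum(state$m_s))
}

# geometry of the shell stack; returns plain list of vectors
.geometry <- function(state, config, mat, props = NULL) {
  N <- length(state$m_w)
  if (is.null(props)) props <- .props_at(state$T_K)
  rho_w <- props$rho[["water"]]
  if (config$shrink) {
    if (config$material_mode == "one_material") {
      rho_s <- .solid_density(mat$d[[1]], state$T_K, props)
      V <- state$m_s / rho_s + state$m_w / rho_w
    } else {
      V <- numeric(N)
      for (k in seq_len(N)) {
        V[k] <- state$m_s[k] / .solid_density(mat$d[[k]], state$T_K, props) +
          state$m_w[k] / rho_w
      }
    }
  } else {
    V <- state$V0_shells
  }
  r_out <- (3 * cumsum(V) / (4 * pi))^(1 / 3)
  r_in <- c(0, r_out[-N])
  list(V = V, r_out = r_out,
       r_c = ((r_out^3 + r_in^3) / 2)^(1 / 3),
       A = 4 * pi * r_out^2, c_w = state$m_w / V)
}

#' Boundary-layer transfer coefficients (Ranz-Marshall)
#'
#' Sherwood and Nusselt closures `Sh = 2 + 0.6 Re^0.5 Sc^0.33`,
#' `Nu = 2 + 0.6 Re^0.5 Pr^0.33` with `Re = U 2R / nu_air`; external mass
#' transfer coefficient `beta_ext = Sh D_air / 2R`; effective heat transfer
#' coefficient as the series combination of `h_int = lambda_eff / 0.25R` and
#' `h_ext = Nu lambda_air / 2R`.
#'
#' @param R Current seed radius, m.
#' @param U Air speed, m s^-1.
#' @param T_film_K Boundary-layer film temperature at which air properties
#'   are evaluated, K.
#' @param lambda_eff Effective thermal conductivity of the seed, W m^-1 K^-1.
#' @return A tibble with `Re`, `Sh`, `Nu`, `beta_ext`, `h_int`, `h_ext`,
#'   `h_eff`.
#' @export
transfer_coefficients <- function(R, U, T_film_K = 298.15, lambda_eff = 0.4) {
  tc <- .transfer(R, U, T_film_K, lambda_eff)
  tibble::as_tibble(tc)
}

.transfer <- function(R, U, T_film_K, lambda_eff) {
  ap <- .air_props(T_film_K)
  Re <- U * 2 * R / ap$nu_air
  Sc <- ap$nu_air / ap$D_air
  Sh <- 2 + 0.6 * Re^0.5 * Sc^0.33
  Nu <- 2 + 0.6 * Re^0.5 * ap$Pr^0.33
  h_int <- lambda_eff / (0.25 * R)
  h_ext <- Nu * ap$lambda_air / (2 * R)
  list(Re = Re, Sh = Sh, Nu = Nu,
       beta_ext = Sh * ap$D_air / (2 * R),
       h_int = h_int, h_ext = h_ext,
       h_eff = 1 / (1 / h_int + 1 / h_ext))
}

#' Evaporative mass flux at the seed surface
#'
#' `J_evap = beta_ext M_w / (R_gas T_avg) (a_w p_sat(T) - RH p_sat(T))` with
#' the boundary-layer average temperature `T_avg = (T_air + 2 T)/3`. Both
#' saturation pressures are evaluated at the seed temperature (verbatim
#' form); `psat_air_at_air_temp = TRUE` evaluates the air-side term at
#' `T_air` for sensitivity studies. Negative values (condensation) are
#' allowed.
#'
#' @param aw_surface Surface water activity (outer-shell centred value).
#' @param T_seed_K,T_air_K Seed and air temperatures, K.
#' @param RH_air Air relative humidity, fraction.
#' @param beta_ext External mass transfer coefficient, m s^-1.
#' @param constants A [material_constants()] set.
#' @param psat_air_at_air_temp See description.
#' @return Flux in kg m^-2 s^-1 (positive = evaporation).
#' @export
evaporative_flux <- function(aw_surface, T_seed_K, T_air_K, RH_air, beta_ext,
                             constants = material_constants(),
                             psat_air_at_air_temp = FALSE) {
  T_avg <- (T_air_K + 2 * T_seed_K) / 3
  p_seed <- saturation_pressure(T_seed_K)
  p_air_side <- if (psat_air_at_air_temp) saturation_pressure(T_air_K) else p_seed
  beta_ext * constants$M_w / (constants$R_gas * T_avg) *
    (aw_surface * p_seed - RH_air * p_air_side)
}

#' Lumped heat-balance rate
#'
#' `dT/dt = (h_eff (T_air - T) - L(T) J_evap) A / (rho_eff cp_eff V)` with
#' the temperature-dependent latent heat
#' `L = dH_evap0 + (cp_v - cp_w)(T - T0)`. The `"verbatim"` convention uses
#' `h_eff (T - T_air)` as typeset in the source equation.
#'
#' @param T_seed_K,T_air_K Seed and air temperatures, K.
#' @param J_evap Evaporative flux, kg m^-2 s^-1.
#' @param h_eff Effective heat transfer coefficient, W m^-2 K^-1.
#' @param area Seed surface area, m^2.
#' @param rho_eff,cp_eff,volume Effective density, specific heat and seed
#'   volume.
#' @param constants A [material_constants()] set.
#' @param sign_convention `"physical"` or `"verbatim"`.
#' @return dT/dt in K s^-1.
#' @export
heat_rate <- function(T_seed_K, T_air_K, J_evap, h_eff, area, rho_eff,
                      cp_eff, volume, constants = material_constants(),
                      sign_convention = c("physical", "verbatim")) {
  sign_convention <- match.arg(sign_convention)
  L <- constants$dH_evap0 + (constants$cp_v - constants$cp_w) *
    (T_seed_K - constants$T0)
  conv <- if (sign_convention == "physical") h_eff * (T_air_K - T_seed_K)
          else h_eff * (T_seed_K - T_air_K)
  (conv - L * J_evap) * area / (rho_eff * cp_eff * volume)
}

#' Internal diffusive mass flows between shells
#'
#' Fickian flows across the N-1 internal interfaces, central differencing
#' between shell volume centroids, interface diffusivity at the arithmetic
#' mean of the adjacent water mass fractions. Positive = outward.
#'
#' @param state A `seed_state`.
#' @param config A [drying_config()].
#' @return A tibble with one row per internal interface: `interface`,
#'   `area`, `D`, `flow_kg_s`.
#' @export
internal_fluxes <- function(state, config) {
  mat <- .shell_materials(config)
  geo <- .geometry(state, config, mat)
  fl <- .internal_flows(state, config, mat, geo)
  tibble::tibble(interface = seq_len(length(state$m_w) - 1),
                 area = geo$A[-length(geo$A)], D = fl$D_if,
                 flow_kg_s = fl$Q)
}

.internal_flows <- function(state, config, mat, geo) {
  N <- length(state$m_w)
  y_w <- state$m_w / (state$m_w + state$m_s)
  if (!is.null(config$D_override)) {
    D_if <- rep(config$D_override, N - 1)
  } else {
    y_if <- (y_w[-N] + y_w[-1]) / 2
    D_if <- moisture_diffusivity(pmax(y_if, 1e-12), state$T_K,
                                 config$diffusivity)
  }
  dr <- geo$r_c[-1] - geo$r_c[-N]
  Q <- D_if * (geo$c_w[-N] - geo$c_w[-1]) / dr * geo$A[-N]
  list(Q = Q, D_if = D_if, dr = dr, y_w = y_w)
}

# da_w/dc_w for one shell, at fixed solid mass and temperature (volume
# responds to the water perturbation, matching the Lagrangian kinematics)
.aw_slope <- function(m_s, m_w, T_K, d, iso, rho_w, rho_s) {
  eps <- max(m_w * 1e-6, 1e-18)
  m2 <- m_w + eps; m1 <- max(m_w - eps, 0)
  cw <- function(m) m / (m_s / rho_s + m / rho_w)
  aw <- function(m) .aw(m / (m + m_s), T_K, d, iso)$a_w
  (aw(m2) - aw(m1)) / (cw(m2) - cw(m1))
}

#' Water-activity-driven flux at the embryo/coat interface
#'
#' Two-material variant: the flow between the second-outermost (embryo) and
#' outermost (coat) shell is driven by the water-activity difference,
#' `Q = beta_int A (c_avg / a_avg) (a_embryo - a_coat)`, since a
#' concentration difference is not a driving force across dissimilar
#' materials. `beta_int` follows `config$beta_int_rule`.
#'
#' @param state A `seed_state`.
#' @param config A [drying_config()] with `material_mode = "two_material"`
#'   (the rule is also usable in one-material mode for verification).
#' @return The interface mass flow in kg s^-1 (positive = outward), with the
#'   water activities and `beta_int` attached as attributes.
#' @export
coat_flux <- function(state, config) {
  mat <- .shell_materials(config)
  geo <- .geometry(state, config, mat)
  .coat_flow(state, config, mat, geo)
}

.coat_flow <- function(state, config, mat, geo, props = NULL) {
  N <- length(state$m_w)
  y_w <- state$m_w / (state$m_w + state$m_s)
  i <- N - 1
  aw_e <- .aw(y_w[i], state$T_K, mat$d[[i]], mat$iso[[i]], props = props)$a_w
  aw_c <- .aw(y_w[N], state$T_K, mat$d[[N]], mat$iso[[N]], props = props)$a_w
  aw_avg <- (aw_e + aw_c) / 2
  if (aw_avg == 0) abort("coat_flux(): average water activity is zero.")
  c_avg <- (geo$c_w[i] + geo$c_w[N]) / 2
  dr <- geo$r_c[N] - geo$r_c[i]
  D_if <- if (!is.null(config$D_override)) config$D_override else {
    moisture_diffusivity((y_w[i] + y_w[N]) / 2, state$T_K, config$diffusivity)
  }
  if (config$beta_int_rule == "gradient") {
    beta_int <- D_if / dr
  } else {
    if (is.null(props)) props <- .props_at(state$T_K)
    rho_w <- props$rho[["water"]]
    s_e <- .aw_slope(state$m_s[i], state$m_w[i], state$T_K, mat$d[[i]],
                     mat$iso[[i]], rho_w,
                     .solid_density(mat$d[[i]], state$T_K, props))
    s_c <- .aw_slope(state$m_s[N], state$m_w[N], state$T_K, mat$d[[N]],
                     mat$iso[[N]], rho_w,
                     .solid_density(mat$d[[N]], state$T_K, props))
    s_avg <- (s_e + s_c) / 2
    beta_int <- D_if / dr * aw_avg / (c_avg * s_avg)
  }
  Q <- beta_int * geo$A[i] * (c_avg / aw_avg) * (aw_e - aw_c)
  structure(Q, aw_embryo = aw_e, aw_coat = aw_c, beta_int = beta_int)
}

# one explicit Euler step; returns list(state, dt, J_evap, aw_surface)
.step_core <- function(state, config, air, dt = NULL, ctx = NULL) {
  if (is.null(ctx)) ctx <- .step_ctx(config)
  mat <- ctx$mat
  props <- .ctx_props(ctx, state$T_K)
  geo <- .geometry(state, config, mat, props)
  N <- length(state$m_w)
  fl <- .internal_flows(state, config, mat, geo)
  Q <- fl$Q
  if (config$material_mode == "two_material" && N >= 2) {
    Q[N - 1] <- as.numeric(.coat_flow(state, config, mat, geo, props))
  }
  R <- geo$r_out[N]
  y_tot <- state_mc(state)
  et <- .eff_thermal(y_tot, ctx$d_bulk, state$T_K, config$constants, props)

  if (config$boundary == "evaporative") {
    y_s <- fl$y_w[N]
    aw_s <- if (y_s > 0) {
      .aw(y_s, state$T_K, mat$d_surface, mat$iso_surface, props = props)$a_w
    } else 0
    if (isTRUE(mat$iso_surface$clip_aw)) aw_s <- min(aw_s, 1)
    T_avg <- (air$T_air + 2 * state$T_K) / 3
    tc <- .transfer(R, air$U, T_avg, et$lambda_eff)
    J <- evaporative_flux(aw_s, state$T_K, air$T_air, air$RH, tc$beta_ext,
                          config$constants, config$air_psat_at_air_temp)
    D_surf_gap <- NULL
  } else {
    D_surf <- if (!is.null(config$D_override)) config$D_override else {
      moisture_diffusivity(max(fl$y_w[N], 1e-12), state$T_K, config$diffusivity)
    }
    J <- D_surf * geo$c_w[N] / (R - geo$r_c[N])
    aw_s <- NA_real_
    tc <- .transfer(R, air$U, (air$T_air + 2 * state$T_K) / 3, et$lambda_eff)
    D_surf_gap <- c(D_surf, R - geo$r_c[N])
  }
  Q_out <- J * geo$A[N]
  rate <- c(0, Q) - c(Q, Q_out)  # inflow - outflow per shell
  dTdt <- if (config$isothermal) 0 else {
    heat_rate(state$T_K, air$T_air, J, tc$h_eff, geo$A[N], et$rho_eff,
              et$cp_eff, sum(geo$V), config$constants,
              config$sign_convention)
  }

  if (is.null(dt)) {
    dts <- config$dt_safety * min(fl$dr^2 / (2 * fl$D_if))
    if (!is.null(D_surf_gap)) {
      dts <- min(dts, config$dt_safety * D_surf_gap[2]^2 / (2 * D_surf_gap[1]))
    }
    losing <- rate < 0 & state$m_w > 1e-16
    if (any(losing)) {
      dts <- min(dts, config$max_frac_loss *
                   min(state$m_w[losing] / -rate[losing]))
    }
    if (!config$isothermal) {
      # linearised thermal conductance: convection plus the evaporative
      # sensitivity L * dJ/dT (psat steepens ~6 %/K, which can dominate h_eff)
      h_lin <- tc$h_eff
      if (config$boundary == "evaporative" && aw_s > 0) {
        cst <- config$constants
        L <- cst$dH_evap0 + (cst$cp_v - cst$cp_w) * (state$T_K - cst$T0)
        dJdT <- tc$beta_ext * cst$M_w /
          (cst$R_gas * (air$T_air + 2 * state$T_K) / 3) *
          aw_s * .dpsat_dT(state$T_K)
        h_lin <- h_lin + max(0, L * dJdT)
      }
      dts <- min(dts, 0.2 * et$rho_eff * et$cp_eff * sum(geo$V) /
                   (h_lin * geo$A[N]))
    }
    dt <- min(dts, config$dt_max)
    if (!is.finite(dt) || dt <= 1e-9) {
      abort("Time-step selection collapsed (dt <= 1e-9 s); state may be degenerate.")
    }
  }

  m_w_new <- state$m_w + rate * dt
  if (any(m_w_new < 0)) {
    abort(sprintf(
      "Negative shell water mass after update at t = %.1f s; dt = %.3g s too large.",
      state$t, dt
    ))
  }
  state$m_w <- m_w_new
  state$T_K <- state$T_K + dTdt * dt
  state$t <- state$t + dt
  state$evaporated <- state$evaporated + Q_out * dt
  list(state = state, dt = dt, J_evap = J, aw_surface = aw_s)
}

#' Advance the seed state by one time step
#'
#' Computes all fluxes from the current state, selects a stable explicit
#' Euler step (diffusive stability, thermal stability, and a cap on the
#' fractional water loss per shell) unless `dt` is given, and updates water
#' masses, geometry and temperature.
#'
#' @param state A `seed_state`.
#' @param config A [drying_config()].
#' @param air Either an [air_schedule()] (evaluated at `state$t`) or a list
#'   with elements `T_air`, `RH`, `U`.
#' @param dt Optional fixed step, s.
#' @return The updated `seed_state`, with the step actually taken in
#'   attribute `"dt"` and the surface flux in `"J_evap"`.
#' @export
seed_step <- function(state, config, air, dt = NULL) {
  if (inherits(air, "air_schedule")) air <- .air_now(air, state$t)
  res <- .step_core(state, config, air, dt)
  structure(res$state, dt = res$dt, J_evap = res$J_evap)
}

#' Run a drying simulation
#'
#' Integrates the single-seed model over a drying schedule with adaptive
#' explicit Euler steps, recording the mean wet-basis moisture content, the
#' seed temperature and the surface water activity at a fixed cadence.
#'
#' @param config A [drying_config()].
#' @param schedule An [air_schedule()].
#' @param duration Simulated time, s (default 24 h).
#' @param out_dt Output cadence, s (default hourly).
#' @return A `drying_curve` tibble with columns `time_s`, `mc_wb`,
#'   `temp_seed_K`, `aw_surface`. A mass-conservation audit (initial water,
#'   residual water, cumulative evaporation) is attached as attribute
#'   `"mass_audit"`, and the configuration as `"config"`.
#' @examples
#' \donttest{
#' cfg <- drying_config(N = 5)
#' curve <- run_drying(cfg, air_schedule(25, 0.30), duration = 3600)
#' }
#' @export
run_drying <- function(config, schedule, duration = 86400, out_dt = 3600) {
  state <- initialize_seed(config)
  water0 <- sum(state$m_w)
  n_out <- floor(duration / out_dt) + 1L
  out_t <- numeric(n_out); out_mc <- numeric(n_out)
  out_T <- numeric(n_out); out_aw <- numeric(n_out)
  ctx <- .step_ctx(config)
  mat <- ctx$mat

  record <- function(i, state) {
    out_t[i] <<- state$t
    out_mc[i] <<- state_mc(state)
    out_T[i] <<- state$T_K
    y_s <- state$m_w[config$N] / (state$m_w[config$N] + state$m_s[config$N])
    out_aw[i] <<- if (config$boundary == "evaporative" && y_s > 0) {
      .aw(y_s, state$T_K, mat$d_surface, mat$iso_surface)$a_w
    } else NA_real_
  }
  record(1L, state)
  i_out <- 2L
  next_out <- out_dt
  while (state$t < duration - 1e-9) {
    air <- .air_now(schedule, state$t)
    res <- .step_core(state, config, air, dt = NULL, ctx = ctx)
    # clip the step so output times are hit exactly
    if (state$t + res$dt > next_out + 1e-12) {
      res <- .step_core(state, config, air, dt = next_out - state$t, ctx = ctx)
    }
    state <- res$state
    if (abs(state$t - next_out) < 1e-9) {
      record(i_out, state)
      i_out <- i_out + 1L
      next_out <- next_out + out_dt
      if (next_out > duration + 1e-9) break
    }
  }
  curve <- tibble::tibble(time_s = out_t[seq_len(i_out - 1L)],
                          mc_wb = out_mc[seq_len(i_out - 1L)],
                          temp_seed_K = out_T[seq_len(i_out - 1L)],
                          aw_surface = out_aw[seq_len(i_out - 1L)])
  class(curve) <- c("drying_curve", class(curve))
  attr(curve, "mass_audit") <- list(
    water_initial = water0, water_final = sum(state$m_w),
    evaporated = state$evaporated,
    solid_initial = NULL
  )
  attr(curve, "final_state") <- state
  attr(curve, "config") <- config
  curve
}

#' Biot number of the seed
#'
#' `Bi = h_ext R / lambda_eff` with the external Ranz-Marshall Nusselt
#' closure; values below ~0.4 justify the lumped (uniform) seed temperature.
#'
#' @param config A [drying_config()] (evaluated at the initial state).
#' @param U Air speed, m s^-1.
#' @param T_air_K Air temperature, K.
#' @return The Biot number (dimensionless).
#' @export
compute_biot <- function(config = drying_config(), U = 0.235,
                         T_air_K = 298.15) {
  state <- initialize_seed(config)
  mat <- .shell_materials(config)
  geo <- .geometry(state, config, mat)
  et <- .eff_thermal(state_mc(state),
                     attr(config$composition, "dry_fractions"),
                     state$T_K, config$constants)
  T_avg <- (T_air_K + 2 * state$T_K) / 3
  tc <- .transfer(geo$r_out[config$N], U, T_avg, et$lambda_eff)
  tc$h_ext * geo$r_out[config$N] / et$lambda_eff
}
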