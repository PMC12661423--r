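#' Couchman-Karasz glass-transition parameters
#'
#' Component glass-transition temperatures and specific-heat increments for
#' the Couchman-Karasz mixing rule. Water values are the usual literature
#' constants (T_g,w = 136 K, dCp_w = 1.94e3 J kg^-1 K^-1); the solid values
#' are documented placeholders chosen so that the seed matrix at 25 deg C
#' crosses its glass transition near 8 % moisture (wet basis), typical for
#' oil-rich seed biopolymers, which also leaves the upper humidity steps of a
#' desorption table in the rubbery state where the bare Flory-Huggins model
#' is fitted.
#'
#' @param T_g_w,T_g_s Glass-transition temperatures of water and of the dry
#'   solid, K (`T_g_w < T_g_s`).
#' @param dCp_w,dCp_s Specific-heat increments at the transition,
#'   J kg^-1 K^-1.
#' @return A `ck_params` list.
#' @export
ck_params <- function(T_g_w = 136, T_g_s = 350, dCp_w = 1940, dCp_s = 500) {
  if (!(T_g_w < T_g_s)) abort("`T_g_w` must be below `T_g_s`.")
  if (dCp_w <= 0 || dCp_s <= 0) abort("Specific-heat increments must be positive.")
  structure(list(T_g_w = T_g_w, T_g_s = T_g_s, dCp_w = dCp_w, dCp_s = dCp_s),
            class = "ck_params")
}

#' Sorption-isotherm parameter set
#'
#' Parameters of the Flory-Huggins water-activity model and its glassy-state
#' additions. `model` selects the addition: `"FH"` (none), `"FH_FV"`
#' (free-volume term driven by the Couchman-Karasz glass-transition slope) or
#' `"FH_LS"` (Leibler-Sekimoto elastic term with bulk modulus `K_g`).
#'
#' @param model `"FH"`, `"FH_FV"` or `"FH_LS"`.
#' @param chi_ws Concentrated-regime interaction parameter (dimensionless).
#'   Fitted values for cabbage seed material: 1.244 (whole seed), 1.302
#'   (embryo), 0.465 (coat).
#' @param chi0 Semi-dilute interaction parameter; fixed at 0.5.
#' @param N_s Molar-volume ratio of solute to solvent; the default 1000 makes
#'   the `(1 - 1/N_s)` entropic factor effectively 1 (polymer limit).
#' @param K_g Glassy bulk modulus, Pa (Leibler-Sekimoto addition).
#' @param ck A [ck_params()] set.
#' @param constants A [material_constants()] set (supplies `M_w`, `R_gas`,
#'   `nu_w`).
#' @param clip_aw If `TRUE`, water activities above 1 are clipped to 1.
#'   Default off: Flory-Huggins with `chi_ws > 1` can legitimately exceed 1 at
#'   intermediate water contents and clipping would silently alter fluxes; a
#'   diagnostic is emitted instead.
#' @param ls_form Reading of the Leibler-Sekimoto logarithm. `"retention"`
#'   (default) uses `ln((1 - phi_w_tg)/(1 - phi_w))`, which is negative in
#'   the glassy state and therefore lowers the water activity — the direction
#'   required by increased water retention of drying seeds and by the fitted
#'   `K_g`. `"as_printed"` uses the inverted ratio (positive in the glassy
#'   state); see the methods vignette.
#' @return An `isotherm_params` list.
#' @export
isotherm_params <- function(model = c("FH", "FH_FV", "FH_LS"), chi_ws = 1.244,
                            chi0 = 0.5, N_s = 1000, K_g = 3.3e9,
                            ck = ck_params(),
                            constants = material_constants(),
                            clip_aw = FALSE,
                            ls_form = c("retention", "as_printed")) {
  model <- match.arg(model)
  if (chi0 != 0.5) abort("`chi0` is fixed at 0.5.")
  if (N_s <= 1) abort("`N_s` must exceed 1.")
  if (K_g <= 0) abort("`K_g` must be positive.")
  structure(list(model = model, chi_ws = chi_ws, chi0 = chi0, N_s = N_s,
                 K_g = K_g, ck = ck, constants = constants,
                 clip_aw = clip_aw, ls_form = match.arg(ls_form)),
            class = "isotherm_params")
}

#' Effective Flory-Huggins interaction parameter
#'
#' Interpolates between the concentrated-regime value `chi_ws` and the
#' semi-dilute value 0.5: `chi_eff = chi_ws` for `chi_ws <= 0.5`, else
#' `chi_ws - (chi_ws - 0.5) phi_w^2`. Continuous in `chi_ws` at 0.5.
#'
#' @param chi_ws Concentrated-regime interaction parameter.
#' @param phi_w Water volume fraction in \[0, 1\] (vectorised).
#' @param chi0 Semi-dilute value (0.5).
#' @export
chi_eff <- function(chi_ws, phi_w, chi0 = 0.5) {
  if (any(phi_w < 0 | phi_w > 1)) abort("`phi_w` must lie in [0, 1].")
  if (chi_ws <= chi0) rep_len(chi_ws, length(phi_w))
  else chi_ws - (chi_ws - chi0) * phi_w^2
}

# internal: T_g and its analytic derivative for vector y_w
.tg_ck <- function(y_w, ck) {
  A <- ck$dCp_w; B <- ck$dCp_s
  den <- y_w * A + (1 - y_w) * B
  list(
    T_g = (y_w * A * ck$T_g_w + (1 - y_w) * B * ck$T_g_s) / den,
    dTg_dyw = A * B * (ck$T_g_w - ck$T_g_s) / den^2
  )
}

#' Couchman-Karasz glass-transition temperature of the water-solid mixture
#'
#' `T_g(y_w) = (y_w dCp_w T_g_w + (1-y_w) dCp_s T_g_s) /
#' (y_w dCp_w + (1-y_w) dCp_s)` with its closed-form derivative with respect
#' to the water mass fraction (needed analytically by the free-volume
#' addition so the solver sees a smooth isotherm).
#'
#' @param y_w Water mass fraction in \[0, 1\] (vectorised).
#' @param ck A [ck_params()] set.
#' @return A tibble with columns `y_w`, `T_g` (K) and `dTg_dyw` (K per unit
#'   mass fraction).
#' @export
tg_couchman_karasz <- function(y_w, ck = ck_params()) {
  if (any(y_w < 0 | y_w > 1)) abort("`y_w` must lie in [0, 1].")
  tg <- .tg_ck(y_w, ck)
  tibble::tibble(y_w = y_w, T_g = tg$T_g, dTg_dyw = tg$dTg_dyw)
}

#' Free-volume chemical-potential addition (glassy state)
#'
#' `mu_FV = (M_w dCp_s / (R_gas T)) (1 - y_w)^2 (1 - T/T_g) dT_g/dy_w`,
#' active only below the glass transition (`T < T_g(y_w)`), zero otherwise.
#' Negative in the glassy state (water plasticises, `dT_g/dy_w < 0`), which
#' lowers the water activity and raises the equilibrium water content.
#'
#' @param y_w Water mass fraction (vectorised).
#' @param T_K Temperature, K.
#' @param params An [isotherm_params()] set.
#' @return Dimensionless chemical-potential contribution.
#' @export
mu_fv <- function(y_w, T_K, params = isotherm_params()) {
  tg <- .tg_ck(y_w, params$ck)
  cst <- params$constants
  out <- cst$M_w * params$ck$dCp_s / (cst$R_gas * T_K) * (1 - y_w)^2 *
    (1 - T_K / tg$T_g) * tg$dTg_dyw
  out[T_K >= tg$T_g] <- 0
  out
}

#' Leibler-Sekimoto elastic chemical-potential addition (glassy state)
#'
#' Couples the water chemical potential to unrelaxed elastic stress through
#' the glassy bulk modulus `K_g`:
#' `mu_LS = (nu_w K_g / (R_gas T)) ln((1 - phi_w_tg)/(1 - phi_w))`
#' (the default `"retention"` reading), active only for `phi_w < phi_w_tg`
#' (drier than the glass transition) and exactly zero at the transition.
#' The term is negative in the glassy state, lowering the water activity and
#' raising the equilibrium water content — the "non-equilibrium" isotherm
#' shift of seeds that retain more water during fast drying.
#' `ls_form = "as_printed"` in [isotherm_params()] selects the inverted
#' (positive) ratio; the methods vignette discusses the two readings.
#'
#' @param phi_w Water volume fraction (vectorised).
#' @param T_K Temperature, K.
#' @param params An [isotherm_params()] set (supplies `K_g`, `nu_w` and
#'   `ls_form`).
#' @param phi_w_tg Water volume fraction at the glass transition for this
#'   temperature (see [phi_at_tg()]).
#' @export
mu_ls <- function(phi_w, T_K, params = isotherm_params(), phi_w_tg) {
  if (phi_w_tg >= 1) abort("`phi_w_tg` = 1 is a degenerate reference state.")
  cst <- params$constants
  lr <- log((1 - phi_w_tg) / (1 - phi_w))
  if (identical(params$ls_form, "as_printed")) lr <- -lr
  out <- cst$nu_w * params$K_g / (cst$R_gas * T_K) * lr
  out[phi_w >= phi_w_tg] <- 0
  out
}

#' Water volume fraction at the glass transition
#'
#' Inverts the Couchman-Karasz relation `T_g(y_w) = T` (closed form) and
#' converts the crossing water mass fraction to a volume fraction via the
#' oil-excluded mixing rule.
#'
#' @param T_K Temperature, K; must lie strictly between `T_g_w` and `T_g_s`.
#' @param comp A [seed_composition()] (dry-matter recipe; its own `y_w` is
#'   ignored).
#' @param params An [isotherm_params()] set.
#' @return `phi_w_tg`, the water volume fraction at which the mixture passes
#'   its glass transition at temperature `T_K`.
#' @export
phi_at_tg <- function(T_K, comp, params = isotherm_params()) {
  ck <- params$ck
  if (T_K <= ck$T_g_w || T_K >= ck$T_g_s) {
    abort(sprintf(
      "T = %.2f K has no glass-transition crossing: need T in (%g, %g) K.",
      T_K, ck$T_g_w, ck$T_g_s
    ))
  }
  q <- ck$dCp_s * (T_K - ck$T_g_s) / (ck$dCp_w * (ck$T_g_w - T_K))
  y_star <- q / (1 + q)
  .phi_w(y_star, attr(comp, "dry_fractions"), T_K, exclude_oil = TRUE)
}

# internal: water activity for vector y_w given dry recipe, fast path used by
# the solver. Returns list(a_w, phi_w).
.aw <- function(y_w, T_K, d, params, phi_w_tg = NULL, props = NULL) {
  phi <- .phi_w(y_w, d, T_K, exclude_oil = TRUE, props = props)
  ce <- if (params$chi_ws <= params$chi0) params$chi_ws
        else params$chi_ws - (params$chi_ws - params$chi0) * phi^2
  lnaw <- log(phi) + (1 - 1 / params$N_s) * (1 - phi) + ce * (1 - phi)^2
  if (params$model == "FH_FV") {
    lnaw <- lnaw + mu_fv(y_w, T_K, params)
  } else if (params$model == "FH_LS") {
    ck <- params$ck
    if (T_K > ck$T_g_w && T_K < ck$T_g_s) {
      if (is.null(phi_w_tg)) {
        q <- ck$dCp_s * (T_K - ck$T_g_s) / (ck$dCp_w * (ck$T_g_w - T_K))
        phi_w_tg <- .phi_w(q / (1 + q), d, T_K, exclude_oil = TRUE,
                           props = props)
      }
      lr <- log((1 - phi_w_tg) / (1 - phi))
      if (identical(params$ls_form, "as_printed")) lr <- -lr
      add <- params$constants$nu_w * params$K_g /
        (params$constants$R_gas * T_K) * lr
      add[phi >= phi_w_tg] <- 0
      lnaw <- lnaw + add
    }
  }
  aw <- exp(lnaw)
  aw[phi <= 0] <- 0
  if (isTRUE(params$clip_aw)) aw <- pmin(aw, 1)
  list(a_w = aw, phi_w = phi)
}

#' Water activity of the seed material
#'
#' Flory-Huggins water activity
#' `a_w = exp(ln phi_w + (1 - 1/N_s)(1 - phi_w) + chi_eff (1 - phi_w)^2 + mu_glassy)`
#' with the water volume fraction from the oil-excluded mixing rule and the
#' model-selected glassy addition (none, free-volume, or Leibler-Sekimoto).
#'
#' Values above 1 are physically admissible for `chi_ws > 1` at intermediate
#' water contents and are reported with a diagnostic rather than clipped
#' (set `clip_aw = TRUE` in [isotherm_params()] to clip).
#'
#' @param y_w Water mass fraction in (0, 1\] (vectorised).
#' @param T_K Temperature, K.
#' @param comp A [seed_composition()]; only its dry-matter recipe is used.
#' @param params An [isotherm_params()] set.
#' @return Water activity (dimensionless, >= 0).
#' @export
water_activity <- function(y_w, T_K, comp = default_composition(),
                           params = isotherm_params()) {
  if (any(y_w <= 0)) abort("`y_w` must be positive (got a value <= 0).")
  if (any(y_w > 1)) abort("`y_w` must not exceed 1.")
  res <- .aw(y_w, T_K, attr(comp, "dry_fractions"), params)
  if (!isTRUE(params$clip_aw) && any(res$a_w > 1)) {
    inform(
      "water_activity() produced values > 1 (possible for chi_ws > 1); not clipped.",
      .frequency = "once", .frequency_id = "seeddry_aw_gt1"
    )
  }
  res$a_w
}

#' Equilibrium moisture content at a given relative humidity
#'
#' Inverts the isotherm: the smallest water mass fraction in (0, 0.99) whose
#' water activity equals `RH`, found by a grid scan for the first sign change
#' followed by bracketed bisection. This is the model's predicted final
#' moisture content for drying air at (`RH`, `T_K`).
#'
#' @param RH Water activity / relative humidity target in (0, 1).
#' @param T_K Temperature, K.
#' @inheritParams water_activity
#' @return Equilibrium wet-basis moisture content (mass fraction).
#' @export
equilibrium_moisture <- function(RH, T_K, comp = default_composition(),
                                 params = isotherm_params()) {
  if (RH <= 0 || RH >= 1) abort("`RH` must lie strictly within (0, 1).")
  d <- attr(comp, "dry_fractions")
  grid <- exp(seq(log(1e-7), log(0.99), length.out = 600))
  aw <- .aw(grid, T_K, d, params)$a_w
  f <- aw - RH
  idx <- which(f[-length(f)] <= 0 & f[-1] > 0)
  if (length(idx) == 0) {
    abort(sprintf(
      "No isotherm crossing for RH = %.3f: scanned a_w range [%.3g, %.3g].",
      RH, min(aw), max(aw)
    ))
  }
  i <- idx[1]
  uniroot(function(y) .aw(y, T_K, d, params)$a_w - RH,
          lower = grid[i], upper = grid[i + 1], tol = 1e-13)$root
}

#' Tabulate a sorption isotherm
#'
#' Evaluates the water activity model over a grid of water contents, returning
#' a tibble suitable for plotting or export.
#'
#' @inheritParams water_activity
#' @param n Number of grid points.
#' @return A tibble with columns `y_w`, `phi_w`, `a_w`.
#' @export
sorption_curve <- function(params = isotherm_params(),
                           comp = default_composition(), T_K = 298.15,
                           n = 200) {
  y <- seq(1e-4, 0.95, length.out = n)
  res <- .aw(y, T_K, attr(comp, "dry_fractions"), params)
  tibble::tibble(y_w = y, phi_w = res$phi_w, a_w = res$a_w)
}
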