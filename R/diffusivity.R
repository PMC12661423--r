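#' Moisture-diffusivity parameter set
#'
#' Parameters of the empirical moisture/temperature diffusivity law
#' `D_w = (a log10(y_w) + b) exp(-E_a/R (1/T - 1/T_ref))` with a glassy-state
#' floor. Defaults are the fitted cabbage-seed values: `a = 3e-11`,
#' `b = 9e-11` m^2 s^-1, `E_a = 14.18e3` J mol^-1, floor `1e-12` m^2 s^-1.
#'
#' @param a Slope of the log10 moisture term, m^2 s^-1.
#' @param b Intercept, m^2 s^-1 (the diffusivity at `y_w = 1`, `T = T_ref`).
#' @param E_a Activation energy, J mol^-1.
#' @param T_ref Reference temperature, K.
#' @param floor Lower diffusivity limit, m^2 s^-1 (diffusion levels off
#'   rather than vanishing in the glassy state).
#' @param multiplier Factor converting the measured water diffusivity to the
#'   mutual diffusivity used by the transport equation; default 1 (the two
#'   are identified).
#' @return A `diffusivity_params` list.
#' @export
diffusivity_params <- function(a = 3e-11, b = 9e-11, E_a = 14.18e3,
                               T_ref = 298.15, floor = 1.0e-12,
                               multiplier = 1) {
  if (b <= 0) abort("`b` must be positive.")
  if (floor <= 0) abort("`floor` must be positive.")
  structure(list(a = a, b = b, E_a = E_a, T_ref = T_ref, floor = floor,
                 multiplier = multiplier),
            class = "diffusivity_params")
}

#' Arrhenius temperature factor of the diffusivity
#'
#' `exp(-E_a/R_gas (1/T - 1/T_ref))`; equals 1 at the reference temperature
#' and exceeds 1 above it (for positive activation energy).
#'
#' @param T_K Temperature, K (vectorised).
#' @param params A [diffusivity_params()] set.
#' @param R_gas Gas constant, J mol^-1 K^-1.
#' @export
arrhenius_factor <- function(T_K, params = diffusivity_params(),
                             R_gas = 8.314) {
  if (any(T_K <= 0)) abort("`T_K` must be positive.")
  exp(-params$E_a / R_gas * (1 / T_K - 1 / params$T_ref))
}

#' Moisture diffusivity of the seed material
#'
#' Evaluates the log-moisture Arrhenius law and clamps the result from below
#' at `params$floor`. The clamp is applied to the full expression (after the
#' temperature factor), so warming cannot lift a clamped value. Non-positive
#' `y_w` is treated as fully glassy (floor) with a diagnostic.
#'
#' @param y_w Water mass fraction (vectorised).
#' @param T_K Temperature, K.
#' @param params A [diffusivity_params()] set.
#' @return Diffusivity in m^2 s^-1, always `>= params$floor`.
#' @export
moisture_diffusivity <- function(y_w, T_K, params = diffusivity_params()) {
  bad <- y_w <= 0
  if (any(bad)) {
    inform("moisture_diffusivity(): y_w <= 0 treated as floor diffusivity.",
           .frequency = "once", .frequency_id = "seeddry_D_floor")
    y_w[bad] <- NA_real_
  }
  raw <- (params$a * log10(y_w) + params$b) * arrhenius_factor(T_K, params)
  raw[bad] <- params$floor
  pmax(raw * params$multiplier, params$floor)
}

#' Fit the moisture dependence of the diffusivity
#'
#' Linear least squares of measured diffusivities at the reference
#' temperature against `log10(y_w)`, giving slope `a` and intercept `b`.
#' Points at or below the clamp floor carry no information about the law and
#' are excluded with a warning.
#'
#' @param points A data frame with columns `yw` and `Dw` (m^2 s^-1), measured
#'   at the reference temperature.
#' @param params A [diffusivity_params()] set (supplies the floor).
#' @return A `diffusivity_fit` object with elements `a`, `b`, `fit` (the
#'   underlying `lm`), `n`. Supports [tidy()] and [glance()].
#' @export
fit_diffusivity_ab <- function(points, params = diffusivity_params()) {
  points <- tibble::as_tibble(points)
  if (!all(c("yw", "Dw") %in% names(points))) {
    abort("`points` needs columns `yw` and `Dw`.")
  }
  clamped <- points$Dw <= params$floor * (1 + 1e-9)
  if (any(clamped)) {
    warn(sprintf("fit_diffusivity_ab(): excluding %d clamped point(s) at the diffusivity floor.",
                 sum(clamped)))
  }
  pts <- points[!clamped, , drop = FALSE]
  if (nrow(pts) < 2) abort("Need >= 2 points above the clamp region.")
  if (length(unique(pts$yw)) < 2) {
    abort("Degenerate design: all `yw` equal; cannot identify the slope.")
  }
  fit <- lm(Dw ~ I(log10(yw)), data = pts)
  structure(
    list(a = unname(coef(fit)[2]), b = unname(coef(fit)[1]), fit = fit,
         n = nrow(pts), n_dropped = sum(clamped)),
    class = "diffusivity_fit"
  )
}

#' Fit the activation energy of the diffusivity
#'
#' With `(a, b)` fixed, fits `E_a` by least squares on the observed ratio
#' `Dw / Dw(T_ref)` against the Arrhenius factor, using diffusivity points
#' measured away from the reference temperature.
#'
#' @param points A data frame with columns `yw`, `Dw` and `temp_K`.
#' @param params A [diffusivity_params()] set with the fitted `(a, b)`.
#' @param interval Search interval for `E_a`, J mol^-1.
#' @return An `ea_fit` object with elements `E_a`, `rss`, `n`.
#' @export
fit_activation_energy <- function(points, params = diffusivity_params(),
                                  interval = c(-1e5, 2e5)) {
  points <- tibble::as_tibble(points)
  if (!all(c("yw", "Dw", "temp_K") %in% names(points))) {
    abort("`points` needs columns `yw`, `Dw`, `temp_K`.")
  }
  off_ref <- abs(points$temp_K - params$T_ref) > 1e-9
  if (!any(off_ref)) {
    abort("All points are at the reference temperature; E_a is unidentifiable.")
  }
  pts <- points[off_ref, , drop = FALSE]
  base <- params$a * log10(pts$yw) + params$b
  if (any(base <= 0)) abort("Points in the clamped moisture range cannot be used.")
  ratio_obs <- pts$Dw / base
  obj <- function(ea) {
    p <- params; p$E_a <- ea
    sum((ratio_obs - arrhenius_factor(pts$temp_K, p))^2)
  }
  opt <- optimize(obj, interval = interval, tol = 1e-9)
  # polish: for well-posed data the optimizer is already tight; keep as is
  structure(
    list(E_a = opt$minimum, rss = opt$objective, n = nrow(pts),
         data = tibble::tibble(yw = pts$yw, temp_K = pts$temp_K,
                               ratio = ratio_obs)),
    class = "ea_fit"
  )
}

#' @export
print.diffusivity_fit <- function(x, ...) {
  cat(sprintf("<diffusivity_fit> a = %.4g, b = %.4g m^2/s (n = %d)\n",
              x$a, x$b, x$n))
  invisible(x)
}

#' @export
print.ea_fit <- function(x, ...) {
  cat(sprintf("<ea_fit> E_a = %.5g J/mol (n = %d, RSS = %.3g)\n",
              x$E_a, x$n, x$rss))
  invisible(x)
}

#' @export
tidy.diffusivity_fit <- function(x, ...) {
  # summary.lm warns on noiseless (exact) fits; the NA/0 errors are still valid
  sm <- suppressWarnings(summary(x$fit))
  tibble::tibble(term = c("a", "b"), estimate = c(x$a, x$b),
                 std.error = unname(sm$coefficients[c(2, 1), 2]))
}

#' @export
glance.diffusivity_fit <- function(x, ...) {
  tibble::tibble(n = x$n, n_dropped = x$n_dropped,
                 sigma = suppressWarnings(summary(x$fit))$sigma)
}

#' @export
tidy.ea_fit <- function(x, ...) {
  tibble::tibble(term = "E_a", estimate = x$E_a, std.error = NA_real_)
}

#' @export
glance.ea_fit <- function(x, ...) {
  tibble::tibble(rss = x$rss, n = x$n)
}
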