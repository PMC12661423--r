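# Deterministic generators for every input the package consumes: sorption
# tables, diffusivity tables, drying "experiments", air schedules and
# seed-bed images. Each generator is a pure function of its arguments and
# seed, so fixtures are reproducible byte for byte and the full test suite
# runs with no external data.

#' Generate a synthetic sorption table
#'
#' Equilibrium moisture contents from the isotherm model at a grid of water
#' activities, with optional multiplicative Gaussian noise (truncated so the
#' moisture content stays inside (0, 1); drying-balance noise scales with
#' the signal, hence multiplicative).
#'
#' @param params An [isotherm_params()] set (the generating truth).
#' @param comp A [seed_composition()].
#' @param T_K Temperature, K.
#' @param aw Water-activity grid in (0, 1); the default mirrors a
#'   humidity-step desorption protocol.
#' @param noise_sd Relative noise standard deviation (0 = noiseless).
#' @param seed Integer seed; identical arguments give identical output.
#' @param direction `"desorption"` or `"sorption"` label.
#' @return A `sorption_table` tibble.
#' @export
gen_sorption_table <- function(params = isotherm_params(),
                               comp = default_composition(),
                               T_K = 298.15,
                               aw = c(0.10, 0.20, 0.30, 0.40, 0.50, 0.60,
                                      0.70, 0.80, 0.95),
                               noise_sd = 0, seed = 1,
                               direction = "desorption") {
  if (any(aw <= 0 | aw >= 1)) abort("`aw` grid must lie within (0, 1).")
  mc <- vapply(aw, function(a) equilibrium_moisture(a, T_K, comp, params),
               numeric(1))
  if (noise_sd > 0) {
    mc <- withr::with_seed(seed, mc * (1 + rnorm(length(mc), 0, noise_sd)))
    mc <- pmin(pmax(mc, 1e-6), 0.999)
  }
  as_sorption_table(tibble::tibble(aw = aw, mc_wb = mc, temp_K = T_K,
                                   direction = direction))
}

#' Generate a synthetic drying experiment
#'
#' Runs the single-seed model and perturbs the sampled moisture curve with
#' multiplicative Gaussian noise, emulating an experimental drying curve
#' measured by periodic weighing.
#'
#' @param config A [drying_config()].
#' @param schedule An [air_schedule()].
#' @param duration Simulated time, s.
#' @param out_dt Sampling cadence, s.
#' @param noise_sd Relative noise standard deviation.
#' @param seed Integer seed.
#' @return A `drying_curve` tibble (noised copy; the clean model curve is
#'   attached as attribute `"truth"`).
#' @export
gen_drying_experiment <- function(config, schedule, duration = 86400,
                                  out_dt = 3600, noise_sd = 0, seed = 1) {
  curve <- run_drying(config, schedule, duration = duration, out_dt = out_dt)
  out <- curve
  if (noise_sd > 0) {
    out$mc_wb <- withr::with_seed(
      seed, out$mc_wb * (1 + rnorm(nrow(out), 0, noise_sd))
    )
    out$mc_wb <- pmin(pmax(out$mc_wb, 1e-9), 0.999)
  }
  attr(out, "truth") <- curve
  out
}

#' Analytic Fickian-sphere solution (oracle)
#'
#' Normalized mean concentration of a sphere with constant diffusivity,
#' fixed radius and zero surface concentration:
#' `MR(t) = (6/pi^2) sum n^-2 exp(-n^2 pi^2 D t / R^2)`. The truncated sum
#' carries an exact-Basel-tail correction damped by the first omitted
#' exponential, so `MR(0) = 1` exactly while large-time values decay to zero;
#' the residual truncation error is bounded by the omitted tail itself.
#'
#' @param t Time(s), s (vectorised).
#' @param D Diffusivity, m^2 s^-1.
#' @param R Sphere radius, m.
#' @param terms Number of series terms (>= 50).
#' @return Normalized mean concentration in \[0, 1\].
#' @export
analytic_sphere_mc <- function(t, D, R, terms = 10000) {
  if (any(t < 0)) abort("`t` must be >= 0.")
  if (terms < 50) abort("Use at least 50 series terms.")
  n <- seq_len(terms)
  Fo <- t * D / R^2
  En <- exp(-outer(Fo, n^2 * pi^2))
  head_sum <- as.numeric(En %*% (1 / n^2))
  tail_basel <- pi^2 / 6 - sum(1 / n^2)
  (6 / pi^2) * (head_sum + tail_basel * exp(-(terms + 1)^2 * pi^2 * Fo))
}

#' Generate a synthetic seed-bed image
#'
#' Writes a greyscale PNG of black (0) and white (1) "seed" pixels. Patterns:
#' `"segregated"` (left 2/5 of the frame black, rest white — the split sits
#' on a cell boundary of the default 5-cell grid, so every cell is pure),
#' `"mixed"` (independent Bernoulli(0.5) pixels) and `"intermediate"` (each
#' pixel is random with probability `mix`, else follows the segregated
#' pattern), so the mixing entropy grows monotonically with `mix`.
#'
#' @param path Output PNG path.
#' @param pattern `"segregated"`, `"mixed"` or `"intermediate"`.
#' @param mix Mixedness in \[0, 1\] for the intermediate pattern.
#' @param size Image side length in pixels.
#' @param seed Integer seed.
#' @return The path, invisibly; the pixel matrix as attribute `"pixels"`.
#' @export
gen_mixing_image <- function(path, pattern = c("segregated", "mixed",
                                               "intermediate"),
                             mix = 0.5, size = 100, seed = 1) {
  pattern <- match.arg(pattern)
  base <- matrix(1, size, size)
  base[, seq_len(round(size * 2 / 5))] <- 0
  img <- withr::with_seed(seed, switch(pattern,
    segregated = base,
    mixed = matrix(rbinom(size^2, 1, 0.5), nrow = size),
    intermediate = {
      rnd <- matrix(rbinom(size^2, 1, 0.5), nrow = size)
      use <- matrix(runif(size^2) < mix, nrow = size)
      ifelse(use, rnd, base)
    }
  ))
  storage.mode(img) <- "double"
  png::writePNG(img, target = path)
  invisible(structure(path, pixels = img))
}

#' Generate a segregated-to-mixed image sequence
#'
#' Writes a series of PNG frames whose mixedness ramps from 0 to 1, imitating
#' a fluidised bed homogenising over time (one frame every `dt` seconds).
#'
#' @param dir Output directory (created if needed).
#' @param n Number of frames.
#' @param size Image side length in pixels.
#' @param dt Time between frames, s.
#' @param seed Integer seed.
#' @return A tibble with columns `filename`, `time_s` (sidecar table format).
#' @export
gen_mixing_sequence <- function(dir, n = 6, size = 100, dt = 120, seed = 1) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  mixes <- seq(0, 1, length.out = n)
  files <- sprintf("bed_%04d.png", seq_len(n) - 1)
  for (i in seq_len(n)) {
    pat <- if (mixes[i] == 0) "segregated" else "intermediate"
    gen_mixing_image(file.path(dir, files[i]), pattern = pat, mix = mixes[i],
                     size = size, seed = seed + i)
  }
  tibble::tibble(filename = files, time_s = (seq_len(n) - 1) * dt)
}

#' Generate a fluctuating measured-air schedule
#'
#' Emulates inlet sensor logs of an industrial dryer: the set-point plus
#' smooth random fluctuations (moving-average filtered Gaussian noise).
#'
#' @param duration Schedule length, s.
#' @param step Sampling interval, s.
#' @param temp_C,rh Set-point air temperature (deg C) and RH (fraction).
#' @param temp_sd,rh_sd Fluctuation scales (deg C, RH fraction).
#' @param speed Air speed, m s^-1.
#' @param seed Integer seed.
#' @return An [air_schedule()] built from the generated series.
#' @export
gen_air_schedule <- function(duration = 86400, step = 600, temp_C = 25,
                             rh = 0.30, temp_sd = 0.5, rh_sd = 0.01,
                             speed = 0.235, seed = 1) {
  t <- seq(0, duration, by = step)
  smooth_noise <- function(n, sd) {
    x <- rnorm(n + 8, 0, sd)
    as.numeric(stats::filter(x, rep(1 / 9, 9), sides = 2))[5:(n + 4)]
  }
  ser <- withr::with_seed(seed, tibble::tibble(
    time_s = t,
    temp_air_C = temp_C + smooth_noise(length(t), temp_sd),
    rh_air_pct = pmin(pmax(rh * 100 + smooth_noise(length(t), rh_sd * 100),
                           0), 100),
    air_speed_m_s = speed
  ))
  air_schedule(series = ser)
}
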