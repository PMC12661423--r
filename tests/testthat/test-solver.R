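test_that("air schedules validate, interpolate and average", {
  expect_error(air_schedule(25, rh = 1.2), "0, 1")
  ser <- tibble::tibble(time_s = c(0, 600, 1200), temp_air_C = c(25, 30, 30),
                        rh_air_pct = c(30, 20, 20))
  sch <- air_schedule(series = ser)
  a <- air_at(sch, c(0, 300, 5000))
  expect_equal(a$T_air_K, c(298.15, 300.65, 303.15))  # linear, then held
  expect_equal(a$RH, c(0.30, 0.25, 0.20))
  expect_error(air_schedule(series = ser[c(2, 1, 3), ]), "increasing")
  out <- air_schedule(series = dplyr::mutate(ser, temp_air_C = temp_air_C + 2,
                                             rh_air_pct = rh_air_pct + 10))
  avg <- average_schedules(sch, out)
  expect_equal(air_at(avg, 0)$T_air_K, 299.15)
  expect_equal(air_at(avg, 0)$RH, 0.35)
})

test_that("initialisation builds equal-volume shells with uniform moisture", {
  cfg <- drying_config(N = 10)
  st <- initialize_seed(cfg)
  geo <- seeddry:::.geometry(st, cfg, seeddry:::.shell_materials(cfg))
  expect_equal(sum(geo$V), 4 / 3 * pi * cfg$R0^3, tolerance = 1e-12)
  expect_equal(max(geo$V) / min(geo$V), 1, tolerance = 1e-9)   # equal volumes
  expect_true(all(diff(geo$r_out) > 0))
  expect_equal(max(geo$c_w) - min(geo$c_w), 0, tolerance = 1e-9 * geo$c_w[1])
  expect_equal(state_mc(st), cfg$MC0, tolerance = 1e-10)
  expect_error(drying_config(MC0 = 1.2), "0, 1")
  expect_error(drying_config(N = 2), ">= 3")
})

test_that("transfer coefficients follow the Ranz-Marshall closures", {
  # pure-diffusion limit
  tc0 <- transfer_coefficients(1e-3, U = 0, T_film_K = 298.15, lambda_eff = 0.4)
  expect_equal(tc0$Sh, 2)
  expect_equal(tc0$Nu, 2)
  # series resistances: h_eff below both
  tc <- transfer_coefficients(1e-3, 0.235, 298.15, 0.4)
  expect_lt(tc$h_eff, min(tc$h_int, tc$h_ext))
  # frozen spreadsheet oracle at U = 0.235 m/s, R = 1 mm, air at 298.15 K
  expect_equal(tc$beta_ext, 0.0612451467335976, tolerance = 1e-12)
  expect_equal(tc$h_ext, 64.4446884957988, tolerance = 1e-12)
  expect_equal(tc$h_eff, 61.9494912062609, tolerance = 1e-12)
})

test_that("evaporative flux uses the boundary-layer average temperature", {
  cst <- material_constants()
  # equilibrium: a_w = RH gives zero flux
  expect_equal(evaporative_flux(0.3, 298.15, 298.15, 0.3, 0.06, cst), 0)
  # hand evaluation incl. T_avg = (303.15 + 2*293.15)/3 = 296.4833 K
  J <- evaporative_flux(0.8, 293.15, 303.15, 0.3, 0.06, cst)
  T_avg <- (303.15 + 2 * 293.15) / 3
  expect_equal(T_avg, 296.4833, tolerance = 1e-6)
  J_hand <- 0.06 * cst$M_w / (cst$R_gas * T_avg) *
    (0.8 - 0.3) * saturation_pressure(293.15)
  expect_equal(J, J_hand, tolerance = 1e-12)
  # condensation (negative flux) is allowed
  expect_lt(evaporative_flux(0.1, 298.15, 298.15, 0.9, 0.06, cst), 0)
})

test_that("internal Fickian flows match a hand-computed two-interface toy", {
  cfg <- drying_config(N = 3, shrink = FALSE, isothermal = TRUE,
                       boundary = "dirichlet_zero", D_override = 2e-10)
  V <- rep(1e-9, 3)
  st <- toy_state(m_s = rep(1e-6, 3), m_w = c(4e-7, 3e-7, 2e-7), V = V)
  fl <- internal_fluxes(st, cfg)
  # independent arithmetic: radii from cumulative volumes, centroid gradient
  r_out <- (3 * cumsum(V) / (4 * pi))^(1 / 3)
  r_in <- c(0, r_out[-3])
  r_c <- ((r_out^3 + r_in^3) / 2)^(1 / 3)
  A <- 4 * pi * r_out^2
  c_w <- c(4e-7, 3e-7, 2e-7) / V  # kg m^-3
  q1 <- 2e-10 * (c_w[1] - c_w[2]) / (r_c[2] - r_c[1]) * A[1]
  q2 <- 2e-10 * (c_w[2] - c_w[3]) / (r_c[3] - r_c[2]) * A[2]
  expect_equal(fl$flow_kg_s, c(q1, q2), tolerance = 1e-12)
  # uniform concentration: no internal flow
  st0 <- toy_state(rep(1e-6, 3), rep(3e-7, 3), V)
  expect_equal(internal_fluxes(st0, cfg)$flow_kg_s, c(0, 0))
  # antisymmetry: reversing the gradient flips the sign
  str <- toy_state(rep(1e-6, 3), c(2e-7, 3e-7, 4e-7), V)
  expect_equal(internal_fluxes(str, cfg)$flow_kg_s, -c(q1, q2),
               tolerance = 1e-12)
})

test_that("heat balance rests at air temperature and finds a wet-bulb state", {
  cst <- material_constants()
  expect_equal(heat_rate(298.15, 298.15, 0, 60, 1e-5, 1100, 2500, 4e-9, cst), 0)
  expect_gt(heat_rate(293.15, 298.15, 0, 60, 1e-5, 1100, 2500, 4e-9, cst), 0)
  # verbatim convention reverses the convective sign
  expect_lt(heat_rate(293.15, 298.15, 0, 60, 1e-5, 1100, 2500, 4e-9, cst,
                      sign_convention = "verbatim"), 0)
  # steady state h_eff (T_air - T) = L J(T) reproduces a pseudo-wet-bulb
  # temperature below the air temperature (root-find oracle, a_w = 1 surface)
  T_air <- 298.15; RH <- 0.30
  balance <- function(T) {
    tc <- transfer_coefficients(1e-3, 0.235, (T_air + 2 * T) / 3, 0.4)
    J <- evaporative_flux(1, T, T_air, RH, tc$beta_ext, cst)
    heat_rate(T, T_air, J, tc$h_eff, 1.26e-5, 1100, 2500, 4.19e-9, cst)
  }
  T_wb <- uniroot(balance, c(273.5, 298.1), tol = 1e-8)$root
  expect_lt(T_wb, T_air)
  expect_gt(T_wb, 278)   # physically sensible depression for 25 C / 30 % RH
  expect_equal(balance(T_wb), 0, tolerance = 1e-6)
})

test_that("a seed in equilibrium with the air is a fixed point of the stepper", {
  mc0 <- 0.10  # rubbery, a_w < 1
  cfg <- drying_config(N = 6, MC0 = mc0, isotherm = iso_fh(1.244))
  aw0 <- water_activity(mc0, 298.15, whole_comp, cfg$isotherm)
  sch <- air_schedule(25, rh = aw0)
  st <- initialize_seed(cfg)
  st1 <- st
  for (i in 1:200) st1 <- seed_step(st1, cfg, sch, dt = 1)
  expect_equal(st1$m_w, st$m_w, tolerance = 1e-9)
  expect_equal(st1$T_K, st$T_K, tolerance = 1e-9)
})

test_that("one step conserves mass exactly against the evaporated accumulator", {
  cfg <- drying_config(N = 8)
  st <- initialize_seed(cfg)
  st1 <- seed_step(st, cfg, sched25)
  expect_equal(sum(st$m_w) - sum(st1$m_w), st1$evaporated, tolerance = 1e-9)
  # negative water guard: a huge forced step must abort, not go negative
  expect_error(seed_step(st, cfg, sched25, dt = 1e5), "Negative shell water")
})

test_that("drying runs conserve water, keep solids Lagrangian and shrink", {
  cfg <- drying_config(N = 8)
  st0 <- initialize_seed(cfg)
  curve <- run_drying(cfg, sched25, duration = 4 * 3600, out_dt = 900)
  ma <- attr(curve, "mass_audit")
  expect_equal(ma$water_initial - ma$water_final, ma$evaporated,
               tolerance = 1e-8)
  fin <- attr(curve, "final_state")
  expect_equal(fin$m_s, st0$m_s, tolerance = 1e-12)
  # monotone drying while air is drier than the seed
  expect_true(all(diff(curve$mc_wb) <= 0))
  expect_true(all(diff(curve$time_s) > 0))
  # radius shrinks during net drying
  mat <- seeddry:::.shell_materials(cfg)
  r0 <- max(seeddry:::.geometry(st0, cfg, mat)$r_out)
  r1 <- max(seeddry:::.geometry(fin, cfg, mat)$r_out)
  expect_lt(r1, r0)
  # seed temperature dips (evaporative cooling) then recovers toward the air
  expect_lt(min(curve$temp_seed_K), 298.15)
  expect_gt(dplyr::last(curve$temp_seed_K), 297)
})

test_that("moisture curves converge as the shell count doubles", {
  sch <- sched25
  cs <- lapply(c(5, 10, 20), function(N) {
    run_drying(drying_config(N = N), sch, duration = 6 * 3600, out_dt = 1800)
  })
  err5 <- max(abs(cs[[1]]$mc_wb - cs[[3]]$mc_wb))
  err10 <- max(abs(cs[[2]]$mc_wb - cs[[3]]$mc_wb))
  expect_lt(err10, err5)          # refinement reduces the deviation
  expect_lt(err10, 0.35 * err5)   # at least ~first-order gain per doubling
})

test_that("the water-activity interface flux reduces to the Fickian flux", {
  iso <- iso_ls(1.244)
  cfg2 <- drying_config(N = 6, material_mode = "two_material",
                        isotherm_embryo = iso, isotherm_coat = iso,
                        composition_embryo = whole_comp,
                        composition_coat = whole_comp)
  cfg1 <- drying_config(N = 6, isotherm = iso, composition = whole_comp)
  st <- initialize_seed(cfg1)
  st$m_w <- st$m_w * seq(1.03, 0.97, length.out = 6)  # small outward gradient
  q_aw <- as.numeric(coat_flux(st, cfg2))
  q_fick <- internal_fluxes(st, cfg1)$flow_kg_s[5]
  expect_equal(q_aw / q_fick, 1, tolerance = 0.01)
  # equal activities give zero flow, and water runs down the a_w gradient
  st0 <- initialize_seed(cfg1)
  expect_equal(as.numeric(coat_flux(st0, cfg2)), 0, tolerance = 1e-25)
  expect_gt(q_aw, 0)
  expect_lt(as.numeric(coat_flux({
    s <- st; s$m_w <- rev(st$m_w); s
  }, cfg2)), 0)
})

test_that("two-material model with identical materials matches one-material", {
  iso <- iso_ls(1.244)
  cfg1 <- drying_config(N = 10, isotherm = iso)
  cfg2 <- drying_config(N = 10, material_mode = "two_material",
                        isotherm_embryo = iso, isotherm_coat = iso,
                        composition_embryo = whole_comp,
                        composition_coat = whole_comp)
  c1 <- run_drying(cfg1, sched25, duration = 4 * 3600, out_dt = 1800)
  c2 <- run_drying(cfg2, sched25, duration = 4 * 3600, out_dt = 1800)
  expect_lt(max(abs(c1$mc_wb - c2$mc_wb)), 0.01)
})

test_that("the genuine coat/embryo model runs and evaporates via the coat", {
  cfg <- drying_config(N = 8, material_mode = "two_material")
  curve <- run_drying(cfg, sched25, duration = 2 * 3600, out_dt = 1800)
  expect_true(all(diff(curve$mc_wb) <= 0))
  fin <- attr(curve, "final_state")
  y_coat <- fin$m_w[8] / (fin$m_w[8] + fin$m_s[8])
  aw_coat <- water_activity(y_coat, fin$T_K, default_composition("coat"),
                            cfg$isotherm_coat)
  expect_equal(dplyr::last(curve$aw_surface), aw_coat, tolerance = 1e-9)
})

test_that("Biot number stays lumped-capacity small and scales with air speed", {
  # quiescent-air limit: Nu -> 2, so Bi -> lambda_air / lambda_eff
  cfg <- drying_config()
  et <- effective_thermal(default_composition("whole", y_w = cfg$MC0),
                          cfg$T0_seed, cfg$constants)
  expect_equal(compute_biot(cfg, U = 0),
               seeddry:::.air_props((298.15 + 2 * 298.15) / 3)$lambda_air /
                 et$lambda_eff,
               tolerance = 1e-9)
  expect_lt(compute_biot(cfg, U = 0.235), 0.4)
  expect_gt(compute_biot(cfg, U = 1), compute_biot(cfg, U = 0.235))
})

test_that("time-varying measured-air schedules drive the solver", {
  sch <- gen_air_schedule(duration = 2 * 3600, step = 300, temp_C = 25,
                          rh = 0.30, seed = 4)
  cfg <- drying_config(N = 6)
  curve <- run_drying(cfg, sch, duration = 2 * 3600, out_dt = 900)
  expect_true(all(diff(curve$mc_wb) < 0))
  expect_equal(nrow(curve), 9)
})
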