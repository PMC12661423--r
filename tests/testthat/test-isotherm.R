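test_that("chi_eff interpolates between concentrated and semi-dilute regimes", {
  expect_equal(chi_eff(0.465, c(0, 0.3, 0.9)), rep(0.465, 3))
  expect_equal(chi_eff(1.244, 0), 1.244)
  expect_equal(chi_eff(1.244, 0.5), 1.058, tolerance = 1e-12)  # hand arithmetic
  # continuity at chi_ws = 0.5
  expect_equal(chi_eff(0.5 + 1e-12, 0.7), chi_eff(0.5, 0.7), tolerance = 1e-9)
  expect_error(chi_eff(1.2, 1.5), "0, 1")
})

test_that("Couchman-Karasz T_g has the right limits and analytic derivative", {
  ck <- ck_params()
  expect_equal(tg_couchman_karasz(0, ck)$T_g, ck$T_g_s)
  expect_equal(tg_couchman_karasz(1, ck)$T_g, ck$T_g_w)
  # derivative vs central finite difference
  h <- 1e-7
  for (yw in c(0.05, 0.15, 0.5, 0.9)) {
    fd <- (tg_couchman_karasz(yw + h, ck)$T_g -
             tg_couchman_karasz(yw - h, ck)$T_g) / (2 * h)
    expect_equal(tg_couchman_karasz(yw, ck)$dTg_dyw, fd, tolerance = 1e-6)
  }
  expect_true(all(tg_couchman_karasz(seq(0, 1, 0.1), ck)$dTg_dyw < 0))
})

test_that("free-volume addition vanishes at the transition and is negative below", {
  p <- isotherm_params(model = "FH_FV")
  # at the glass transition (1 - T/T_g) = 0
  ystar <- yw_at_tg(298.15)
  expect_equal(mu_fv(ystar, 298.15, p), 0, tolerance = 1e-10)
  expect_identical(mu_fv(1, 298.15, p), 0)          # (1-y_w)^2 = 0 and rubbery
  expect_identical(mu_fv(0.3, 298.15, p), 0)        # rubbery side inactive
  # glassy side: dT_g/dy_w < 0 and T < T_g make the addition negative
  glassy_y <- seq(0.005, ystar * 0.95, length.out = 20)
  expect_true(all(mu_fv(glassy_y, 298.15, p) < 0))
})

test_that("Leibler-Sekimoto addition is zero at the transition and linear in K_g", {
  p <- isotherm_params(model = "FH_LS", K_g = 3.3e9)
  expect_identical(mu_ls(0.25, 298.15, p, phi_w_tg = 0.25), 0)
  p2 <- p; p2$K_g <- 2 * p$K_g
  expect_equal(mu_ls(0.1, 298.15, p2, 0.25), 2 * mu_ls(0.1, 298.15, p, 0.25))
  # frozen arbitrary-precision oracle, |mu_LS| at phi 0.1, phi_tg 0.25,
  # T 298.15 K, K_g 3.3e9 Pa, nu_w = M_w/rho_w(25 C)
  expect_equal(mu_ls(0.1, 298.15, p, 0.25), -4.39505922752773,
               tolerance = 1e-10)
  pv <- isotherm_params(model = "FH_LS", K_g = 3.3e9, ls_form = "as_printed")
  expect_equal(mu_ls(0.1, 298.15, pv, 0.25), +4.39505922752773,
               tolerance = 1e-10)
  expect_error(mu_ls(0.1, 298.15, p, phi_w_tg = 1), "degenerate")
})

test_that("phi_at_tg inverts the glass-transition curve", {
  p <- isotherm_params()
  # grid-scan oracle: finest y_w whose T_g crosses 298.15 K
  grid <- seq(1e-6, 0.5, length.out = 1e6)
  tg <- tg_couchman_karasz(grid, p$ck)$T_g
  y_scan <- grid[which.min(abs(tg - 298.15))]
  phi_scan <- water_volume_fraction(
    default_composition("whole", y_w = y_scan), 298.15)
  expect_equal(phi_at_tg(298.15, whole_comp, p), phi_scan, tolerance = 1e-5)
  # round trip through the closed form
  ystar <- yw_at_tg(310, p$ck)
  expect_equal(tg_couchman_karasz(ystar, p$ck)$T_g, 310, tolerance = 1e-8)
  # toward T_g,s the crossing moisture (hence phi) vanishes
  expect_lt(phi_at_tg(p$ck$T_g_s - 0.01, whole_comp, p), 1e-4)
  expect_error(phi_at_tg(500, whole_comp, p), "no glass-transition")
  expect_error(phi_at_tg(100, whole_comp, p), "no glass-transition")
})

test_that("water activity has the Flory-Huggins limits and frozen oracle value", {
  p <- iso_fh(1.244)
  expect_equal(water_activity(1, 298.15, whole_comp, p), 1, tolerance = 1e-12)
  expect_lt(water_activity(1e-5, 298.15, whole_comp, p), 1e-3)
  # frozen arbitrary-precision oracle: y_w = 0.2 (phi = 0.36647), FH model
  withr::local_options(rlib_message_verbosity = "verbose")
  expect_message(
    aw <- water_activity(0.2, 298.15, whole_comp, p),
    "not clipped"
  )
  expect_equal(aw, 1.09225729353347, tolerance = 1e-10)
  expect_error(water_activity(0, 298.15, whole_comp, p), "positive")
  expect_error(water_activity(-0.1, 298.15, whole_comp, p), "positive")
  # clip option
  pc <- isotherm_params(model = "FH", chi_ws = 1.244, clip_aw = TRUE)
  expect_identical(water_activity(0.2, 298.15, whole_comp, pc), 1)
})

test_that("water activity is continuous across the glass transition", {
  ystar <- yw_at_tg(298.15)
  for (m in c("FH_FV", "FH_LS")) {
    p <- isotherm_params(model = m, chi_ws = 1.244)
    for (eps in c(1e-3, 1e-5)) {
      gap <- abs(water_activity(ystar - eps, 298.15, whole_comp, p) -
                   water_activity(ystar + eps, 298.15, whole_comp, p))
      expect_lt(gap, 200 * eps)  # shrinks proportionally with eps
    }
  }
})

test_that("FH activity with chi <= 0.5 rises monotonically with moisture", {
  cur <- sorption_curve(iso_fh(0.465), coat_comp, 298.15, n = 400)
  expect_true(all(diff(cur$a_w) > 0))
})

test_that("equilibrium moisture inverts the isotherm and orders the variants", {
  for (m in c("FH", "FH_FV", "FH_LS")) {
    p <- isotherm_params(model = m, chi_ws = 1.244)
    for (rh in c(0.1, 0.3, 0.6)) {
      y <- equilibrium_moisture(rh, 298.15, whole_comp, p)
      expect_equal(water_activity(y, 298.15, whole_comp, p), rh,
                   tolerance = 1e-6)
    }
  }
  # glassy corrections raise the retained moisture: FH_LS > FH_FV > FH
  eq <- vapply(c("FH", "FH_FV", "FH_LS"), function(m) {
    equilibrium_moisture(0.3, 298.15, whole_comp,
                         isotherm_params(model = m, chi_ws = 1.244))
  }, numeric(1))
  expect_true(eq[["FH_LS"]] > eq[["FH_FV"]])
  expect_true(eq[["FH_FV"]] > eq[["FH"]])
  # wetter air gives wetter equilibria, toward the wet limit (coat isotherm)
  eqc <- vapply(c(0.5, 0.9, 0.999), function(r) {
    equilibrium_moisture(r, 298.15, coat_comp, iso_fh(0.465))
  }, numeric(1))
  expect_true(all(diff(eqc) > 0))
  expect_gt(eqc[3], 0.5)
  expect_error(equilibrium_moisture(1.2, 298.15), "strictly within")
})

test_that("chi fitting recovers generating parameters from synthetic tables", {
  # chi > 0.5 branch; grid chosen in the rubbery range
  p <- iso_fh(1.244)
  tab <- gen_sorption_table(p, whole_comp, aw = c(0.90, 0.93, 0.96))
  fit <- fit_chi(tab, whole_comp, p)
  expect_equal(fit$chi_ws, 1.244, tolerance = 1e-6)
  # chi <= 0.5 branch (coat material): wetter isotherm, wider rubbery range
  p2 <- iso_fh(0.465)
  tab2 <- gen_sorption_table(p2, coat_comp, aw = c(0.6, 0.7, 0.8, 0.9))
  fit2 <- fit_chi(tab2, coat_comp, p2)
  expect_equal(fit2$chi_ws, 0.465, tolerance = 1e-6)
  # 1 % multiplicative noise at fixed seed: recovery within 2 %
  tab3 <- suppressMessages(gen_sorption_table(
    p, whole_comp, aw = seq(0.84, 0.97, by = 0.01), noise_sd = 0.01, seed = 7))
  fit3 <- suppressMessages(fit_chi(tab3, whole_comp, p))
  expect_equal(fit3$chi_ws, 1.244, tolerance = 0.02)
  expect_true(is.finite(fit3$se) && fit3$se > 0)
  # too few rubbery rows
  glassy_tab <- gen_sorption_table(p, whole_comp, aw = c(0.2, 0.3, 0.4))
  expect_error(suppressMessages(fit_chi(glassy_tab, whole_comp, p)), ">= 3")
  # tidiers
  expect_named(tidy(fit), c("term", "estimate", "std.error"))
  expect_equal(glance(fit)$n, 3)
})

test_that("K_g fitting recovers the modulus from glassy final moisture contents", {
  p <- iso_ls(1.244, K_g = 3.3e9)
  rhs <- c(0.10, 0.20, 0.30, 0.40)
  mcs <- vapply(rhs, function(r) equilibrium_moisture(r, 298.15, whole_comp, p),
                numeric(1))
  fit <- fit_kg(tibble::tibble(rh = rhs, temp_K = 298.15, mc_wb = mcs),
                whole_comp, p)
  expect_equal(fit$K_g, 3.3e9, tolerance = 1e-3)
  # a single exact glassy point identifies the one free parameter
  fit1 <- fit_kg(tibble::tibble(rh = 0.3, temp_K = 298.15, mc_wb = mcs[3]),
                 whole_comp, p)
  expect_equal(fit1$K_g, 3.3e9, tolerance = 1e-3)
  # rubbery points carry no information
  wet <- tibble::tibble(rh = 0.97, temp_K = 298.15, mc_wb = 0.2)
  expect_error(fit_kg(wet, whole_comp, p), "rubbery")
  expect_equal(tidy(fit)$term, "K_g")
})
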