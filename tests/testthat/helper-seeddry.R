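# shared fixtures: all synthetic, built in code
whole_comp <- default_composition("whole")
coat_comp <- default_composition("coat")

iso_fh <- function(chi = 1.244) isotherm_params(model = "FH", chi_ws = chi)
iso_ls <- function(chi = 1.244, K_g = 3.3e9) {
  isotherm_params(model = "FH_LS", chi_ws = chi, K_g = K_g)
}

sched25 <- air_schedule(25, 0.30)

# moisture mass fraction at which the default mixture crosses its glass
# transition at temperature T (closed-form Couchman-Karasz inversion,
# recomputed here independently of the package internals)
yw_at_tg <- function(T_K, ck = ck_params()) {
  q <- ck$dCp_s * (T_K - ck$T_g_s) / (ck$dCp_w * (ck$T_g_w - T_K))
  q / (1 + q)
}

# build a seed_state by hand (non-shrinking geometry), for flux oracles
toy_state <- function(m_s, m_w, V, T_K = 298.15) {
  structure(list(m_s = m_s, m_w = m_w, T_K = T_K, t = 0, evaporated = 0,
                 V0_shells = V),
            class = "seed_state")
}
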