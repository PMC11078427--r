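# Shared fixtures: all synthetic, built in code at test time.

# 6-row toy table, 2 groups x 2 scores.
toy_table <- function() {
  data.frame(
    id = 1:6,
    pop = rep(c("A", "B"), each = 3L),
    y = c(1.2, 0.5, -0.3, 2.0, 1.1, -0.7),
    pgs1 = c(0.9, 0.1, -0.5, 1.6, 0.8, -1.0),
    pgs2 = c(0.3, -0.2, 0.4, 1.1, 0.2, -0.4))
}

# Draw K = 2 populations under a simulation setting.
draw_pair <- function(setting = "I", tau = 0.4, phi = 0.5, delta = 0,
                      n = 500, P = 3, seed = 1) {
  mats <- build_setting_matrices(setting, tau, phi, delta, P = P)
  set.seed(seed)
  list(simulate_population(mats$A, n, "A"),
       simulate_population(mats$B, n, "B"))
}

# assemble_joint without the small-sample advisory warning (tests often use
# deliberately small n).
joint_quiet <- function(samples) {
  withCallingHandlers(
    assemble_joint(samples),
    corcompare_small_sample = function(w) invokeRestart("muffleWarning"))
}
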