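# Shared in-code fixtures. Everything is generated at test time; nothing
# is read from disk except the bundled example designs.

# A tiny hand-written calibration table with easy arithmetic.
tiny_records <- function() {
  data.frame(
    peg_pi = c(20, 40, 60, 80),
    focus_z = c(0, 2, 4, 6),
    conjugate_conc = c(0, 0, 2, 2),
    youngs_modulus = c(2, 6, 12, 20),
    linewidth = c(50, 120, 200, 280),
    bound_signal = c(0, 0, 1.5, 2)
  )
}

tiny_space <- function(...) state_space(tiny_records(), ...)

# Seeded medium synthetic calibration shared across tests (kernel-smoothing
# tests, solver round trips). Cached per session.
.calib_cache <- new.env(parent = emptyenv())
shared_calibration <- function(seed = 101) {
  key <- as.character(seed)
  if (is.null(.calib_cache[[key]])) {
    .calib_cache[[key]] <- gen_calibration(seed = seed)
  }
  .calib_cache[[key]]
}

# Independent scalar-loop Nadaraya-Watson oracle (no vectorization, no
# shared code with the implementation).
nw_oracle <- function(records, x, z, bw = 0.1, rx = 40, rz = 6) {
  num_e <- num_w <- num_b <- den <- 0
  for (i in seq_len(nrow(records))) {
    dx <- (records$peg_pi[i] - x) / rx
    dz <- (records$focus_z[i] - z) / rz
    tau <- (1 / (bw * 2 * pi)) * exp(-0.5 * ((dx / bw)^2 + (dz / bw)^2))
    num_e <- num_e + tau * records$youngs_modulus[i]
    num_w <- num_w + tau * records$linewidth[i]
    num_b <- num_b + tau * records$bound_signal[i]
    den <- den + tau
  }
  c(youngs_modulus = num_e / den, linewidth = num_w / den,
    bound_signal = num_b / den)
}

# Closed-form Sneddon force, written independently of the package.
sneddon_oracle <- function(delta, E, theta_deg = 18, nu = 0.5) {
  (2 / pi) * tan(theta_deg * pi / 180) * E / (1 - nu^2) * delta^2
}

example_design <- function(name) {
  read_design(system.file("extdata", paste0(name, ".json"),
                          package = "nichefab"))
}

example_space <- function(...) {
  load_calibration(system.file("extdata", "synthetic_calibration.csv",
                               package = "nichefab"), ...)
}
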