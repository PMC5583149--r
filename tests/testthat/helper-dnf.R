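# shared fixtures built in code

std <- dnf_preset()

# localized Gaussian input bump on a periodic grid, width in degrees
gauss_bump <- function(grid, center_deg, amp, sigma_deg = 10.8) {
  d <- abs(grid$sites - center_deg)
  d <- pmin(d, grid$extent - d)
  amp * exp(-d^2 / (2 * sigma_deg^2))
}

# O(n^2) brute-force convolution oracle: explicit double loop over site pairs
brute_lateral <- function(out, kern, grid) {
  n <- grid$n_sites
  drive <- numeric(n)
  for (i in seq_len(n)) {
    acc <- 0
    for (j in seq_len(n)) {
      m <- abs(i - j)
      if (grid$periodic) m <- min(m, n - m)
      acc <- acc + kern[m + 1] * out[j]
    }
    drive[i] <- acc
  }
  drive
}

# relax the field under a fixed input for n steps
relax <- function(state, input, kern, tp, dyn, grid, n = 400) {
  for (i in seq_len(n)) state <- field_step(state, input, kern, tp, dyn, grid)
  state
}

# smaller of the two roots of the bias-rule quadratic, via polyroot
bias_rule_root <- function(mu) {
  r <- polyroot(c(1, -(2 + 1 / mu), 1 / mu))
  min(Re(r[abs(Im(r)) < 1e-9]))
}
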