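# Shared fixtures built in code.

# noise-free (x, y) pairs on y = k * x^alpha
power_pairs <- function(k, alpha, x) data.frame(x = x, y = k * x^alpha)

make_region <- function(shh = c(200, 500), fgf8 = c(800, 1000)) {
  crosstalk_region(shh, fgf8)
}

# a small feasible blastema measurement for image tests
demo_measurement <- function() {
  list(L = 2000, shh = c(50, 420), fgf8 = c(600, 1300))
}

demo_image <- function(seed = 1L, ...) {
  m <- demo_measurement()
  generate_section_image(m$L, m$shh, m$fgf8, seed = seed, ...)
}

# closed-form root of S(x) = K anterior to the source, independent of the
# grid-based anterior_boundary(): solves B*cosh(beta*(L - x)) = K exactly.
boundary_oracle <- function(params, L, level = 0.5) {
  theta <- source_size(params, L)
  beta <- 1 / params$beta_inv
  # level 0.5 on the Hill readout corresponds to S = K
  target <- params$K * (level / (1 - level))^(1 / params$h)
  B <- sinh(beta * theta) / sinh(beta * L)
  s0g <- params$s0_over_gamma
  if (target / (s0g * B) < 1) return(numeric(0))
  L - acosh(target / (s0g * B)) / beta
}
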