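# Shared fixtures and independent oracles for the test suite.

# 2 subjects x 2 observers, single measurement: values 1,2 / 3,5.
toy_data <- function() {
  agreement_data(subject = c("s1", "s1", "s2", "s2"),
                 observer = c("o1", "o2", "o1", "o2"),
                 value = c(1, 2, 3, 5))
}

# Random balanced dataset using the current RNG state.
random_balanced <- function(a = 5, b = 4, c = 1, mu = 10,
                            sigma_A = 2, sigma_B = 1, sigma_E = 0.7) {
  simulate_loam_data(a = a, b = b, c = c, mu = mu, sigma_A = sigma_A,
                     sigma_B = sigma_B, sigma_E = sigma_E)
}

# Brute-force sums of squares straight from the defining sums, written as
# explicit loops so it shares no code path with sums_of_squares().
brute_force_ss <- function(data) {
  subs <- unique(data$subject)
  obs <- unique(data$observer)
  a <- length(subs); b <- length(obs)
  cc <- nrow(data) / (a * b)
  gm <- mean(data$value)
  SSA <- 0; SSB <- 0; SSE <- 0
  mi <- sapply(subs, function(s) mean(data$value[data$subject == s]))
  mj <- sapply(obs, function(o) mean(data$value[data$observer == o]))
  for (s in subs) SSA <- SSA + b * cc * (mi[[s]] - gm)^2
  for (o in obs) SSB <- SSB + a * cc * (mj[[o]] - gm)^2
  for (r in seq_len(nrow(data))) {
    SSE <- SSE + (data$value[r] - mi[[data$subject[r]]] -
                    mj[[data$observer[r]]] + gm)^2
  }
  list(SSA = SSA, SSB = SSB, SSE = SSE)
}

# Assemble a loam_ss object from raw components (for interval tests that feed
# synthetic sums of squares rather than data).
make_ss <- function(SSA = 0, SSB, SSE, a, b, c = 1) {
  nu_A <- a - 1; nu_B <- b - 1; nu_E <- a * b * c - a - b + 1
  structure(list(SSA = SSA, SSB = SSB, SSE = SSE,
                 nu_A = nu_A, nu_B = nu_B, nu_E = nu_E,
                 MSA = SSA / nu_A, MSB = SSB / nu_B, MSE = SSE / nu_E,
                 N = a * b * c, dims = c(a = a, b = b, c = c)),
            class = "loam_ss")
}
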