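# Independent brute-force oracles, kept deliberately naive and separate from
# the package implementations they check.

# alternation: enumerate every 4-entry window, count all-distinct ones
oracle_alternation_percent <- function(seq, denominator = "entries_minus_2") {
  n <- length(seq)
  stopifnot(n >= 4)
  wins <- 0
  for (i in 1:(n - 3)) {
    w <- seq[i:(i + 3)]
    if (!any(duplicated(w))) wins <- wins + 1
  }
  denom <- if (denominator == "entries_minus_2") n - 2 else n - 3
  100 * wins / denom
}

# random no-consecutive-repeat sequence over the color labels
random_arm_sequence <- function(n, labels = c("B", "G", "R", "W")) {
  out <- character(n)
  out[1] <- sample(labels, 1)
  for (i in seq_len(n - 1)) {
    out[i + 1] <- sample(setdiff(labels, out[i]), 1)
  }
  out
}

# transition tally by direct paste-and-table
oracle_uni_counts <- function(seq) {
  keys <- paste0(seq[-length(seq)], ">", seq[-1])
  table(keys)
}

# fine-grid quadrature oracle for the photometric integrals (0.1-nm step)
oracle_band_irradiance <- function(lux, peak_nm, fwhm_nm) {
  lambda <- seq(300, 800, by = 0.1)
  sigma <- fwhm_nm / (2 * sqrt(2 * log(2)))
  s <- dnorm(lambda, peak_nm, sigma)
  s <- s / sum((s[-1] + s[-length(s)]) / 2 * diff(lambda))
  v <- vis4m::cie_photopic_luminosity(lambda)
  overlap <- sum((s * v)[-1] + (s * v)[-length(s)]) / 2 * 0.1
  lux / (683 * overlap) * 100
}
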