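# random DVH fixtures used by the property-style tests

random_diff_dvh <- function(n_bins = NULL, max_dose = 40) {
  if (is.null(n_bins)) n_bins <- sample(2:25, 1)
  doses <- sort(runif(n_bins, 0, max_dose))
  vols <- rgamma(n_bins, shape = 1)
  make_differential(doses, vols / sum(vols), "random")
}

# strictly decreasing cumulative curve (no flat segments), for the
# V/D inverse-consistency checks
random_strict_cum <- function(n = 8, max_dose = 40) {
  doses <- c(0, sort(runif(n - 1, 1, max_dose)))
  vf <- c(1, sort(runif(n - 2, 0.05, 0.95), decreasing = TRUE), 0)
  make_cumulative(doses, vf, "random")
}

parotid_rs <- ntcp_presets("parotid_xerostomia_rs")
lacrimal_rs <- ntcp_presets("lacrimal_dryeye_rs")

# independent scalar form of the Poisson response, kept separate from the
# package's vectorized implementation
oracle_poisson <- function(D, d50, gamma) {
  2^(-exp(exp(1) * gamma * (1 - D / d50)))
}

# s -> 0 (parallel) limit: geometric mean of -ln P weighted by bin volume
oracle_rs_parallel <- function(d, p) {
  P <- oracle_poisson(d$bin_dose, p$d50, p$gamma)
  exp(-exp(sum(d$bin_volume * log(-log(P)))))
}

# s = 1 (serial) closed form
oracle_rs_serial <- function(d, p) {
  P <- oracle_poisson(d$bin_dose, p$d50, p$gamma)
  1 - prod((1 - P)^d$bin_volume)
}
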