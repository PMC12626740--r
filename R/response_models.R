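#' Relative-seriality model parameters
#'
#' Parameter set of the Poisson / relative-seriality (RS) dose-response
#' model: `d50` is the uniform whole-organ dose giving a 50% complication
#' rate, `gamma` the maximum normalized slope of the sigmoid response
#' curve, and `s` the relative-seriality parameter (`s = 1` serial organ,
#' `s -> 0` parallel organ).
#'
#' @param d50 dose in Gy, > 0.
#' @param gamma dimensionless slope, > 0.
#' @param s relative seriality, > 0.
#' @param endpoint_label toxicity endpoint the parameters describe.
#' @return An object of class `rs_params`.
#' @seealso [ntcp_presets()] for the shipped parotid/lacrimal presets.
#' @examples
#' rs_params(24.9, 0.26, 1e-4, "xerostomia")
#' @export
rs_params <- function(d50, gamma, s, endpoint_label = "") {
  if (!is.numeric(d50) || d50 <= 0) stop("d50 must be > 0", call. = FALSE)
  if (!is.numeric(gamma) || gamma <= 0) stop("gamma must be > 0", call. = FALSE)
  if (!is.numeric(s) || s <= 0) stop("s must be > 0", call. = FALSE)
  structure(list(d50 = d50, gamma = gamma, s = s,
                 endpoint_label = as.character(endpoint_label)),
            class = "rs_params")
}

#' Lyman-Kutcher-Burman model parameters
#'
#' Probit model of the generalized equivalent uniform dose: `td50` is the
#' uniform tolerance dose giving 50% complication probability, `m` the
#' slope parameter and `n` the volume-effect parameter (small `n` =
#' serial behaviour). No preset values are shipped for the whole-brain
#' endpoints; callers must supply their own fitted parameters.
#'
#' @param td50 dose in Gy, > 0.
#' @param m dimensionless slope, > 0.
#' @param n dimensionless volume effect, > 0.
#' @param endpoint_label toxicity endpoint.
#' @return An object of class `lkb_params`.
#' @export
lkb_params <- function(td50, m, n, endpoint_label = "") {
  if (!is.numeric(td50) || td50 <= 0) stop("td50 must be > 0", call. = FALSE)
  if (!is.numeric(m) || m <= 0) stop("m must be > 0", call. = FALSE)
  if (!is.numeric(n) || n <= 0) stop("n must be > 0", call. = FALSE)
  structure(list(td50 = td50, m = m, n = n,
                 endpoint_label = as.character(endpoint_label)),
            class = "lkb_params")
}

#' Shipped relative-seriality parameter presets
#'
#' Published RS parameter sets for acute toxicity after whole-brain
#' radiotherapy at 30 Gy in 10 fractions: parotid-gland xerostomia
#' (D50 = 24.9 Gy, gamma = 0.26, s = 1e-4) and lacrimal-gland dry eye
#' (D50 = 63.9 Gy, gamma = 0.34, s = 1e-4). The tiny `s` encodes a
#' highly parallel organ response; note that with these shallow slopes
#' the model's predicted risk at zero dose is deliberately nonzero
#' (about 24.5% for parotid, 17.4% for lacrimal) - a property of the
#' published parameterization, not an implementation artifact.
#'
#' @param name optional preset name; when missing the full named list is
#'   returned.
#' @return A named list of `rs_params` (or one `rs_params`).
#' @examples
#' ntcp_presets("parotid_xerostomia_rs")$d50
#' @export
ntcp_presets <- function(name = NULL) {
  reg <- list(
    parotid_xerostomia_rs = rs_params(24.9, 0.26, 1e-4, "xerostomia"),
    lacrimal_dryeye_rs = rs_params(63.9, 0.34, 1e-4, "dry_eye"))
  if (is.null(name)) return(reg)
  if (!name %in% names(reg))
    stop("unknown preset '", name, "'; available: ",
         paste(names(reg), collapse = ", "), call. = FALSE)
  reg[[name]]
}

# log of P(D) under the Poisson response: ln P = -ln2 * exp(e*gamma*(1 - D/D50))
log_poisson_response <- function(dose, p) {
  -log(2) * exp(exp(1) * p$gamma * (1 - dose / p$d50))
}

#' Poisson dose-response probability for uniform irradiation
#'
#' `P(D) = 2^(-exp(e * gamma * (1 - D/D50)))`, the Poisson-based sigmoid
#' used by the relative-seriality model. Strictly increasing in dose,
#' equal to 0.5 at `D = D50`, and saturating at 1 for large dose.
#'
#' @param dose dose in Gy (vectorized), `>= 0`.
#' @param p an `rs_params` object.
#' @return Response probability in (0, 1).
#' @examples
#' poisson_response(24.9, ntcp_presets("parotid_xerostomia_rs")) # 0.5
#' @export
poisson_response <- function(dose, p) {
  stopifnot(inherits(p, "rs_params"))
  if (any(dose < 0)) stop("dose must be >= 0", call. = FALSE)
  exp(log_poisson_response(dose, p))
}

# log(1 - exp(a)) for a <= 0, accurate over the whole range
log1mexp <- function(a) {
  out <- numeric(length(a))
  hi <- a > -log(2)
  out[hi] <- log(-expm1(a[hi]))
  out[!hi] <- log1p(-exp(a[!hi]))
  out
}

#' Relative-seriality NTCP of a dose distribution
#'
#' Combines per-bin Poisson responses `P(D_i)` into the organ-level
#' complication probability
#' `NTCP = (1 - prod_i (1 - P(D_i)^s)^(dv_i))^(1/s)`.
#' The product is accumulated in log space (`log1p`/`expm1` primitives):
#' at the published `s = 1e-4` the naive product underflows. A single-bin
#' DVH reduces exactly to [poisson_response()] for any `s`; a bin driven
#' to `P = 1` forces NTCP = 1 (serial-limit continuity).
#'
#' @param d a `dvh_diff` (a `dvh_cum` is converted).
#' @param p an `rs_params` object.
#' @return NTCP in \[0, 1\].
#' @examples
#' prs <- ntcp_presets("parotid_xerostomia_rs")
#' rs_ntcp(make_differential(24.9, 1, "parotid"), prs) # 0.5
#' @export
rs_ntcp <- function(d, p) {
  stopifnot(inherits(p, "rs_params"))
  d <- as_differential(d)
  lp <- log_poisson_response(d$bin_dose, p)    # ln P_i, in (-Inf, 0]
  if (any(lp == 0 & d$bin_volume > 0)) return(1)
  # sum_i dv_i * ln(1 - P_i^s); bins with P_i = 0 contribute 0
  term <- log1mexp(p$s * lp)
  S <- sum(d$bin_volume * term)
  if (S == 0) return(0)                        # all-zero response
  exp(log1mexp(S) / p$s)
}

#' Generalized equivalent uniform dose
#'
#' `gEUD = (sum_i dv_i * D_i^(1/n))^n`: the uniform dose producing the
#' same effect as the heterogeneous distribution. `n = 1` gives the mean
#' dose (parallel organ); `n -> 0` approaches the maximum dose (serial).
#'
#' @param d a `dvh_diff` (a `dvh_cum` is converted).
#' @param n volume-effect parameter, > 0.
#' @return gEUD in Gy, between the minimum and maximum occupied bin dose.
#' @examples
#' geud(make_differential(c(10, 30), c(0.5, 0.5)), n = 1) # 20
#' @export
geud <- function(d, n) {
  if (!is.numeric(n) || n <= 0) stop("n must be > 0", call. = FALSE)
  d <- as_differential(d)
  sum(d$bin_volume * d$bin_dose^(1 / n))^n
}

#' Lyman-Kutcher-Burman NTCP
#'
#' `NTCP = Phi((gEUD - TD50) / (m * TD50))` with `Phi` the standard normal
#' cumulative distribution; exactly 0.5 when gEUD equals TD50.
#'
#' @param d a `dvh_diff` (a `dvh_cum` is converted).
#' @param p an `lkb_params` object.
#' @return NTCP in (0, 1).
#' @export
lkb_ntcp <- function(d, p) {
  stopifnot(inherits(p, "lkb_params"))
  g <- geud(d, p$n)
  stats::pnorm((g - p$td50) / (p$m * p$td50))
}

#' Numerically recover the maximum normalized slope of the response curve
#'
#' Evaluates the Poisson response on a dense grid of normalized dose
#' `x = D/D50` in \[0, 3\] (step 1e-4) and returns the maximum
#' central-difference slope `dP/dx`. For the Poisson form this maximum
#' equals `gamma` analytically, and is attained where the response
#' probability passes through `1/e`.
#'
#' @param p an `rs_params` object.
#' @param step grid step in normalized dose (default 1e-4).
#' @return A list with `gamma_hat` (maximum slope), `x_at_max` (normalized
#'   dose of the maximum) and `p_at_max` (response there, approx. `1/e`).
#' @examples
#' max_normalized_slope(ntcp_presets("parotid_xerostomia_rs"))$gamma_hat
#' @export
max_normalized_slope <- function(p, step = 1e-4) {
  stopifnot(inherits(p, "rs_params"))
  x <- seq(0, 3, by = step)
  y <- exp(-log(2) * exp(exp(1) * p$gamma * (1 - x)))
  sl <- (y[-(1:2)] - y[seq_len(length(y) - 2L)]) / (2 * step)
  i <- which.max(sl)
  list(gamma_hat = sl[i], x_at_max = x[i + 1L], p_at_max = y[i + 1L])
}

#' Rescale a DVH to equi-effective dose in 2-Gy fractions (EQD2)
#'
#' Per-bin linear-quadratic conversion
#' `EQD2_i = D_i * (D_i/n_fractions + alpha_beta) / (2 + alpha_beta)`;
#' volumes are unchanged. Opt-in only: the shipped RS presets were fitted
#' and applied at the same 3 Gy/fraction schedule, so the default NTCP
#' pipeline uses physical dose with no conversion.
#'
#' @param d a `dvh_diff` object.
#' @param n_fractions number of fractions, `>= 1`.
#' @param alpha_beta tissue alpha/beta ratio in Gy, > 0.
#' @return A `dvh_diff` with rescaled bin doses.
#' @examples
#' eqd2_dvh(make_differential(30, 1), n_fractions = 10, alpha_beta = 3)
#' @export
eqd2_dvh <- function(d, n_fractions, alpha_beta) {
  stopifnot(inherits(d, "dvh_diff"))
  if (n_fractions < 1) stop("n_fractions must be >= 1", call. = FALSE)
  if (!is.numeric(alpha_beta) || alpha_beta <= 0)
    stop("alpha_beta must be > 0", call. = FALSE)
  eq <- d$bin_dose * (d$bin_dose / n_fractions + alpha_beta) / (2 + alpha_beta)
  make_differential(eq, d$bin_volume, d$structure_label,
                    if (is.na(d$volume_cc)) NULL else d$volume_cc)
}
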