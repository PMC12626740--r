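#' Dose-volume histogram containers
#'
#' `ntcplan` works on per-structure dose-volume histograms in two standard
#' forms. A *differential* DVH stores, for each dose bin `D_i` (Gy), the
#' fraction `dv_i` of the structure volume whose dose falls in that bin;
#' it is the direct argument of every NTCP formula. A *cumulative* DVH
#' stores, on an ascending dose grid, the volume fraction receiving at
#' least that dose; it is the form plotted in treatment-planning systems
#' and used for `V_xGy` / `D_x%` metrics.
#'
#' Both containers use the relative-volume convention internally (volume
#' fractions summing to 1 / starting at 1); absolute volumes in cc are
#' converted at the file I/O boundary and the total, when known, is kept
#' in the `volume_cc` attribute.
#'
#' @name dvh
#' @keywords internal
NULL

#' Construct a differential DVH
#'
#' Builds a validated differential DVH from per-bin doses and volume
#' fractions. Bins are sorted by ascending dose; volume fractions whose
#' raw sum differs from 1 by less than 1% are renormalized (with a
#' message), while larger deviations are treated as an error because they
#' usually signal absolute-volume input that should have been declared as
#' such at the I/O boundary.
#'
#' @param doses numeric vector of bin doses in Gy (representative dose of
#'   each bin; the lower bin edge under the package's rebinning convention).
#' @param volumes numeric vector of non-negative volume fractions, same
#'   length as `doses`.
#' @param label structure label (e.g. `"parotid"`).
#' @param volume_cc optional absolute structure volume in cc, carried as
#'   metadata only.
#'
#' @return An object of class `dvh_diff` with fields `bin_dose`,
#'   `bin_volume`, `structure_label`, `volume_cc`.
#' @examples
#' make_differential(c(20, 10), c(0.5, 0.5), "parotid")
#' @export
make_differential <- function(doses, volumes, label = "structure",
                              volume_cc = NULL) {
  if (length(doses) != length(volumes) || length(doses) < 1L)
    stop("'doses' and 'volumes' must have equal length >= 1", call. = FALSE)
  if (!is.numeric(doses) || !is.numeric(volumes))
    stop("'doses' and 'volumes' must be numeric", call. = FALSE)
  if (anyNA(doses) || anyNA(volumes))
    stop("DVH bins must not contain NA", call. = FALSE)
  if (any(doses < 0))
    stop("negative bin dose", call. = FALSE)
  if (any(volumes < 0))
    stop("negative bin volume", call. = FALSE)
  o <- order(doses)
  doses <- doses[o]; volumes <- volumes[o]
  if (anyDuplicated(doses)) {
    # merge duplicate-dose bins rather than failing the ascending invariant
    volumes <- as.numeric(tapply(volumes, doses, sum))
    doses <- sort(unique(doses))
  }
  s <- sum(volumes)
  if (abs(s - 1) > 0.01)
    stop(sprintf(
      "bin volumes sum to %.6g, more than 1%% away from 1; ",
      s), "supply volume fractions (absolute volumes are converted on read)",
      call. = FALSE)
  if (abs(s - 1) > 1e-9) {
    message(sprintf("renormalizing bin volumes (raw sum %.6f)", s))
    volumes <- volumes / s
  }
  structure(
    list(bin_dose = as.numeric(doses), bin_volume = as.numeric(volumes),
         structure_label = as.character(label),
         volume_cc = if (is.null(volume_cc)) NA_real_ else as.numeric(volume_cc)),
    class = "dvh_diff")
}

#' Construct a cumulative DVH
#'
#' @param dose_grid ascending numeric dose grid in Gy.
#' @param volume_fraction non-increasing volume fractions; must be 1
#'   (within 1e-6) at dose 0 when the grid starts at 0.
#' @param label structure label.
#' @param volume_cc optional absolute structure volume in cc.
#'
#' @return An object of class `dvh_cum`.
#' @examples
#' make_cumulative(c(0, 20, 40), c(1, 0.5, 0), "parotid")
#' @export
make_cumulative <- function(dose_grid, volume_fraction, label = "structure",
                            volume_cc = NULL) {
  if (length(dose_grid) != length(volume_fraction) || length(dose_grid) < 1L)
    stop("grid and fractions must have equal length >= 1", call. = FALSE)
  if (anyNA(dose_grid) || anyNA(volume_fraction))
    stop("cumulative DVH must not contain NA", call. = FALSE)
  if (any(dose_grid < 0)) stop("negative dose in grid", call. = FALSE)
  o <- order(dose_grid)
  dose_grid <- dose_grid[o]; volume_fraction <- volume_fraction[o]
  if (any(diff(dose_grid) <= 0))
    stop("dose grid must be strictly ascending", call. = FALSE)
  if (any(diff(volume_fraction) > 1e-9))
    stop("cumulative volume fractions must be non-increasing", call. = FALSE)
  if (dose_grid[1] == 0 && abs(volume_fraction[1] - 1) > 1e-6)
    stop("cumulative DVH must start at volume fraction 1 at dose 0",
         call. = FALSE)
  if (volume_fraction[length(volume_fraction)] < -1e-12)
    stop("negative volume fraction", call. = FALSE)
  structure(
    list(dose_grid = as.numeric(dose_grid),
         volume_fraction = pmin(pmax(as.numeric(volume_fraction), 0), 1),
         structure_label = as.character(label),
         volume_cc = if (is.null(volume_cc)) NA_real_ else as.numeric(volume_cc)),
    class = "dvh_cum")
}

#' @export
print.dvh_diff <- function(x, ...) {
  cat(sprintf("Differential DVH '%s': %d bins, %.2f-%.2f Gy, mean %.2f Gy\n",
              x$structure_label, length(x$bin_dose),
              min(x$bin_dose), max(x$bin_dose),
              sum(x$bin_dose * x$bin_volume)))
  invisible(x)
}

#' @export
print.dvh_cum <- function(x, ...) {
  cat(sprintf("Cumulative DVH '%s': %d grid points, max dose %.2f Gy\n",
              x$structure_label, length(x$dose_grid), max(x$dose_grid)))
  invisible(x)
}

#' Convert a differential DVH to cumulative form
#'
#' The cumulative value at grid dose `D` is the total bin volume at doses
#' `>= D`. The grid is the union of 0 Gy and the bin doses, so the curve
#' starts at 1 and steps down at each occupied bin.
#'
#' @param d a `dvh_diff` object.
#' @return A `dvh_cum` object on the bin-edge grid.
#' @examples
#' to_cumulative(make_differential(c(10, 20), c(0.5, 0.5)))
#' @export
to_cumulative <- function(d) {
  stopifnot(inherits(d, "dvh_diff"))
  grid <- sort(unique(c(0, d$bin_dose)))
  vf <- vapply(grid, function(g) sum(d$bin_volume[d$bin_dose >= g]),
               numeric(1))
  make_cumulative(grid, vf, d$structure_label,
                  if (is.na(d$volume_cc)) NULL else d$volume_cc)
}

#' Convert a cumulative DVH to differential form
#'
#' Each differential bin takes the lower grid edge as its dose and the drop
#' in cumulative volume across the interval as its volume; the mass still
#' present at the last grid dose is assigned to that dose. Zero-volume bins
#' are dropped, which makes `to_differential(to_cumulative(d))` the
#' identity on the shared grid.
#'
#' @param c a `dvh_cum` object.
#' @return A `dvh_diff` object.
#' @examples
#' to_differential(make_cumulative(c(0, 20, 40), c(1, 0.5, 0)))
#' @export
to_differential <- function(c) {
  stopifnot(inherits(c, "dvh_cum"))
  vf <- c$volume_fraction
  dv <- c(-diff(vf), vf[length(vf)])
  keep <- dv > 1e-15
  if (!any(keep))
    stop("cumulative DVH carries no volume", call. = FALSE)
  make_differential(c$dose_grid[keep], dv[keep], c$structure_label,
                    if (is.na(c$volume_cc)) NULL else c$volume_cc)
}

as_differential <- function(x) {
  if (inherits(x, "dvh_diff")) x else to_differential(x)
}

as_cumulative <- function(x) {
  if (inherits(x, "dvh_cum")) x else to_cumulative(x)
}

#' Volume receiving at least a given dose (V_xGy)
#'
#' Linear interpolation on the cumulative curve, closed at `x` ("equal to
#' or greater than x Gy"). Doses beyond the grid return 0; doses below the
#' grid start return 1.
#'
#' @param c a `dvh_cum` object.
#' @param x dose in Gy, `x >= 0`.
#' @return Volume fraction in \[0, 1\].
#' @examples
#' cdvh <- make_cumulative(c(0, 10, 20, 30), c(1, 1, 0.5, 0))
#' volume_at_dose(cdvh, 15) # 0.75
#' @export
volume_at_dose <- function(c, x) {
  stopifnot(inherits(c, "dvh_cum"))
  if (any(x < 0)) stop("dose must be >= 0", call. = FALSE)
  if (length(c$dose_grid) == 1L)
    return(ifelse(x <= c$dose_grid, c$volume_fraction, 0))
  out <- stats::approx(c$dose_grid, c$volume_fraction, xout = x,
                       yleft = 1, yright = 0, ties = "ordered")$y
  pmin(pmax(out, 0), 1)
}

#' Minimum dose to the hottest fraction of the structure (D_x%)
#'
#' Inverse linear interpolation of the cumulative curve. On flat segments
#' the highest dose attaining the requested fraction is returned, the
#' conservative choice when reporting organ-at-risk dose.
#'
#' @param c a `dvh_cum` object.
#' @param x volume fraction in (0, 1\]; e.g. `x = 0.02` gives D_2%.
#' @return Dose in Gy.
#' @examples
#' cdvh <- make_cumulative(c(0, 10, 20, 30), c(1, 1, 0.5, 0))
#' dose_at_volume(cdvh, 0.25) # 25 Gy
#' @export
dose_at_volume <- function(c, x) {
  stopifnot(inherits(c, "dvh_cum"))
  if (any(x <= 0 | x > 1))
    stop("volume fraction must be in (0, 1]", call. = FALSE)
  vf <- c$volume_fraction; dg <- c$dose_grid
  vapply(x, function(xi) {
    if (xi <= min(vf)) return(max(dg))      # fraction never drops below xi
    if (xi > max(vf)) return(min(dg))
    # highest dose with volume_fraction >= xi, then interpolate to the next
    i <- max(which(vf >= xi))
    if (abs(vf[i] - xi) <= 1e-12 || i == length(dg)) return(dg[i])
    dg[i] + (vf[i] - xi) / (vf[i] - vf[i + 1]) * (dg[i + 1] - dg[i])
  }, numeric(1))
}

#' Summary dose metrics of a DVH
#'
#' @param d a `dvh_diff` (or `dvh_cum`, converted internally).
#' @return A list with `d_max` (largest occupied bin dose), `d_min`
#'   (smallest occupied bin dose) and `d_mean` (volume-weighted mean dose),
#'   all in Gy.
#' @examples
#' summary_metrics(make_differential(c(10, 20), c(0.5, 0.5)))
#' @export
summary_metrics <- function(d) {
  d <- as_differential(d)
  occ <- d$bin_volume > 0
  list(d_max = max(d$bin_dose[occ]),
       d_min = min(d$bin_dose[occ]),
       d_mean = sum(d$bin_dose * d$bin_volume))
}

#' Resample a differential DVH onto a regular bin grid
#'
#' Rebinning assigns each bin's volume to the regular bin containing its
#' dose (lower-edge convention, default width 0.1 Gy).
#'
#' @param d a `dvh_diff` object.
#' @param bin_width bin width in Gy (> 0).
#' @return A `dvh_diff` on the regular grid.
#' @export
rebin_differential <- function(d, bin_width = 0.1) {
  stopifnot(inherits(d, "dvh_diff"), bin_width > 0)
  edge <- floor(d$bin_dose / bin_width) * bin_width
  v <- as.numeric(tapply(d$bin_volume, edge, sum))
  make_differential(sort(unique(edge)), v, d$structure_label,
                    if (is.na(d$volume_cc)) NULL else d$volume_cc)
}
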