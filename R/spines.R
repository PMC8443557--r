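#' Fit a Gaussian to one spine intensity profile and return its 2-sigma
#' diameter
#'
#' Least-squares fit of `A * exp(-(x - mu)^2 / (2 sigma^2)) + C` (the
#' constant offset absorbs background staining intensity); the diameter is
#' `2 * sigma`.
#'
#' @param positions_um Strictly increasing positions along the profile axis
#'   (um), at least 5 samples.
#' @param intensities Intensities (arbitrary units) at those positions.
#' @return Diameter in um (2 sigma of the fitted Gaussian).
#' @export
fit_profile_diameter <- function(positions_um, intensities) {
  x <- as.numeric(positions_um); y <- as.numeric(intensities)
  if (length(x) < 5) stop("profile needs at least 5 samples")
  if (any(diff(x) <= 0)) stop("positions must be strictly increasing")
  if (max(y) <= min(y)) stop("flat profile: no discernible peak to fit")
  c0 <- min(y)
  a0 <- max(y) - c0
  mu0 <- x[which.max(y)]
  # crude width start: half-maximum span, falling back to a fifth of the range
  half <- c0 + a0 / 2
  span <- range(x[y >= half])
  s0 <- max((span[2] - span[1]) / 2.3548, diff(range(x)) / 10)
  resid_fn <- function(p) y - (p[1] * exp(-(x - p[2])^2 / (2 * p[3]^2)) + p[4])
  fit <- minpack.lm::nls.lm(par = c(A = a0, mu = mu0, s = s0, C = c0),
                            fn = resid_fn,
                            lower = c(0, min(x), 1e-6, -Inf),
                            upper = c(Inf, max(x), Inf, Inf),
                            control = minpack.lm::nls.lm.control(maxiter = 200))
  if (!fit$info %in% 1:4)
    stop("Gaussian profile fit did not converge: ", fit$message, call. = FALSE)
  2 * abs(fit$par[["s"]])
}

#' Fit transverse and axial diameters for a table of spine profiles
#'
#' @param profiles Data frame with columns `spine_id`, `axis` (`"t"` or
#'   `"a"`), `position_um`, `intensity` (the layout written by
#'   [gen_spine_profiles()]).
#' @return Data frame with one row per spine: `spine_id`, `d_t_um`,
#'   `d_a_um`, `volume_um3`.
#' @export
fit_spine_profiles <- function(profiles) {
  stopifnot(all(c("spine_id", "axis", "position_um", "intensity") %in%
                  names(profiles)))
  ids <- unique(profiles$spine_id)
  one <- function(id, ax) {
    p <- profiles[profiles$spine_id == id & profiles$axis == ax, ]
    p <- p[order(p$position_um), ]
    fit_profile_diameter(p$position_um, p$intensity)
  }
  d_t <- vapply(ids, one, numeric(1), ax = "t")
  d_a <- vapply(ids, one, numeric(1), ax = "a")
  data.frame(spine_id = ids, d_t_um = d_t, d_a_um = d_a,
             volume_um3 = spine_volume(d_t, d_a))
}

#' Spine head volume from transverse and axial diameters
#'
#' The spheroid closed form `pi * d_t^2 * d_a / 6` (reduces to the sphere
#' volume when both diameters are equal).
#'
#' @param d_t_um Transverse diameter(s) in um (> 0).
#' @param d_a_um Axial diameter(s) in um (> 0).
#' @return Volume(s) in um^3.
#' @export
spine_volume <- function(d_t_um, d_a_um) {
  if (any(d_t_um <= 0) || any(d_a_um <= 0))
    stop("spine diameters must be positive")
  pi * d_t_um^2 * d_a_um / 6
}

#' Is a spine usable as an optical-density calibration reference?
#'
#' References must have diameter > 0.4 um (the regime where the 2-sigma
#' convention matches the physical head diameter) and volume < 0.4 um^3.
#' With two diameters per spine, the diameter criterion is applied to the
#' smaller of the two (both axes resolvable).
#'
#' @param d_t_um,d_a_um Diameters in um.
#' @param volume_um3 Volume in um^3.
#' @return Logical vector.
#' @export
is_reference_spine <- function(d_t_um, d_a_um, volume_um3) {
  pmin(d_t_um, d_a_um) > 0.4 & volume_um3 < 0.4
}

#' Calibrate the optical-density-to-volume proportionality
#'
#' Through-origin least squares of `volume = c * od` over reference spines
#' (proportional relationship, no intercept). Records failing the reference
#' criteria are excluded and counted.
#'
#' @param records Data frame with columns `d_t_um`, `d_a_um`, `volume_um3`,
#'   `optical_density`.
#' @return List of class `od_calibration`: `coefficient` (um^3 per OD
#'   unit), `n_used`, `n_excluded`.
#' @export
calibrate_od <- function(records) {
  stopifnot(all(c("d_t_um", "d_a_um", "volume_um3", "optical_density") %in%
                  names(records)))
  ref <- is_reference_spine(records$d_t_um, records$d_a_um,
                            records$volume_um3) &
    records$optical_density > 0
  n_excluded <- sum(!ref)
  use <- records[ref, ]
  if (nrow(use) < 3)
    stop("need at least 3 reference spines for calibration (have ",
         nrow(use), ")")
  coefficient <- sum(use$optical_density * use$volume_um3) /
    sum(use$optical_density^2)
  if (!(coefficient > 0)) stop("calibration produced a non-positive slope")
  structure(list(coefficient = coefficient, n_used = nrow(use),
                 n_excluded = n_excluded), class = "od_calibration")
}

#' Estimate spine volume from optical density
#'
#' @param od Optical density (> 0).
#' @param cal An [calibrate_od()] result.
#' @return Estimated volume(s) in um^3.
#' @export
estimate_volume_from_od <- function(od, cal) {
  stopifnot(inherits(cal, "od_calibration"))
  if (any(od <= 0)) stop("optical density must be positive")
  cal$coefficient * od
}

#' Spine density over a dendritic segment
#'
#' @param spine_count Number of spines on the segment (>= 0).
#' @param start_um,end_um Segment bounds in um from the soma (end > start);
#'   the analysis convention is 25-50 um at birth and 50-75 um afterwards.
#' @return Spines per um.
#' @export
spine_density <- function(spine_count, start_um, end_um) {
  if (any(end_um <= start_um)) stop("segment must have positive length")
  if (any(spine_count < 0)) stop("spine count must be non-negative")
  spine_count / (end_um - start_um)
}

#' Two-sample Kolmogorov-Smirnov comparison of distributions
#'
#' Used to compare spine-volume (and PSD-length) distributions between
#' groups. The p-value is exact when the smaller sample has at most 10
#' observations, asymptotic otherwise.
#'
#' @param sample_a,sample_b Non-empty numeric samples.
#' @return List with `statistic` (D) and `p.value` (two-sided).
#' @export
compare_distributions_ks <- function(sample_a, sample_b) {
  if (!length(sample_a) || !length(sample_b))
    stop("both samples must be non-empty")
  exact <- min(length(sample_a), length(sample_b)) <= 10
  kt <- suppressWarnings(stats::ks.test(sample_a, sample_b, exact = exact))
  list(statistic = unname(kt$statistic), p.value = kt$p.value)
}
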