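# Color-space plumbing: XYZ <-> CAT16 LMS, CIE 1976 u'v' chromaticity,
# Planckian radiator synthesis, Planckian/daylight loci, named whites.

#' CAT16 cone-response matrix
#'
#' The 3x3 matrix mapping CIE 1931 XYZ tristimulus values to CAT16 cone
#' excitations (Li et al. 2017).  Its rows each sum to 1, so the equal-energy
#' white (X = Y = Z) maps to equal cone responses.
#'
#' @format A 3x3 numeric matrix with rows L, M, S and columns X, Y, Z.
#' @export
M16 <- matrix(c(
   0.401288,  0.650173, -0.051461,
  -0.250268,  1.204414,  0.045854,
  -0.002079,  0.048952,  0.953127),
  nrow = 3L, byrow = TRUE,
  dimnames = list(c("L", "M", "S"), c("X", "Y", "Z")))

.M16_inv <- solve(M16)

# Second radiation constant, m K — the value conventional in colorimetric
# CCT work.
.c2 <- 1.4388e-2

# Published vK20/WGM reference white, CAT16 cone space.  These are the
# printed constants for the nominal 15000 K "sky blue" reference point
# (chromaticity u'v' = (0.185, 0.425)); note that this nominal chromaticity
# sits about 0.0017 u'v' away from the CIE-1931 Planckian curve at 15000 K,
# so the stored constant is deliberately distinct from reference_white
# ("cct:15000"), which synthesizes the radiator from Planck's law.
.LMS_15000K <- c(L = 95.41, M = 103.87, S = 169.81)

.XYZ_D65 <- c(X = 95.047, Y = 100, Z = 108.883)
.XYZ_A   <- c(X = 109.850, Y = 100, Z = 35.585)

#' Convert XYZ tristimulus values to CAT16 cone responses
#'
#' @param xyz A length-3 numeric vector `(X, Y, Z)` or an n x 3 matrix, one
#'   stimulus per row.
#' @return Cone responses `(L, M, S)` with the same shape as the input.
#'   The transform is linear and clamp-free; extreme stimuli can yield
#'   non-positive cone responses, which downstream adaptation operations
#'   reject.
#' @seealso [lms_to_xyz()], [M16]
#' @export
#' @examples
#' xyz_to_lms(c(100, 100, 100))   # equal-energy white -> (100, 100, 100)
xyz_to_lms <- function(xyz) {
  m <- as_triple_matrix(xyz, "XYZ")
  restore_shape(m %*% t(M16), m, c("L", "M", "S"))
}

#' Convert CAT16 cone responses to XYZ tristimulus values
#'
#' Exact inverse of [xyz_to_lms()].
#'
#' @param lms A length-3 numeric vector `(L, M, S)` or an n x 3 matrix.
#' @return Tristimulus values with the same shape as the input.
#' @export
lms_to_xyz <- function(lms) {
  m <- as_triple_matrix(lms, "LMS")
  restore_shape(m %*% t(.M16_inv), m, c("X", "Y", "Z"))
}

#' CIE 1976 u'v' chromaticity of a stimulus
#'
#' @param xyz A length-3 numeric vector or n x 3 matrix of tristimulus
#'   values.  The projective denominator `X + 15 Y + 3 Z` must be positive.
#' @return Chromaticity `(up, vp)`; a length-2 vector for a single stimulus,
#'   an n x 2 matrix otherwise.  Invariant under positive scaling of the
#'   input.
#' @export
#' @examples
#' xyz_to_upvp(c(100, 100, 100))  # (4/19, 9/19)
xyz_to_upvp <- function(xyz) {
  m <- as_triple_matrix(xyz, "XYZ")
  den <- m[, 1L] + 15 * m[, 2L] + 3 * m[, 3L]
  if (any(den <= 0))
    stop_domain("invalid stimulus: X + 15Y + 3Z must be positive")
  out <- cbind(up = 4 * m[, 1L] / den, vp = 9 * m[, 2L] / den)
  if (isTRUE(attr(m, "was_vector"))) {
    out <- drop(out)
    names(out) <- c("up", "vp")
  }
  out
}

#' Lift a u'v' chromaticity back to XYZ at a chosen luminance
#'
#' @param upvp A length-2 vector `(up, vp)` or n x 2 matrix.
#' @param Y Luminance assigned to the result (default 100, the convention
#'   for whites).
#' @return Tristimulus values with `xyz_to_upvp()` equal to the input.
#' @export
upvp_to_xyz <- function(upvp, Y = 100) {
  if (is.null(dim(upvp))) {
    if (length(upvp) != 2L) stop_param("upvp must have length 2")
    upvp <- matrix(as.double(upvp), nrow = 1L)
    vec <- TRUE
  } else {
    if (ncol(upvp) != 2L) stop_param("upvp must have 2 columns")
    vec <- FALSE
  }
  up <- upvp[, 1L]; vp <- upvp[, 2L]
  if (any(vp <= 0)) stop_domain("v' must be positive to recover XYZ")
  den <- 6 * up - 16 * vp + 12
  x <- 9 * up / den
  y <- 4 * vp / den
  out <- cbind(X = x / y * Y, Y = rep_len(Y, length(y)), Z = (1 - x - y) / y * Y)
  if (vec) {
    out <- drop(out)
    names(out) <- c("X", "Y", "Z")
  }
  out
}

#' Relative spectral power distribution of a Planckian radiator
#'
#' Evaluates Planck's law (relative, arbitrary scale) on a wavelength grid.
#'
#' @param temperature Blackbody temperature in kelvin, within
#'   \[1000, 1e6\].
#' @param wavelength Strictly increasing uniform wavelength grid in nm
#'   (default 360-830 at 1 nm, the grid used for the named whites).
#' @return A data frame with columns `wavelength` (nm) and `value`
#'   (relative power, scaled so the maximum is 1).
#' @export
#' @examples
#' spd <- planckian_spd(6500)
planckian_spd <- function(temperature, wavelength = seq(360, 830, by = 1)) {
  if (length(temperature) != 1L || !is.finite(temperature) ||
      temperature < 1000 || temperature > 1e6)
    stop_param("temperature must be a single value in [1000, 1e6] K")
  if (length(wavelength) < 2L || any(diff(wavelength) <= 0))
    stop_param("wavelength must be a strictly increasing grid")
  lam <- wavelength * 1e-9
  val <- lam^-5 / expm1(.c2 / (lam * temperature))
  data.frame(wavelength = wavelength, value = val / max(val))
}

#' Integrate a spectral power distribution to XYZ
#'
#' Riemann-sum integration against the embedded CIE 1931 2-degree
#' color-matching functions, normalized so the result has `Y = 100`.
#'
#' @param spd A data frame with numeric columns `wavelength` (nm, strictly
#'   increasing, within the CMF support 360-830 nm) and `value`
#'   (non-negative relative power), e.g. from [planckian_spd()].
#' @return A length-3 tristimulus vector with `Y = 100`.
#' @export
spd_to_xyz <- function(spd) {
  if (!is.data.frame(spd) || !all(c("wavelength", "value") %in% names(spd)))
    stop_param("spd must be a data frame with columns wavelength and value")
  wl <- spd$wavelength; val <- spd$value
  if (length(wl) < 2L || any(diff(wl) <= 0))
    stop_param("spd wavelengths must be strictly increasing with >= 2 samples")
  if (any(wl < 360 | wl > 830))
    stop_param("spd grid lies outside the CMF support [360, 830] nm")
  if (any(val < 0) || anyNA(val))
    stop_domain("spd values must be non-negative and finite")
  cmf <- cie1931_cmf(wl)
  xyz <- c(sum(cmf[, "xbar"] * val), sum(cmf[, "ybar"] * val),
           sum(cmf[, "zbar"] * val))
  if (xyz[2L] <= 0) stop_domain("spd has zero luminance; cannot normalize")
  out <- xyz / xyz[2L] * 100
  names(out) <- c("X", "Y", "Z")
  out
}

#' Cone responses of a named or computed reference white
#'
#' @param name One of `"EE"` (equal-energy, exactly `(100, 100, 100)`),
#'   `"15000K"` (the published sky-blue reference constant
#'   `(95.41, 103.87, 169.81)`), `"D65"`, `"A"`, or `"cct:<kelvin>"`, in
#'   which case the white is synthesized as a Planckian radiator and pushed
#'   through [spd_to_xyz()] and [xyz_to_lms()].
#' @return A length-3 CAT16 cone-response vector, `Y`-normalized to 100.
#' @export
#' @examples
#' reference_white("EE")
#' reference_white("15000K")
#' reference_white("cct:6500")
reference_white <- function(name) {
  parse_illuminant(name)$lms
}

#' Parse an illuminant specification
#'
#' Accepts the specification strings used throughout the package —
#' `"EE"`, `"D65"`, `"A"`, `"15000K"`, `"cct:<kelvin>"`,
#' `"xyz:<X>,<Y>,<Z>"` — or a bare numeric XYZ triple.
#'
#' @param spec Specification string or length-3 numeric XYZ vector.
#' @return A list with elements `label`, `xyz`, and `lms`.
#' @export
parse_illuminant <- function(spec) {
  if (is.numeric(spec)) {
    xyz <- as_triple_matrix(spec, "illuminant XYZ")[1L, ]
    if (any(xyz < 0)) stop_domain("illuminant XYZ must be non-negative")
    names(xyz) <- c("X", "Y", "Z")
    return(list(label = sprintf("xyz:%g,%g,%g", xyz[1], xyz[2], xyz[3]),
                xyz = xyz, lms = xyz_to_lms(xyz)))
  }
  if (!is.character(spec) || length(spec) != 1L || is.na(spec))
    stop_param("illuminant spec must be a single string or numeric triple")
  if (spec == "EE") {
    xyz <- c(X = 100, Y = 100, Z = 100)
    return(list(label = "EE", xyz = xyz, lms = xyz_to_lms(xyz)))
  }
  if (spec == "D65") {
    return(list(label = "D65", xyz = .XYZ_D65, lms = xyz_to_lms(.XYZ_D65)))
  }
  if (spec == "A") {
    return(list(label = "A", xyz = .XYZ_A, lms = xyz_to_lms(.XYZ_A)))
  }
  if (spec == "15000K") {
    return(list(label = "15000K", xyz = lms_to_xyz(.LMS_15000K),
                lms = .LMS_15000K))
  }
  if (grepl("^cct:", spec)) {
    cct <- suppressWarnings(as.numeric(sub("^cct:", "", spec)))
    if (is.na(cct)) stop_param("malformed cct spec: '%s'", spec)
    xyz <- spd_to_xyz(planckian_spd(cct))
    return(list(label = spec, xyz = xyz, lms = xyz_to_lms(xyz)))
  }
  if (grepl("^xyz:", spec)) {
    parts <- suppressWarnings(as.numeric(strsplit(sub("^xyz:", "", spec),
                                                  ",", fixed = TRUE)[[1L]]))
    if (length(parts) != 3L || anyNA(parts))
      stop_param("malformed xyz spec: '%s'", spec)
    return(parse_illuminant(parts))
  }
  stop_param("unknown illuminant spec: '%s'", spec)
}

# CIE daylight-locus chromaticity polynomial (two cubic branches in 1/T),
# valid for 4000 K <= T <= 25000 K.
daylight_xy <- function(cct) {
  if (any(cct < 4000 | cct > 25000))
    stop_param("daylight locus is defined for 4000 K <= T <= 25000 K")
  tt <- 1e3 / cct
  x <- ifelse(cct <= 7000,
              0.244063 + 0.09911 * tt + 2.9678 * tt^2 - 4.6070 * tt^3,
              0.237040 + 0.24748 * tt + 1.9018 * tt^2 - 2.0064 * tt^3)
  y <- -3.000 * x^2 + 2.870 * x - 0.275
  cbind(x = x, y = y)
}

xy_to_upvp <- function(xy) {
  den <- -2 * xy[, 1L] + 12 * xy[, 2L] + 3
  cbind(up = 4 * xy[, 1L] / den, vp = 9 * xy[, 2L] / den)
}

#' Sample the Planckian or daylight locus in u'v'
#'
#' Points are sampled at uniform reciprocal-temperature (mired) spacing,
#' which is approximately uniform perceptually.
#'
#' @param kind `"planckian"` or `"daylight"`.
#' @param t_range Length-2 kelvin range.  The daylight branch requires
#'   4000-25000 K (validity of the CIE chromaticity polynomial); the
#'   Planckian branch accepts 1000 K to 1e6 K.
#' @param n Number of samples.
#' @return A data frame with columns `cct`, `mired`, `up`, `vp`.
#' @export
#' @examples
#' head(locus_points("planckian", c(2000, 20000), n = 5))
locus_points <- function(kind = c("planckian", "daylight"),
                         t_range = c(2000, 25000), n = 100) {
  kind <- match.arg(kind)
  if (length(t_range) != 2L || t_range[1L] >= t_range[2L])
    stop_param("t_range must be an increasing kelvin pair")
  if (n < 2L) stop_param("n must be at least 2")
  mired <- seq(1e6 / t_range[2L], 1e6 / t_range[1L], length.out = n)
  cct <- 1e6 / mired
  if (kind == "daylight") {
    uv <- xy_to_upvp(daylight_xy(cct))
  } else {
    if (any(cct < 1000 | cct > 1e6))
      stop_param("planckian locus supported for 1000 K <= T <= 1e6 K")
    uv <- t(vapply(cct, function(T)
      xyz_to_upvp(spd_to_xyz(planckian_spd(T))), numeric(2L)))
    colnames(uv) <- c("up", "vp")
  }
  data.frame(cct = cct, mired = mired, up = uv[, "up"], vp = uv[, "vp"])
}

#' Distance from a chromaticity to a sampled locus
#'
#' Minimum Euclidean u'v' distance from the query point(s) to a densely
#' sampled locus; the sampling density (default 2000 points, mired-uniform)
#' bounds the chord error well below 1e-4 u'v'.
#'
#' @param upvp A length-2 chromaticity or n x 2 matrix.
#' @inheritParams locus_points
#' @return Numeric vector of distances, one per query point.
#' @export
locus_distance <- function(upvp, kind = c("planckian", "daylight"),
                           t_range = c(2000, 50000), n = 2000) {
  kind <- match.arg(kind)
  if (is.null(dim(upvp))) upvp <- matrix(upvp, nrow = 1L)
  key <- sprintf("locus_%s_%g_%g_%d", kind, t_range[1L], t_range[2L], n)
  pts <- .wgmcat_cache[[key]]
  if (is.null(pts)) {
    pts <- locus_points(kind, t_range, n)
    .wgmcat_cache[[key]] <- pts
  }
  vapply(seq_len(nrow(upvp)), function(i)
    sqrt(min((pts$up - upvp[i, 1L])^2 + (pts$vp - upvp[i, 2L])^2)),
    numeric(1L))
}
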