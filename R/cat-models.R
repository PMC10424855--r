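# The adaptation transforms.  Every model in this family divides the cone
# response to the stimulus by an "effective adapting white"; the models
# differ only in how that denominator combines the adapting, reference and
# (for vK20) previous illuminants:
#
#   von Kries : n
#   linear    : D n + (1 - D) r          (CAT16 configuration: r = EE)
#   vk20      : Dn n + Dr r + Dp p,  Dn + Dr + Dp = 1
#   gm        : sqrt(n r)
#   wgm       : n^D r^(1 - D)
#
# The denominator is also the model's predicted neutral: the stimulus whose
# cone response equals it adapts to (1, 1, 1), i.e. appears achromatic.

#' Bundle chromatic-adaptation model parameters
#'
#' @param model One of `"wgm"`, `"gm"`, `"von_kries"`, `"linear"`
#'   (the D-factor linear transform; with the default `"EE"` reference this
#'   is the CAT16 configuration), or `"vk20"`.
#' @param D Degree of adaptation in \[0, 1\] (`"wgm"` and `"linear"`):
#'   `D = 1` is complete adaptation to the adapting stimulus ("discounting
#'   the illuminant"), `D = 0` is adaptation to the reference condition.
#' @param Dn,Dr,Dp vK20 weights on the adapting, reference, and previous
#'   illuminants; each in \[0, 1\] and summing to 1.  `Dp` defaults to 0
#'   (no previous-illuminant term), in which case `Dr` defaults to `1 - Dn`.
#' @param reference Reference illuminant: a spec string (see
#'   [parse_illuminant()]) or a length-3 cone-response vector.  Defaults to
#'   `"EE"` for `"linear"`/`"von_kries"` and `"15000K"` otherwise.
#' @param previous Previous adapting illuminant (vK20 only), same forms as
#'   `reference`; required when `Dp > 0`.
#' @return An object of class `cat_params`.
#' @export
#' @examples
#' cat_params("wgm", D = 0.7)
#' cat_params("linear", D = 0.7, reference = "EE")
#' cat_params("vk20", Dn = 0.7)
cat_params <- function(model = c("wgm", "gm", "von_kries", "linear", "vk20"),
                       D = NULL, Dn = NULL, Dr = NULL, Dp = NULL,
                       reference = NULL, previous = NULL) {
  model <- match.arg(model)
  if (is.null(reference))
    reference <- if (model %in% c("linear", "von_kries")) "EE" else "15000K"
  ref_lms <- resolve_anchor(reference, "reference")
  prev_lms <- if (!is.null(previous)) resolve_anchor(previous, "previous")
  p <- list(model = model, reference_lms = ref_lms, previous_lms = prev_lms)
  if (model %in% c("wgm", "linear")) {
    if (is.null(D)) stop_param("model '%s' requires D", model)
    if (length(D) != 1L || !is.finite(D) || D < 0 || D > 1)
      stop_param("D must be a single value in [0, 1]")
    p$D <- as.double(D)
  } else if (model == "vk20") {
    if (is.null(Dn)) stop_param("vk20 requires Dn")
    if (is.null(Dp)) Dp <- 0
    if (is.null(Dr)) Dr <- 1 - Dn - Dp
    w <- c(Dn = Dn, Dr = Dr, Dp = Dp)
    if (any(!is.finite(w)) || any(w < 0) || any(w > 1))
      stop_param("Dn, Dr, Dp must each lie in [0, 1]")
    if (abs(sum(w) - 1) > 1e-9)
      stop_param("Dn + Dr + Dp must equal 1 (got %.12f)", sum(w))
    if (w[["Dp"]] > 0 && is.null(prev_lms))
      stop_param("vk20 with Dp > 0 requires a previous illuminant")
    p[c("Dn", "Dr", "Dp")] <- as.list(as.double(w))
  } else if (!is.null(D) && model == "gm") {
    stop_param("the plain geometric-mean model has no D; use model 'wgm'")
  }
  structure(p, class = "cat_params")
}

resolve_anchor <- function(x, what) {
  lms <- if (is.character(x)) parse_illuminant(x)$lms
         else as_triple_matrix(x, what)[1L, ]
  check_positive(lms, sprintf("%s cone response", what))
  names(lms) <- c("L", "M", "S")
  lms
}

#' @export
print.cat_params <- function(x, ...) {
  cat("<cat_params>", x$model, "\n")
  if (!is.null(x$D)) cat("  D:", x$D, "\n")
  if (!is.null(x$Dn)) cat("  Dn/Dr/Dp:", x$Dn, x$Dr, x$Dp, "\n")
  cat("  reference LMS:", paste(signif(x$reference_lms, 6), collapse = ", "),
      "\n")
  invisible(x)
}

# The effective adapting white (the adaptation denominator) of a model, for
# an n x 3 matrix of adapting cone responses.  Returns an n x 3 matrix.
adapt_denominator <- function(params, adapting) {
  n <- as_triple_matrix(adapting, "adapting")
  check_positive(n, "adapting cone response")
  nr <- nrow(n)
  out <- switch(params$model,
    von_kries = n,
    linear = params$D * n + (1 - params$D) * rep_rows(params$reference_lms, nr),
    vk20 = {
      acc <- params$Dn * n + params$Dr * rep_rows(params$reference_lms, nr)
      if (params$Dp > 0)
        acc <- acc + params$Dp * rep_rows(params$previous_lms, nr)
      acc
    },
    gm = sqrt(n * rep_rows(params$reference_lms, nr)),
    wgm = n^params$D * rep_rows(params$reference_lms, nr)^(1 - params$D))
  restore_shape(out, n, c("L", "M", "S"))
}

#' von Kries adaptation
#'
#' Independent scaling of each cone channel by its response to the adapting
#' stimulus.
#'
#' @param stim Cone response of the stimulus (length-3 vector or n x 3
#'   matrix).
#' @param adapting Cone response of the adapting stimulus; strictly
#'   positive.
#' @return Post-adaptation signal `(La, Ma, Sa)`, the channelwise ratio.
#' @export
#' @examples
#' von_kries_adapt(c(50, 100, 200), c(100, 100, 100))
von_kries_adapt <- function(stim, adapting) {
  s <- as_triple_matrix(stim, "stim")
  n <- as_triple_matrix(adapting, "adapting")
  check_positive(n, "adapting cone response")
  if (nrow(n) == 1L && nrow(s) > 1L) n <- rep_rows(drop(n), nrow(s))
  restore_shape(s / n, s, c("La", "Ma", "Sa"))
}

#' D-factor linear adaptation (CAT16 configuration)
#'
#' Divides each channel by the mixture `D * n + (1 - D) * r` of the adapting
#' and reference whites.  With `reference = "EE"` this is the simplified
#' CAT16 transform.
#'
#' @inheritParams von_kries_adapt
#' @param params A [cat_params()] object with `model = "linear"`.
#' @return Post-adaptation signal.
#' @export
linear_cat_adapt <- function(stim, adapting, params) {
  stopifnot(inherits(params, "cat_params"), params$model == "linear")
  adapt_signal(stim, adapting, params)
}

#' vK20 adaptation
#'
#' Three-anchor von Kries-type transform whose denominator mixes the
#' adapting, reference (default the 15000 K sky-blue constant) and previous
#' illuminants with weights `Dn + Dr + Dp = 1`.
#'
#' @inheritParams linear_cat_adapt
#' @param params A [cat_params()] object with `model = "vk20"`.
#' @export
vk20_adapt <- function(stim, adapting, params) {
  stopifnot(inherits(params, "cat_params"), params$model == "vk20")
  adapt_signal(stim, adapting, params)
}

#' Weighted-geometric-mean adaptation
#'
#' Divides each channel by `n^D * r^(1 - D)`.  At `D = 1` this is von Kries
#' scaling; at `D = 0`, division by the reference white; at `D = 0.5`, the
#' plain geometric-mean model.
#'
#' @inheritParams linear_cat_adapt
#' @param params A [cat_params()] object with `model = "wgm"`.
#' @export
wgm_adapt <- function(stim, adapting, params) {
  stopifnot(inherits(params, "cat_params"), params$model == "wgm")
  adapt_signal(stim, adapting, params)
}

#' Apply any supported adaptation model
#'
#' Generic entry point dispatching on `params$model`.
#'
#' @inheritParams von_kries_adapt
#' @param params A [cat_params()] object.
#' @return Post-adaptation signal `(La, Ma, Sa)`.
#' @export
adapt_signal <- function(stim, adapting, params) {
  stopifnot(inherits(params, "cat_params"))
  s <- as_triple_matrix(stim, "stim")
  d <- as_triple_matrix(adapt_denominator(params, adapting), "denominator")
  check_positive(d, "adaptation denominator")
  if (nrow(d) == 1L && nrow(s) > 1L) d <- rep_rows(drop(d), nrow(s))
  restore_shape(s / d, s, c("La", "Ma", "Sa"))
}

#' Geometric-mean predicted neutral
#'
#' The channelwise geometric mean of the adapting and reference cone
#' responses: the steady-state adapted signal predicted for the adapting
#' stimulus, and hence the stimulus predicted to appear achromatic.
#'
#' @param adapting,reference Strictly positive cone-response triples (or
#'   n x 3 matrices).
#' @return Predicted neutral cone response `sqrt(n * r)`.
#' @export
gm_neutral <- function(adapting, reference) {
  wgm_neutral(adapting, reference, D = 0.5)
}

#' Weighted-geometric-mean predicted neutral
#'
#' @inheritParams gm_neutral
#' @param D Degree of adaptation in \[0, 1\].
#' @return `n^D * r^(1 - D)` channelwise; the log of each channel
#'   interpolates linearly between the log anchors.
#' @export
#' @examples
#' wgm_neutral(c(100, 100, 100), reference_white("15000K"), D = 0.5)
wgm_neutral <- function(adapting, reference, D) {
  if (length(D) != 1L || !is.finite(D) || D < 0 || D > 1)
    stop_param("D must be a single value in [0, 1]")
  n <- as_triple_matrix(adapting, "adapting")
  r <- as_triple_matrix(reference, "reference")
  check_positive(n, "adapting cone response")
  check_positive(r, "reference cone response")
  if (nrow(r) == 1L && nrow(n) > 1L) r <- rep_rows(drop(r), nrow(n))
  restore_shape(n^D * r^(1 - D), n, c("L", "M", "S"))
}

#' Corresponding cone response under the reference illuminant
#'
#' Re-expresses a post-adaptation signal as the cone response of the
#' stimulus as perceived under the reference illuminant:
#' `(Lc, Mc, Sc) = (La * Lr, Ma * Mr, Sa * Sr)`.
#'
#' @param adapted Post-adaptation signal (length-3 vector or n x 3 matrix).
#' @param reference Reference-white cone response.
#' @return Adapted cone response `(Lc, Mc, Sc)`.
#' @export
to_corresponding <- function(adapted, reference) {
  a <- as_triple_matrix(adapted, "adapted")
  r <- as_triple_matrix(reference, "reference")[1L, ]
  restore_shape(a * rep_rows(r, nrow(a)), a, c("Lc", "Mc", "Sc"))
}

#' Corresponding color across two illuminants
#'
#' The three-step transform: XYZ to cone space, adaptation under the first
#' illuminant, exact inverse adaptation under the second, back to XYZ.  The
#' result is the stimulus under `illum2` whose post-adaptation signal equals
#' that of `stim_xyz` under `illum1`.
#'
#' @param stim_xyz Stimulus tristimulus values (length-3 vector or n x 3
#'   matrix).
#' @param illum1,illum2 Illuminant specs ([parse_illuminant()] forms).
#' @param params A [cat_params()] object.
#' @return Corresponding tristimulus values under `illum2`.
#' @export
#' @examples
#' p <- cat_params("wgm", D = 0.7)
#' corresponding_color(c(40, 45, 30), "A", "D65", p)
corresponding_color <- function(stim_xyz, illum1, illum2, params) {
  stopifnot(inherits(params, "cat_params"))
  s <- as_triple_matrix(stim_xyz, "stim_xyz")
  n1 <- parse_illuminant(illum1)$lms
  n2 <- parse_illuminant(illum2)$lms
  d1 <- adapt_denominator(params, n1)
  d2 <- adapt_denominator(params, n2)
  lms <- xyz_to_lms(s)
  if (is.null(dim(lms))) lms <- matrix(lms, nrow = 1L)
  out <- lms * rep_rows(d2 / d1, nrow(lms))
  restore_shape(lms_to_xyz(out), s, c("X", "Y", "Z"))
}

#' Predicted achromatic (neutral) chromaticity of a model
#'
#' The chromaticity of the stimulus whose post-adaptation signal is
#' achromatic (`La = Ma = Sa`), i.e. of the model's adaptation denominator,
#' normalized to `Y = 100` (presentation only; chromaticity is
#' scale-invariant).
#'
#' @param adapting Adapting cone response (length-3 vector or n x 3
#'   matrix) or an illuminant spec string.
#' @param params A [cat_params()] object.
#' @return u'v' chromaticity; length-2 vector for one condition, n x 2
#'   matrix otherwise.
#' @export
#' @examples
#' predict_neutral("cct:6500", cat_params("wgm", D = 0.5))
predict_neutral <- function(adapting, params) {
  if (is.character(adapting)) adapting <- parse_illuminant(adapting)$lms
  den <- adapt_denominator(params, adapting)
  xyz <- lms_to_xyz(den)
  xyz_to_upvp(xyz)
}

#' Luminance-dependent degree of adaptation of CIECAM16
#'
#' Optional helper computing `D = F * (1 - (1/3.6) * exp((-La - 42) / 92))`,
#' clamped to \[0, 1\].  Provided for reference; no function in this package
#' applies it implicitly — `D` is always an explicit parameter or a fitted
#' quantity.
#'
#' @param La Adapting luminance in cd/m^2.
#' @param F Surround factor (1 for average surround).
#' @return Degree of adaptation in \[0, 1\].
#' @export
cat16_degree_of_adaptation <- function(La, F = 1) {
  if (any(La < 0)) stop_param("La must be non-negative")
  clamp01(F * (1 - (1 / 3.6) * exp((-La - 42) / 92)))
}
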