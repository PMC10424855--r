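# Seeded generators for achromatic-matching and corresponding-color
# datasets with known ground truth.  Observer scatter is modeled as
# isotropic bivariate Gaussian noise in u'v' — the space of the error
# metric, where the JND (~0.004) is defined — not in cone space.

#' Specify a synthetic corresponding-color experiment
#'
#' The defaults describe the headline configuration studied throughout the
#' package: a WGM ground truth with 70% adaptation toward each adapting
#' white, a 15000 K reference, eight Planckian adapting conditions spaced
#' uniformly in mired from 3000 K to 15000 K, twenty trials per condition,
#' and observer noise of one JND (0.004 u'v').
#'
#' @param model Ground-truth model (`"wgm"`, `"gm"`, `"linear"`,
#'   `"von_kries"`, `"vk20"`).
#' @param D Ground-truth degree of adaptation (ignored by `"gm"` and
#'   `"von_kries"`).
#' @param reference Reference illuminant spec.
#' @param adapting Character vector of adapting illuminant specs, e.g.
#'   from [make_adapting_set()].
#' @param n_trials Trials (repeat observations) per adapting condition.
#' @param noise_sigma Observer noise standard deviation per u'v' axis.
#' @param seed Integer seed; fixed seed means bitwise-reproducible output.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(model = "wgm", D = 0.7, reference = "15000K",
                           adapting = make_adapting_set(c(3000, 15000), n = 8),
                           n_trials = 20, noise_sigma = 0.004, seed = 1) {
  if (is.data.frame(adapting)) adapting <- adapting$illum
  if (!is.character(adapting) || length(adapting) < 1L)
    stop_param("adapting must be a non-empty character vector of specs")
  if (n_trials < 1L) stop_param("n_trials must be >= 1")
  if (noise_sigma < 0) stop_param("noise_sigma must be >= 0")
  if (length(seed) != 1L || !is.finite(seed))
    stop_param("seed must be a single integer")
  params <- switch(model,
    wgm = cat_params("wgm", D = D, reference = reference),
    linear = cat_params("linear", D = D, reference = reference),
    gm = cat_params("gm", reference = reference),
    von_kries = cat_params("von_kries", reference = reference),
    vk20 = cat_params("vk20", Dn = D, reference = reference),
    stop_param("unknown ground-truth model '%s'", model))
  structure(list(model = model, D = D, reference = reference,
                 params = params, adapting = adapting,
                 n_trials = as.integer(n_trials),
                 noise_sigma = noise_sigma, seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Build a set of adapting-illuminant specs
#'
#' Either an explicit CCT list (each becomes a Planckian `cct:` spec;
#' 2856 and 6504 map to the standard illuminants A and D65), or a
#' mired-uniform sequence across a kelvin range.
#'
#' @param cct Numeric vector of CCTs, or a length-2 kelvin range when `n`
#'   is given.
#' @param n Number of mired-uniform points when `cct` is a range.
#' @param luminance Optional luminance labels in cd/m^2, recycled across
#'   conditions and stored as metadata only (the transforms are
#'   chromaticity-driven).
#' @param named_standards Map 2856 K to `"A"` and 6504 K to `"D65"`
#'   (default `TRUE`).
#' @return A data frame with columns `illum`, `cct`, and optionally
#'   `luminance`.
#' @export
#' @examples
#' make_adapting_set(c(2856, 6504))
#' make_adapting_set(c(3000, 15000), n = 8)
make_adapting_set <- function(cct, n = NULL, luminance = NULL,
                              named_standards = TRUE) {
  if (!is.numeric(cct) || length(cct) < 1L)
    stop_param("cct must be numeric")
  if (!is.null(n)) {
    if (length(cct) != 2L || cct[1L] >= cct[2L])
      stop_param("with n, cct must be an increasing kelvin range")
    mired <- seq(1e6 / cct[1L], 1e6 / cct[2L], length.out = n)
    cct <- 1e6 / mired
  }
  if (any(cct < 1000 | cct > 1e6))
    stop_param("CCTs must lie in [1000, 1e6] K")
  if (anyDuplicated(round(cct, 6)))
    stop_param("duplicate CCTs in adapting set")
  illum <- vapply(cct, function(T) {
    if (named_standards && isTRUE(all.equal(T, 2856, tolerance = 1e-9)))
      return("A")
    if (named_standards && isTRUE(all.equal(T, 6504, tolerance = 1e-9)))
      return("D65")
    sprintf("cct:%.6g", T)
  }, character(1L))
  out <- data.frame(illum = illum, cct = cct, stringsAsFactors = FALSE)
  if (!is.null(luminance)) out$luminance <- rep_len(luminance, nrow(out))
  out
}

# Perturb chromaticities by isotropic Gaussian noise and lift back to XYZ
# at the luminance of the unperturbed stimulus.
jitter_upvp <- function(xyz, sigma) {
  if (sigma == 0) return(xyz)
  m <- as_triple_matrix(xyz, "xyz")
  uv <- xyz_to_upvp(m)
  if (is.null(dim(uv))) uv <- matrix(uv, nrow = 1L)
  uv <- uv + matrix(stats::rnorm(2L * nrow(uv), sd = sigma), ncol = 2L)
  restore_shape(upvp_to_xyz(uv, Y = m[, 2L]), m, c("X", "Y", "Z"))
}

#' Generate achromatic (neutral) matching data
#'
#' For each adapting condition, the ground-truth model's predicted neutral
#' chromaticity is perturbed by isotropic Gaussian observer noise in u'v'
#' and lifted back to XYZ at Y = 100 — emulating an observer repeatedly
#' selecting the stimulus that appears neutral under that illuminant.
#'
#' @param spec A [synthetic_spec()].
#' @return A `cc_dataset` of `kind = "neutral"` records with a
#'   `ground_truth` attribute.
#' @export
generate_neutral_matches <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  rows <- lapply(seq_along(spec$adapting), function(i) {
    il <- parse_illuminant(spec$adapting[i])
    pred_uv <- predict_neutral(il$lms, spec$params)
    obs <- upvp_to_xyz(matrix(rep(pred_uv, each = spec$n_trials), ncol = 2L) +
                       matrix(stats::rnorm(2L * spec$n_trials,
                                           sd = spec$noise_sigma), ncol = 2L),
                       Y = 100)
    if (is.null(dim(obs))) obs <- matrix(obs, nrow = 1L)
    data.frame(pair_id = sprintf("c%02d_t%03d", i, seq_len(spec$n_trials)),
               condition_id = spec$adapting[i], kind = "neutral",
               phase = 1L, X = obs[, 1L], Y = obs[, 2L], Z = obs[, 3L],
               illum_X = unname(il$xyz[1L]), illum_Y = unname(il$xyz[2L]),
               illum_Z = unname(il$xyz[3L]), stringsAsFactors = FALSE)
  })
  out <- as_cc_dataset(do.call(rbind, rows))
  attr(out, "ground_truth") <- ground_truth_list(spec)
  out
}

#' Default chromatic stimulus grid around a white
#'
#' A fixed 5 x 5 grid in u'v' (half-width 0.04) centered on the adapting
#' white, replicated at luminances Y = 20, 50, 100 — a compact analogue of
#' the saturated-and-neutral sample sets used in memory-matching studies.
#'
#' @param illum Illuminant spec the grid is centered on.
#' @param half_width Grid half-width in u'v' (default 0.04).
#' @param Y_levels Luminance levels (default `c(20, 50, 100)`).
#' @return An n x 3 matrix of XYZ stimuli.
#' @export
default_stimulus_grid <- function(illum, half_width = 0.04,
                                  Y_levels = c(20, 50, 100)) {
  uv0 <- xyz_to_upvp(parse_illuminant(illum)$xyz)
  off <- seq(-half_width, half_width, length.out = 5L)
  g <- expand.grid(du = off, dv = off, Y = Y_levels)
  upvp_to_xyz(cbind(uv0[1L] + g$du, uv0[2L] + g$dv), Y = g$Y)
}

#' Generate corresponding-color pairs
#'
#' Each stimulus seen under an adapting illuminant is mapped through the
#' ground-truth transform to its corresponding color under a second
#' illuminant, then perturbed by observer noise in u'v' (luminance kept) —
#' emulating a memory-matching experiment.  Each adapting condition in the
#' spec serves as the phase-1 illuminant.
#'
#' @param spec A [synthetic_spec()]; `n_trials` replicates each stimulus.
#' @param stimulus_set Optional n x 3 XYZ matrix of phase-1 stimuli; the
#'   default is [default_stimulus_grid()] around each phase-1 white.
#' @param illum2 Phase-2 illuminant spec (default `"D65"`).
#' @return A `cc_dataset` of `kind = "pair"` records (two rows per pair)
#'   with a `ground_truth` attribute.
#' @export
generate_corresponding_pairs <- function(spec, stimulus_set = NULL,
                                         illum2 = "D65") {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  il2 <- parse_illuminant(illum2)
  rows <- list()
  for (i in seq_along(spec$adapting)) {
    il1 <- parse_illuminant(spec$adapting[i])
    stim1 <- if (is.null(stimulus_set)) default_stimulus_grid(il1$label)
             else as_triple_matrix(stimulus_set, "stimulus_set")
    if (is.null(dim(stim1))) stim1 <- matrix(stim1, nrow = 1L)
    for (t in seq_len(spec$n_trials)) {
      stim2 <- corresponding_color(stim1, il1$label, il2$label, spec$params)
      if (is.null(dim(stim2))) stim2 <- matrix(stim2, nrow = 1L)
      stim2 <- jitter_upvp(stim2, spec$noise_sigma)
      if (is.null(dim(stim2))) stim2 <- matrix(stim2, nrow = 1L)
      ids <- sprintf("c%02d_t%03d_s%03d", i, t, seq_len(nrow(stim1)))
      rows[[length(rows) + 1L]] <- data.frame(
        pair_id = rep(ids, 2L), condition_id = spec$adapting[i],
        kind = "pair", phase = rep(c(1L, 2L), each = nrow(stim1)),
        X = c(stim1[, 1L], stim2[, 1L]), Y = c(stim1[, 2L], stim2[, 2L]),
        Z = c(stim1[, 3L], stim2[, 3L]),
        illum_X = rep(c(il1$xyz[1L], il2$xyz[1L]), each = nrow(stim1)),
        illum_Y = rep(c(il1$xyz[2L], il2$xyz[2L]), each = nrow(stim1)),
        illum_Z = rep(c(il1$xyz[3L], il2$xyz[3L]), each = nrow(stim1)),
        stringsAsFactors = FALSE)
    }
  }
  out <- as_cc_dataset(do.call(rbind, rows))
  attr(out, "ground_truth") <- c(ground_truth_list(spec),
                                 list(illum2 = il2$label))
  out
}

ground_truth_list <- function(spec) {
  list(model = spec$model, D = spec$D, reference = spec$reference,
       noise_sigma = spec$noise_sigma, n_trials = spec$n_trials,
       seed = spec$seed, adapting = spec$adapting)
}
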