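# Corresponding-color error protocol: both members of a pair are adapted to
# the model's reference state, converted to u'v', and compared by Euclidean
# distance.  A perfect model maps both members to the same point.

#' Euclidean distance in the CIE 1976 u'v' diagram
#'
#' @param a,b Length-2 chromaticities `(up, vp)` or n x 2 matrices.
#' @return Non-negative distance(s); roughly 0.004 u'v' corresponds to one
#'   just-noticeable difference for simple stimuli.
#' @export
#' @examples
#' delta_upvp(c(0.2105, 0.4737), c(0.2105, 0.4777))  # 0.004 = ~1 JND
delta_upvp <- function(a, b) {
  if (is.null(dim(a))) a <- matrix(a, nrow = 1L)
  if (is.null(dim(b))) b <- matrix(b, nrow = 1L)
  if (ncol(a) != 2L || ncol(b) != 2L)
    stop_param("chromaticities must have 2 columns")
  if (nrow(a) == 1L && nrow(b) > 1L) a <- a[rep(1L, nrow(b)), , drop = FALSE]
  if (nrow(b) == 1L && nrow(a) > 1L) b <- b[rep(1L, nrow(a)), , drop = FALSE]
  drop(sqrt(rowSums((a - b)^2)))
}

# Chromaticity of stimuli after adaptation to the model's reference state:
# stim -> LMS -> divide by the model denominator for this illuminant ->
# multiply by the reference white -> XYZ -> u'v'.  Vectorized over rows.
corresponding_upvp <- function(stim_xyz, illum_xyz, params) {
  s <- as_triple_matrix(stim_xyz, "stim_xyz")
  n <- as_triple_matrix(illum_xyz, "illum_xyz")
  slms <- s %*% t(M16)
  nlms <- n %*% t(M16)
  check_positive(nlms, "adapting cone response")
  if (nrow(nlms) == 1L && nrow(slms) > 1L)
    nlms <- rep_rows(drop(nlms), nrow(slms))
  den <- adapt_denominator(params, nlms)
  if (is.null(dim(den))) den <- matrix(den, nrow = 1L)
  corr <- (slms / den) * rep_rows(params$reference_lms, nrow(slms))
  xyz_to_upvp(corr %*% t(.M16_inv))
}

#' Prediction error for one corresponding-color pair
#'
#' Implements the pairwise protocol: each member is transformed to the
#' model's reference viewing state (adaptation under its own illuminant,
#' then [to_corresponding()] with the model reference), converted to u'v',
#' and the Euclidean distance between the two images is returned.  The
#' metric is symmetric in the two members and zero for a model-consistent
#' pair.
#'
#' @param pair A list (or one-row data-frame-like) with elements `stim1`,
#'   `illum1`, `stim2`, `illum2`; stimuli are XYZ triples, illuminants any
#'   [parse_illuminant()] form.
#' @param params A [cat_params()] object.
#' @return Non-negative Delta u'v' error.
#' @export
#' @examples
#' p <- cat_params("wgm", D = 0.7)
#' pr <- list(stim1 = c(40, 45, 30), illum1 = "A",
#'            stim2 = corresponding_color(c(40, 45, 30), "A", "D65", p),
#'            illum2 = "D65")
#' pair_error(pr, p)  # 0: the pair is model-consistent
pair_error <- function(pair, params) {
  stopifnot(inherits(params, "cat_params"))
  uv1 <- corresponding_upvp(pair$stim1, parse_illuminant(pair$illum1)$xyz,
                            params)
  uv2 <- corresponding_upvp(pair$stim2, parse_illuminant(pair$illum2)$xyz,
                            params)
  delta_upvp(uv1, uv2)
}

#' Prediction error for one achromatic match
#'
#' Distance between the chromaticity of an observer-selected neutral
#' stimulus and the model's predicted neutral for that adapting condition.
#'
#' @param observed_xyz Tristimulus values of the stimulus selected as
#'   neutral.
#' @param adapting Adapting illuminant ([parse_illuminant()] form).
#' @param params A [cat_params()] object.
#' @return Non-negative Delta u'v' error.
#' @export
neutral_match_error <- function(observed_xyz, adapting, params) {
  if (is.character(adapting)) adapting <- parse_illuminant(adapting)$lms
  delta_upvp(xyz_to_upvp(observed_xyz), predict_neutral(adapting, params))
}

#' Evaluate a model on a corresponding-color dataset
#'
#' Computes the per-record Delta u'v' error (pairwise protocol for
#' `kind = "pair"` records, neutral-match protocol for `kind = "neutral"`),
#' per-condition and overall means, and the JND-scaled means
#' (1 JND = 0.004 u'v').
#'
#' @param dataset A `cc_dataset` (see [as_cc_dataset()], [read_dataset()],
#'   or the synthetic generators).
#' @param params A [cat_params()] object.
#' @return An object of class `evaluation_report`: a list with `model`,
#'   `errors` (per-record data frame), `by_condition`, `mean_dupv`,
#'   `mean_jnd`, `n`.
#' @export
evaluate_dataset <- function(dataset, params) {
  dataset <- as_cc_dataset(dataset)
  if (nrow(dataset) == 0L) stop_param("dataset is empty")
  stopifnot(inherits(params, "cat_params"))
  neut <- dataset[dataset$kind == "neutral", , drop = FALSE]
  errors <- data.frame(pair_id = character(0), condition_id = character(0),
                       kind = character(0), error = numeric(0),
                       stringsAsFactors = FALSE)
  if (nrow(neut) > 0L) {
    illum <- as.matrix(neut[, c("illum_X", "illum_Y", "illum_Z")])
    pred <- predict_neutral(xyz_to_lms(illum), params)
    if (is.null(dim(pred))) pred <- matrix(pred, nrow = 1L)
    obs <- xyz_to_upvp(as.matrix(neut[, c("X", "Y", "Z")]))
    if (is.null(dim(obs))) obs <- matrix(obs, nrow = 1L)
    errors <- rbind(errors, data.frame(
      pair_id = as.character(neut$pair_id),
      condition_id = as.character(neut$condition_id),
      kind = "neutral", error = delta_upvp(obs, pred),
      stringsAsFactors = FALSE))
  }
  pr <- dataset[dataset$kind == "pair", , drop = FALSE]
  if (nrow(pr) > 0L) {
    p1 <- pr[pr$phase == 1L, , drop = FALSE]
    p2 <- pr[pr$phase == 2L, , drop = FALSE]
    p2 <- p2[match(p1$pair_id, p2$pair_id), , drop = FALSE]
    uv1 <- corresponding_upvp(as.matrix(p1[, c("X", "Y", "Z")]),
                              as.matrix(p1[, c("illum_X", "illum_Y", "illum_Z")]),
                              params)
    uv2 <- corresponding_upvp(as.matrix(p2[, c("X", "Y", "Z")]),
                              as.matrix(p2[, c("illum_X", "illum_Y", "illum_Z")]),
                              params)
    if (is.null(dim(uv1))) uv1 <- matrix(uv1, nrow = 1L)
    if (is.null(dim(uv2))) uv2 <- matrix(uv2, nrow = 1L)
    errors <- rbind(errors, data.frame(
      pair_id = as.character(p1$pair_id),
      condition_id = as.character(p1$condition_id),
      kind = "pair", error = delta_upvp(uv1, uv2),
      stringsAsFactors = FALSE))
  }
  cond_mean <- tapply(errors$error, errors$condition_id, mean)
  agg <- data.frame(condition_id = names(cond_mean),
                    mean_dupv = as.numeric(cond_mean),
                    mean_jnd = as.numeric(cond_mean) / 0.004,
                    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(model = params$model, params = params, errors = errors,
                 by_condition = agg,
                 mean_dupv = mean(errors$error),
                 mean_jnd = mean(errors$error) / 0.004,
                 n = nrow(errors)),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> model %s: %d records, mean dupv %.5f (%.2f JND)\n",
              x$model, x$n, x$mean_dupv, x$mean_jnd))
  invisible(x)
}

#' Serialize an evaluation report
#'
#' @param report An `evaluation_report`.
#' @param path Optional file path; when given, JSON is written there.
#' @return The JSON string, invisibly when written to a file.
#' @export
report_to_json <- function(report, path = NULL) {
  stopifnot(inherits(report, "evaluation_report"))
  obj <- list(model = report$model, n_pairs = report$n,
              mean_dupv = report$mean_dupv, mean_jnd = report$mean_jnd,
              by_condition = report$by_condition,
              errors = report$errors$error)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' One-way ANOVA comparison of model errors
#'
#' Fixed-effects one-way ANOVA on per-pair prediction errors grouped by
#' model.  If the within-group variance is exactly zero while group means
#' differ, the F statistic is unbounded; the returned sentinel is
#' `F = Inf, p = 0`.  Identical groups give `F = 0, p = 1`.
#'
#' @param errors_by_model Named list mapping a model label to its numeric
#'   vector of per-pair errors; at least two groups of at least two
#'   observations each.
#' @param welch Use Welch's correction for unequal variances (default
#'   `FALSE`, the classical F test).
#' @return A list with elements `F`, `p`, `df_between`, `df_within`.
#' @export
#' @examples
#' compare_models_anova(list(a = c(1, 2, 3), b = c(2, 3, 4)))
compare_models_anova <- function(errors_by_model, welch = FALSE) {
  if (!is.list(errors_by_model) || length(errors_by_model) < 2L)
    stop_param("need at least two groups of errors")
  if (any(vapply(errors_by_model, length, 1L) < 2L))
    stop_param("each group needs at least two observations")
  if (is.null(names(errors_by_model)))
    names(errors_by_model) <- paste0("model", seq_along(errors_by_model))
  df <- data.frame(
    error = unlist(errors_by_model, use.names = FALSE),
    model = factor(rep(names(errors_by_model),
                       vapply(errors_by_model, length, 1L))))
  if (welch) {
    ft <- stats::oneway.test(error ~ model, data = df, var.equal = FALSE)
    return(list(F = unname(ft$statistic), p = unname(ft$p.value),
                df_between = unname(ft$parameter[1L]),
                df_within = unname(ft$parameter[2L])))
  }
  df1 <- length(errors_by_model) - 1L
  df2 <- nrow(df) - length(errors_by_model)
  # degenerate layouts, decided on the raw groups (the aov QR residuals are
  # never exactly zero): constant groups make the F statistic unbounded
  # unless the group means coincide too
  means <- vapply(errors_by_model, mean, numeric(1L))
  if (all(vapply(errors_by_model, function(g) stats::var(g) == 0, TRUE))) {
    if (max(means) - min(means) > 0)
      return(list(F = Inf, p = 0, df_between = df1, df_within = df2))
    return(list(F = 0, p = 1, df_between = df1, df_within = df2))
  }
  # equal group means make the between-group sum of squares exactly zero;
  # report the exact statistic rather than the QR round-off
  if (max(means) - min(means) == 0)
    return(list(F = 0, p = 1, df_between = df1, df_within = df2))
  fit <- stats::aov(error ~ model, data = df)
  tab <- summary(fit)[[1L]]
  msb <- tab["model", "Mean Sq"]
  msw <- tab["Residuals", "Mean Sq"]
  f <- msb / msw
  list(F = f, p = stats::pf(f, df1, df2, lower.tail = FALSE),
       df_between = df1, df_within = df2)
}
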