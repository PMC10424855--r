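test_that("von Kries scaling normalizes the adapting stimulus to unity", {
  expect_equal(unname(von_kries_adapt(c(50, 100, 200), c(100, 100, 100))),
               c(0.5, 1, 2), tolerance = 1e-12)
  lms <- c(80, 120, 60)
  expect_equal(unname(von_kries_adapt(lms, lms)), c(1, 1, 1),
               tolerance = 1e-12)
  expect_error(von_kries_adapt(c(1, 1, 1), c(0, 1, 1)),
               class = "wgmcat_domain_error")
})

test_that("the linear transform interpolates between von Kries and the reference", {
  ref <- c(100, 100, 100)
  p1 <- cat_params("linear", D = 1, reference = ref)
  p0 <- cat_params("linear", D = 0, reference = ref)
  ph <- cat_params("linear", D = 0.5, reference = ref)
  stim <- c(100, 100, 100); adapting <- c(110, 100, 80)
  expect_equal(linear_cat_adapt(stim, adapting, p1),
               von_kries_adapt(stim, adapting), tolerance = 1e-12)
  expect_equal(unname(linear_cat_adapt(stim, adapting, p0)), stim / ref,
               tolerance = 1e-12)
  expect_equal(unname(linear_cat_adapt(stim, adapting, ph)),
               c(100 / 105, 1, 100 / 90), tolerance = 1e-12)
  expect_error(cat_params("linear", D = 1.2), class = "wgmcat_parameter_error")
})

test_that("vk20 reduces to von Kries and to the linear transform", {
  set.seed(7)
  stim <- rand_lms(1)[1, ]; adapting <- rand_lms(1)[1, ]
  pv <- cat_params("vk20", Dn = 1, Dr = 0, Dp = 0)
  expect_equal(vk20_adapt(stim, adapting, pv),
               von_kries_adapt(stim, adapting), tolerance = 1e-12)
  ref <- reference_white("15000K")
  p_vk <- cat_params("vk20", Dn = 0.7)
  p_lin <- cat_params("linear", D = 0.7, reference = ref)
  expect_equal(vk20_adapt(stim, adapting, p_vk),
               linear_cat_adapt(stim, adapting, p_lin), tolerance = 1e-15)
  # implied neutral lies on the straight LMS segment between the anchors
  den <- 0.7 * adapting + 0.3 * ref
  expect_equal(unname(vk20_adapt(den, adapting, p_vk)), c(1, 1, 1),
               tolerance = 1e-12)
  expect_error(cat_params("vk20", Dn = 0.5, Dr = 0.6, Dp = 0.1),
               class = "wgmcat_parameter_error")
  expect_error(cat_params("vk20", Dn = 0.5, Dp = 0.5),
               class = "wgmcat_parameter_error")  # Dp > 0 without previous
})

test_that("geometric-mean neutral is the channelwise root of the anchors", {
  ref <- reference_white("15000K")
  expect_equal(unname(gm_neutral(c(100, 100, 100), ref)),
               c(sqrt(9541), sqrt(10387), sqrt(16981)), tolerance = 1e-12)
  anchors <- rand_lms(1)[1, ]
  expect_equal(unname(gm_neutral(anchors, anchors)), unname(anchors),
               tolerance = 1e-12)
  expect_equal(gm_neutral(c(100, 100, 100), ref),
               wgm_neutral(c(100, 100, 100), ref, D = 0.5),
               tolerance = 1e-15)
})

test_that("wgm neutral endpoints, log-linearity, and monotonicity in D", {
  set.seed(8)
  n <- rand_lms(1)[1, ]; r <- rand_lms(1)[1, ]
  expect_equal(unname(wgm_neutral(n, r, 1)), unname(n), tolerance = 1e-12)
  expect_equal(unname(wgm_neutral(n, r, 0)), unname(r), tolerance = 1e-12)
  for (D in c(0.2, 0.5, 0.9))
    expect_equal(log(unname(wgm_neutral(n, r, D))),
                 D * log(unname(n)) + (1 - D) * log(unname(r)),
                 tolerance = 1e-12)
  Ds <- seq(0, 1, by = 0.05)
  path <- t(vapply(Ds, function(D) unname(wgm_neutral(n, r, D)), numeric(3)))
  for (ch in 1:3) {
    d <- diff(path[, ch])
    if (n[ch] > r[ch]) expect_true(all(d > 0)) else expect_true(all(d < 0))
  }
  expect_error(wgm_neutral(n, r, 1.01), class = "wgmcat_parameter_error")
})

test_that("wgm adaptation reduces to von Kries at D = 1 and is log-linear", {
  set.seed(9)
  stim <- rand_lms(1000); adapting <- rand_lms(1000)
  p1 <- cat_params("wgm", D = 1)
  vk <- von_kries_adapt(stim, adapting)
  expect_lt(max(abs(wgm_adapt(stim, adapting, p1) / vk - 1)), 1e-12)
  p0 <- cat_params("wgm", D = 0)
  expect_equal(wgm_adapt(stim, adapting, p0),
               stim / rep(reference_white("15000K"), each = 1000),
               tolerance = 1e-12, ignore_attr = TRUE)
  # for an EE reference the log-output is the von Kries log-output scaled
  # by D; brute-force channel arithmetic over random triples
  pee <- cat_params("wgm", D = 0.65, reference = "EE")
  got <- log(wgm_adapt(stim[1:100, ], adapting[1:100, ], pee))
  want <- matrix(NA_real_, 100, 3)
  for (i in 1:100) for (ch in 1:3)
    want[i, ch] <- log(stim[i, ch]) -
      (0.65 * log(adapting[i, ch]) + 0.35 * log(100))
  expect_equal(got, want, tolerance = 1e-12, ignore_attr = TRUE)
  # the predicted neutral adapts to exactly (1, 1, 1)
  pw <- cat_params("wgm", D = 0.37)
  nn <- wgm_neutral(adapting[1, ], reference_white("15000K"), 0.37)
  expect_equal(unname(wgm_adapt(nn, adapting[1, ], pw)), c(1, 1, 1),
               tolerance = 1e-12)
})

test_that("corresponding cone responses rescale by the reference white", {
  ref <- reference_white("15000K")
  expect_equal(unname(to_corresponding(c(1, 1, 1), ref)), unname(ref))
  expect_equal(unname(to_corresponding(c(1, 1, 1), reference_white("EE"))),
               c(100, 100, 100))
  x <- rand_lms(1)[1, ]; n <- rand_lms(1)[1, ]
  expect_equal(unname(to_corresponding(von_kries_adapt(x, n), n)), unname(x),
               tolerance = 1e-12)
})

test_that("corresponding colors invert exactly across illuminant pairs", {
  set.seed(10)
  p <- cat_params("wgm", D = 0.7)
  stims <- rand_xyz(200)
  fwd <- corresponding_color(stims, "A", "D65", p)
  back <- corresponding_color(fwd, "D65", "A", p)
  expect_lt(max(abs(back - stims)), 1e-9)
  same <- corresponding_color(stims, "A", "A", p)
  expect_lt(max(abs(same - stims)), 1e-9)
  # complete adaptation maps the first white to the second white
  p1 <- cat_params("wgm", D = 1)
  w <- corresponding_color(parse_illuminant("A")$xyz, "A", "D65", p1)
  expect_equal(unname(w), unname(parse_illuminant("D65")$xyz),
               tolerance = 1e-9)
})

test_that("predicted neutrals sit at the model denominator's chromaticity", {
  ref_uv <- xyz_to_upvp(lms_to_xyz(reference_white("15000K")))
  p0 <- cat_params("wgm", D = 0)
  expect_equal(predict_neutral("cct:4000", p0), ref_uv, tolerance = 1e-12)
  # linear-model neutral is a convex combination in cone space
  n <- parse_illuminant("cct:4000")$lms
  r <- reference_white("EE")
  plin <- cat_params("linear", D = 0.3, reference = "EE")
  expect_equal(predict_neutral(n, plin),
               xyz_to_upvp(lms_to_xyz(0.3 * n + 0.7 * r)), tolerance = 1e-12)
})

test_that("wgm neutrals track the Planckian locus for Planckian adaptors", {
  for (cct in c(3000, 4000, 6500, 10000)) {
    for (D in c(0.3, 0.5, 0.7)) {
      uv <- predict_neutral(sprintf("cct:%d", cct), cat_params("wgm", D = D))
      expect_lt(locus_distance(uv), 0.01)
    }
  }
})

test_that("the CIECAM16 luminance-based D helper is clamped and increasing", {
  D <- cat16_degree_of_adaptation(c(0, 10, 100, 1000, 1e5))
  expect_true(all(D >= 0 & D <= 1))
  expect_true(all(diff(D) >= 0))
  expect_equal(cat16_degree_of_adaptation(100),
               1 - (1 / 3.6) * exp((-100 - 42) / 92), tolerance = 1e-12)
})
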