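# Shared fixtures.  Random triples are strictly positive in both XYZ and
# cone space so every transform is applicable.

rand_xyz <- function(n, lo = 5, hi = 150) {
  out <- matrix(numeric(0), ncol = 3L)
  while (nrow(out) < n) {
    m <- matrix(stats::runif(6L * n, lo, hi), ncol = 3L)
    keep <- rowSums(xyz_to_lms(m) <= 0) == 0L
    out <- rbind(out, m[keep, , drop = FALSE])
  }
  out <- out[seq_len(n), , drop = FALSE]
  dimnames(out) <- list(NULL, c("X", "Y", "Z"))
  out
}

rand_lms <- function(n, lo = 5, hi = 200) {
  matrix(stats::runif(3L * n, lo, hi), ncol = 3L,
         dimnames = list(NULL, c("L", "M", "S")))
}

# A tiny model-consistent pair dataset: stimuli under illum1, mapped by the
# ground-truth transform to illum2.
toy_pair_dataset <- function(params, illum1 = "A", illum2 = "D65",
                             stims = rbind(c(40, 45, 30), c(70, 60, 20),
                                           c(25, 30, 45))) {
  il1 <- parse_illuminant(illum1)
  il2 <- parse_illuminant(illum2)
  stim2 <- corresponding_color(stims, illum1, illum2, params)
  n <- nrow(stims)
  as_cc_dataset(data.frame(
    pair_id = rep(sprintf("p%d", seq_len(n)), 2L),
    condition_id = illum1, kind = "pair",
    phase = rep(c(1L, 2L), each = n),
    X = c(stims[, 1L], stim2[, 1L]),
    Y = c(stims[, 2L], stim2[, 2L]),
    Z = c(stims[, 3L], stim2[, 3L]),
    illum_X = rep(c(il1$xyz[[1L]], il2$xyz[[1L]]), each = n),
    illum_Y = rep(c(il1$xyz[[2L]], il2$xyz[[2L]]), each = n),
    illum_Z = rep(c(il1$xyz[[3L]], il2$xyz[[3L]]), each = n),
    stringsAsFactors = FALSE))
}
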