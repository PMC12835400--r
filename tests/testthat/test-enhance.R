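test_that("time-domain energy ratio matches closed forms", {
  a <- tone_track(400, 0.05, amp = 0.3)
  expect_equal(energy_ratio_db(a, a)$value_db, 0)
  expect_equal(energy_ratio_db(track_scale(a, 2), a)$value_db,
               10 * log10(4), tolerance = 1e-12)        # 6.0206 dB
  r <- energy_ratio_db(audio_track(c(1, 1)), audio_track(c(1, 0)))
  expect_equal(r$value_db, 10 * log10(2), tolerance = 1e-12)  # 3.0103 dB
  z <- energy_ratio_db(a, audio_track(rep(0, length(a$samples))))
  expect_true(z$infinite)
  expect_error(energy_ratio_db(a, tone_track(400, 0.06)), "length")
})

test_that("electrodogram-domain ratio sums squared magnitudes over frames and channels", {
  x <- gen_voice_like(voice_spec(duration = 0.2, seed = 5))
  e <- encode_ace(x)
  expect_equal(electrodogram_ratio_db(e, e)$value_db, 0)
  doubled <- electrodogram(e$values * 2, e$frame_rate, "lgf", e$N)
  r <- electrodogram_ratio_db(doubled, e)
  expect_equal(r$value_db, 10 * log10(4), tolerance = 1e-12)
  # all-inactive denominator flags infinite
  empty <- electrodogram(matrix(NA_real_, nrow(e$values), 22), e$frame_rate, "lgf", e$N)
  expect_true(electrodogram_ratio_db(e, empty)$infinite)
  expect_error(electrodogram_ratio_db(e,
    electrodogram(e$values[1:3, ], e$frame_rate, "lgf")), "shape")
})

test_that("split gain shifts the pairwise energy ratio by exactly its total", {
  a <- gen_voice_like(voice_spec(duration = 0.2, seed = 1))
  b <- gen_instrument_like(instrument_spec(duration = 0.2, seed = 2))
  before <- energy_ratio_db(a, b)$value_db
  for (g in 0:8) {
    pair <- apply_split_gain(a, b, g)
    after <- energy_ratio_db(pair$target, pair$interferer)$value_db
    expect_equal(after - before, g, tolerance = 1e-9)
  }
  # 6 dB total is realized as +3 dB on target and -3 dB on interferer
  p6 <- apply_split_gain(a, b, 6)
  expect_equal(p6$target$samples, a$samples * 10^(3 / 20), tolerance = 1e-12)
  expect_equal(p6$interferer$samples, b$samples * 10^(-3 / 20), tolerance = 1e-12)
  p0 <- apply_split_gain(a, b, 0)
  expect_track_equal(p0$target, a)
  expect_error(apply_split_gain(a, b, Inf), "finite")
})

test_that("mix_at_ratio realizes the requested ratio and its degenerate cases", {
  a <- gen_voice_like(voice_spec(duration = 0.2, seed = 3))
  b <- noise_track(0.2, seed = 4)
  for (r in c(-5, 0, 5)) {
    mix <- mix_at_ratio(a, b, r)
    comp <- attr(mix, "components")
    expect_equal(energy_ratio_db(comp$target, comp$interferer)$value_db, r,
                 tolerance = 1e-9)
    expect_equal(mix$samples, comp$target$samples + comp$interferer$samples)
  }
  # equal-energy inputs at 0 dB reduce to the plain sum
  b_eq <- track_scale(b, track_rms(a) / track_rms(b))
  # make energies exactly equal
  b_eq <- track_scale(b_eq, sqrt(sum(a$samples^2) / sum(b_eq$samples^2)))
  mix0 <- mix_at_ratio(a, b_eq, 0)
  expect_equal(mix0$samples, a$samples + b_eq$samples, tolerance = 1e-9)
  # -Inf sentinel: target alone
  alone <- mix_at_ratio(a, b, -Inf)
  expect_equal(alone$samples, a$samples)
  expect_error(mix_at_ratio(a, audio_track(rep(0, length(a$samples))), 5), "zero energy")
})

test_that("vir_eqi equals the linear ratio under bypass and shrinks under the LGF", {
  v <- gen_voice_like(voice_spec(duration = 0.3, seed = 6))
  expect_equal(vir_eqi(v, v)$value_db, 0)
  lin <- ace_config(bypass_lgf = TRUE, bypass_nofm = TRUE)
  r_lin <- vir_eqi(track_scale(v, 2), v, lin)
  expect_equal(r_lin$value_db, 10 * log10(4), tolerance = 0.1)
  expect_equal(r_lin$equation_tag, "VIR_eqi")
  # full nonlinear strategy compresses the 6.02 dB time-domain difference
  r_full <- vir_eqi(track_scale(v, 2), v, ace_config())
  expect_lt(r_full$value_db, 10 * log10(4))
  expect_gt(r_full$value_db, 0)
})

test_that("equivalence table is linear under bypass and compressive in full", {
  v <- gen_voice_like(voice_spec(duration = 0.4, seed = 11))
  i <- gen_instrument_like(instrument_spec(duration = 0.4, seed = 12))
  lin <- ace_config(bypass_lgf = TRUE, bypass_nofm = TRUE)
  tl <- build_equivalence_table(v, i, c(0, 2, 4), lin)
  offset <- tl$end_to_end_db[1]
  expect_equal(tl$end_to_end_db, c(0, 2, 4) + offset, tolerance = 0.1)
  tab <- build_equivalence_table(v, i, 0:8, ace_config())
  expect_true(all(diff(tab$end_to_end_db) > 0))           # strictly increasing
  expect_true(all(diff(tab$end_to_end_db) <= 1 + 1e-9))   # increments <= 1 dB steps
  one <- build_equivalence_table(v, i, 0, ace_config())
  expect_equal(nrow(one), 1L)
  expect_equal(one$end_to_end_db, vir_eqi(v, i, ace_config())$value_db)
  expect_error(build_equivalence_table(v, i, c(3, 1)), "increasing")
})
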