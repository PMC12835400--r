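test_that("AGC is identity when disabled and below threshold", {
  x <- tone_track(500, 0.1, amp = 0.9)
  expect_identical(apply_agc(x, agc_params(enabled = FALSE)), x)
  # constant-amplitude sinusoid below the compression threshold passes through
  quiet <- tone_track(500, 0.1, amp = 0.05)
  agc <- agc_params(enabled = TRUE, threshold_db = -20)  # thr amp 0.1
  y <- apply_agc(quiet, agc)
  expect_equal(y$samples, quiet$samples, tolerance = 1e-6)
})

test_that("AGC limiter holds steady-state peaks at the threshold", {
  thr <- 10^(-20 / 20)
  x <- tone_track(500, 0.5, amp = 2 * thr)
  y <- apply_agc(x, agc_params(enabled = TRUE, threshold_db = -20, ratio = Inf))
  tail_peak <- max(abs(y$samples[4000:8000]))
  expect_equal(tail_peak, thr, tolerance = 0.02)
  expect_lt(tail_peak, 2 * thr)
})

test_that("analysis filterbank is linear and localizes tones", {
  cfg <- ace_config()
  z <- audio_track(rep(0, 400))
  expect_true(all(abs(analysis_filterbank(z, cfg)) == 0))
  # tone at an FFT bin centre concentrates energy in the band holding it
  bin <- 17                                 # 1-based; freq (bin-1)*125 Hz
  x <- tone_track((bin - 1) * 125, 0.1, amp = 0.5)
  env <- band_envelopes(analysis_filterbank(x, cfg), cfg)
  band_of_bin <- cfg$band_table[attr(cfg$band_table, "bins") == bin]
  expect_equal(unname(which.max(colMeans(env))), band_of_bin)
  # linearity: scaling the waveform scales all magnitudes
  f1 <- analysis_filterbank(x, cfg)
  f2 <- analysis_filterbank(track_scale(x, 0.5), cfg)
  expect_equal(abs(f2), 0.5 * abs(f1), tolerance = 1e-12)
  expect_error(analysis_filterbank(audio_track(rep(0, 64)), cfg), "shorter")
})

test_that("band envelopes combine bins by root-sum-square", {
  cfg <- ace_config()
  n_bins <- cfg$fft_size / 2 + 1
  frames <- matrix(0 + 0i, nrow = 2, ncol = n_bins)
  # find a band with at least two bins and put magnitudes 3 and 4 in it
  bt <- cfg$band_table
  wide <- which(tabulate(bt) >= 2)[1]
  bins <- attr(bt, "bins")[bt == wide][1:2]
  frames[1, bins[1]] <- 3
  frames[1, bins[2]] <- 4i
  env <- band_envelopes(frames, cfg)
  expect_equal(env[1, wide], 5, tolerance = 1e-12)
  expect_equal(env[2, ], rep(0, cfg$M))
  # single nonzero bin alone gives that bin's magnitude
  narrow_band <- bt[1]
  frames2 <- matrix(0 + 0i, nrow = 1, ncol = n_bins)
  frames2[1, attr(bt, "bins")[1]] <- 1
  expect_equal(band_envelopes(frames2, cfg)[1, narrow_band], 1, tolerance = 1e-12)
})

test_that("LGF maps base to inactive, saturation to one, midpoint to its closed form", {
  p <- lgf_params()
  expect_true(is.na(lgf_compress(matrix(p$base_level), p)[1, 1]))
  expect_equal(lgf_compress(matrix(p$sat_level), p)[1, 1], 1)
  expect_equal(lgf_compress(matrix(2 * p$sat_level), p)[1, 1], 1)
  # frozen value: log(1 + 416.2 * 0.5) / log(1 + 416.2) evaluated directly
  mid <- (p$base_level + p$sat_level) / 2
  expect_equal(lgf_compress(matrix(mid), p)[1, 1], 0.8855149428, tolerance = 1e-9)
  expect_error(lgf_params(rho = -1), "rho")
  expect_error(lgf_params(base_level = 0.9, sat_level = 0.5), "base_level")
})

test_that("LGF is monotone non-decreasing in its input", {
  p <- lgf_params()
  for (seed in 1:5) {
    set.seed(seed)
    e1 <- matrix(runif(40, 0, 0.8), 8, 5)
    e2 <- e1 + matrix(runif(40, 0, 0.2), 8, 5)
    y1 <- lgf_compress(e1, p); y1[is.na(y1)] <- 0
    y2 <- lgf_compress(e2, p); y2[is.na(y2)] <- 0
    expect_true(all(y2 - y1 >= -1e-12))
  }
})

test_that("N-of-M keeps the N largest per frame with lower-index tie-breaks", {
  expect_equal(sum(!is.na(select_n_of_m(matrix(0, 1, 22), 8))), 0)
  # exactly 8 nonzero of 22 with N = 8: all retained unchanged
  v <- rep(0, 22); v[c(2, 5, 7, 9, 12, 15, 18, 21)] <- runif(8, 0.1, 1)
  out <- select_n_of_m(matrix(v, 1), 8)
  expect_equal(which(!is.na(out[1, ])), c(2, 5, 7, 9, 12, 15, 18, 21))
  expect_equal(out[1, !is.na(out[1, ])], v[v > 0])
  # descending frame: the 8 largest values win (sort-based oracle)
  f <- matrix(22:1, 1)
  out2 <- select_n_of_m(f, 8)
  expect_equal(which(!is.na(out2[1, ])), 1:8)
  expect_equal(out2[1, 1:8], 22:15)
  # ties break toward the lower electrode index
  tie <- rep(c(0.5, 0.1), 11)
  out3 <- select_n_of_m(matrix(tie, 1), 3)
  expect_equal(which(!is.na(out3[1, ])), c(1, 3, 5))
})

test_that("subject mapping is affine on the electrical dynamic range", {
  m <- subject_map(M = 3, N = 2, thl = c(100, 110, 120), mcl = c(200, 190, 220))
  sp <- matrix(c(0, 0.5, 1), 1)
  out <- map_to_current(sp, m)
  expect_equal(out[1, ], c(100, 150, 220))
  sp2 <- matrix(c(NA, 0.25, NA), 1)
  out2 <- map_to_current(sp2, m)
  expect_true(is.na(out2[1, 1]) && is.na(out2[1, 3]))
  expect_equal(out2[1, 2], 130)
  expect_error(subject_map(M = 2, N = 1, thl = 200, mcl = 100), "thl")
  expect_error(map_to_current(matrix(1.5, 1, 3), m), "\\[0, 1\\]")
})

test_that("full ACE encode honours channel counts and silence", {
  cfg <- ace_config()
  silence <- audio_track(rep(0, 1600))
  e0 <- encode_ace(silence, cfg)
  expect_equal(sum(!is.na(e0$values)), 0)
  x <- gen_voice_like(voice_spec(duration = 0.3, seed = 4))
  e <- encode_ace(x, cfg)
  expect_equal(e$M, 22)
  active <- rowSums(!is.na(e$values))
  expect_true(all(active <= 8))
  expect_gt(max(active), 0)
  expect_true(all(e$values >= 0 & e$values <= 1, na.rm = TRUE))
  # current-domain entries lie within [thl, mcl]
  cfg_cur <- ace_config(output = "current")
  ec <- encode_ace(x, cfg_cur)
  expect_true(all(ec$values >= 100 & ec$values <= 200, na.rm = TRUE))
})

test_that("frames with at least N supra-base bands stimulate exactly N channels", {
  cfg <- ace_config()
  set.seed(11)
  loud <- audio_track(0.5 * stats::rnorm(3200))   # broadband, many active bands
  e <- encode_ace(loud, cfg)
  env <- band_envelopes(analysis_filterbank(loud, cfg), cfg)
  supra <- rowSums(env > cfg$lgf$base_level)
  active <- rowSums(!is.na(e$values))
  expect_true(all(active[supra >= 8] == 8))
})

test_that("bypassing AGC, LGF and N-of-M yields a chain linear in amplitude", {
  cfg <- ace_config(bypass_lgf = TRUE, bypass_nofm = TRUE)
  # harmonic complex
  tt <- seq_len(3200) / 16000
  x <- audio_track(0.05 * (sin(2 * pi * 220 * tt) + 0.5 * sin(2 * pi * 440 * tt) +
                           0.25 * sin(2 * pi * 880 * tt)))
  ea <- encode_ace(track_scale(x, 2), cfg)
  eb <- encode_ace(track_scale(x, 0.5), cfg)
  r <- electrodogram_ratio_db(ea, eb)
  expect_equal(r$value_db, 20 * log10(2 / 0.5), tolerance = 0.1)
})

test_that("encoding is deterministic and electrodograms round-trip through text", {
  x <- gen_voice_like(voice_spec(duration = 0.2, seed = 9))
  e1 <- encode_ace(x); e2 <- encode_ace(x)
  expect_identical(e1$values, e2$values)
  p <- withr::local_tempfile(fileext = ".elec")
  write_electrodogram(e1, p)
  e3 <- read_electrodogram(p)
  expect_equal(e3$values, unname(e1$values), tolerance = 1e-10)
  expect_equal(e3$frame_rate, e1$frame_rate)
  expect_equal(e3$domain_tag, "lgf")
  expect_equal(e3$N, e1$N)
})

test_that("band table is monotone, covers all bands once and respects geometry", {
  for (M in c(8, 16, 22)) {
    bt <- default_band_table(128, 16000, M)
    expect_false(is.unsorted(bt))
    expect_equal(sort(unique(as.integer(bt))), 1:M)
    expect_equal(length(bt), length(attr(bt, "bins")))
    expect_false(anyDuplicated(attr(bt, "bins")) > 0)
  }
  expect_error(default_band_table(16, 16000, 22), "fewer")
})
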