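test_that("config validation enforces the documented invariants", {
  expect_error(tasnet_config(L = 15), "even")
  expect_error(tasnet_config(P = 4), "odd")
  expect_error(tasnet_config(N = 0), "positive")
  expect_error(tasnet_config(output_domain = "lgf", lgf_bands = 0), "lgf_bands")
  expect_equal(tasnet_config(output_domain = "time")$encoder_activation, "linear")
  expect_equal(tasnet_config(output_domain = "lgf")$encoder_activation, "relu")
})

test_that("parameter counts match the independent layer-by-layer oracle", {
  # tiny config, conv mask head (S != N)
  cfg <- tiny_time_cfg()
  expect_equal(count_parameters(build_separator(cfg)),
               count_params_oracle(6, 4, 4, 6, 4, 3, 2, 1, domain = "time"))
  # tiny config from the shape contract family
  cfg2 <- tasnet_config(N = 4, L = 2, B = 2, H = 4, S = 2, P = 3, X = 1, R = 1)
  expect_equal(count_parameters(build_separator(cfg2)),
               count_params_oracle(4, 2, 2, 4, 2, 3, 1, 1, domain = "time"))
  # complementary mask head (S == N, two sources)
  cfg3 <- tasnet_config(N = 8, L = 4, B = 4, H = 8, S = 8, P = 3, X = 2, R = 2)
  expect_equal(count_parameters(build_separator(cfg3)),
               count_params_oracle(8, 4, 4, 8, 8, 3, 2, 2, domain = "time"))
  # lgf-domain decoder
  cfg4 <- tiny_lgf_cfg()
  expect_equal(count_parameters(build_separator(cfg4)),
               count_params_oracle(6, 4, 4, 6, 4, 3, 2, 1, domain = "lgf", M = 5))
  # a single affine map sanity anchor: 3 inputs, 2 outputs, bias -> 8
  expect_equal(2 * 3 + 2, 8)
})

test_that("published front-end columns build and land near their printed budgets", {
  p <- tasnet_presets()
  n_speech <- count_parameters(build_separator(p$speech_front_end))
  expect_lt(abs(n_speech - 824000) / 824000, 0.02)
  n_music <- count_parameters(build_separator(p$music_front_end))
  expect_lt(abs(n_music - 2431000) / 2431000, 0.02)
  # and they agree with the counting oracle exactly
  expect_equal(n_speech, count_params_oracle(128, 16, 64, 128, 128, 3, 8, 3))
  expect_equal(n_music, count_params_oracle(128, 16, 128, 256, 128, 3, 8, 3))
})

test_that("initialization is deterministic in config seed", {
  m1 <- build_separator(tiny_time_cfg(seed = 42))
  m2 <- build_separator(tiny_time_cfg(seed = 42))
  expect_identical(m1$params, m2$params)
  m3 <- build_separator(tiny_time_cfg(seed = 43))
  expect_false(identical(m1$params, m3$params))
})

test_that("separation honours the output shape contract", {
  model <- build_separator(tiny_time_cfg())
  mix <- noise_track(0.05, seed = 3)
  out <- separate(model, mix)
  expect_length(out$sources, 2L)
  for (s in out$sources) expect_equal(length(s$samples), length(mix$samples))
  # near-zero input gives near-zero outputs
  zmix <- audio_track(rep(1e-12, 800))
  z <- separate(model, zmix)
  for (s in z$sources) expect_lt(sqrt(mean(s$samples^2)), 1e-6)
  # lgf-domain model emits frames x lgf_bands per source
  ml <- build_separator(tiny_lgf_cfg())
  outl <- separate(ml, mix)
  expect_equal(outl$domain, "lgf")
  for (e in outl$sources) {
    expect_s3_class(e, "electrodogram")
    expect_equal(ncol(e$values), 5L)
  }
  # inference is deterministic for fixed weights
  out2 <- separate(model, mix)
  expect_identical(out$sources[[1]]$samples, out2$sources[[1]]$samples)
})

test_that("front-end and lgf variants differ only in the declared aspects", {
  base <- list(N = 8, L = 4, B = 4, H = 8, S = 4, P = 3, X = 2, R = 1, seed = 3)
  fe <- build_separator(do.call(tasnet_config, c(base, list(output_domain = "time"))))
  ee <- build_separator(do.call(tasnet_config, c(base, list(output_domain = "lgf",
                                                            lgf_bands = 5))))
  sf <- tasnet_structure(fe); se <- tasnet_structure(ee)
  expect_identical(sf$trunk_shapes, se$trunk_shapes)     # shared encoder/TCN
  expect_false(identical(sf$encoder_activation, se$encoder_activation))
  expect_false(identical(sf$head, se$head))
})

test_that("lgf targets are the pre-selection LGF encodings of clean sources", {
  cfg <- ace_config(fft_size = 128, hop = 64)
  silence <- audio_track(rep(0, 1600))
  expect_true(all(lgf_targets(list(silence), cfg)[[1]] == 0))
  v <- gen_voice_like(voice_spec(duration = 0.2, seed = 8))
  t2 <- lgf_targets(list(v, v), cfg)
  expect_identical(t2[[1]], t2[[2]])
  # linear-bypass config: targets scale proportionally with the source
  lin <- ace_config(fft_size = 128, hop = 64, bypass_lgf = TRUE, bypass_nofm = TRUE)
  ta <- lgf_targets(list(v), lin)[[1]]
  tb <- lgf_targets(list(track_scale(v, 0.5)), lin)[[1]]
  expect_equal(tb, 0.5 * ta, tolerance = 1e-10)
  # selection can be included on request, capping per-frame activity
  tsel <- lgf_targets(list(v), ace_config(), include_selection = TRUE)[[1]]
  expect_true(all(rowSums(tsel > 0) <= 8))
})

test_that("checkpoints round-trip through JSON text", {
  model <- build_separator(tiny_time_cfg(seed = 12))
  p <- withr::local_tempfile(fileext = ".json")
  save_separator(model, p)
  m2 <- load_separator(p)
  expect_equal(m2$params, model$params, tolerance = 1e-12)
  expect_equal(unclass(m2$cfg), unclass(model$cfg))
  mix <- noise_track(0.03, seed = 5)
  expect_equal(separate(m2, mix)$sources[[1]]$samples,
               separate(model, mix)$sources[[1]]$samples, tolerance = 1e-12)
  expect_error(load_separator("/nonexistent/ckpt.json"), "no such checkpoint")
})
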