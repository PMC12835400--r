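# Shared fixtures: all built in code, deterministic under fixed seeds.

# short sinusoid track
tone_track <- function(freq = 500, dur = 0.1, amp = 0.1, rate = 16000,
                       phase = 0, label = "tone") {
  tt <- seq_len(round(dur * rate)) / rate
  audio_track(amp * sin(2 * pi * freq * tt + phase), rate, label)
}

# deterministic noise track
noise_track <- function(dur = 0.1, amp = 0.05, rate = 16000, seed = 1) {
  set.seed(seed)
  audio_track(amp * stats::rnorm(round(dur * rate)), rate, "noise")
}

# tiny separator config used across tests (fast to build and train)
tiny_time_cfg <- function(seed = 7)
  tasnet_config(N = 6, L = 4, B = 4, H = 6, S = 4, P = 3, X = 2, R = 1,
                output_domain = "time", seed = seed)

tiny_lgf_cfg <- function(seed = 7)
  tasnet_config(N = 6, L = 4, B = 4, H = 6, S = 4, P = 3, X = 2, R = 1,
                output_domain = "lgf", lgf_bands = 5, seed = seed)

# independent layer-by-layer parameter-count oracle: sums each layer's
# weight and bias sizes from the hyperparameters alone (never calls the
# model's own counter). Mirrors the documented architecture: encoder conv
# (no bias), global layer norm, 1x1 bottleneck, R*X uniform blocks
# (1x1 in-conv, PReLU, norm, depthwise conv, PReLU, norm, skip 1x1,
# residual 1x1), PReLU mask head (plus 1x1 conv head when S != N or more
# than two sources), and the domain-specific decoder.
count_params_oracle <- function(N, L, B, H, S, P, X, R, C = 2,
                                domain = "time", M = 22) {
  n <- N * L                       # encoder
  n <- n + 2 * N                   # encoder norm
  n <- n + N * B + B               # bottleneck 1x1
  per_block <- (B * H + H) + 1 + 2 * H +      # in conv, PReLU, norm
    (P * H + H) + 1 + 2 * H +                 # depthwise conv, PReLU, norm
    (H * S + S) + (H * B + B)                 # skip and residual 1x1
  n <- n + R * X * per_block
  n <- n + 1                                  # mask PReLU
  if (!(C == 2 && S == N)) n <- n + S * C * N + C * N   # mask 1x1 conv
  if (domain == "time") {
    n + L * N                                 # transposed-conv decoder
  } else {
    D <- max(1, ceiling(N / 2))
    n + (D * N * P + D) + (M * D + M)         # stepwise-reduction decoder
  }
}

expect_track_equal <- function(a, b, tol = 1e-12) {
  expect_equal(a$samples, b$samples, tolerance = tol)
  expect_equal(a$rate, b$rate)
}
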