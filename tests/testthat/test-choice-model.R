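test_that("bias parameters are validated and expose their negated counterparts", {
  p <- bias_params(0.4, -0.2, 0.1)
  expect_equal(peer_bias(p), -0.4)
  expect_equal(incongruent_bias(p), 0.2)
  expect_equal(recency_bias(p), -0.1)
  expect_error(bias_params(1.5, 0), "\\[-1, 1\\]")
  expect_error(bias_params(0, 0, -2), "\\[-1, 1\\]")
  expect_error(bias_params(NA, 0), "non-missing")
})

test_that("bias-to-weight map is the affine (1+b)/2 and rejects out-of-range input", {
  expect_equal(bias_weight(c(-1, 0, 1)), c(0, 0.5, 1))
  b <- seq(-1, 1, by = 0.25)
  expect_true(all(diff(bias_weight(b)) > 0))
  expect_error(bias_weight(1.01), "\\[-1, 1\\]")
})

test_that("variant weights are the product of source, congruence and order factors", {
  v <- variant_pair("first")
  # neutral biases: every factor is 0.5
  expect_equal(
    variant_weight(bias_params(0, 0, 0), "peer_to_peer", v$expert), 0.125
  )
  # expert bias 0.5 in E2N: 0.75 (source) x 0.5 (congruence) x 0.5 (order)
  expect_equal(
    variant_weight(bias_params(0.5, 0, 0), "expert_to_novice", v$expert),
    0.1875
  )
  # total expert bias kills the peer variant
  expect_equal(
    variant_weight(bias_params(1, 0, 0), "expert_to_novice", v$peer), 0
  )
})

test_that("choice probabilities normalize and handle the degenerate boundary", {
  v <- variant_pair("first")
  expect_equal(
    choice_probability(bias_params(0, 0, 0), "peer_to_peer", v$expert, v$peer),
    0.5
  )
  # full congruence bias in E2N: the expert's (congruent) variant is certain
  expect_equal(
    choice_probability(bias_params(0, 1, 0), "expert_to_novice",
      v$expert, v$peer),
    1
  )
  # hand-computed normalized product
  expect_equal(
    choice_probability(bias_params(0.5, 0, 0), "expert_to_novice",
      v$expert, v$peer),
    0.75
  )
  # eb = 1, cb = 1 in P2P zeroes both weights: declared fallback
  expect_equal(
    choice_probability(bias_params(1, 1, 0), "peer_to_peer",
      v$expert, v$peer),
    0.5
  )
  expect_error(
    choice_probability(bias_params(0, 0), "peer_to_peer", v$expert, v$expert),
    "opposite"
  )
})

test_that("choice_probability agrees with an independent re-derivation", {
  draws <- random_bias_draws(200)
  v <- variant_pair("first")
  for (i in seq_len(nrow(draws))) {
    for (ctx in transmission_contexts()) {
      p <- bias_params(draws$eb[i], draws$cb[i], draws$pb[i])
      expect_equal(
        choice_probability(p, ctx, v$expert, v$peer),
        brute_choice_prob(draws$eb[i], draws$cb[i], draws$pb[i], ctx,
          v$expert, v$peer),
        tolerance = 1e-14
      )
    }
  }
})

test_that("model symmetries hold to machine precision", {
  draws <- random_bias_draws(300)
  v1 <- variant_pair("first")
  v2 <- variant_pair("last")
  for (i in seq_len(nrow(draws))) {
    eb <- draws$eb[i]
    cb <- draws$cb[i]
    pb <- draws$pb[i]
    for (ctx in transmission_contexts()) {
      # normalization: complementary probabilities sum to 1 exactly
      p_fwd <- choice_probability(bias_params(eb, cb, pb), ctx,
        v1$expert, v1$peer)
      p_rev <- choice_probability(bias_params(eb, cb, pb), ctx,
        v1$peer, v1$expert)
      expect_lt(abs(p_fwd + p_rev - 1), 1e-15)
    }
    # expert/peer symmetry across contexts under sign flip
    expect_equal(
      choice_probability(bias_params(eb, cb, 0), "expert_to_novice",
        v1$expert, v1$peer),
      choice_probability(bias_params(-eb, cb, 0), "peer_to_peer",
        v1$peer, v1$expert),
      tolerance = 1e-12
    )
    # congruence sign flip maps each context onto the other
    expect_equal(
      choice_probability(bias_params(eb, -cb, 0), "expert_to_novice",
        v1$expert, v1$peer),
      choice_probability(bias_params(eb, cb, 0), "peer_to_peer",
        v1$expert, v1$peer),
      tolerance = 1e-12
    )
    # flipping both biases swaps the two variants within a context
    expect_equal(
      choice_probability(bias_params(-eb, -cb, 0), "expert_to_novice",
        v1$expert, v1$peer),
      choice_probability(bias_params(eb, cb, 0), "expert_to_novice",
        v1$peer, v1$expert),
      tolerance = 1e-12
    )
    # neutral primacy makes learning order irrelevant
    expect_equal(
      choice_probability(bias_params(eb, cb, 0), "peer_to_peer",
        v1$expert, v1$peer),
      choice_probability(bias_params(eb, cb, 0), "peer_to_peer",
        v2$expert, v2$peer),
      tolerance = 1e-12
    )
  }
})

test_that("expert-variant probability is non-decreasing in expert bias", {
  v <- variant_pair("first")
  eb_grid <- seq(-0.95, 0.95, by = 0.05)
  for (cb in c(-0.6, 0, 0.6)) {
    for (ctx in transmission_contexts()) {
      probs <- vapply(eb_grid, function(eb) {
        choice_probability(bias_params(eb, cb, 0), ctx, v$expert, v$peer)
      }, numeric(1))
      expect_true(all(diff(probs) >= -1e-12))
    }
  }
})

test_that("the vectorized expert-production probability matches the scalar model", {
  draws <- random_bias_draws(100, seed = 7)
  for (ctx in transmission_contexts()) {
    for (ord in c("first", "last")) {
      v <- variant_pair(ord)
      vec <- transbias:::prob_expert_produced(
        draws$eb, draws$cb, draws$pb, ctx, ord
      )
      scl <- vapply(seq_len(nrow(draws)), function(i) {
        choice_probability(
          bias_params(draws$eb[i], draws$cb[i], draws$pb[i]), ctx,
          v$expert, v$peer
        )
      }, numeric(1))
      expect_equal(vec, scl, tolerance = 1e-14)
    }
  }
})
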