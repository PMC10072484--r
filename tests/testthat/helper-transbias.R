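# the published production counts: expert-to-novice 27 expert / 3 peer,
# peer-to-peer 14 expert / 18 peer (30 and 32 participants)
paper_counts <- function() count_table(27, 3, 14, 18)

paper_design <- function() experiment_design(30, 32)

# independent re-derivation of the choice probability, written directly
# from the model definition (weights (1+b)/2, multiplicative factors,
# Luce normalization); used as the oracle for choice_probability()
brute_choice_prob <- function(eb, cb, pb, context, produced, alternative) {
  wgt <- function(v) {
    p_e <- (1 + eb) / 2
    p_c <- (1 + cb) / 2
    p_l <- (1 + pb) / 2
    cong <- if (context == "expert_to_novice") "expert" else "peer"
    f1 <- if (v$source == "expert") p_e else 1 - p_e
    f2 <- if (v$source == cong) p_c else 1 - p_c
    f3 <- if (v$order == "last") p_l else 1 - p_l
    f1 * f2 * f3
  }
  wp <- wgt(produced)
  wa <- wgt(alternative)
  if (wp + wa == 0) 0.5 else wp / (wp + wa)
}

# the participant's two variants, parameterised by the expert variant's
# learning order
variant_pair <- function(expert_order = "first") {
  expert <- variant_attrs("expert", "parity", expert_order)
  list(expert = expert, peer = opposite_variant(expert))
}

random_bias_draws <- function(n, seed = 42) {
  set.seed(seed)
  tibble::tibble(
    eb = runif(n, -1, 1), cb = runif(n, -1, 1), pb = runif(n, -1, 1)
  )
}

tiny_grid_spec <- function(step = 0.5, s = 200, tolerance = 0) {
  grid_spec(
    expert = grid_axis(step = step), congruent = grid_axis(step = step),
    s = s, tolerance = tolerance
  )
}
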