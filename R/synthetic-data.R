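#' Generate a synthetic participant cohort
#'
#' Builds a participant-level dataset with the statistical structure the
#' analysis assumes: two conditions of `n_per_condition` participants,
#' the four (learning-context order x strategy order) counterbalancing
#' cells exactly balanced within each condition, and each participant's
#' produced variant drawn from the choice model at `true_params` given
#' their own congruence and learning-order attributes. Optionally flags
#' `n_excluded_e2n` expert-to-novice participants as excluded,
#' uniformly at random (emulating post-test exclusions).
#'
#' Which strategy the expert taught is determined by the
#' counterbalancing cell: the expert occupies the first learning slot
#' under `expert_first`, and the strategy in that slot is the first
#' strategy of the participant's strategy order.
#'
#' @param true_params The generating [bias_params()].
#' @param n_per_condition Participants per condition; must be divisible
#'   by 4 so the counterbalancing is exact.
#' @param n_excluded_e2n Number of expert-to-novice participants to flag
#'   as excluded.
#' @param seed Optional integer seed.
#' @return A tibble with one row per participant: `participant_id`,
#'   `condition`, `learning_order` (`expert_first`/`peer_first`),
#'   `strategy_order` (`parity_first`/`skipping_first`),
#'   `expert_strategy`, `produced_source`, `produced_strategy`,
#'   `excluded`.
#' @export
#' @examples
#' cohort <- generate_participants(bias_params(0.4, 0.5), 32,
#'   n_excluded_e2n = 2, seed = 1
#' )
#' tabulate_productions(cohort)
generate_participants <- function(true_params, n_per_condition = 32,
                                  n_excluded_e2n = 0, seed = NULL) {
  stopifnot(inherits(true_params, "bias_params"))
  if (n_per_condition < 4 || n_per_condition %% 4 != 0) {
    abort("`n_per_condition` must be a positive multiple of 4 (counterbalancing)")
  }
  if (n_excluded_e2n < 0 || n_excluded_e2n > n_per_condition) {
    abort("`n_excluded_e2n` must lie in [0, n_per_condition]")
  }
  if (!is.null(seed)) set.seed(seed)
  per_cell <- n_per_condition / 4
  cohort <- tidyr::expand_grid(
    condition = .contexts,
    learning_order = c("expert_first", "peer_first"),
    strategy_order = c("parity_first", "skipping_first"),
    replicate = seq_len(per_cell)
  )
  cohort <- dplyr::mutate(
    cohort,
    participant_id = sprintf("P%03d", dplyr::row_number()),
    expert_strategy = ifelse(
      (.data$learning_order == "expert_first") ==
        (.data$strategy_order == "parity_first"),
      "parity", "skipping"
    ),
    expert_order = ifelse(.data$learning_order == "expert_first",
      "first", "last")
  )
  p_expert <- vapply(seq_len(nrow(cohort)), function(i) {
    prob_expert_produced(
      true_params$expert_bias, true_params$congruent_bias,
      true_params$primacy_bias,
      context = cohort$condition[i], expert_order = cohort$expert_order[i]
    )
  }, numeric(1))
  cohort$produced_source <- ifelse(runif(nrow(cohort)) < p_expert,
    "expert", "peer")
  cohort <- dplyr::mutate(
    cohort,
    produced_strategy = ifelse(.data$produced_source == "expert",
      .data$expert_strategy,
      ifelse(.data$expert_strategy == "parity", "skipping", "parity")
    ),
    excluded = FALSE
  )
  if (n_excluded_e2n > 0) {
    e2n_rows <- which(cohort$condition == "expert_to_novice")
    cohort$excluded[sample(e2n_rows, n_excluded_e2n)] <- TRUE
  }
  dplyr::select(
    cohort, "participant_id", "condition", "learning_order",
    "strategy_order", "expert_strategy", "produced_source",
    "produced_strategy", "excluded"
  )
}

#' Tally a participant cohort into a production count table
#'
#' Counts unexcluded participants by condition and produced source
#' (four-cell), optionally split by the produced variant's learning
#' order (eight-cell). A produced expert-sourced variant was learned
#' first exactly when the participant's learning order is
#' `expert_first`; a produced peer-sourced variant, the reverse.
#'
#' @param records A participant tibble (see [generate_participants()]).
#' @param layout `"four_cell"` or `"eight_cell"`.
#' @return A [count_table]; cells absent from the data are zero.
#' @export
tabulate_productions <- function(records,
                                 layout = c("four_cell", "eight_cell")) {
  layout <- match.arg(layout)
  records <- tibble::as_tibble(records)
  needed <- c("condition", "produced_source", "excluded")
  if (layout == "eight_cell") needed <- c(needed, "learning_order")
  if (!all(needed %in% names(records))) {
    abort(paste0(
      "participant records need columns: ", paste(needed, collapse = ", ")
    ))
  }
  match_context(records$condition)
  records <- dplyr::filter(records, !.data$excluded)
  if (layout == "four_cell") {
    tallies <- dplyr::count(records, .data$condition, .data$produced_source)
    grid <- tidyr::expand_grid(condition = .contexts, produced_source = .sources)
  } else {
    records <- dplyr::mutate(
      records,
      produced_order = ifelse(
        (.data$produced_source == "expert") ==
          (.data$learning_order == "expert_first"),
        "first", "last"
      )
    )
    tallies <- dplyr::count(
      records, .data$condition, .data$produced_source, .data$produced_order
    )
    grid <- tidyr::expand_grid(
      condition = .contexts, produced_source = .sources,
      produced_order = .orders
    )
  }
  out <- dplyr::left_join(grid, tallies, by = names(grid))
  out$n[is.na(out$n)] <- 0L
  out <- dplyr::rename(out, context = "condition", count = "n")
  as_count_table(out)
}
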