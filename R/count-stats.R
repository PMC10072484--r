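#' Chi-squared goodness of fit against equal expected counts
#'
#' Pearson goodness-of-fit test of two counts against the null of equal
#' expected frequencies; the statistic reduces to
#' \eqn{(a - b)^2 / (a + b)} on 1 degree of freedom. No continuity
#' correction is applied.
#'
#' @param count_a,count_b Non-negative integer counts, not both zero.
#' @return A one-row tibble: `method`, `statistic`, `df`, `p_value`.
#' @export
#' @examples
#' chisq_goodness_of_fit(41, 21)
chisq_goodness_of_fit <- function(count_a, count_b) {
  if (count_a < 0 || count_b < 0 ||
    count_a != as.integer(count_a) || count_b != as.integer(count_b)) {
    abort("counts must be non-negative integers")
  }
  if (count_a + count_b == 0) {
    abort("goodness of fit is undefined when both counts are zero")
  }
  ht <- stats::chisq.test(c(count_a, count_b), p = c(0.5, 0.5))
  tibble::tibble(
    method = "chi-squared goodness of fit",
    statistic = unname(ht$statistic),
    df = unname(ht$parameter),
    p_value = ht$p.value
  )
}

#' Chi-squared test of independence on a 2x2 table
#'
#' Pearson test with expected counts from the product of the margins.
#' The continuity correction is off by default (matching the
#' goodness-of-fit convention); set `correct = TRUE` for Yates'
#' correction.
#'
#' @param table A 2x2 matrix (or coercible) of non-negative counts with
#'   no zero row or column margin.
#' @param correct Apply Yates' continuity correction.
#' @return A one-row tibble: `method`, `statistic`, `df`, `p_value`.
#' @export
#' @examples
#' chisq_independence(matrix(c(10, 2, 4, 12), 2))
chisq_independence <- function(table, correct = FALSE) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2L, 2L))) {
    abort("`table` must be a 2x2 matrix of counts")
  }
  if (any(table < 0) || anyNA(table)) {
    abort("counts must be non-negative")
  }
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    abort("independence test is undefined with a zero margin")
  }
  ht <- stats::chisq.test(table, correct = correct)
  tibble::tibble(
    method = paste0(
      "chi-squared test of independence",
      if (correct) " (Yates)" else ""
    ),
    statistic = unname(ht$statistic),
    df = unname(ht$parameter),
    p_value = ht$p.value
  )
}

#' Bonferroni-corrected significance threshold
#'
#' @param base_alpha Family-wise significance level in (0, 1].
#' @param m Number of tests, a positive integer.
#' @return `base_alpha / m`.
#' @export
#' @examples
#' bonferroni_alpha(0.05, 3)
bonferroni_alpha <- function(base_alpha, m) {
  if (!(base_alpha > 0 && base_alpha <= 1)) {
    abort("`base_alpha` must lie in (0, 1]")
  }
  if (m < 1 || m != as.integer(m)) {
    abort("`m` must be a positive integer")
  }
  base_alpha / m
}

#' Hypothesis-testing suite on production counts
#'
#' Runs the planned count analyses of the two-condition design:
#'
#' 1. overall preference for the expert-sourced variant (both
#'    conditions pooled);
#' 2. preference for the expert's variant in the expert-to-novice
#'    condition (where expert and congruence biases align);
#' 3. preference for the peer's (congruent) variant in the peer-to-peer
#'    condition (where they oppose).
#'
#' These three planned tests share a Bonferroni-corrected threshold
#' `base_alpha / 3`. When participant-level records are supplied,
#' control analyses are added at the uncorrected `base_alpha`: a
#' goodness-of-fit test of the produced strategy (parity vs skipping)
#' and independence tests of the produced source against the learning
#' order and the strategy order.
#'
#' @param x A four-cell [count_table], or a participant tibble from
#'   [generate_participants()] / [read_participants()] (excluded
#'   participants are dropped before testing).
#' @param base_alpha Family-wise significance level.
#' @return A tibble with one row per test: `hypothesis`, `method`,
#'   `statistic`, `df`, `p_value`, `alpha`, `significant`.
#' @export
#' @examples
#' analyze_counts(count_table(27, 3, 14, 18))
analyze_counts <- function(x, base_alpha = 0.05) {
  records <- NULL
  if (inherits(x, "count_table")) {
    if (table_layout(x) != "four_cell") {
      abort("`analyze_counts()` expects a four-cell table")
    }
    counts <- x
  } else if (is.data.frame(x)) {
    records <- dplyr::filter(tibble::as_tibble(x), !.data$excluded)
    counts <- tabulate_productions(records)
  } else {
    abort("`x` must be a count_table or a participant data frame")
  }
  cell <- function(ctx, src) {
    counts$count[counts$context == ctx & counts$produced_source == src]
  }
  alpha3 <- bonferroni_alpha(base_alpha, 3)
  res <- dplyr::bind_rows(
    dplyr::mutate(
      chisq_goodness_of_fit(
        cell("expert_to_novice", "expert") + cell("peer_to_peer", "expert"),
        cell("expert_to_novice", "peer") + cell("peer_to_peer", "peer")
      ),
      hypothesis = "overall: expert vs peer variant", alpha = alpha3
    ),
    dplyr::mutate(
      chisq_goodness_of_fit(
        cell("expert_to_novice", "expert"), cell("expert_to_novice", "peer")
      ),
      hypothesis = "expert-to-novice: expert vs peer variant", alpha = alpha3
    ),
    dplyr::mutate(
      chisq_goodness_of_fit(
        cell("peer_to_peer", "peer"), cell("peer_to_peer", "expert")
      ),
      hypothesis = "peer-to-peer: congruent (peer) vs incongruent (expert)",
      alpha = alpha3
    )
  )
  if (!is.null(records)) {
    strategy_counts <- table(factor(records$produced_strategy, .contents))
    res <- dplyr::bind_rows(
      res,
      dplyr::mutate(
        chisq_goodness_of_fit(strategy_counts[["parity"]],
          strategy_counts[["skipping"]]),
        hypothesis = "control: parity vs skipping produced",
        alpha = base_alpha
      ),
      dplyr::mutate(
        chisq_independence(table(records$produced_source,
          records$learning_order)),
        hypothesis = "control: produced source x learning-context order",
        alpha = base_alpha
      ),
      dplyr::mutate(
        chisq_independence(table(records$produced_source,
          records$strategy_order)),
        hypothesis = "control: produced source x strategy order",
        alpha = base_alpha
      )
    )
  }
  dplyr::relocate(
    dplyr::mutate(res, significant = .data$p_value < .data$alpha),
    "hypothesis"
  )
}
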