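#' Exact probability that one simulated experiment matches the data
#'
#' Closed-form counterpart of the Monte-Carlo match check: the
#' probability that a single simulated experiment at `params` reproduces
#' `observed` cell-for-cell within `tolerance`.
#'
#' For a four-cell table with neutral primacy the per-context expert
#' count is binomial, so the match probability is the product over the
#' two contexts of the binomial mass on the tolerated window around the
#' observed expert count (clipped to `[0, n]`). For an eight-cell table
#' the four learning-order strata (see [design_strata()]) are
#' independent binomials and the window for each stratum is the
#' intersection of the constraints its two cells impose.
#'
#' A four-cell table with a non-zero primacy bias is refused with an
#' explicit error (the collapsed counts are then a binomial convolution
#' this oracle does not evaluate; use the eight-cell layout).
#'
#' @param params A [bias_params()] object.
#' @param observed A [count_table]; per-context totals must equal the
#'   design sizes.
#' @param design An [experiment_design()].
#' @param tolerance Non-negative integer cell-wise tolerance.
#' @return A probability in \eqn{[0, 1]}.
#' @seealso [exact_weighted_moments()], [run_grid()]
#' @export
#' @examples
#' match_probability(bias_params(0, 0), count_table(27, 3, 14, 18))
match_probability <- function(params, observed,
                              design = experiment_design(), tolerance = 0) {
  stopifnot(inherits(params, "bias_params"))
  match_probability_vec(
    params$expert_bias, params$congruent_bias, params$primacy_bias,
    observed, design, tolerance
  )
}

# vectorized over equal-length bias vectors
match_probability_vec <- function(expert_bias, congruent_bias, primacy_bias,
                                  observed, design, tolerance) {
  stopifnot(
    inherits(observed, "count_table"), inherits(design, "experiment_design"),
    tolerance >= 0, tolerance == as.integer(tolerance)
  )
  check_observed_design(observed, design)
  layout <- table_layout(observed)
  if (layout == "four_cell") {
    if (any(primacy_bias != 0)) {
      abort(paste0(
        "four-cell match probabilities are only defined for a neutral ",
        "primacy bias; use an eight-cell table for primacy estimation"
      ))
    }
    prob <- 1
    for (ctx in .contexts) {
      n <- design_n(design, ctx)
      obs_e <- observed$count[observed$context == ctx &
        observed$produced_source == "expert"]
      p <- prob_expert_produced(expert_bias, congruent_bias, 0, ctx)
      prob <- prob * binom_window_mass(obs_e - tolerance, obs_e + tolerance, n, p)
    }
    return(prob)
  }
  strata <- design_strata(design)
  prob <- 1
  for (i in seq_len(nrow(strata))) {
    ctx <- strata$context[i]
    e_order <- strata$expert_order[i]
    p_order <- setdiff(.orders, e_order)
    n_s <- strata$n[i]
    obs_e <- observed$count[observed$context == ctx &
      observed$produced_source == "expert" &
      observed$produced_order == e_order]
    obs_p <- observed$count[observed$context == ctx &
      observed$produced_source == "peer" &
      observed$produced_order == p_order]
    lo <- max(obs_e - tolerance, n_s - obs_p - tolerance)
    hi <- min(obs_e + tolerance, n_s - obs_p + tolerance)
    p <- prob_expert_produced(
      expert_bias, congruent_bias, primacy_bias, ctx, e_order
    )
    prob <- prob * binom_window_mass(lo, hi, n_s, p)
  }
  prob
}

# P(lo <= K <= hi) for K ~ Binomial(n, p), vectorized over p;
# the window is clipped to [0, n]
binom_window_mass <- function(lo, hi, n, p) {
  lo <- max(lo, 0)
  hi <- min(hi, n)
  if (lo > hi) {
    return(rep(0, length(p)))
  }
  mass <- 0
  for (k in lo:hi) {
    mass <- mass + dbinom(k, n, p)
  }
  mass
}

#' Exact match-weighted parameter moments over a grid
#'
#' The infinite-simulation limit of [run_grid()] followed by
#' [summarize_matches()]: each lattice cell is weighted by its exact
#' [match_probability()], and the weighted mean and standard deviation
#' of every varying parameter are computed in closed form. Used to
#' verify the Monte-Carlo estimates and as a fast deterministic
#' estimator in its own right.
#'
#' @inheritParams run_grid
#' @return An object of class `exact_moments`: per-parameter `stats`
#'   tibble (`parameter`, `mean`, `sd`), the lattice with a
#'   `match_probability` column (`weights`), and `expected_matches`,
#'   the expected number of matching runs per grid pass at the spec's
#'   `s`.
#' @export
#' @examples
#' em <- exact_weighted_moments(count_table(27, 3, 14, 18),
#'   spec = grid_spec(
#'     expert = grid_axis(step = 0.1),
#'     congruent = grid_axis(step = 0.1)
#'   )
#' )
#' tidy(em)
exact_weighted_moments <- function(observed, design = experiment_design(),
                                   spec = grid_spec()) {
  stopifnot(inherits(spec, "grid_spec"))
  lattice <- grid_lattice(spec)
  w <- match_probability_vec(
    lattice$expert_bias, lattice$congruent_bias, lattice$primacy_bias,
    observed, design, spec$tolerance
  )
  total <- sum(w)
  if (total == 0) {
    abort(paste0(
      "every lattice cell has zero match probability: ",
      "the exact weighted moments are undefined for this grid"
    ))
  }
  params <- c("expert_bias", "congruent_bias", "primacy_bias")
  params <- params[vapply(params, function(p) {
    length(unique(lattice[[p]])) > 1
  }, logical(1))]
  stats <- purrr::map_dfr(params, function(p) {
    v <- lattice[[p]]
    m <- sum(v * w) / total
    tibble::tibble(
      parameter = p, mean = m, sd = sqrt(sum(w * (v - m)^2) / total)
    )
  })
  structure(
    list(
      stats = stats,
      weights = dplyr::mutate(lattice, match_probability = w),
      expected_matches = total * spec$s,
      spec = spec
    ),
    class = "exact_moments"
  )
}

#' @export
print.exact_moments <- function(x, ...) {
  cat(sprintf(
    "<exact_moments> expected matches per grid pass: %.1f (s = %d)\n",
    x$expected_matches, x$spec$s
  ))
  print(x$stats)
  invisible(x)
}

#' @rdname tidiers
#' @method tidy exact_moments
#' @export
tidy.exact_moments <- function(x, ...) x$stats

#' @rdname tidiers
#' @method glance exact_moments
#' @export
glance.exact_moments <- function(x, ...) {
  tibble::tibble(
    n_cells = nrow(x$weights), s = x$spec$s,
    tolerance = x$spec$tolerance, expected_matches = x$expected_matches
  )
}
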