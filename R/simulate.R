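#' Simulate one participant's production choice
#'
#' Draws which of the two learned variants the participant produces,
#' Bernoulli with probability given by [choice_probability()]. Consumes
#' exactly one uniform random draw.
#'
#' @param params A [bias_params()] object.
#' @param context `"expert_to_novice"` or `"peer_to_peer"`.
#' @param assignment List of the participant's two [variant_attrs()]
#'   (opposite on every attribute); the first element is the candidate
#'   whose probability is evaluated.
#' @return One of the two `variant_attrs` in `assignment`.
#' @export
#' @examples
#' set.seed(1)
#' simulate_participant(
#'   bias_params(1, 0, 0), "expert_to_novice",
#'   list(
#'     variant_attrs("expert", "parity", "first"),
#'     variant_attrs("peer", "skipping", "last")
#'   )
#' )
simulate_participant <- function(params, context, assignment) {
  stopifnot(is.list(assignment), length(assignment) == 2L)
  p <- choice_probability(params, context, assignment[[1]], assignment[[2]])
  if (runif(1) < p) assignment[[1]] else assignment[[2]]
}

# Vectorized draws for one parameter combination: an s x n_cells integer
# matrix of simulated tables (columns in canonical count_table order).
# Per-context learning-order strata are simulated separately; when the
# primacy bias is 0 and the layout is four-cell the strata share one
# choice probability and a single binomial per context is drawn instead
# (same law, half the draws).
draw_cell_counts <- function(expert_bias, congruent_bias, primacy_bias,
                             design, layout, s) {
  strata <- design_strata(design)
  if (layout == "four_cell" && primacy_bias == 0) {
    counts <- lapply(.contexts, function(ctx) {
      n <- design_n(design, ctx)
      p <- prob_expert_produced(expert_bias, congruent_bias, 0, ctx)
      k <- rbinom(s, n, p)
      cbind(k, n - k)
    })
    out <- do.call(cbind, counts)
  } else {
    per_stratum <- purrr::map(seq_len(nrow(strata)), function(i) {
      p <- prob_expert_produced(
        expert_bias, congruent_bias, primacy_bias,
        context = strata$context[i], expert_order = strata$expert_order[i]
      )
      k <- rbinom(s, strata$n[i], p)
      cbind(expert = k, peer = strata$n[i] - k)
    })
    # stratum (context, expert_order = o) puts expert-produced counts in
    # cell (expert, o) and peer-produced counts in the opposite order cell
    out <- matrix(0L, nrow = s, ncol = if (layout == "eight_cell") 8L else 4L)
    for (i in seq_len(nrow(strata))) {
      ctx_off <- (match(strata$context[i], .contexts) - 1L) *
        (if (layout == "eight_cell") 4L else 2L)
      k <- per_stratum[[i]]
      if (layout == "eight_cell") {
        e_slot <- ctx_off + match(strata$expert_order[i], .orders)
        p_slot <- ctx_off + 2L + match(
          setdiff(.orders, strata$expert_order[i]), .orders
        )
        out[, e_slot] <- out[, e_slot] + k[, "expert"]
        out[, p_slot] <- out[, p_slot] + k[, "peer"]
      } else {
        out[, ctx_off + 1L] <- out[, ctx_off + 1L] + k[, "expert"]
        out[, ctx_off + 2L] <- out[, ctx_off + 2L] + k[, "peer"]
      }
    }
  }
  storage.mode(out) <- "integer"
  colnames(out) <- cell_names(layout)
  out
}

cell_names <- function(layout) {
  ctx <- c("e2n", "p2p")
  if (layout == "eight_cell") {
    paste(rep(ctx, each = 4),
      rep(rep(.sources, each = 2), 2), rep(.orders, 4),
      sep = "_"
    )
  } else {
    paste(rep(ctx, each = 2), rep(.sources, 2), sep = "_")
  }
}

counts_row_to_table <- function(row, layout) {
  if (layout == "eight_cell") count_table_8(row) else {
    count_table(row[1], row[2], row[3], row[4])
  }
}

#' Simulate one run of the experiment
#'
#' Simulates every participant's production choice and tallies the
#' counts. With `method = "participant"` each participant is an explicit
#' Bernoulli draw; with `method = "binomial"` the per-stratum counts are
#' drawn directly from their binomial law (same distribution, the
#' vectorized shortcut used by [simulate_counts_batch()]).
#'
#' @param params A [bias_params()] object.
#' @param design An [experiment_design()].
#' @param layout `"four_cell"` or `"eight_cell"`.
#' @param seed Optional integer; if given, the RNG is seeded so repeated
#'   calls return identical tables.
#' @param method `"participant"` or `"binomial"`.
#' @return A [count_table].
#' @export
#' @examples
#' simulate_experiment(bias_params(0.4, 0.5), experiment_design(), seed = 1)
simulate_experiment <- function(params, design = experiment_design(),
                                layout = c("four_cell", "eight_cell"),
                                seed = NULL,
                                method = c("participant", "binomial")) {
  stopifnot(inherits(params, "bias_params"), inherits(design, "experiment_design"))
  layout <- match.arg(layout)
  method <- match.arg(method)
  if (!is.null(seed)) set.seed(seed)
  if (method == "binomial") {
    row <- draw_cell_counts(
      params$expert_bias, params$congruent_bias, params$primacy_bias,
      design, layout, s = 1L
    )[1, ]
    return(counts_row_to_table(row, layout))
  }
  strata <- design_strata(design)
  cells <- setNames(integer(if (layout == "eight_cell") 8L else 4L),
    cell_names(layout))
  for (i in seq_len(nrow(strata))) {
    p <- prob_expert_produced(
      params$expert_bias, params$congruent_bias, params$primacy_bias,
      context = strata$context[i], expert_order = strata$expert_order[i]
    )
    k <- sum(runif(strata$n[i]) < p)
    ctx <- if (strata$context[i] == "expert_to_novice") "e2n" else "p2p"
    if (layout == "eight_cell") {
      e_cell <- paste(ctx, "expert", strata$expert_order[i], sep = "_")
      p_cell <- paste(ctx, "peer", setdiff(.orders, strata$expert_order[i]),
        sep = "_")
    } else {
      e_cell <- paste(ctx, "expert", sep = "_")
      p_cell <- paste(ctx, "peer", sep = "_")
    }
    cells[e_cell] <- cells[e_cell] + k
    cells[p_cell] <- cells[p_cell] + (strata$n[i] - k)
  }
  counts_row_to_table(cells, layout)
}

# Deterministic per-cell RNG substreams: the master seed fixes a
# permutation of candidate seeds, so cell i's stream is independent of
# how many or in what order other cells are simulated.
derive_cell_seeds <- function(seed, n_cells) {
  stopifnot(n_cells >= 1)
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max - 1L, n_cells)
}

#' Batch-simulate count tables over a parameter lattice
#'
#' Draws `s` simulated experiments for every row of a parameter lattice,
#' using per-stratum binomial sampling (distributionally equivalent to
#' per-participant simulation). Each lattice cell gets its own RNG
#' substream derived from `seed`, so results are reproducible cell by
#' cell.
#'
#' @param params A [bias_params()] object or a data frame with columns
#'   `expert_bias`, `congruent_bias` and optionally `primacy_bias` (one
#'   row per lattice cell).
#' @param design An [experiment_design()].
#' @param s Number of simulated experiments per cell.
#' @param layout `"four_cell"` or `"eight_cell"`.
#' @param seed Integer master seed.
#' @return A tibble with columns `cell` (lattice row index), `rep`
#'   (1..s), the parameter values, and one count column per table cell
#'   in canonical order (`e2n_expert`, `e2n_peer`, ... or the eight-cell
#'   equivalents).
#' @export
#' @examples
#' simulate_counts_batch(bias_params(0.4, 0.5), s = 3, seed = 1)
simulate_counts_batch <- function(params, design = experiment_design(),
                                  s = 5000, layout = c("four_cell", "eight_cell"),
                                  seed = 1) {
  layout <- match.arg(layout)
  stopifnot(s >= 1)
  lattice <- as_param_lattice(params)
  seeds <- derive_cell_seeds(seed, nrow(lattice))
  purrr::map_dfr(seq_len(nrow(lattice)), function(i) {
    set.seed(seeds[i])
    counts <- draw_cell_counts(
      lattice$expert_bias[i], lattice$congruent_bias[i],
      lattice$primacy_bias[i], design, layout, s
    )
    dplyr::bind_cols(
      tibble::tibble(cell = i, rep = seq_len(s)),
      lattice[rep(i, s), ],
      tibble::as_tibble(counts)
    )
  })
}

as_param_lattice <- function(params) {
  if (inherits(params, "bias_params")) {
    return(tibble::tibble(
      expert_bias = params$expert_bias,
      congruent_bias = params$congruent_bias,
      primacy_bias = params$primacy_bias
    ))
  }
  params <- tibble::as_tibble(params)
  if (!all(c("expert_bias", "congruent_bias") %in% names(params))) {
    abort("a parameter lattice needs columns expert_bias and congruent_bias")
  }
  if (!"primacy_bias" %in% names(params)) params$primacy_bias <- 0
  bias_weight(params$expert_bias) # range validation
  bias_weight(params$congruent_bias)
  bias_weight(params$primacy_bias)
  params[c("expert_bias", "congruent_bias", "primacy_bias")]
}
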