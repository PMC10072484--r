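#' Experiment design: condition sizes and counterbalancing
#'
#' Describes the two-condition between-groups design. Defaults are the
#' post-exclusion cohort sizes (30 expert-to-novice, 32 peer-to-peer);
#' the pre-exclusion design is `experiment_design(32, 32)`.
#'
#' Counterbalancing of learning order is encoded as an even split per
#' condition: half the participants learned the expert-sourced variant
#' first and half learned it last. With an odd condition size the extra
#' participant is assigned to the "expert variant first" stratum (a
#' fixed, documented tie-break so simulations stay deterministic).
#'
#' @param n_e2n,n_p2p Non-negative integer condition sizes.
#' @return An object of class `experiment_design`.
#' @export
#' @examples
#' experiment_design()
#' design_strata(experiment_design(31, 32))
experiment_design <- function(n_e2n = 30, n_p2p = 32) {
  if (n_e2n < 0 || n_p2p < 0 ||
    n_e2n != as.integer(n_e2n) || n_p2p != as.integer(n_p2p)) {
    abort("condition sizes must be non-negative integers")
  }
  structure(
    list(n_e2n = as.integer(n_e2n), n_p2p = as.integer(n_p2p)),
    class = "experiment_design"
  )
}

#' @export
print.experiment_design <- function(x, ...) {
  cat(sprintf(
    "<experiment_design> expert-to-novice n = %d, peer-to-peer n = %d\n",
    x$n_e2n, x$n_p2p
  ))
  invisible(x)
}

design_n <- function(design, context) {
  if (context == "expert_to_novice") design$n_e2n else design$n_p2p
}

#' @rdname experiment_design
#' @param design An `experiment_design` object.
#' @return `design_strata()` returns a tibble with one row per
#'   (context, learning-order stratum): `context`, `expert_order` (the
#'   learning order of the expert-sourced variant in that stratum) and
#'   the stratum size `n`.
#' @export
design_strata <- function(design) {
  stopifnot(inherits(design, "experiment_design"))
  purrr::map_dfr(.contexts, function(ctx) {
    n <- design_n(design, ctx)
    tibble::tibble(
      context = ctx,
      expert_order = .orders,
      n = c(ceiling(n / 2), floor(n / 2))
    )
  })
}

#' Production count tables
#'
#' A count table records how many participants produced the
#' expert-sourced and peer-sourced variant in each condition. The
#' four-cell layout indexes cells by (context, produced source); the
#' eight-cell layout additionally splits by the produced variant's
#' learning order. Tables are tidy tibbles in a canonical row order so
#' that two tables with the same layout are cell-wise comparable.
#'
#' `count_table()` builds the four-cell table from its four counts;
#' `count_table_8()` builds the eight-cell table (order within each
#' context-source pair is first, last); `as_count_table()` validates and
#' canonicalizes a data frame with columns `context`, `produced_source`,
#' optionally `produced_order`, and `count`.
#'
#' @param e2n_expert,e2n_peer,p2p_expert,p2p_peer Non-negative integer
#'   counts (four-cell).
#' @return A tibble of class `count_table` in canonical cell order.
#' @export
#' @examples
#' count_table(27, 3, 14, 18)
count_table <- function(e2n_expert, e2n_peer, p2p_expert, p2p_peer) {
  as_count_table(tibble::tibble(
    context = rep(.contexts, each = 2),
    produced_source = rep(.sources, 2),
    count = c(e2n_expert, e2n_peer, p2p_expert, p2p_peer)
  ))
}

#' @rdname count_table
#' @param counts For `count_table_8()`, a length-8 vector of counts in
#'   the canonical order: for each context (expert-to-novice then
#'   peer-to-peer), cells (expert, first), (expert, last),
#'   (peer, first), (peer, last).
#' @export
count_table_8 <- function(counts) {
  stopifnot(length(counts) == 8L)
  as_count_table(tibble::tibble(
    context = rep(.contexts, each = 4),
    produced_source = rep(rep(.sources, each = 2), 2),
    produced_order = rep(.orders, 4),
    count = as.vector(counts)
  ))
}

#' @rdname count_table
#' @param x A data frame with the count-table columns.
#' @export
as_count_table <- function(x) {
  x <- tibble::as_tibble(x)
  needed <- c("context", "produced_source", "count")
  if (!all(needed %in% names(x))) {
    abort("a count table needs columns context, produced_source, count")
  }
  layout <- if ("produced_order" %in% names(x)) "eight_cell" else "four_cell"
  match_context(x$context)
  if (!all(x$produced_source %in% .sources)) {
    abort("`produced_source` must be 'expert' or 'peer'")
  }
  if (layout == "eight_cell" && !all(x$produced_order %in% .orders)) {
    abort("`produced_order` must be 'first' or 'last'")
  }
  if (anyNA(x$count) || any(x$count < 0) || any(x$count != as.integer(x$count))) {
    abort("`count` must hold non-negative integers")
  }
  keys <- c("context", "produced_source",
    if (layout == "eight_cell") "produced_order")
  x <- x[c(keys, "count")]
  x$count <- as.integer(x$count)
  n_cells <- if (layout == "eight_cell") 8L else 4L
  if (nrow(x) != n_cells || anyDuplicated(x[keys])) {
    abort(sprintf("a %s count table must have exactly %d distinct cells",
      gsub("_", "-", layout), n_cells))
  }
  ord <- order(
    match(x$context, .contexts),
    match(x$produced_source, .sources),
    if (layout == "eight_cell") match(x$produced_order, .orders) else rep(1L, n_cells)
  )
  out <- x[ord, ]
  class(out) <- c("count_table", class(out))
  out
}

table_layout <- function(tbl) {
  if ("produced_order" %in% names(tbl)) "eight_cell" else "four_cell"
}

# per-context totals, in context order
context_totals <- function(tbl) {
  vapply(
    .contexts,
    function(ctx) sum(tbl$count[tbl$context == ctx]),
    integer(1)
  )
}

check_observed_design <- function(observed, design) {
  totals <- context_totals(observed)
  expected <- c(design$n_e2n, design$n_p2p)
  if (!all(totals == expected)) {
    abort(sprintf(
      "observed per-context totals (%d, %d) do not match the design (%d, %d)",
      totals[1], totals[2], expected[1], expected[2]
    ))
  }
  invisible(observed)
}

#' Cell-wise match between two count tables
#'
#' Two tables match when every cell differs by at most `tolerance`.
#' Exact matching (`tolerance = 0`) is the acceptance rule of the
#' two-parameter estimation; the three-parameter, eight-cell estimation
#' uses `tolerance = 1` because exact eight-way coincidences are
#' vanishingly rare.
#'
#' @param simulated,observed [count_table]s with the same layout.
#' @param tolerance Non-negative integer.
#' @return `TRUE` or `FALSE`.
#' @export
#' @examples
#' is_match(count_table(26, 4, 14, 18), count_table(27, 3, 14, 18), tolerance = 1)
is_match <- function(simulated, observed, tolerance = 0) {
  stopifnot(
    inherits(simulated, "count_table"), inherits(observed, "count_table"),
    tolerance >= 0, tolerance == as.integer(tolerance)
  )
  if (table_layout(simulated) != table_layout(observed)) {
    abort("count tables have different layouts")
  }
  all(abs(simulated$count - observed$count) <= tolerance)
}
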