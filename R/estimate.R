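#' Grid specification for rejection estimation
#'
#' Defines the parameter lattice searched by [run_grid()] and
#' [exact_weighted_moments()], the number of simulated experiments per
#' lattice cell, and the cell-wise match tolerance.
#'
#' The default is the two-parameter search: expert and congruence axes
#' from -1 to 1 in steps of 0.01 (201 points each, both endpoints
#' included), primacy fixed at 0, 5000 simulations per cell, exact
#' matching. [grid_spec_primacy()] is the three-parameter search:
#' expert and congruence in steps of 0.1, primacy in steps of 0.05,
#' tolerance 1 (for eight-cell tables).
#'
#' @param expert,congruent Axis descriptors from [grid_axis()].
#' @param primacy Axis descriptor, or `NULL` to fix the primacy bias
#'   at 0.
#' @param s Simulated experiments per lattice cell.
#' @param tolerance Non-negative integer cell-wise match tolerance.
#' @return An object of class `grid_spec`.
#' @export
#' @examples
#' grid_spec(s = 100)
#' grid_spec_primacy()
grid_spec <- function(expert = grid_axis(), congruent = grid_axis(),
                      primacy = NULL, s = 5000, tolerance = 0) {
  stopifnot(s >= 1, s == as.integer(s),
    tolerance >= 0, tolerance == as.integer(tolerance))
  structure(
    list(
      expert = expert, congruent = congruent, primacy = primacy,
      s = as.integer(s), tolerance = as.integer(tolerance)
    ),
    class = "grid_spec"
  )
}

#' @rdname grid_spec
#' @export
grid_spec_primacy <- function(expert = grid_axis(step = 0.1),
                              congruent = grid_axis(step = 0.1),
                              primacy = grid_axis(step = 0.05),
                              s = 5000, tolerance = 1) {
  grid_spec(expert, congruent, primacy, s = s, tolerance = tolerance)
}

#' @rdname grid_spec
#' @param min,max,step Axis bounds and increment; `min <= max`,
#'   `step > 0`. The axis is `min, min + step, ...` up to `max`.
#' @export
grid_axis <- function(min = -1, max = 1, step = 0.01) {
  if (!(min <= max) || !(step > 0)) {
    abort("a grid axis needs min <= max and step > 0")
  }
  c(min = min, max = max, step = step)
}

axis_values <- function(axis) {
  if (is.null(axis)) return(0)
  k <- floor((axis[["max"]] - axis[["min"]]) / axis[["step"]] + 1e-9)
  axis[["min"]] + axis[["step"]] * (0:k)
}

#' @export
print.grid_spec <- function(x, ...) {
  fmt <- function(a, nm) {
    if (is.null(a)) sprintf("%s fixed at 0", nm)
    else sprintf("%s %g..%g step %g", nm, a[["min"]], a[["max"]], a[["step"]])
  }
  cat("<grid_spec>", fmt(x$expert, "expert"), "|",
    fmt(x$congruent, "congruent"), "|", fmt(x$primacy, "primacy"), "\n")
  cat(sprintf("  s = %d simulations/cell, tolerance = %d\n", x$s, x$tolerance))
  invisible(x)
}

#' @rdname grid_spec
#' @param spec A `grid_spec`.
#' @return `grid_lattice()` returns a tibble with one row per lattice
#'   cell and columns `expert_bias`, `congruent_bias`, `primacy_bias`.
#' @export
grid_lattice <- function(spec) {
  stopifnot(inherits(spec, "grid_spec"))
  g <- expand.grid(
    primacy_bias = axis_values(spec$primacy),
    congruent_bias = axis_values(spec$congruent),
    expert_bias = axis_values(spec$expert),
    KEEP.OUT.ATTRS = FALSE
  )
  tibble::as_tibble(g[c("expert_bias", "congruent_bias", "primacy_bias")])
}

#' Grid-search rejection estimation of bias magnitudes
#'
#' For every cell of the parameter lattice, simulates `spec$s`
#' experiments under the choice model and counts how many reproduce the
#' observed count table cell-for-cell within the match tolerance. The
#' resulting match surface is the rejection-sampling approximation to
#' the likelihood over the lattice, and [summarize_matches()] turns it
#' into parameter estimates.
#'
#' Each lattice cell uses an RNG substream derived deterministically
#' from `seed`, so the grid is reproducible and independent of
#' evaluation order.
#'
#' @param observed A [count_table] of the experimental counts; its
#'   layout (four- or eight-cell) decides the simulated layout.
#' @param design An [experiment_design()]; per-context totals of
#'   `observed` must equal the design sizes.
#' @param spec A [grid_spec()].
#' @param seed Integer master seed.
#' @return A tibble of class `match_grid`: the lattice columns plus
#'   `matches` (in `[0, s]`), with the spec, observed table, design and
#'   seed attached as attributes.
#' @seealso [summarize_matches()], [exact_weighted_moments()],
#'   [autoplot.match_grid()]
#' @export
#' @examples
#' obs <- count_table(27, 3, 14, 18)
#' g <- run_grid(obs, spec = grid_spec(
#'   expert = grid_axis(step = 0.5),
#'   congruent = grid_axis(step = 0.5), s = 200
#' ), seed = 1)
#' summarize_matches(g)
run_grid <- function(observed, design = experiment_design(),
                     spec = grid_spec(), seed = 1) {
  stopifnot(inherits(observed, "count_table"), inherits(spec, "grid_spec"))
  check_observed_design(observed, design)
  layout <- table_layout(observed)
  lattice <- grid_lattice(spec)
  obs <- observed$count
  tol <- spec$tolerance
  s <- spec$s
  seeds <- derive_cell_seeds(seed, nrow(lattice))
  matches <- integer(nrow(lattice))
  for (i in seq_len(nrow(lattice))) {
    set.seed(seeds[i])
    counts <- draw_cell_counts(
      lattice$expert_bias[i], lattice$congruent_bias[i],
      lattice$primacy_bias[i], design, layout, s
    )
    ok <- abs(counts[, 1] - obs[1]) <= tol
    for (j in 2:length(obs)) {
      ok <- ok & abs(counts[, j] - obs[j]) <= tol
    }
    matches[i] <- sum(ok)
  }
  out <- dplyr::mutate(lattice, matches = matches)
  attr(out, "spec") <- spec
  attr(out, "observed") <- observed
  attr(out, "design") <- design
  attr(out, "seed") <- seed
  attr(out, "layout") <- layout
  class(out) <- c("match_grid", class(out))
  out
}

# parameters whose axis actually varies over the lattice
varying_parameters <- function(grid) {
  params <- c("expert_bias", "congruent_bias", "primacy_bias")
  params[vapply(params, function(p) length(unique(grid[[p]])) > 1, logical(1))]
}

# the match multiset for one parameter: each matching run contributes
# its cell's parameter value once
match_values <- function(grid, parameter) {
  rep(grid[[parameter]], grid$matches)
}

#' Summarize a match grid into parameter estimates
#'
#' The match distribution of a parameter is the multiset holding, for
#' every matching simulation run, that run's parameter value; its size
#' is the grid's total match count. This function reports, per varying
#' parameter, the mean and standard deviation of that multiset, a
#' one-sample t test of the mean against 0 (no bias), and, for each
#' pair of varying parameters, a two-sample t test between their
#' multisets (Welch by default).
#'
#' With fewer than two total matches the summary is undefined: the
#' returned object is flagged and all statistics are `NA` (never a
#' silent zero).
#'
#' @param grid A `match_grid` from [run_grid()].
#' @param pooled Use the pooled-variance two-sample t instead of Welch.
#' @return An object of class `match_summary` with [tidy()] and
#'   [glance()] methods.
#' @export
summarize_matches <- function(grid, pooled = FALSE) {
  stopifnot(inherits(grid, "match_grid"))
  spec <- attr(grid, "spec")
  params <- varying_parameters(grid)
  total <- sum(grid$matches)
  if (total < 2) {
    warn("fewer than 2 matching runs: match summary is undefined")
    stats <- tibble::tibble(
      parameter = params, mean = NA_real_, sd = NA_real_,
      n = total, t = NA_real_, df = NA_real_, p_value = NA_real_
    )
    comparisons <- tibble::tibble(
      parameter_1 = character(), parameter_2 = character(),
      t = numeric(), df = numeric(), p_value = numeric()
    )
    return(new_match_summary(stats, comparisons, total, spec, undefined = TRUE))
  }
  multisets <- lapply(setNames(params, params), match_values, grid = grid)
  stats <- purrr::map_dfr(params, function(p) {
    v <- multisets[[p]]
    if (stats::sd(v) == 0) {
      # all matches at one value: t vs 0 is degenerate
      return(tibble::tibble(
        parameter = p, mean = mean(v), sd = 0, n = length(v),
        t = NA_real_, df = length(v) - 1, p_value = NA_real_
      ))
    }
    tt <- t.test(v, mu = 0)
    tibble::tibble(
      parameter = p, mean = mean(v), sd = stats::sd(v), n = length(v),
      t = unname(tt$statistic), df = unname(tt$parameter),
      p_value = tt$p.value
    )
  })
  pairs <- utils::combn(params, 2, simplify = FALSE)
  comparisons <- purrr::map_dfr(pairs, function(pr) {
    v1 <- multisets[[pr[1]]]
    v2 <- multisets[[pr[2]]]
    if (stats::sd(v1) == 0 && stats::sd(v2) == 0) {
      return(tibble::tibble(
        parameter_1 = pr[1], parameter_2 = pr[2],
        t = NA_real_, df = NA_real_, p_value = NA_real_
      ))
    }
    tt <- t.test(v1, v2, var.equal = pooled)
    tibble::tibble(
      parameter_1 = pr[1], parameter_2 = pr[2],
      t = unname(tt$statistic), df = unname(tt$parameter),
      p_value = tt$p.value
    )
  })
  new_match_summary(stats, comparisons, total, spec, undefined = FALSE)
}

new_match_summary <- function(stats, comparisons, total, spec, undefined) {
  structure(
    list(
      stats = stats, comparisons = comparisons,
      total_matches = total, s = spec$s, tolerance = spec$tolerance,
      undefined = undefined
    ),
    class = "match_summary"
  )
}

#' @export
print.match_summary <- function(x, ...) {
  cat(sprintf(
    "<match_summary> %d matching runs (s = %d per cell, tolerance = %d)\n",
    x$total_matches, x$s, x$tolerance
  ))
  if (x$undefined) {
    cat("  undefined: fewer than 2 matches\n")
    return(invisible(x))
  }
  print(x$stats)
  if (nrow(x$comparisons)) {
    cat("pairwise comparisons:\n")
    print(x$comparisons)
  }
  invisible(x)
}

#' Broom-style accessors for estimation results
#'
#' `tidy()` on a `match_summary` returns the per-parameter statistics
#' (mean, sd, n, one-sample t vs 0); `glance()` returns a one-row
#' overview. `tidy()` on a `match_grid` returns the lattice with match
#' counts.
#'
#' @param x A `match_summary`, `match_grid` or `exact_moments` object.
#' @param ... Unused.
#' @return A tibble.
#' @name tidiers
#' @importFrom generics tidy
#' @export
generics::tidy

#' @rdname tidiers
#' @importFrom generics glance
#' @export
generics::glance

#' @rdname tidiers
#' @method tidy match_summary
#' @export
tidy.match_summary <- function(x, ...) x$stats

#' @rdname tidiers
#' @method glance match_summary
#' @export
glance.match_summary <- function(x, ...) {
  tibble::tibble(
    total_matches = x$total_matches, s = x$s,
    tolerance = x$tolerance, undefined = x$undefined
  )
}

#' @rdname tidiers
#' @method tidy match_grid
#' @export
tidy.match_grid <- function(x, ...) {
  out <- x
  attributes(out)[c("spec", "observed", "design", "seed", "layout")] <- NULL
  class(out) <- setdiff(class(out), "match_grid")
  tibble::as_tibble(out)
}

#' @rdname tidiers
#' @method glance match_grid
#' @export
glance.match_grid <- function(x, ...) {
  spec <- attr(x, "spec")
  tibble::tibble(
    n_cells = nrow(x), s = spec$s, tolerance = spec$tolerance,
    total_matches = sum(x$matches), seed = attr(x, "seed"),
    layout = attr(x, "layout")
  )
}
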