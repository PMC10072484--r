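.context_keys <- c(expert_to_novice = "e2n", peer_to_peer = "p2p")

#' Read and write count tables
#'
#' Count tables are exchanged as long-format CSV (columns `context`,
#' `produced_source`, optionally `produced_order`, `count`; enumeration
#' values as lowercase tokens) or as JSON keyed by condition and source,
#' `{"e2n": {"expert": 27, "peer": 3}, "p2p": {...}}`, with a per-order
#' nesting (`{"expert": {"first": ..., "last": ...}, ...}`) for
#' eight-cell tables. The keyed JSON schema avoids any ambiguity about
#' cell order.
#'
#' @param x A [count_table].
#' @param path File path.
#' @return Readers return a [count_table]; writers return `x`
#'   invisibly.
#' @name counts-io
#' @export
write_count_table <- function(x, path) {
  stopifnot(inherits(x, "count_table"))
  readr::write_csv(tibble::as_tibble(x), path)
  invisible(x)
}

#' @rdname counts-io
#' @export
read_count_table <- function(path) {
  as_count_table(readr::read_csv(path, show_col_types = FALSE))
}

#' @rdname counts-io
#' @export
write_counts_json <- function(x, path) {
  stopifnot(inherits(x, "count_table"))
  layout <- table_layout(x)
  out <- lapply(setNames(.contexts, .context_keys[.contexts]), function(ctx) {
    lapply(setNames(.sources, .sources), function(src) {
      rows <- x$context == ctx & x$produced_source == src
      if (layout == "four_cell") {
        x$count[rows]
      } else {
        as.list(setNames(x$count[rows], x$produced_order[rows]))
      }
    })
  })
  jsonlite::write_json(out, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(x)
}

#' @rdname counts-io
#' @export
read_counts_json <- function(path) {
  raw <- jsonlite::read_json(path)
  if (!all(c("e2n", "p2p") %in% names(raw))) {
    abort("counts JSON must have top-level keys 'e2n' and 'p2p'")
  }
  eight <- is.list(raw$e2n$expert)
  rows <- purrr::map_dfr(.contexts, function(ctx) {
    node <- raw[[.context_keys[[ctx]]]]
    if (!all(.sources %in% names(node))) {
      abort(sprintf("counts JSON '%s' needs keys 'expert' and 'peer'",
        .context_keys[[ctx]]))
    }
    purrr::map_dfr(.sources, function(src) {
      if (eight) {
        tibble::tibble(
          context = ctx, produced_source = src, produced_order = .orders,
          count = c(node[[src]]$first, node[[src]]$last)
        )
      } else {
        tibble::tibble(context = ctx, produced_source = src,
          count = node[[src]])
      }
    })
  })
  as_count_table(rows)
}

#' Read and write participant cohorts
#'
#' Participant records use the column set of [generate_participants()],
#' as comma-separated UTF-8 with a header row and lowercase tokens for
#' all enumerations.
#'
#' @param x A participant tibble.
#' @param path File path.
#' @return Readers return a tibble; writers return `x` invisibly.
#' @name participants-io
#' @export
write_participants <- function(x, path) {
  readr::write_csv(tibble::as_tibble(x), path)
  invisible(x)
}

#' @rdname participants-io
#' @export
read_participants <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE,
    col_types = readr::cols(excluded = readr::col_logical()))
  needed <- c("participant_id", "condition", "learning_order",
    "strategy_order", "expert_strategy", "produced_source",
    "produced_strategy", "excluded")
  missing <- setdiff(needed, names(out))
  if (length(missing)) {
    abort(paste0("participant CSV is missing columns: ",
      paste(missing, collapse = ", ")))
  }
  out
}

#' Export and re-import a match grid
#'
#' Writes the lattice in long format, one row per cell with the
#' parameter values, the match count, and the grid's `s` and
#' `tolerance` (so the file is self-describing); re-importing
#' reproduces the cell data exactly.
#'
#' @param grid A `match_grid` from [run_grid()].
#' @param path CSV path.
#' @param plot_path Optional path for a PNG heatmap of the match
#'   surface (lighter = more matches).
#' @return `export_grid()` returns `grid` invisibly; `read_grid()`
#'   returns a `match_grid`.
#' @name grid-io
#' @export
export_grid <- function(grid, path, plot_path = NULL) {
  stopifnot(inherits(grid, "match_grid"))
  spec <- attr(grid, "spec")
  out <- dplyr::mutate(tidy(grid), s = spec$s, tolerance = spec$tolerance)
  readr::write_csv(out, path)
  if (!is.null(plot_path)) {
    p <- autoplot(grid)
    ggplot2::ggsave(plot_path, p, width = 7, height = 6, dpi = 150)
  }
  invisible(grid)
}

#' @rdname grid-io
#' @export
read_grid <- function(path) {
  raw <- readr::read_csv(path, show_col_types = FALSE)
  needed <- c("expert_bias", "congruent_bias", "primacy_bias", "matches",
    "s", "tolerance")
  if (!all(needed %in% names(raw))) {
    abort(paste0("grid CSV is missing columns: ",
      paste(setdiff(needed, names(raw)), collapse = ", ")))
  }
  axis_from <- function(v) {
    u <- sort(unique(v))
    if (length(u) == 1) return(NULL)
    grid_axis(min(u), max(u), min(diff(u)))
  }
  spec <- grid_spec(
    expert = axis_from(raw$expert_bias) %||% grid_axis(),
    congruent = axis_from(raw$congruent_bias) %||% grid_axis(),
    primacy = axis_from(raw$primacy_bias),
    s = raw$s[1], tolerance = raw$tolerance[1]
  )
  out <- raw[c("expert_bias", "congruent_bias", "primacy_bias", "matches")]
  out$matches <- as.integer(out$matches)
  attr(out, "spec") <- spec
  class(out) <- c("match_grid", class(out))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a match summary as JSON
#'
#' @param summary A `match_summary` from [summarize_matches()].
#' @param path File path.
#' @return `summary`, invisibly.
#' @export
write_match_summary_json <- function(summary, path) {
  stopifnot(inherits(summary, "match_summary"))
  out <- list(
    total_matches = summary$total_matches,
    s = summary$s,
    tolerance = summary$tolerance,
    undefined = summary$undefined,
    parameters = summary$stats,
    comparisons = summary$comparisons
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  invisible(summary)
}

#' Read a run configuration file
#'
#' Configurations are flat key-value documents in YAML (`.yaml`/`.yml`)
#' or JSON (`.json`); keys mirror the command-line flags and are
#' overridden by explicit flags.
#'
#' @param path File path.
#' @return A named list.
#' @export
read_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  cfg <- switch(ext,
    yaml = ,
    yml = yaml::read_yaml(path),
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    abort("config files must be .yaml, .yml or .json")
  )
  if (!is.list(cfg)) abort("config file must hold a key-value mapping")
  cfg
}
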