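#' Attributes of a learned variant
#'
#' A participant holds two variants that are opposite on every
#' attribute: who demonstrated it (`source`), which strategy it is
#' (`content`), and when it was learned (`order`).
#'
#' @param source `"expert"` or `"peer"`.
#' @param content `"parity"` or `"skipping"`.
#' @param order `"first"` or `"last"`.
#' @return An object of class `variant_attrs`.
#' @export
#' @examples
#' v <- variant_attrs("expert", "parity", "first")
#' opposite_variant(v)
variant_attrs <- function(source, content, order) {
  source <- match.arg(source, .sources)
  content <- match.arg(content, .contents)
  order <- match.arg(order, .orders)
  structure(
    list(source = source, content = content, order = order),
    class = "variant_attrs"
  )
}

#' @rdname variant_attrs
#' @param variant A `variant_attrs` object.
#' @export
opposite_variant <- function(variant) {
  stopifnot(inherits(variant, "variant_attrs"))
  variant_attrs(
    source = setdiff(.sources, variant$source),
    content = setdiff(.contents, variant$content),
    order = setdiff(.orders, variant$order)
  )
}

#' @export
print.variant_attrs <- function(x, ...) {
  cat(sprintf(
    "<variant> source = %s, content = %s, order = %s\n",
    x$source, x$content, x$order
  ))
  invisible(x)
}

#' Unnormalized weight of a variant in a production context
#'
#' The weight of a variant is the product of three factors, one per
#' biased attribute. Writing \eqn{p = (1 + b)/2} for the weight of bias
#' \eqn{b} (see [bias_weight()]): the source factor is \eqn{p_{expert}}
#' for an expert-sourced variant and \eqn{1 - p_{expert}} otherwise; the
#' congruence factor is \eqn{p_{congruent}} when the variant's source is
#' the context's congruent source ([congruent_source()]) and
#' \eqn{1 - p_{congruent}} otherwise; the order factor is \eqn{p_{last}}
#' for the last-learned variant and \eqn{1 - p_{last}} for the first.
#'
#' @param params A [bias_params()] object.
#' @param context `"expert_to_novice"` or `"peer_to_peer"`.
#' @param variant A [variant_attrs()] object.
#' @return A non-negative number.
#' @export
#' @examples
#' variant_weight(
#'   bias_params(0.5, 0, 0), "expert_to_novice",
#'   variant_attrs("expert", "parity", "first")
#' )
variant_weight <- function(params, context, variant) {
  stopifnot(inherits(params, "bias_params"), inherits(variant, "variant_attrs"))
  context <- match_context(context)
  p_expert <- bias_weight(params$expert_bias)
  p_congruent <- bias_weight(params$congruent_bias)
  p_last <- bias_weight(params$primacy_bias)
  f_source <- if (variant$source == "expert") p_expert else 1 - p_expert
  f_congruence <- if (variant$source == congruent_source(context)) {
    p_congruent
  } else {
    1 - p_congruent
  }
  f_order <- if (variant$order == "last") p_last else 1 - p_last
  f_source * f_congruence * f_order
}

#' Probability that a given variant is produced
#'
#' Luce choice rule over the participant's two variants: the produced
#' variant's probability is its [variant_weight()] divided by the sum of
#' the two variants' weights. The two complementary calls sum to 1
#' exactly. At the degenerate boundary where both weights are exactly
#' zero (possible only at bias magnitudes of 1) the probability is
#' defined as 0.5.
#'
#' @param params A [bias_params()] object.
#' @param context `"expert_to_novice"` or `"peer_to_peer"`.
#' @param produced,alternative The participant's two [variant_attrs()];
#'   they must be opposite on source, content and order.
#' @return A probability in \eqn{[0, 1]}.
#' @export
#' @examples
#' choice_probability(
#'   bias_params(0.5, 0, 0), "expert_to_novice",
#'   produced = variant_attrs("expert", "parity", "first"),
#'   alternative = variant_attrs("peer", "skipping", "last")
#' )
choice_probability <- function(params, context, produced, alternative) {
  stopifnot(
    inherits(produced, "variant_attrs"),
    inherits(alternative, "variant_attrs")
  )
  if (produced$source == alternative$source ||
    produced$content == alternative$content ||
    produced$order == alternative$order) {
    abort("`produced` and `alternative` must be opposite on source, content and order")
  }
  w_produced <- variant_weight(params, context, produced)
  w_alternative <- variant_weight(params, context, alternative)
  total <- w_produced + w_alternative
  if (total == 0) {
    return(0.5)
  }
  w_produced / total
}

# Vectorized probability that the *expert-sourced* variant is produced.
# `expert_order` is the learning order of the expert's variant ("first"
# or "last"); with primacy_bias = 0 the order factor cancels and the
# argument is irrelevant. Content never enters: no content bias is
# modeled. This is the fast path used by the simulator and the oracle;
# it agrees with choice_probability() (tested).
prob_expert_produced <- function(expert_bias, congruent_bias,
                                 primacy_bias = 0, context,
                                 expert_order = "first") {
  context <- match_context(context)
  stopifnot(length(context) == 1L, expert_order %in% .orders)
  p_e <- bias_weight(expert_bias)
  p_c <- bias_weight(congruent_bias)
  p_l <- bias_weight(primacy_bias)
  expert_congruent <- context == "expert_to_novice"
  f_cong_expert <- if (expert_congruent) p_c else 1 - p_c
  f_cong_peer <- if (expert_congruent) 1 - p_c else p_c
  f_ord_expert <- if (expert_order == "last") p_l else 1 - p_l
  f_ord_peer <- if (expert_order == "last") 1 - p_l else p_l
  w_expert <- p_e * f_cong_expert * f_ord_expert
  w_peer <- (1 - p_e) * f_cong_peer * f_ord_peer
  total <- w_expert + w_peer
  ifelse(total == 0, 0.5, w_expert / total)
}
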