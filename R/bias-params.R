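#' Bias parameters of the transmission choice model
#'
#' Bundles the three bias magnitudes of the choice model. Each lies in
#' \eqn{[-1, 1]}; 0 means no bias.
#'
#' * `expert_bias`: positive values favour the variant learned from the
#'   expert, negative values the variant learned from a peer. The peer
#'   bias is its negation.
#' * `congruent_bias`: positive values favour the variant learned in the
#'   context matching the current production context; negative values
#'   favour the incongruent variant.
#' * `primacy_bias`: positive values favour the variant learned *last*,
#'   negative values the variant learned first (the field's sign
#'   convention for this parameter is literal, not mnemonic; the recency
#'   bias is its negation). Defaults to 0, which makes the model
#'   independent of learning order.
#'
#' @param expert_bias,congruent_bias,primacy_bias Numbers in
#'   \eqn{[-1, 1]}.
#' @return An object of class `bias_params`.
#' @seealso [bias_weight()], [choice_probability()]
#' @export
#' @examples
#' bias_params(0.4, 0.5)
#' peer_bias(bias_params(0.4, 0.5))
bias_params <- function(expert_bias = 0, congruent_bias = 0, primacy_bias = 0) {
  vals <- c(
    expert_bias = expert_bias,
    congruent_bias = congruent_bias,
    primacy_bias = primacy_bias
  )
  if (!is.numeric(vals) || length(vals) != 3L || anyNA(vals)) {
    abort("bias parameters must be single non-missing numbers")
  }
  bad <- vals < -1 | vals > 1
  if (any(bad)) {
    abort(paste0(
      "bias parameters must lie in [-1, 1]; out of range: ",
      paste(names(vals)[bad], collapse = ", ")
    ))
  }
  structure(as.list(vals), class = "bias_params")
}

#' @export
print.bias_params <- function(x, ...) {
  cat(sprintf(
    "<bias_params> expert = %g, congruent = %g, primacy = %g\n",
    x$expert_bias, x$congruent_bias, x$primacy_bias
  ))
  invisible(x)
}

#' Derived bias accessors
#'
#' The model is symmetric in each bias: the bias toward one pole of an
#' attribute is the negation of the bias toward the other. These
#' accessors return the negated counterparts of the stored parameters.
#'
#' @param params A [bias_params()] object.
#' @return A number in \eqn{[-1, 1]}.
#' @name derived-biases
#' @export
peer_bias <- function(params) -params$expert_bias

#' @rdname derived-biases
#' @export
incongruent_bias <- function(params) -params$congruent_bias

#' @rdname derived-biases
#' @export
recency_bias <- function(params) -params$primacy_bias

#' Map a bias magnitude to a sampling weight
#'
#' Affine map \eqn{b \mapsto (1 + b) / 2} taking a bias in \eqn{[-1, 1]}
#' to a weight in \eqn{[0, 1]}. A neutral bias (0) maps to 0.5, so under
#' the normalized product model it cancels; the endpoints map to
#' deterministic weights 0 and 1.
#'
#' @param bias Numeric vector with entries in \eqn{[-1, 1]}.
#' @return Numeric vector of weights in \eqn{[0, 1]}.
#' @export
#' @examples
#' bias_weight(c(-1, 0, 1))
bias_weight <- function(bias) {
  if (!is.numeric(bias) || anyNA(bias)) {
    abort("`bias` must be numeric and non-missing")
  }
  if (any(bias < -1 | bias > 1)) {
    abort("`bias` must lie in [-1, 1]")
  }
  (1 + bias) / 2
}
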