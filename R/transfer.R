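#' S-shaped transfer function
#'
#' Maps a continuous position coordinate to (0, 1) through a steep sigmoid
#' centred at 0.5: `1 / (1 + exp(-10 (x - 0.5)))`. Strictly increasing and
#' symmetric about (0.5, 0.5).
#'
#' @param x Numeric vector of position coordinates (any reals).
#' @return Values in (0, 1).
#' @export
#' @examples
#' sigmoid_transfer(c(0, 0.5, 1))
sigmoid_transfer <- function(x) 1 / (1 + exp(-10 * (x - 0.5)))

#' Binarize a continuous position into a feature mask
#'
#' Each coordinate is pushed through [sigmoid_transfer()] and compared with an
#' independent uniform draw `R` on \[0, 1\]. Two conventions are available:
#'
#' * `"as_printed"` (default): bit = 0 if `R < x_s`, bit = 1 if `R >= x_s` —
#'   the piecewise rule exactly as published, under which a *high* transfer
#'   value means a *low* selection probability.
#' * `"conventional"`: bit = 1 if `R < x_s`, the usual stochastic-threshold
#'   rule where the transfer value is the selection probability.
#'
#' The two are mirror images; the wrapper search works under either because
#' fitness is always evaluated on the realized mask. Uses the current R
#' random stream.
#'
#' @param position Numeric vector (the agent's continuous position).
#' @param convention `"as_printed"` or `"conventional"`.
#' @return Integer 0/1 vector of the same length.
#' @export
binarize <- function(position, convention = c("as_printed", "conventional")) {
  convention <- match.arg(convention)
  xs <- sigmoid_transfer(position)
  R <- stats::runif(length(position))
  bits <- if (convention == "as_printed") as.integer(R >= xs)
          else as.integer(R < xs)
  bits
}

#' Repair an empty feature mask
#'
#' A wrapper fitness is undefined on the empty subset. If no bit is set, one
#' uniformly chosen bit is switched on; otherwise the mask is returned
#' unchanged. Uses the current R random stream.
#'
#' @param mask Integer 0/1 vector.
#' @return A mask with at least one bit set.
#' @export
repair_mask <- function(mask) {
  if (sum(mask) == 0L) {
    mask[sample.int(length(mask), 1L)] <- 1L
  }
  mask
}
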