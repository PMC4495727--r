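#' Construct a gamble
#'
#' A gamble is a discrete set of probability--value outcome pairs. The
#' probabilities must be nonnegative and sum to 1 (tolerance 1e-9).
#'
#' @param probability Numeric vector of outcome probabilities.
#' @param value Numeric vector of outcome payoffs, same length.
#' @param label Optional name for the gamble.
#'
#' @return A tibble with columns `probability` and `value` (class `gamble`,
#'   label stored as an attribute). Any data frame with these two columns is
#'   accepted wherever a gamble is expected.
#'
#' @examples
#' bike <- gamble(c(0.5, 0.25, 0.25), c(100, -10, -90), label = "bike")
#' expected_value(bike)
#' @export
gamble <- function(probability, value, label = NULL) {
  g <- tibble(probability = as.numeric(probability), value = as.numeric(value))
  validate_gamble(g)
  attr(g, "label") <- label
  class(g) <- c("gamble", class(g))
  g
}

validate_gamble <- function(g) {
  if (!is.data.frame(g) || !all(c("probability", "value") %in% names(g))) {
    abort("a gamble is a data frame with columns `probability` and `value`",
          class = "sdtvalue_invalid_gamble")
  }
  p <- g$probability
  if (nrow(g) < 1L) {
    abort("a gamble needs at least one outcome", class = "sdtvalue_invalid_gamble")
  }
  if (any(!is.finite(p)) || any(!is.finite(g$value))) {
    abort("gamble probabilities and values must be finite",
          class = "sdtvalue_invalid_gamble")
  }
  if (any(p < 0) || abs(sum(p) - 1) > 1e-9) {
    abort(sprintf(
      "outcome probabilities must be nonnegative and sum to 1 (got %.12g)",
      sum(p)
    ), class = "sdtvalue_invalid_gamble")
  }
  invisible(g)
}

#' Parse a gamble from a "p:v,p:v,..." string
#'
#' Command-line convenience: `"0.5:100,0.25:-10,0.25:-90"` becomes a
#' three-outcome [gamble()].
#'
#' @param spec Character scalar of comma-separated `probability:value` pairs.
#' @param label Optional gamble label.
#' @return A [gamble()].
#' @export
parse_gamble <- function(spec, label = NULL) {
  if (!is.character(spec) || length(spec) != 1L || !nzchar(spec)) {
    abort("`spec` must be a single non-empty string like \"0.5:100,0.5:-50\"",
          class = "sdtvalue_invalid_gamble")
  }
  pairs <- strsplit(strsplit(spec, ",", fixed = TRUE)[[1]], ":", fixed = TRUE)
  bad <- which(vapply(pairs, length, integer(1)) != 2L)
  if (length(bad)) {
    abort(sprintf("malformed outcome %d in gamble string: %s", bad[1],
                  paste(pairs[[bad[1]]], collapse = ":")),
          class = "sdtvalue_invalid_gamble")
  }
  nums <- suppressWarnings(vapply(pairs, as.numeric, numeric(2)))
  if (any(is.na(nums))) {
    abort("gamble string contains non-numeric entries",
          class = "sdtvalue_invalid_gamble")
  }
  gamble(nums[1, ], nums[2, ], label = label)
}

#' Expected value of a gamble
#'
#' The probability-weighted sum of outcome values, `sum(p_i * v_i)` -- the
#' valuation rule of expected-value theory.
#'
#' @param g A [gamble()] or any data frame with `probability` and `value`
#'   columns.
#' @return A single number in payoff units.
#'
#' @examples
#' expected_value(gamble(c(0.5, 0.5), c(25, 75))) # 50
#' @export
expected_value <- function(g) {
  validate_gamble(g)
  sum(g$probability * g$value)
}
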