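#' The standard logistic function
#'
#' \eqn{\Psi(x) = \exp(x) / (1 + \exp(x))}, the response kernel of the 2PL and
#' 3PL models. Computed via [stats::plogis()] for numerical stability in the
#' tails.
#'
#' @param x Numeric vector of finite values.
#' @return Probabilities in (0, 1), the same length as `x`.
#' @examples
#' logistic(0)        # 0.5
#' 1 - logistic(0.5)  # 0.378, the tail probability used in the trade-off maps
#' @export
logistic <- function(x) {
  if (!is.numeric(x) || any(!is.finite(x))) {
    abort("`x` must be numeric and finite.", class = "irtlink_domain_error")
  }
  plogis(x)
}

#' Validate a table of 3PL item parameters
#'
#' Checks the invariants of the 3PL parameterization: discrimination `a > 0`,
#' finite difficulty `b`, and lower asymptote `c` in `[0, 1)`. `c = 0` is the
#' 2PL submodel; `c = 1` would make an item completely uninformative and is
#' rejected.
#'
#' @param items Data frame with columns `a`, `b`, `c` (and usually `item_id`).
#' @param require_id Require an `item_id` column as well?
#' @return The validated table as a tibble, invisibly usable in a pipe.
#' @export
validate_items <- function(items, require_id = FALSE) {
  if (!is.data.frame(items)) {
    abort("`items` must be a data frame of item parameters.",
          class = "irtlink_validation_error")
  }
  needed <- c(if (require_id) "item_id", "a", "b", "c")
  missing_cols <- setdiff(needed, names(items))
  if (length(missing_cols) > 0) {
    abort(paste0("`items` is missing column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "irtlink_validation_error")
  }
  items <- as_tibble(items)
  if (any(!is.finite(items$a)) || any(items$a <= 0)) {
    abort("Item discriminations `a` must be finite and > 0.",
          class = "irtlink_validation_error")
  }
  if (any(!is.finite(items$b))) {
    abort("Item difficulties `b` must be finite.",
          class = "irtlink_validation_error")
  }
  if (any(!is.finite(items$c)) || any(items$c < 0) || any(items$c >= 1)) {
    abort("Lower asymptotes `c` must lie in [0, 1).",
          class = "irtlink_validation_error")
  }
  items
}

#' 3PL response probability
#'
#' Probability of a correct response under the three-parameter logistic model,
#' \eqn{p(\theta) = c + (1 - c)\Psi[a(\theta - b)]}. Arguments are recycled to
#' a common length, so a single item can be evaluated on a grid of abilities
#' or a set of items at one ability.
#'
#' @param theta Ability value(s).
#' @param a Discrimination(s), `> 0`.
#' @param b Difficulty(ies).
#' @param c Lower asymptote(s) in `[0, 1)`.
#' @return Numeric vector of probabilities in `(c, 1)`.
#' @examples
#' prob_3pl(0, a = 1, b = -0.5, c = 0)     # 0.622
#' prob_3pl(0, a = 1, b = -0.5, c = 0.25)  # 0.25 + 0.75 * logistic(0.5)
#' @export
prob_3pl <- function(theta, a, b, c = 0) {
  if (any(!is.finite(theta))) {
    abort("`theta` must be finite.", class = "irtlink_domain_error")
  }
  validate_items(tibble(a = a, b = b, c = c))
  c + (1 - c) * plogis(a * (theta - b))
}

# I x Q matrix of response probabilities for an item table on an ability grid
irf_matrix <- function(items, theta) {
  c_ <- items$c
  c_ + (1 - c_) * plogis(outer(items$a, theta) - items$a * items$b)
}

#' Convert between the standard and slope-intercept 3PL parameterizations
#'
#' The slope-intercept form writes the logistic argument as
#' \eqn{\alpha\vartheta + \beta} instead of \eqn{a(\theta - b)}; the two are
#' related bijectively by \eqn{\alpha = a}, \eqn{\beta = -ab}. The lower
#' asymptote is untouched. Response probabilities are identical under both
#' forms for any ability.
#'
#' @param items For `to_slope_intercept()`, a table with columns `a`, `b`, `c`;
#'   for `from_slope_intercept()`, one with `alpha`, `beta`, `c`. An `item_id`
#'   column, if present, is carried along.
#' @return A tibble in the other parameterization.
#' @examples
#' to_slope_intercept(data.frame(a = 2, b = 1.5, c = 0.2))  # alpha 2, beta -3
#' @export
to_slope_intercept <- function(items) {
  items <- validate_items(items)
  out <- tibble(alpha = items$a, beta = -items$a * items$b, c = items$c)
  if ("item_id" %in% names(items)) out <- tibble(item_id = items$item_id, !!!out)
  out
}

#' @rdname to_slope_intercept
#' @export
from_slope_intercept <- function(items) {
  items <- as_tibble(items)
  needed <- setdiff(c("alpha", "beta", "c"), names(items))
  if (length(needed) > 0) {
    abort(paste0("Missing column(s): ", paste(needed, collapse = ", ")),
          class = "irtlink_validation_error")
  }
  if (any(!is.finite(items$alpha)) || any(items$alpha <= 0)) {
    abort("Slopes `alpha` must be finite and > 0.",
          class = "irtlink_validation_error")
  }
  out <- tibble(a = items$alpha, b = -items$beta / items$alpha, c = items$c)
  if ("item_id" %in% names(items)) out <- tibble(item_id = items$item_id, !!!out)
  validate_items(out)
}

#' Multiplicative Rasch parameters and their log transform
#'
#' The Rasch model can be written multiplicatively as
#' \eqn{p = \vartheta / (\vartheta + \beta)} with \eqn{\vartheta, \beta > 0}.
#' Taking logs, \eqn{\theta = \ln\vartheta} and \eqn{b = \ln\beta}, recovers
#' the additive form (a 3PL with `a = 1`, `c = 0`). The multiplicative form is
#' invariant to a common rescaling of \eqn{\vartheta} and \eqn{\beta} -- the
#' scale indeterminacy that identifiability restrictions must resolve.
#'
#' @param vartheta Multiplicative ability, `> 0`.
#' @param beta_m Multiplicative difficulty, `> 0`.
#' @return `rasch_log_transform()`: a tibble with columns `theta` and `b`;
#'   `rasch_multiplicative_prob()`: success probabilities.
#' @examples
#' rasch_log_transform(1, 1)             # theta 0, b 0
#' rasch_multiplicative_prob(exp(1), 1)  # e / (e + 1) = logistic(1)
#' @export
rasch_log_transform <- function(vartheta, beta_m) {
  if (any(!is.finite(vartheta)) || any(vartheta <= 0) ||
      any(!is.finite(beta_m)) || any(beta_m <= 0)) {
    abort("Multiplicative Rasch parameters must be finite and > 0.",
          class = "irtlink_domain_error")
  }
  tibble(theta = log(vartheta), b = log(beta_m))
}

#' @rdname rasch_log_transform
#' @export
rasch_multiplicative_prob <- function(vartheta, beta_m) {
  if (any(!is.finite(vartheta)) || any(vartheta <= 0) ||
      any(!is.finite(beta_m)) || any(beta_m <= 0)) {
    abort("Multiplicative Rasch parameters must be finite and > 0.",
          class = "irtlink_domain_error")
  }
  vartheta / (vartheta + beta_m)
}

#' Bernoulli log-likelihood of a response matrix
#'
#' The joint likelihood of a persons-by-items 0/1 response matrix is the
#' product of independent Bernoulli terms with success probabilities given by
#' the 3PL model. Probabilities are clamped away from 0 and 1 at `floor`
#' (with a warning when clamping occurs) so the log never becomes infinite.
#' The value is invariant under a simultaneous linking transform of all
#' abilities and item parameters.
#'
#' @param responses P x I matrix (or data frame) with entries 0/1; `NA`
#'   entries are excluded from the likelihood.
#' @param theta Length-P ability vector.
#' @param items Item table with P columns conforming: one row per item
#'   (columns `a`, `b`, `c`), I rows.
#' @param floor Clamping floor for probabilities, default `1e-12`.
#' @return The scalar log-likelihood.
#' @export
response_loglik <- function(responses, theta, items, floor = 1e-12) {
  u <- as.matrix(responses)
  items <- validate_items(items)
  if (nrow(u) != length(theta) || ncol(u) != nrow(items)) {
    abort("Dimensions of `responses`, `theta`, and `items` do not conform.",
          class = "irtlink_validation_error")
  }
  if (!all(u %in% c(0, 1, NA))) {
    abort("`responses` must contain only 0, 1, or NA.",
          class = "irtlink_validation_error")
  }
  p <- t(irf_matrix(items, theta))  # P x I
  if (any(p < floor | p > 1 - floor)) {
    warn("Response probabilities clamped away from 0/1.")
    p <- pmin(pmax(p, floor), 1 - floor)
  }
  sum(u * log(p) + (1 - u) * log(1 - p), na.rm = TRUE)
}

#' Simulate a 3PL response matrix
#'
#' Independent Bernoulli draws with success probabilities from the 3PL model.
#'
#' @param items Item table (`a`, `b`, `c`), one row per item.
#' @param theta Ability vector, one entry per person.
#' @param seed Optional integer seed for reproducibility.
#' @return Integer P x I matrix of 0/1 responses; item ids (when present) are
#'   used as column names.
#' @export
simulate_responses <- function(items, theta, seed = NULL) {
  items <- validate_items(items)
  if (!is.null(seed)) set.seed(seed)
  p <- t(irf_matrix(items, theta))  # P x I
  u <- matrix(rbinom(length(p), 1L, p), nrow = length(theta))
  if ("item_id" %in% names(items)) colnames(u) <- as.character(items$item_id)
  u
}
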