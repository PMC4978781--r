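#' Linear linking function between two 3PL calibrations
#'
#' A linking function reconciles the parameter values that the same items and
#' persons obtain under the different identifiability restrictions of two
#' separate calibrations. For the 3PL model in its standard parameterization
#' the linking function is linear: abilities and difficulties map as
#' \eqn{\theta^* = u\theta + v}, \eqn{b^* = ub + v}, discriminations as
#' \eqn{a^* = a/u}, and lower asymptotes by the identity \eqn{c^* = c}.
#'
#' The direction convention throughout the package is **source = calibration
#' 1, target = calibration 2**: `apply_link()` maps source-scale values onto
#' the target scale.
#'
#' @param u Slope, `> 0`.
#' @param v Intercept.
#' @return An object of class `irt_link`.
#' @examples
#' lk <- linear_link(1.208, -0.707)
#' invert_link(lk)
#' @export
linear_link <- function(u, v) {
  if (length(u) != 1 || length(v) != 1 || !is.finite(u) || !is.finite(v)) {
    abort("`u` and `v` must be finite scalars.",
          class = "irtlink_validation_error")
  }
  if (u <= 0) {
    abort("Link slope `u` must be > 0.", class = "irtlink_validation_error")
  }
  structure(list(u = u, v = v, direction = "cal1_to_cal2"),
            class = "irt_link")
}

#' @export
print.irt_link <- function(x, digits = 4, ...) {
  cat("<irt_link> theta* = u * theta + v (", x$direction, ")\n", sep = "")
  cat("  u =", format(x$u, digits = digits),
      " v =", format(x$v, digits = digits), "\n")
  invisible(x)
}

#' @export
tidy.irt_link <- function(x, ...) {
  tibble(term = c("u", "v"), estimate = c(x$u, x$v))
}

#' Invert or compose linear links
#'
#' The inverse of \eqn{\theta^* = u\theta + v} is the link \eqn{(1/u, -v/u)};
#' composing `first` then `second` gives the link
#' \eqn{(u_2 u_1,\; u_2 v_1 + v_2)}. Composition with the inverse returns the
#' identity link.
#'
#' @param link,first,second `irt_link` objects.
#' @return An `irt_link`.
#' @export
invert_link <- function(link) {
  linear_link(1 / link$u, -link$v / link$u)
}

#' @rdname invert_link
#' @export
compose_links <- function(first, second) {
  linear_link(second$u * first$u, second$u * first$v + second$v)
}

#' Apply a linear link to item parameters or abilities
#'
#' Maps source-calibration values onto the target-calibration scale:
#' `(a, b, c)` becomes `(a/u, ub + v, c)` and abilities become
#' `u * theta + v`. Response probabilities are invariant:
#' `prob_3pl(theta, a, b, c)` equals the probability of the transformed item
#' at the transformed ability.
#'
#' @param items Item table (`a`, `b`, `c`; `item_id` carried along).
#' @param link An `irt_link`.
#' @return `apply_link()`: the transformed item tibble; `apply_link_theta()`:
#'   the transformed ability vector.
#' @examples
#' it <- tibble::tibble(a = 2.612, b = -0.843, c = 0.213)
#' apply_link(it, linear_link(1.208, -0.707))  # b* close to -1.725
#' @export
apply_link <- function(items, link) {
  items <- validate_items(items)
  stopifnot(inherits(link, "irt_link"))
  mutate(items, a = .data$a / link$u, b = link$u * .data$b + link$v)
}

#' @rdname apply_link
#' @param theta Ability value(s) on the source scale.
#' @export
apply_link_theta <- function(theta, link) {
  stopifnot(inherits(link, "irt_link"))
  link$u * theta + link$v
}

#' Identify the linking parameters from minimal designs
#'
#' With the parameter values treated as known, the linking parameters `(u, v)`
#' are already identified by a single common item:
#' \eqn{u = a_1 / a_2} (source over target discrimination) and
#' \eqn{v = b_2 - u b_1}. Two common items identify them through difficulties
#' alone, \eqn{u = (b_{1,2} - b_{2,2}) / (b_{1,1} - b_{2,1})}, provided the
#' source difficulties differ; the intercept from either item must then agree
#' and is cross-checked. Two common persons identify them analogously through
#' abilities; a *single* common person does not identify `(u, v)`, and
#' `link_from_two_persons()` refuses such a design.
#'
#' @param source,target One-row item tables for the same item in the source
#'   (calibration 1) and target (calibration 2) runs.
#' @return An `irt_link`.
#' @examples
#' link_from_one_item(tibble::tibble(a = 2.612, b = -0.843, c = 0.213),
#'                    tibble::tibble(a = 2.162, b = -1.725, c = 0.191))
#' @export
link_from_one_item <- function(source, target) {
  source <- validate_items(source); target <- validate_items(target)
  stopifnot(nrow(source) == 1, nrow(target) == 1)
  u <- source$a / target$a
  linear_link(u, target$b - u * source$b)
}

#' @rdname link_from_one_item
#' @param b_source,b_target Length-2 difficulty vectors for two common items
#'   in the two calibrations.
#' @param tol Agreement tolerance for the two intercept solutions on
#'   noise-free inputs.
#' @export
link_from_two_items_b <- function(b_source, b_target, tol = 1e-8) {
  stopifnot(length(b_source) == 2, length(b_target) == 2)
  if (b_source[1] == b_source[2]) {
    abort("Degenerate design: the two source difficulties are equal.",
          class = "irtlink_identifiability_error")
  }
  u <- (b_target[1] - b_target[2]) / (b_source[1] - b_source[2])
  if (u <= 0) {
    abort("Difficulty differences imply a non-positive slope.",
          class = "irtlink_identifiability_error")
  }
  v1 <- b_target[1] - u * b_source[1]
  v2 <- b_target[2] - u * b_source[2]
  if (abs(v1 - v2) > tol) {
    warn(paste0("Intercepts from the two items differ by ",
                format(abs(v1 - v2)), "; reporting their mean."))
  }
  linear_link(u, (v1 + v2) / 2)
}

#' @rdname link_from_one_item
#' @param theta_source,theta_target Ability values of common persons in the
#'   two calibrations.
#' @export
link_from_two_persons <- function(theta_source, theta_target) {
  if (length(theta_source) < 2 || length(theta_target) < 2) {
    abort(paste0("A single common person does not identify (u, v); ",
                 "at least two common persons are required."),
          class = "irtlink_identifiability_error")
  }
  stopifnot(length(theta_source) == 2, length(theta_target) == 2)
  if (theta_source[1] == theta_source[2]) {
    abort("Degenerate design: the two source abilities are equal.",
          class = "irtlink_identifiability_error")
  }
  u <- (theta_target[1] - theta_target[2]) / (theta_source[1] - theta_source[2])
  if (u <= 0) {
    abort("Ability differences imply a non-positive slope.",
          class = "irtlink_identifiability_error")
  }
  linear_link(u, theta_target[1] - u * theta_source[1])
}
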