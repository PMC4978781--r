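#' Linking function for the slope-intercept parameterization
#'
#' Writing the logistic argument as \eqn{\alpha\vartheta + \beta} instead of
#' \eqn{a(\theta - b)} changes the linking problem: the linking function
#' acquires a third parameter, mapping
#' \eqn{\alpha^* = (\alpha - u)/v}, \eqn{\beta^* = \beta + u},
#' \eqn{c^* = c}, and \eqn{\vartheta^* = (\vartheta - u)/w}. Its parameters
#' are identifiable only from designs with **both** a common item and a
#' common person; item-only or person-only designs are refused.
#'
#' @param u Intercept shift.
#' @param v Slope divisor, `> 0`.
#' @param w Ability divisor, nonzero.
#' @return An object of class `irt_si_link`.
#' @export
si_link <- function(u, v, w) {
  if (!all(is.finite(c(u, v, w)))) {
    abort("Link parameters must be finite.", class = "irtlink_validation_error")
  }
  if (v <= 0) {
    abort("Slope divisor `v` must be > 0.", class = "irtlink_validation_error")
  }
  if (w == 0) {
    abort("Ability divisor `w` must be nonzero.",
          class = "irtlink_validation_error")
  }
  structure(list(u = u, v = v, w = w, direction = "cal1_to_cal2"),
            class = "irt_si_link")
}

#' @export
print.irt_si_link <- function(x, digits = 4, ...) {
  cat("<irt_si_link> slope-intercept linking (", x$direction, ")\n", sep = "")
  cat("  u =", format(x$u, digits = digits),
      " v =", format(x$v, digits = digits),
      " w =", format(x$w, digits = digits), "\n")
  invisible(x)
}

#' Apply a slope-intercept link to item parameters and an ability
#'
#' Transforms `(alpha, beta, c)` and `vartheta` jointly and reports the
#' residual of the invariance identity
#' \eqn{\alpha^*\vartheta^* + \beta^* = \alpha\vartheta + \beta}, which holds
#' when the link's parameters are mutually consistent (for a link identified
#' from a common item and person, it is zero for that pair by construction).
#'
#' @param items Slope-intercept item table (`alpha`, `beta`, `c`).
#' @param vartheta Ability value(s) in the slope-intercept parameterization.
#' @param link An `irt_si_link`.
#' @return A list with elements `items` (transformed tibble), `vartheta`
#'   (transformed abilities), and `residual` (max absolute invariance
#'   residual over all item-ability pairs).
#' @export
si_apply_link <- function(items, vartheta, link) {
  stopifnot(inherits(link, "irt_si_link"))
  items <- as_tibble(items)
  needed <- setdiff(c("alpha", "beta", "c"), names(items))
  if (length(needed) > 0) {
    abort(paste0("Missing column(s): ", paste(needed, collapse = ", ")),
          class = "irtlink_validation_error")
  }
  out <- mutate(items,
                alpha = (.data$alpha - link$u) / link$v,
                beta = .data$beta + link$u)
  vt <- (vartheta - link$u) / link$w
  before <- outer(items$alpha, vartheta) + items$beta
  after <- outer(out$alpha, vt) + out$beta
  list(items = out, vartheta = vt, residual = max(abs(after - before)))
}

#' Identify a slope-intercept link from a common item and a common person
#'
#' Solves \eqn{u = \beta_{i,2} - \beta_{i,1}},
#' \eqn{v = (\alpha_{i,1} - u)/\alpha_{i,2}}, and
#' \eqn{w = (\vartheta_{p,1} - u)/\vartheta_{p,2}} for a design containing at
#' least one common item *and* one common person. Designs missing either are
#' not identified and raise an error.
#'
#' @param item_source,item_target One-row slope-intercept tables (`alpha`,
#'   `beta`, `c`) for a common item in the two calibrations, or `NULL` if the
#'   design has no common item.
#' @param person_source,person_target Scalar abilities for a common person in
#'   the two calibrations, or `NULL` if the design has no common person.
#' @return An `irt_si_link`.
#' @export
si_link_from_design <- function(item_source, item_target,
                                person_source, person_target) {
  has_item <- !is.null(item_source) && !is.null(item_target)
  has_person <- !is.null(person_source) && !is.null(person_target)
  if (!has_item || !has_person) {
    abort(paste0("The slope-intercept linking parameters are identifiable ",
                 "only for designs with both common items and common ",
                 "persons."),
          class = "irtlink_identifiability_error")
  }
  item_source <- as_tibble(item_source); item_target <- as_tibble(item_target)
  stopifnot(nrow(item_source) == 1, nrow(item_target) == 1,
            length(person_source) == 1, length(person_target) == 1)
  if (item_target$alpha == 0) {
    abort("Target slope must be nonzero.",
          class = "irtlink_identifiability_error")
  }
  if (person_target == 0) {
    abort("Target ability must be nonzero.",
          class = "irtlink_identifiability_error")
  }
  u <- item_target$beta - item_source$beta
  v <- (item_source$alpha - u) / item_target$alpha
  w <- (person_source - u) / person_target
  si_link(u, v, w)
}
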