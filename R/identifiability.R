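#' Maris parameterization of the equal-discrimination 3PL
#'
#' With all discriminations equal (wlog `a = 1`), the 3PL success probability
#' can be written as \eqn{\pi = (\vartheta + \delta) / (\vartheta + \beta)}
#' with \eqn{\vartheta = e^\theta}, \eqn{\beta = e^b}, and
#' \eqn{\delta = c e^b}. In this form, adding a constant to every
#' \eqn{\vartheta} while subtracting it from every \eqn{\beta} and
#' \eqn{\delta} leaves all response probabilities unchanged -- a compensating
#' trade-off demonstrating the lack of identifiability of the
#' equal-discrimination model.
#'
#' @param theta Ability.
#' @param b Difficulty.
#' @param c Lower asymptote in `[0, 1)`.
#' @return A tibble with columns `vartheta`, `beta_m`, `delta`.
#' @export
maris_params <- function(theta, b, c) {
  if (any(c < 0) || any(c >= 1)) {
    abort("`c` must lie in [0, 1).", class = "irtlink_domain_error")
  }
  tibble(vartheta = exp(theta), beta_m = exp(b), delta = c * exp(b))
}

#' @rdname maris_params
#' @param vartheta,beta_m,delta Maris-form parameters, all positive with
#'   `delta < beta_m`.
#' @export
maris_prob <- function(vartheta, beta_m, delta) {
  check_maris(vartheta, beta_m, delta)
  (vartheta + delta) / (vartheta + beta_m)
}

check_maris <- function(vartheta, beta_m, delta) {
  if (any(vartheta <= 0)) {
    abort("`vartheta` must be > 0.", class = "irtlink_domain_error")
  }
  if (any(beta_m <= 0)) {
    abort("`beta_m` must be > 0.", class = "irtlink_domain_error")
  }
  if (any(delta <= 0)) {
    abort("`delta` must be > 0.", class = "irtlink_domain_error")
  }
  if (any(delta >= beta_m)) {
    abort("`delta` must be < `beta_m` (equivalently c < 1).",
          class = "irtlink_domain_error")
  }
  invisible(NULL)
}

#' Compensating additive shift of Maris-form parameters
#'
#' Adds `constant` to every `vartheta` and subtracts it from every `beta_m`
#' and `delta`. All success probabilities are preserved exactly; the shifted
#' parameters must stay positive with `delta < beta_m`.
#'
#' @param params Tibble as returned by [maris_params()].
#' @param constant The shift; may be negative.
#' @return Shifted parameter tibble.
#' @examples
#' p <- tibble::tibble(vartheta = 2, beta_m = 3, delta = 1)
#' maris_shift(p, 0.5)  # (2.5, 2.5, 0.5); probability (2+1)/(2+3) preserved
#' @export
maris_shift <- function(params, constant) {
  check_maris(params$vartheta, params$beta_m, params$delta)
  out <- mutate(as_tibble(params),
                vartheta = .data$vartheta + constant,
                beta_m = .data$beta_m - constant,
                delta = .data$delta - constant)
  if (any(out$vartheta <= 0)) {
    abort("Shift drives `vartheta` non-positive.",
          class = "irtlink_domain_error")
  }
  if (any(out$delta <= 0)) {
    abort("Shift drives `delta` non-positive.",
          class = "irtlink_domain_error")
  }
  check_maris(out$vartheta, out$beta_m, out$delta)
  out
}

#' Admissible range of the asymptote-scaling factor kappa
#'
#' When all persons share one ability \eqn{\theta}, the complement of each
#' item's asymptote, \eqn{\gamma = 1 - c}, can be rescaled to
#' \eqn{\gamma^* = \kappa\gamma} and compensated by adjusting the item's
#' difficulty, its discrimination, or the common ability, leaving all response
#' probabilities unchanged. The compensation requires
#' \eqn{\kappa[1 + e^{a(\theta - b)}] - 1 > 0}, i.e.
#' \eqn{\kappa > 1 - \Psi}; compensating through the discrimination
#' additionally requires the adjusted slope to stay positive, which doubles
#' the bound to \eqn{2(1 - \Psi)} and requires \eqn{\theta > b}.
#'
#' @param item One-row item table (`a`, `b`, `c`).
#' @param theta The common ability.
#' @param target Which parameter absorbs the compensation: `"b"`, `"a"`, or
#'   `"theta"`.
#' @return Named numeric vector `c(lower, upper)` for the open-closed interval
#'   `(lower, 1]`.
#' @examples
#' it <- tibble::tibble(a = 1, b = -0.5, c = 0.25)
#' kappa_admissible_range(it, 0, "b")  # lower bound 0.378
#' kappa_admissible_range(it, 0, "a")  # lower bound 0.755
#' @export
kappa_admissible_range <- function(item, theta, target = c("b", "a", "theta")) {
  target <- match.arg(target)
  item <- validate_items(item)
  stopifnot(nrow(item) == 1, length(theta) == 1)
  one_minus_psi <- 1 - plogis(item$a * (theta - item$b))
  if (target == "a") {
    if (theta <= item$b) {
      abort("Compensating through `a` requires theta > b.",
            class = "irtlink_infeasible_error")
    }
    lower <- 2 * one_minus_psi
  } else {
    lower <- one_minus_psi
  }
  c(lower = lower, upper = 1)
}

#' Compensating parameter trade-off for a rescaled lower asymptote
#'
#' Given the rescaling \eqn{\gamma^* = \kappa\gamma} of an item's asymptote
#' complement under a common ability \eqn{\theta}, returns the adjusted
#' parameter value that restores every response probability:
#' \deqn{b^* = \theta - \ln(\kappa[1 + e^{a(\theta-b)}] - 1)/a,}
#' \deqn{a^* = \ln(\kappa[1 + e^{a(\theta-b)}] - 1)/(\theta - b),}
#' \deqn{\theta^* = b + \ln(\kappa[1 + e^{a(\theta-b)}] - 1)/a.}
#' The trade-off through `a` normally requires \eqn{a^* > 0}
#' (\eqn{\kappa > 2(1-\Psi)}); setting `allow_negative_a = TRUE` admits the
#' negative branch down to the common bound \eqn{1 - \Psi}, as used to plot
#' the dashed branch of the trade-off curves.
#'
#' @inheritParams kappa_admissible_range
#' @param kappa Scaling factor applied to `gamma = 1 - c`, in the admissible
#'   range for the chosen target.
#' @param allow_negative_a Permit a negative adjusted discrimination?
#' @return The adjusted parameter value (scalar).
#' @examples
#' it <- tibble::tibble(a = 1, b = -0.5, c = 0.25)
#' compensating_tradeoff(it, 0, kappa = 1, target = "b")  # unchanged: -0.5
#' compensating_tradeoff(it, 0, kappa = 0.38, target = "a",
#'                       allow_negative_a = TRUE)         # about -10
#' @export
compensating_tradeoff <- function(item, theta, kappa,
                                  target = c("b", "a", "theta"),
                                  allow_negative_a = FALSE) {
  target <- match.arg(target)
  item <- validate_items(item)
  stopifnot(nrow(item) == 1, length(theta) == 1, length(kappa) == 1)
  a <- item$a; b <- item$b
  arg <- kappa * (1 + exp(a * (theta - b))) - 1
  if (arg <= 0) {
    abort(paste0("kappa = ", format(kappa), " is below the admissible bound ",
                 "1 - Psi = ", format(1 - plogis(a * (theta - b))),
                 "; the compensating log argument is non-positive."),
          class = "irtlink_infeasible_error")
  }
  switch(target,
    b = theta - log(arg) / a,
    theta = b + log(arg) / a,
    a = {
      if (theta == b) {
        abort("Compensating through `a` is undefined at theta == b.",
              class = "irtlink_infeasible_error")
      }
      a_star <- log(arg) / (theta - b)
      if (a_star <= 0 && !allow_negative_a) {
        abort(paste0("Adjusted discrimination would be non-positive ",
                     "(requires kappa > 2(1 - Psi) and theta > b); set ",
                     "`allow_negative_a = TRUE` for the negative branch."),
              class = "irtlink_infeasible_error")
      }
      a_star
    })
}

#' Trade-off curves across a grid of kappa values
#'
#' Evaluates all three compensating trade-offs on a grid of \eqn{\kappa}
#' values for one item and a common ability, producing the data behind the
#' classic trade-off figure: adjusted difficulty `b_star`, discrimination
#' `a_star` (negative branch included, flagged by `a_star_negative`), and
#' ability `theta_star`. Grid points outside a target's admissible range are
#' returned as `NA` rather than errors so full-grid curves can be drawn.
#'
#' @inheritParams compensating_tradeoff
#' @param kappa_grid Numeric vector of positive scaling factors.
#' @return A tibble with columns `kappa`, `b_star`, `a_star`, `theta_star`,
#'   `a_star_negative`. With the default `allow_negative_a = FALSE`, the
#'   `a_star` column is `NA` below its own bound `2(1 - Psi)`; with the
#'   override it extends down to the common bound as a negative branch.
#' @export
tradeoff_curves <- function(item, theta, kappa_grid, allow_negative_a = FALSE) {
  if (length(kappa_grid) == 0) {
    abort("`kappa_grid` must be nonempty.", class = "irtlink_validation_error")
  }
  item <- validate_items(item)
  stopifnot(nrow(item) == 1)
  common_lower <- kappa_admissible_range(item, theta, "b")[["lower"]]
  a_lower <- if (theta > item$b) 2 * common_lower else Inf
  purrr::map_dfr(kappa_grid, function(k) {
    feasible <- k > common_lower & k <= 1
    if (!feasible) {
      return(tibble(kappa = k, b_star = NA_real_, a_star = NA_real_,
                    theta_star = NA_real_, a_star_negative = NA))
    }
    a_star <- if (theta == item$b || (!allow_negative_a && k <= a_lower)) {
      NA_real_
    } else {
      compensating_tradeoff(item, theta, k, "a", allow_negative_a = TRUE)
    }
    tibble(kappa = k,
           b_star = compensating_tradeoff(item, theta, k, "b"),
           a_star = a_star,
           theta_star = compensating_tradeoff(item, theta, k, "theta"),
           a_star_negative = !is.na(a_star) && a_star <= 0)
  })
}

#' Plot trade-off curves
#'
#' @param object A tibble from [tradeoff_curves()].
#' @param ... Unused.
#' @return A ggplot: adjusted parameter values against kappa, one facet per
#'   parameter, with the negative branch of the discrimination dashed.
#' @export
plot_tradeoff_curves <- function(object, ...) {
  long <- tidyr::pivot_longer(object, c("b_star", "a_star", "theta_star"),
                              names_to = "parameter", values_to = "value")
  long$branch <- ifelse(long$parameter == "a_star" &
                          !is.na(long$value) & long$value <= 0,
                        "negative", "admissible")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$kappa, y = .data$value,
                                     linetype = .data$branch)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::facet_wrap(~parameter, scales = "free_y") +
    ggplot2::scale_linetype_manual(
      values = c(admissible = "solid", negative = "dashed"), guide = "none") +
    ggplot2::labs(x = expression(kappa), y = "compensated value")
}
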