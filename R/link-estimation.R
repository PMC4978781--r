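#' Per-common-item linking estimates
#'
#' Applies the one-item identification \eqn{\hat u_i = \hat a_{i,1} / \hat
#' a_{i,2}}, \eqn{\hat v_i = \hat b_{i,2} - \hat u_i \hat b_{i,1}} to every
#' common item of a pair of calibrations, matched by `item_id`. When per-item
#' covariance tables are supplied, first-order delta-method standard errors
#' are filled in via [delta_se_per_item()].
#'
#' @param source,target Item tables (`item_id`, `a`, `b`, `c`) from
#'   calibration 1 (source) and calibration 2 (target).
#' @param cov_source,cov_target Optional covariance tables (`item_id`,
#'   `var_a`, `var_b`, `var_c`, `cov_ab`, `cov_ac`, `cov_bc`), one row per
#'   item within each calibration.
#' @return A tibble with columns `item_id`, `u`, `v` and, when covariances
#'   are supplied, `se_u`, `se_v`.
#' @examples
#' src <- read_item_table(irtlink_example("cal1_items.csv"))
#' tgt <- read_item_table(irtlink_example("cal2_items.csv"))
#' per_item_links(src, tgt)
#' @export
per_item_links <- function(source, target, cov_source = NULL,
                           cov_target = NULL) {
  source <- validate_items(source, require_id = TRUE)
  target <- validate_items(target, require_id = TRUE)
  unmatched <- c(setdiff(source$item_id, target$item_id),
                 setdiff(target$item_id, source$item_id))
  if (length(unmatched) > 0) {
    abort(paste0("Item ids not present in both calibrations: ",
                 paste(unique(unmatched), collapse = ", ")),
          class = "irtlink_join_error")
  }
  joined <- inner_join(source, target, by = "item_id",
                       suffix = c("_1", "_2"))
  out <- tibble(item_id = joined$item_id,
                u = joined$a_1 / joined$a_2,
                v = joined$b_2 - (joined$a_1 / joined$a_2) * joined$b_1)
  if (!is.null(cov_source) && !is.null(cov_target)) {
    out <- delta_se_per_item(out, source, target, cov_source, cov_target)
  }
  out
}

check_cov_table <- function(cov, label) {
  cov <- as_tibble(cov)
  needed <- setdiff(c("item_id", "var_a", "var_b", "var_c",
                      "cov_ab", "cov_ac", "cov_bc"), names(cov))
  if (length(needed) > 0) {
    abort(paste0("Covariance table ", label, " is missing column(s): ",
                 paste(needed, collapse = ", ")),
          class = "irtlink_validation_error")
  }
  if (any(cov$var_a < 0 | cov$var_b < 0 | cov$var_c < 0)) {
    abort("Covariance table diagonals must be nonnegative.",
          class = "irtlink_validation_error")
  }
  # the linking computations only use the (a, b) block (the asymptote links
  # by the identity); that block must be positive semidefinite. Covariances
  # printed at few decimals can be slightly indefinite, so warn and proceed.
  bad <- cov$var_a * cov$var_b - cov$cov_ab^2 < -1e-12
  if (any(bad)) {
    warn(paste0("(a, b) covariance blocks in ", label, " are not positive ",
                "semidefinite (typically input rounding) for item(s): ",
                paste(cov$item_id[bad], collapse = ", "), "; proceeding."))
  }
  cov
}

#' Delta-method standard errors for per-item linking estimates
#'
#' First-order propagation of the estimation covariances of
#' \eqn{(\hat a, \hat b)} in the two calibrations through
#' \eqn{\hat u_i = a_1 / a_2} and \eqn{\hat v_i = b_2 - \hat u_i b_1}.
#' Calibrations are treated as independent; within a calibration, the
#' item's `cov_ab` enters the intercept variance. Entries involving `c`
#' are unused because the asymptote links by the identity.
#'
#' @param per_item Tibble from [per_item_links()].
#' @inheritParams per_item_links
#' @return `per_item` with columns `se_u`, `se_v` added.
#' @export
delta_se_per_item <- function(per_item, source, target, cov_source,
                              cov_target) {
  source <- validate_items(source, require_id = TRUE)
  target <- validate_items(target, require_id = TRUE)
  cov_source <- check_cov_table(cov_source, "cov_source")
  cov_target <- check_cov_table(cov_target, "cov_target")
  missing_ids <- setdiff(per_item$item_id,
                         intersect(cov_source$item_id, cov_target$item_id))
  if (length(missing_ids) > 0) {
    abort(paste0("Missing covariance rows for item(s): ",
                 paste(missing_ids, collapse = ", ")),
          class = "irtlink_validation_error")
  }
  d <- per_item |>
    inner_join(rename_with_suffix(source, "_1"), by = "item_id") |>
    inner_join(rename_with_suffix(target, "_2"), by = "item_id") |>
    inner_join(rename_with_suffix(cov_source, "_1"), by = "item_id") |>
    inner_join(rename_with_suffix(cov_target, "_2"), by = "item_id")
  var_u <- d$var_a_1 / d$a_2^2 + d$a_1^2 * d$var_a_2 / d$a_2^4
  # gradient of v = b2 - (a1/a2) b1 wrt (a1, b1, a2, b2)
  g_a1 <- -d$b_1 / d$a_2
  g_b1 <- -d$u
  g_a2 <- d$u * d$b_1 / d$a_2
  var_v <- g_a1^2 * d$var_a_1 + g_b1^2 * d$var_b_1 +
    g_a2^2 * d$var_a_2 + d$var_b_2 +
    2 * g_a1 * g_b1 * d$cov_ab_1 + 2 * g_a2 * d$cov_ab_2
  mutate(per_item, se_u = sqrt(var_u), se_v = sqrt(var_v))
}

rename_with_suffix <- function(tbl, suffix) {
  keep <- setdiff(names(tbl), "item_id")
  stats::setNames(tbl[c("item_id", keep)], c("item_id", paste0(keep, suffix)))
}

new_pooled_link <- function(method, u, se_u, v, se_v, per_item = NULL,
                            details = list()) {
  structure(list(method = method, u = u, se_u = se_u, v = v, se_v = se_v,
                 per_item = per_item, details = details,
                 direction = "cal1_to_cal2"),
            class = "pooled_link")
}

#' @export
print.pooled_link <- function(x, digits = 4, ...) {
  cat("<pooled_link> method:", x$method, "(cal1 -> cal2)\n")
  fmt <- function(z) if (is.null(z) || is.na(z)) "NA" else format(z, digits = digits)
  cat("  u =", fmt(x$u), "(SE", paste0(fmt(x$se_u), ")"),
      " v =", fmt(x$v), "(SE", paste0(fmt(x$se_v), ")"), "\n")
  invisible(x)
}

#' @export
tidy.pooled_link <- function(x, ...) {
  tibble(term = c("u", "v"), estimate = c(x$u, x$v),
         std.error = c(x$se_u %||% NA_real_, x$se_v %||% NA_real_))
}

#' @export
glance.pooled_link <- function(x, ...) {
  tibble(method = x$method, u = x$u, se_u = x$se_u %||% NA_real_,
         v = x$v, se_v = x$se_v %||% NA_real_,
         n_items = if (is.null(x$per_item)) NA_integer_ else
           nrow(x$per_item))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Precision-weighted pooling of per-item linking estimates
#'
#' Each common item yields its own estimate of the same `(u, v)`; the pooled
#' estimator weights them by the inverse of their squared standard errors,
#' \deqn{\hat u = \left(\sum_i \hat\sigma_{u_i}^{-2}\hat u_i\right) /
#'       \left(\sum_i \hat\sigma_{u_i}^{-2}\right),\qquad
#'       \hat\sigma_u = \left(\sum_i \hat\sigma_{u_i}^{-2}\right)^{-1/2},}
#' and identically for `v`. The pooled standard error is never larger than
#' the smallest per-item standard error.
#'
#' @param per_item Tibble with columns `item_id`, `u`, `se_u`, `v`, `se_v`,
#'   all SEs `> 0`.
#' @return A `pooled_link` object.
#' @export
pool_precision_weighted <- function(per_item) {
  per_item <- as_tibble(per_item)
  needed <- setdiff(c("u", "se_u", "v", "se_v"), names(per_item))
  if (length(needed) > 0) {
    abort(paste0("`per_item` is missing column(s): ",
                 paste(needed, collapse = ", "), "; run delta_se_per_item()."),
          class = "irtlink_validation_error")
  }
  if (any(per_item$se_u <= 0) || any(per_item$se_v <= 0)) {
    abort("All per-item standard errors must be > 0 (finite weights).",
          class = "irtlink_validation_error")
  }
  wu <- per_item$se_u^-2
  wv <- per_item$se_v^-2
  new_pooled_link("precision_weighted",
                  u = sum(wu * per_item$u) / sum(wu),
                  se_u = sum(wu)^-0.5,
                  v = sum(wv * per_item$v) / sum(wv),
                  se_v = sum(wv)^-0.5,
                  per_item = per_item)
}

#' Moment-based linking estimators
#'
#' `mean_mean()` estimates the slope as the ratio of mean discriminations,
#' \eqn{u = \mu(a_1)/\mu(a_2)}; `mean_sigma()` as the ratio of difficulty
#' standard deviations, \eqn{u = \sigma(b_2)/\sigma(b_1)} (or of ability SDs
#' in a common-person design); `log_mean_mean()` replaces the arithmetic mean
#' of the discriminations by the geometric mean. All take the intercept from
#' \eqn{v = \mu(b_2) - u\,\mu(b_1)}. When covariance tables are supplied,
#' standard errors are computed by the first-order delta method, treating
#' items as independent with the printed per-item `(a, b)` covariance inside
#' each calibration, and propagating the dependence of `v` on `u`.
#' `mean_sigma()` uses population (divide-by-n) standard deviations; the
#' slope is invariant to that choice.
#'
#' @inheritParams per_item_links
#' @param mode For `mean_sigma()`: `"items"` pools over common-item
#'   difficulties; `"persons"` expects `source` and `target` to be vectors of
#'   common-person abilities (no standard errors in that mode).
#' @return A `pooled_link` object.
#' @export
mean_mean <- function(source, target, cov_source = NULL, cov_target = NULL) {
  source <- validate_items(source, require_id = TRUE)
  target <- validate_items(target, require_id = TRUE)
  joined <- inner_join(source, target, by = "item_id", suffix = c("_1", "_2"))
  n <- nrow(joined)
  if (mean(joined$a_2) == 0) {
    abort("Mean target discrimination is zero.", class = "irtlink_domain_error")
  }
  u <- mean(joined$a_1) / mean(joined$a_2)
  v <- mean(joined$b_2) - u * mean(joined$b_1)
  se_u <- se_v <- NULL
  if (!is.null(cov_source) && !is.null(cov_target)) {
    cov1 <- check_cov_table(cov_source, "cov_source")
    cov2 <- check_cov_table(cov_target, "cov_target")
    cov1 <- cov1[match(joined$item_id, cov1$item_id), ]
    cov2 <- cov2[match(joined$item_id, cov2$item_id), ]
    m_a2 <- mean(joined$a_2); m_a1 <- mean(joined$a_1); m_b1 <- mean(joined$b_1)
    gu_a1 <- 1 / (n * m_a2)
    gu_a2 <- -m_a1 / (n * m_a2^2)
    var_u <- sum(gu_a1^2 * cov1$var_a) + sum(gu_a2^2 * cov2$var_a)
    gv_a1 <- -m_b1 / (n * m_a2)
    gv_b1 <- -u / n
    gv_a2 <- m_b1 * m_a1 / (n * m_a2^2)
    gv_b2 <- 1 / n
    var_v <- sum(gv_a1^2 * cov1$var_a) + sum(gv_b1^2 * cov1$var_b) +
      sum(gv_a2^2 * cov2$var_a) + sum(gv_b2^2 * cov2$var_b) +
      2 * sum(gv_a1 * gv_b1 * cov1$cov_ab) +
      2 * sum(gv_a2 * gv_b2 * cov2$cov_ab)
    se_u <- sqrt(var_u); se_v <- sqrt(var_v)
  }
  new_pooled_link("mean_mean", u = u, se_u = se_u, v = v, se_v = se_v,
                  details = list(n_items = n))
}

#' @rdname mean_mean
#' @export
mean_sigma <- function(source, target, cov_source = NULL, cov_target = NULL,
                       mode = c("items", "persons")) {
  mode <- match.arg(mode)
  if (mode == "persons") {
    th1 <- source; th2 <- target
    if (sd_pop(th1) == 0) {
      abort("Zero dispersion of source abilities.",
            class = "irtlink_domain_error")
    }
    u <- sd_pop(th2) / sd_pop(th1)
    v <- mean(th2) - u * mean(th1)
    return(new_pooled_link("mean_sigma_persons", u = u, se_u = NULL,
                           v = v, se_v = NULL,
                           details = list(n_persons = length(th1))))
  }
  source <- validate_items(source, require_id = TRUE)
  target <- validate_items(target, require_id = TRUE)
  joined <- inner_join(source, target, by = "item_id", suffix = c("_1", "_2"))
  n <- nrow(joined)
  b1 <- joined$b_1; b2 <- joined$b_2
  s1 <- sd_pop(b1); s2 <- sd_pop(b2)
  if (s1 == 0) {
    abort("Zero dispersion of source difficulties.",
          class = "irtlink_domain_error")
  }
  u <- s2 / s1
  v <- mean(b2) - u * mean(b1)
  se_u <- se_v <- NULL
  if (!is.null(cov_source) && !is.null(cov_target)) {
    cov1 <- check_cov_table(cov_source, "cov_source")
    cov2 <- check_cov_table(cov_target, "cov_target")
    cov1 <- cov1[match(joined$item_id, cov1$item_id), ]
    cov2 <- cov2[match(joined$item_id, cov2$item_id), ]
    # d sigma(b)/d b_i = (b_i - mu(b)) / (n sigma(b)), population SD
    gu_b1 <- -s2 / s1^2 * (b1 - mean(b1)) / (n * s1)
    gu_b2 <- (b2 - mean(b2)) / (n * s2) / s1
    var_u <- sum(gu_b1^2 * cov1$var_b) + sum(gu_b2^2 * cov2$var_b)
    gv_b1 <- -gu_b1 * mean(b1) - u / n
    gv_b2 <- 1 / n - gu_b2 * mean(b1)
    var_v <- sum(gv_b1^2 * cov1$var_b) + sum(gv_b2^2 * cov2$var_b)
    se_u <- sqrt(var_u); se_v <- sqrt(var_v)
  }
  new_pooled_link("mean_sigma", u = u, se_u = se_u, v = v, se_v = se_v,
                  details = list(n_items = n))
}

sd_pop <- function(x) sqrt(mean((x - mean(x))^2))

#' @rdname mean_mean
#' @export
log_mean_mean <- function(source, target) {
  source <- validate_items(source, require_id = TRUE)
  target <- validate_items(target, require_id = TRUE)
  joined <- inner_join(source, target, by = "item_id", suffix = c("_1", "_2"))
  if (any(joined$a_1 <= 0) || any(joined$a_2 <= 0)) {
    abort("Geometric means require positive discriminations.",
          class = "irtlink_domain_error")
  }
  u <- exp(mean(log(joined$a_1)) - mean(log(joined$a_2)))
  v <- mean(joined$b_2) - u * mean(joined$b_1)
  new_pooled_link("log_mean_mean", u = u, se_u = NULL, v = v, se_v = NULL,
                  details = list(n_items = nrow(joined)))
}

#' Response-function linking estimators (Stocking-Lord and Haebara)
#'
#' Finds `(u, v)` by matching item response functions of the common items
#' over an ability grid. The Stocking-Lord criterion is the squared
#' difference of the *summed* response functions,
#' \deqn{\sum_q \left[\sum_i p(\theta_q; a_{i,2}, b_{i,2}, c_{i,2}) -
#'  \sum_i p(\theta_q; a_{i,1}/u,\; u b_{i,1} + v,\; c_{i,1})\right]^2,}
#' while the Haebara variant sums squared per-item differences. Minimized by
#' bounded derivative-free optimization (`optim`, L-BFGS-B) with
#' `u` in (0.1, 10), `v` in (-5, 5), start (1, 0). Because the criterion
#' involves the asymptotes, estimation error in `c` contaminates these
#' estimators even though `c` itself links by the identity.
#'
#' @inheritParams per_item_links
#' @param theta_grid Ability grid for the criterion; default 41 equispaced
#'   points on `[-4, 4]` with unit weights.
#' @param criterion `"stocking_lord"` or `"haebara"`.
#' @return A `pooled_link` object; `details` carries the criterion value and
#'   optimizer diagnostics.
#' @export
stocking_lord <- function(source, target, theta_grid = seq(-4, 4, length.out = 41),
                          criterion = c("stocking_lord", "haebara")) {
  criterion <- match.arg(criterion)
  source <- validate_items(source, require_id = TRUE)
  target <- validate_items(target, require_id = TRUE)
  if (length(theta_grid) == 0) {
    abort("`theta_grid` must be nonempty.", class = "irtlink_validation_error")
  }
  joined <- inner_join(source, target, by = "item_id", suffix = c("_1", "_2"))
  tgt_items <- tibble(a = joined$a_2, b = joined$b_2, c = joined$c_2)
  p_target <- irf_matrix(tgt_items, theta_grid)  # I x Q
  objective <- function(par) {
    u <- par[1]; v <- par[2]
    src <- tibble(a = joined$a_1 / u, b = u * joined$b_1 + v, c = joined$c_1)
    p_source <- irf_matrix(src, theta_grid)
    if (criterion == "stocking_lord") {
      sum((colSums(p_target) - colSums(p_source))^2)
    } else {
      sum((p_target - p_source)^2)
    }
  }
  fit <- suppressWarnings(optim(c(1, 0), objective, method = "L-BFGS-B",
                                lower = c(0.1, -5), upper = c(10, 5)))
  if (fit$convergence != 0) {
    # L-BFGS-B can stop abnormally when started at (or very near) the
    # minimum; retry derivative-free from the same start with a box penalty
    penalized <- function(par) {
      if (par[1] < 0.1 || par[1] > 10 || par[2] < -5 || par[2] > 5) {
        return(1e12)
      }
      objective(par)
    }
    nm <- optim(c(1, 0), penalized, method = "Nelder-Mead",
                control = list(reltol = 1e-14, maxit = 2000))
    if (nm$value <= fit$value) fit <- nm
    if (fit$convergence != 0 && fit$value > 1e-10) {
      abort(paste0("Response-function criterion failed to converge: ",
                   fit$message %||% paste("code", fit$convergence)),
            class = "irtlink_optim_error")
    }
  }
  new_pooled_link(criterion, u = fit$par[1], se_u = NULL,
                  v = fit$par[2], se_v = NULL,
                  details = list(value = fit$value,
                                 counts = fit$counts,
                                 n_items = nrow(joined)))
}

#' Standard-error trajectories as common items are added
#'
#' Rebuilds the pooled estimates using the first `k` items of a given order,
#' for `k = 1, ..., n`, tracing how each method's standard errors shrink as
#' the linking design grows. The precision-weighted standard errors are
#' monotone nonincreasing by construction, and the full-design (`k = n`) row
#' is identical for every order.
#'
#' @param per_item Per-item estimates with standard errors (for the
#'   precision-weighted method).
#' @param order Integer permutation of `seq_len(nrow(per_item))` giving the
#'   order in which items join the design; defaults to table order.
#' @param source,target,cov_source,cov_target Item and covariance tables,
#'   required for the `"mean_mean"` and `"mean_sigma"` methods.
#' @param methods Character subset of `c("precision_weighted", "mean_mean",
#'   "mean_sigma")`.
#' @return A tibble with columns `n_items`, `method`, `u`, `se_u`, `v`,
#'   `se_v`.
#' @export
sequential_se_curve <- function(per_item, order = seq_len(nrow(per_item)),
                                source = NULL, target = NULL,
                                cov_source = NULL, cov_target = NULL,
                                methods = "precision_weighted") {
  if (anyDuplicated(order) || !setequal(order, seq_len(nrow(per_item)))) {
    abort("`order` must be a permutation of the item rows.",
          class = "irtlink_validation_error")
  }
  methods <- match.arg(methods, c("precision_weighted", "mean_mean",
                                  "mean_sigma"), several.ok = TRUE)
  needs_tables <- any(methods %in% c("mean_mean", "mean_sigma"))
  if (needs_tables && (is.null(source) || is.null(target))) {
    abort("`source`/`target` tables are required for the moment methods.",
          class = "irtlink_validation_error")
  }
  purrr::map_dfr(seq_along(order), function(k) {
    ids <- per_item$item_id[order[seq_len(k)]]
    rows <- list()
    if ("precision_weighted" %in% methods) {
      fit <- pool_precision_weighted(
        per_item[per_item$item_id %in% ids, , drop = FALSE])
      rows <- c(rows, list(glance(fit)))
    }
    if (k >= 2 && "mean_mean" %in% methods) {
      fit <- mean_mean(source[source$item_id %in% ids, ],
                       target[target$item_id %in% ids, ],
                       cov_source, cov_target)
      rows <- c(rows, list(glance(fit)))
    }
    if (k >= 2 && "mean_sigma" %in% methods) {
      fit <- mean_sigma(source[source$item_id %in% ids, ],
                        target[target$item_id %in% ids, ],
                        cov_source, cov_target)
      rows <- c(rows, list(glance(fit)))
    }
    mutate(bind_rows(rows), n_items = k, .before = 1)
  }) |>
    select("n_items", "method", "u", "se_u", "v", "se_v")
}

#' Plot sequential standard-error curves
#'
#' @param curves Tibble from [sequential_se_curve()].
#' @return A ggplot of `se_u` and `se_v` against the number of common items,
#'   one line type per method.
#' @export
plot_se_curves <- function(curves) {
  long <- tidyr::pivot_longer(curves, c("se_u", "se_v"),
                              names_to = "parameter", values_to = "se")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$n_items, y = .data$se,
                                     linetype = .data$method)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::facet_wrap(~parameter, scales = "free_y") +
    ggplot2::labs(x = "number of common items", y = "standard error")
}
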