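#' Normal quadrature grid for marginal likelihood integration
#'
#' Equispaced nodes with normalized standard-normal masses, the standard
#' Bock-Aitkin device for integrating the ability distribution out of the
#' likelihood.
#'
#' @param n_nodes Number of nodes (default 61).
#' @param range Node range (default `c(-5, 5)`).
#' @param mean,sd Mean and SD of the normal density placed on the grid.
#' @return A list with `nodes` and `weights` (weights sum to 1).
#' @export
normal_quadrature <- function(n_nodes = 61, range = c(-5, 5), mean = 0,
                              sd = 1) {
  nodes <- seq(range[1], range[2], length.out = n_nodes)
  w <- dnorm(nodes, mean, sd)
  list(nodes = nodes, weights = w / sum(w))
}

default_em_control <- function() {
  list(tol = 1e-4, max_cycles = 500L, n_nodes = 61L, node_range = c(-5, 5),
       a_bounds = c(0.05, 5), c_bounds = c(0.001, 0.5), b_bounds = c(-6, 6),
       c_prior = NULL, prob_floor = 1e-10)
}

#' Marginal maximum likelihood calibration of the 2PL/3PL model
#'
#' Two-stage calibration: item parameters are estimated by marginal maximum
#' likelihood with the abilities integrated over a standard-normal
#' distribution (the de facto identifiability restriction
#' \eqn{\mu_\theta = 0, \sigma_\theta = 1}), via a Bock-Aitkin EM algorithm
#' on an equispaced quadrature grid; abilities are then estimated per person
#' by EAP given the item estimates. Because of the restriction, the
#' estimates converge not to the generating values but to their re-expression
#' on the calibration's own scale -- the differential effect that parameter
#' linking must undo.
#'
#' The unpenalized 3PL likelihood is poorly behaved in the asymptotes, so for
#' `model = "3pl"` a weak logit-normal prior on `c` (mode at `c_prior_mean`)
#' is applied by default, together with box constraints on all parameters;
#' for `model = "2pl"` the asymptote is fixed at 0 and no prior is used.
#'
#' @param responses P x I matrix of 0/1 responses (columns are items; column
#'   names, when present, become item ids). Items answered all-0 or all-1 are
#'   rejected.
#' @param model `"2pl"` or `"3pl"`.
#' @param c_prior_mean Prior mode for `c` under `model = "3pl"`; set to
#'   `NULL` to disable the prior.
#' @param c_prior_sd Logit-scale prior SD (weak default 1).
#' @param control List overriding entries of the default control: `tol`
#'   (max absolute parameter change, default 1e-4), `max_cycles` (500),
#'   `n_nodes` (61), `node_range` (`c(-5, 5)`), parameter bounds, and
#'   `prob_floor`.
#' @return An object of class `calibration`: a list with `items` (tibble of
#'   `item_id`, `a`, `b`, `c`), `item_cov` (per-item covariance tibble from
#'   the inverse expected-information blocks), `abilities` (EAP tibble),
#'   `loglik` (marginal log-likelihood trace), `converged`, `cycles`,
#'   `model`, and `prior` info.
#' @export
mml_em_3pl <- function(responses, model = c("3pl", "2pl"),
                       c_prior_mean = 0.25, c_prior_sd = 1,
                       control = list()) {
  model <- match.arg(model)
  ctrl <- utils::modifyList(default_em_control(), control)
  u <- as.matrix(responses)
  storage.mode(u) <- "double"
  if (nrow(u) < 2 || ncol(u) < 2) {
    abort("Need at least 2 persons and 2 items.",
          class = "irtlink_validation_error")
  }
  if (!all(u %in% c(0, 1))) {
    abort("`responses` must contain only 0 and 1.",
          class = "irtlink_validation_error")
  }
  pbar <- colMeans(u)
  if (any(pbar == 0) || any(pbar == 1)) {
    abort("Constant (all-0 or all-1) items cannot be calibrated.",
          class = "irtlink_validation_error")
  }
  item_ids <- colnames(u) %||% as.character(seq_len(ncol(u)))
  n_items <- ncol(u)
  quad <- normal_quadrature(ctrl$n_nodes, ctrl$node_range)
  use_prior <- model == "3pl" && !is.null(c_prior_mean)
  prior_mu <- if (use_prior) qlogis(c_prior_mean) else NA_real_

  # start values: slope 1, difficulty from the inverse logistic of p-values
  a <- rep(1, n_items)
  b <- -qlogis(pmin(pmax(pbar, 0.02), 0.98))
  c_ <- if (model == "3pl") rep(0.2, n_items) else rep(0, n_items)

  loglik_trace <- numeric(0)
  converged <- FALSE
  log_w <- log(quad$weights)
  floor_ <- ctrl$prob_floor

  for (cycle in seq_len(ctrl$max_cycles)) {
    items_now <- tibble(a = a, b = b, c = c_)
    p_iq <- irf_matrix(items_now, quad$nodes)
    p_iq <- pmin(pmax(p_iq, floor_), 1 - floor_)
    lp <- log(p_iq); lq <- log1p(-p_iq)
    # P x Q person-node log-likelihood, then posterior weights
    ll_pq <- u %*% lp + (1 - u) %*% lq
    ll_pq <- sweep(ll_pq, 2, log_w, "+")
    m <- apply(ll_pq, 1, max)
    post <- exp(ll_pq - m)
    denom <- rowSums(post)
    loglik <- sum(log(denom) + m)
    if (use_prior) {
      # the EM ascent property holds for the penalized marginal likelihood
      loglik <- loglik - sum((qlogis(c_) - prior_mu)^2 / (2 * c_prior_sd^2))
    }
    post <- post / denom
    loglik_trace <- c(loglik_trace, loglik)

    n_q <- colSums(post)             # expected persons per node
    r_iq <- crossprod(u, post)       # I x Q expected correct per node

    a_old <- a; b_old <- b; c_old <- c_
    for (i in seq_len(n_items)) {
      fit <- mstep_item(quad$nodes, n_q, r_iq[i, ], a[i], b[i], c_[i],
                        model, ctrl, use_prior, prior_mu, c_prior_sd)
      a[i] <- fit[1]; b[i] <- fit[2]; c_[i] <- fit[3]
    }
    delta <- max(abs(c(a - a_old, b - b_old, c_ - c_old)))
    if (delta < ctrl$tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warn(paste0("EM did not reach tol ", format(ctrl$tol), " within ",
                ctrl$max_cycles, " cycles (last change ",
                format(delta, digits = 3), "); result flagged."))
  }
  boundary <- c_ >= ctrl$c_bounds[2] - 1e-8
  if (model == "3pl" && any(boundary)) {
    warn(paste0("Asymptote estimate at the upper bound for item(s): ",
                paste(item_ids[boundary], collapse = ", ")))
  }

  items <- tibble(item_id = item_ids, a = a, b = b, c = c_)
  # posterior node weights at the final estimates, for the information
  p_iq <- pmin(pmax(irf_matrix(items, quad$nodes), floor_), 1 - floor_)
  ll_pq <- sweep(u %*% log(p_iq) + (1 - u) %*% log1p(-p_iq), 2, log_w, "+")
  m <- apply(ll_pq, 1, max)
  post <- exp(ll_pq - m)
  post <- post / rowSums(post)
  item_cov <- item_information_cov(items, quad, u, post, p_iq, model)
  abilities <- eap_abilities(u, items, quad)
  structure(list(items = items, item_cov = item_cov, abilities = abilities,
                 loglik = loglik_trace, converged = converged,
                 cycles = length(loglik_trace), model = model,
                 prior = list(used = use_prior, c_prior_mean = c_prior_mean,
                              c_prior_sd = c_prior_sd),
                 quadrature = quad),
            class = "calibration")
}

# per-item M-step: maximize expected Bernoulli log-likelihood on the grid
mstep_item <- function(nodes, n_q, r_q, a0, b0, c0, model, ctrl,
                       use_prior, prior_mu, prior_sd) {
  npar <- if (model == "3pl") 3L else 2L
  obj <- function(par) {
    a <- par[1]; b <- par[2]; c_ <- if (npar == 3L) par[3] else 0
    p <- c_ + (1 - c_) * plogis(a * (nodes - b))
    p <- pmin(pmax(p, ctrl$prob_floor), 1 - ctrl$prob_floor)
    val <- -sum(r_q * log(p) + (n_q - r_q) * log1p(-p))
    if (use_prior && npar == 3L) {
      val <- val + (qlogis(c_) - prior_mu)^2 / (2 * prior_sd^2)
    }
    val
  }
  gr <- function(par) {
    a <- par[1]; b <- par[2]; c_ <- if (npar == 3L) par[3] else 0
    psi <- plogis(a * (nodes - b))
    p <- c_ + (1 - c_) * psi
    p <- pmin(pmax(p, ctrl$prob_floor), 1 - ctrl$prob_floor)
    w <- (r_q - n_q * p) / (p * (1 - p))
    dpsi <- psi * (1 - psi)
    g_a <- -sum(w * (1 - c_) * dpsi * (nodes - b))
    g_b <- sum(w * (1 - c_) * dpsi * a)
    if (npar == 2L) return(c(g_a, g_b))
    g_c <- -sum(w * (1 - psi))
    if (use_prior) {
      g_c <- g_c + (qlogis(c_) - prior_mu) / (prior_sd^2 * c_ * (1 - c_))
    }
    c(g_a, g_b, g_c)
  }
  lower <- c(ctrl$a_bounds[1], ctrl$b_bounds[1], ctrl$c_bounds[1])[seq_len(npar)]
  upper <- c(ctrl$a_bounds[2], ctrl$b_bounds[2], ctrl$c_bounds[2])[seq_len(npar)]
  start <- pmin(pmax(c(a0, b0, c0)[seq_len(npar)], lower), upper)
  fit <- optim(start, obj, gr, method = "L-BFGS-B", lower = lower,
               upper = upper, control = list(maxit = 30))
  out <- fit$par
  # guard the EM ascent property: never accept a worse point than the start
  if (fit$value > obj(start)) out <- start
  c(out, if (npar == 2L) 0)
}

# block-diagonal per-item covariances from the cross-product (empirical
# Fisher) information: sum over persons of the outer products of the
# per-person marginal score vectors, with the ability integrated over the
# quadrature posterior. Unlike the complete-data information, this accounts
# for the posterior uncertainty in the abilities.
item_information_cov <- function(items, quad, u, post, p_iq, model) {
  npar <- if (model == "3pl") 3L else 2L
  purrr::map_dfr(seq_len(nrow(items)), function(i) {
    a <- items$a[i]; b <- items$b[i]; c_ <- items$c[i]
    psi <- plogis(a * (quad$nodes - b))
    p <- pmin(pmax(p_iq[i, ], 1e-10), 1 - 1e-10)
    dpsi <- psi * (1 - psi)
    g <- cbind(a = (1 - c_) * dpsi * (quad$nodes - b),
               b = -(1 - c_) * dpsi * a,
               c = 1 - psi)[, seq_len(npar), drop = FALSE]
    w <- g / (p * (1 - p))              # Q x npar
    s <- u[, i] * (post %*% w) - post %*% (p * w)  # P x npar score matrix
    info <- crossprod(s)
    cov <- tryCatch(solve(info), error = function(e) {
      warn(paste0("Singular information for item ", items$item_id[i],
                  "; covariances set to NA."))
      matrix(NA_real_, npar, npar)
    })
    tibble(item_id = items$item_id[i],
           var_a = cov[1, 1], var_b = cov[2, 2],
           var_c = if (npar == 3L) cov[3, 3] else 0,
           cov_ab = cov[1, 2],
           cov_ac = if (npar == 3L) cov[1, 3] else 0,
           cov_bc = if (npar == 3L) cov[2, 3] else 0)
  })
}

#' @export
print.calibration <- function(x, ...) {
  cat("<calibration>", x$model, "MML-EM,", nrow(x$items), "items,",
      nrow(x$abilities), "persons\n")
  cat("  cycles:", x$cycles, " converged:", x$converged,
      " final loglik:", format(tail(x$loglik, 1), digits = 8), "\n")
  if (x$prior$used) {
    cat("  logit-normal prior on c: mode", x$prior$c_prior_mean,
        "sd", x$prior$c_prior_sd, "\n")
  }
  invisible(x)
}

#' @export
tidy.calibration <- function(x, ...) {
  left_join(x$items, x$item_cov, by = "item_id") |>
    mutate(se_a = sqrt(.data$var_a), se_b = sqrt(.data$var_b),
           se_c = sqrt(.data$var_c)) |>
    select("item_id", "a", "se_a", "b", "se_b", "c", "se_c")
}

#' @export
glance.calibration <- function(x, ...) {
  tibble(model = x$model, n_items = nrow(x$items),
         n_persons = nrow(x$abilities), cycles = x$cycles,
         converged = x$converged, loglik = tail(x$loglik, 1))
}

#' Expected a posteriori ability estimates
#'
#' Posterior mean of ability per person under a normal prior on the
#' quadrature grid, given calibrated item parameters.
#'
#' @param responses P x I 0/1 matrix.
#' @param items Calibrated item table (`a`, `b`, `c`).
#' @param quad Quadrature grid from [normal_quadrature()].
#' @return A tibble with columns `person`, `theta` (EAP), `se` (posterior
#'   SD).
#' @export
eap_abilities <- function(responses, items,
                          quad = normal_quadrature()) {
  u <- as.matrix(responses)
  items <- validate_items(items)
  p_iq <- pmin(pmax(irf_matrix(items, quad$nodes), 1e-12), 1 - 1e-12)
  ll_pq <- u %*% log(p_iq) + (1 - u) %*% log1p(-p_iq)
  ll_pq <- sweep(ll_pq, 2, log(quad$weights), "+")
  m <- apply(ll_pq, 1, max)
  post <- exp(ll_pq - m)
  post <- post / rowSums(post)
  eap <- as.vector(post %*% quad$nodes)
  psd <- sqrt(pmax(as.vector(post %*% quad$nodes^2) - eap^2, 0))
  tibble(person = seq_len(nrow(u)), theta = eap, se = psd)
}
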