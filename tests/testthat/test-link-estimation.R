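tbls <- load_example_tables()

test_that("per-item links reproduce the published worked-example estimates", {
  per_item <- per_item_links(tbls$cal1, tbls$cal2)
  expect_equal(nrow(per_item), 20)
  expect_equal(round(per_item$u[per_item$item_id == "11"], 3), 1.372)
  expect_equal(round(per_item$u, 3), tbls$published$u)
  expect_equal(round(per_item$v, 3), tbls$published$v)
  # identical calibrations give the identity link for every item
  same <- per_item_links(tbls$cal1, tbls$cal1)
  expect_equal(same$u, rep(1, 20))
  expect_equal(same$v, rep(0, 20))
  # a noise-free transformed table returns the true link in every row
  truth <- linear_link(1.31, -0.42)
  moved <- apply_link(tbls$cal1, truth)
  est <- per_item_links(tbls$cal1, moved)
  expect_equal(est$u, rep(truth$u, 20), tolerance = 1e-12)
  expect_equal(est$v, rep(truth$v, 20), tolerance = 1e-12)
  expect_error(per_item_links(tbls$cal1,
                              dplyr::mutate(tbls$cal2,
                                            item_id = paste0("x", item_id))),
               class = "irtlink_join_error")
})

test_that("delta-method standard errors propagate the printed covariances", {
  per_item <- per_item_links(tbls$cal1, tbls$cal2, tbls$cov1, tbls$cov2)
  # the published SEs were computed from unrounded covariances; ours from the
  # printed 3-decimal ones. Each published SE must lie in the interval that
  # half-unit perturbations of every printed covariance entry can produce.
  expect_lt(abs(per_item$se_u[1] - 0.105), 0.002)
  expect_lt(abs(per_item$se_v[1] - 0.104), 0.003)
  for (i in seq_len(20)) {
    lo_cov1 <- dplyr::mutate(tbls$cov1, var_a = pmax(var_a - 5e-4, 0),
                             var_b = pmax(var_b - 5e-4, 0))
    hi_cov1 <- dplyr::mutate(tbls$cov1, var_a = var_a + 5e-4,
                             var_b = var_b + 5e-4)
    lo_cov2 <- dplyr::mutate(tbls$cov2, var_a = pmax(var_a - 5e-4, 0),
                             var_b = pmax(var_b - 5e-4, 0))
    hi_cov2 <- dplyr::mutate(tbls$cov2, var_a = var_a + 5e-4,
                             var_b = var_b + 5e-4)
    lo <- suppressWarnings(
      delta_se_per_item(per_item[i, ], tbls$cal1, tbls$cal2, lo_cov1, lo_cov2))
    hi <- suppressWarnings(
      delta_se_per_item(per_item[i, ], tbls$cal1, tbls$cal2, hi_cov1, hi_cov2))
    expect_gte(tbls$published$se_u[i], lo$se_u - 1e-3)
    expect_lte(tbls$published$se_u[i], hi$se_u + 1e-3)
  }
  # zero covariances give zero SEs
  zero1 <- dplyr::mutate(tbls$cov1, dplyr::across(-item_id, ~0))
  zero2 <- dplyr::mutate(tbls$cov2, dplyr::across(-item_id, ~0))
  z <- delta_se_per_item(per_item_links(tbls$cal1, tbls$cal2),
                         tbls$cal1, tbls$cal2, zero1, zero2)
  expect_equal(z$se_u, rep(0, 20))
  expect_equal(z$se_v, rep(0, 20))
  expect_error(delta_se_per_item(per_item, tbls$cal1, tbls$cal2,
                                 tbls$cov1[-1, ], tbls$cov2),
               class = "irtlink_validation_error")
})

test_that("delta-method SEs agree with a parametric Monte-Carlo oracle", {
  # one mid-range item at covariance magnitudes of the worked example
  i <- 5
  per_item <- per_item_links(tbls$cal1, tbls$cal2, tbls$cov1, tbls$cov2)
  n_draws <- 20000
  set.seed(30)
  draw <- function(mean_a, mean_b, cv) {
    m <- matrix(c(cv$var_a, cv$cov_ab, cv$cov_ab, cv$var_b), 2, 2)
    ch <- chol(m)
    z <- matrix(rnorm(2 * n_draws), n_draws, 2) %*% ch
    cbind(a = mean_a + z[, 1], b = mean_b + z[, 2])
  }
  d1 <- draw(tbls$cal1$a[i], tbls$cal1$b[i], tbls$cov1[i, ])
  d2 <- draw(tbls$cal2$a[i], tbls$cal2$b[i], tbls$cov2[i, ])
  u_draws <- d1[, "a"] / d2[, "a"]
  v_draws <- d2[, "b"] - u_draws * d1[, "b"]
  expect_equal(per_item$se_u[i], sd(u_draws), tolerance = 0.05)
  expect_equal(per_item$se_v[i], sd(v_draws), tolerance = 0.05)
})

test_that("precision-weighted pooling follows the inverse-variance formulas", {
  per_item <- per_item_links(tbls$cal1, tbls$cal2, tbls$cov1, tbls$cov2)
  pw <- pool_precision_weighted(per_item)
  expect_equal(round(pw$u, 3), 1.226)
  expect_lt(abs(pw$se_u - 0.026), 0.002)
  expect_lt(abs(pw$se_v - 0.023), 0.002)
  # pooled SE can never exceed any per-item SE
  expect_lte(pw$se_u, min(per_item$se_u))
  expect_lte(pw$se_v, min(per_item$se_v))
  # single item: pooled equals that item
  one <- pool_precision_weighted(per_item[3, ])
  expect_equal(c(one$u, one$se_u, one$v, one$se_v),
               c(per_item$u[3], per_item$se_u[3], per_item$v[3],
                 per_item$se_v[3]))
  # equal SEs reduce the pooled estimate to the arithmetic mean
  eq <- dplyr::mutate(per_item, se_u = 0.1, se_v = 0.2)
  pooled_eq <- pool_precision_weighted(eq)
  expect_equal(pooled_eq$u, mean(per_item$u))
  expect_equal(pooled_eq$v, mean(per_item$v))
  expect_error(pool_precision_weighted(dplyr::mutate(per_item, se_u = 0)),
               class = "irtlink_validation_error")
  # broom-style accessors
  td <- tidy(pw)
  expect_equal(td$term, c("u", "v"))
  expect_equal(glance(pw)$method, "precision_weighted")
})

test_that("moment methods reproduce the worked example and recover exactly", {
  mm <- mean_mean(tbls$cal1, tbls$cal2, tbls$cov1, tbls$cov2)
  expect_equal(round(mm$u, 3), 1.237)
  expect_lt(abs(mm$se_u - 0.027), 0.002)
  expect_equal(round(mm$v, 3), -0.706)
  expect_lt(abs(mm$se_v - 0.078), 0.002)
  ms <- mean_sigma(tbls$cal1, tbls$cal2, tbls$cov1, tbls$cov2)
  expect_equal(round(ms$u, 3), 1.197)
  expect_lt(abs(ms$se_u - 0.118), 0.002)
  expect_equal(round(ms$v, 3), -0.696)
  expect_lt(abs(ms$se_v - 0.084), 0.002)

  # identity on identical tables
  expect_equal(c(mean_mean(tbls$cal1, tbls$cal1)$u,
                 mean_mean(tbls$cal1, tbls$cal1)$v), c(1, 0))
  expect_equal(c(mean_sigma(tbls$cal1, tbls$cal1)$u,
                 mean_sigma(tbls$cal1, tbls$cal1)$v), c(1, 0))
  expect_equal(c(log_mean_mean(tbls$cal1, tbls$cal1)$u,
                 log_mean_mean(tbls$cal1, tbls$cal1)$v), c(1, 0))

  # exact recovery on a noise-free transformed table
  truth <- linear_link(1.7, 0.35)
  moved <- apply_link(tbls$cal1, truth)
  for (fit in list(mean_mean(tbls$cal1, moved), mean_sigma(tbls$cal1, moved),
                   log_mean_mean(tbls$cal1, moved))) {
    expect_equal(c(fit$u, fit$v), c(truth$u, truth$v), tolerance = 1e-12)
  }
  # difficulties scaled and shifted: moments respond affinely
  doubled <- dplyr::mutate(tbls$cal1, b = 2 * b + 0.3)
  ms2 <- mean_sigma(tbls$cal1, doubled)
  expect_equal(c(ms2$u, ms2$v), c(2, 0.3), tolerance = 1e-12)
  # geometric and arithmetic slopes coincide for constant discriminations
  const_a <- dplyr::mutate(tbls$cal1, a = 1.3)
  expect_equal(log_mean_mean(const_a, const_a)$u, mean_mean(const_a, const_a)$u)
  # person-mode mean/sigma
  th1 <- rnorm(50); th2 <- 1.5 * th1 - 0.2
  msp <- mean_sigma(th1, th2, mode = "persons")
  expect_equal(c(msp$u, msp$v), c(1.5, -0.2), tolerance = 1e-10)
})

test_that("response-function criteria recover noise-free links and expose
           their sensitivity to the asymptotes", {
  truth <- linear_link(1.4, -0.6)
  moved <- apply_link(tbls$cal1, truth)
  sl <- stocking_lord(tbls$cal1, moved)
  expect_equal(c(sl$u, sl$v), c(truth$u, truth$v), tolerance = 1e-6)
  expect_lt(sl$details$value, 1e-10)
  hb <- stocking_lord(tbls$cal1, moved, criterion = "haebara")
  expect_equal(c(hb$u, hb$v), c(truth$u, truth$v), tolerance = 1e-6)
  ident <- stocking_lord(tbls$cal1, tbls$cal1)
  expect_equal(c(ident$u, ident$v), c(1, 0), tolerance = 1e-6)

  # perturbing the target asymptotes biases the response-function estimate
  # while the per-item identification of (u, v) is untouched
  set.seed(31)
  perturbed <- dplyr::mutate(moved, c = pmin(pmax(c + runif(20, -0.1, 0.1),
                                                  0.01), 0.6))
  sl_pert <- stocking_lord(tbls$cal1, perturbed)
  expect_gt(abs(sl_pert$u - truth$u) + abs(sl_pert$v - truth$v), 1e-4)
  per_item <- per_item_links(tbls$cal1, perturbed)
  expect_equal(per_item$u, rep(truth$u, 20), tolerance = 1e-12)
  expect_equal(per_item$v, rep(truth$v, 20), tolerance = 1e-12)
})

test_that("sequential SE curves shrink monotonically to an order-invariant
           endpoint", {
  per_item <- per_item_links(tbls$cal1, tbls$cal2, tbls$cov1, tbls$cov2)
  curve <- sequential_se_curve(per_item)
  expect_equal(nrow(curve), 20)
  expect_equal(curve$u[1], per_item$u[1])
  expect_equal(curve$se_u[1], per_item$se_u[1])
  expect_true(all(diff(curve$se_u) <= 1e-12))
  expect_true(all(diff(curve$se_v) <= 1e-12))
  set.seed(32)
  for (rep in 1:3) {
    ord <- sample(20)
    shuffled <- sequential_se_curve(per_item, ord)
    expect_true(all(diff(shuffled$se_u) <= 1e-12))
    expect_equal(shuffled$se_u[20], curve$se_u[20], tolerance = 1e-12)
    expect_equal(shuffled$u[20], curve$u[20], tolerance = 1e-12)
  }
  # all three methods: shape contract 20 rows x 3 methods (moment methods
  # defined from k = 2)
  full <- sequential_se_curve(per_item, seq_len(20), tbls$cal1, tbls$cal2,
                              tbls$cov1, tbls$cov2,
                              methods = c("precision_weighted", "mean_mean",
                                          "mean_sigma"))
  expect_equal(nrow(full), 20 + 19 + 19)
  expect_equal(round(full$se_u[full$method == "precision_weighted" &
                                 full$n_items == 20], 3), 0.026)
  expect_error(sequential_se_curve(per_item, c(1, 1, 3:20)),
               class = "irtlink_validation_error")
})
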