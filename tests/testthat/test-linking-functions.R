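test_that("applying a link transforms parameters and preserves probabilities", {
  it <- tibble::tibble(a = 1.4, b = 0.6, c = 0.2)
  expect_equal(apply_link(it, linear_link(1, 0)), it)
  # worked-example common item 1: calibration 1 -> calibration 2
  item1 <- tibble::tibble(a = 2.612, b = -0.843, c = 0.213)
  moved <- apply_link(item1, linear_link(1.208, -0.707))
  expect_equal(round(moved$b, 3), -1.725)
  expect_equal(moved$c, item1$c)

  set.seed(20)
  th <- seq(-4, 4, length.out = 101)
  for (rep in 1:10) {
    item <- random_items(1)
    lk <- random_link()
    starred <- apply_link(item, lk)
    expect_identical(starred$c, item$c)
    expect_equal(prob_3pl(apply_link_theta(th, lk), starred$a, starred$b,
                          starred$c),
                 prob_3pl(th, item$a, item$b, item$c), tolerance = 1e-12)
  }
  expect_error(linear_link(-2, 0), class = "irtlink_validation_error")
})

test_that("link inversion and composition follow the affine algebra", {
  inv <- invert_link(linear_link(2, 1))
  expect_equal(c(inv$u, inv$v), c(0.5, -0.5))
  lk <- linear_link(1.2, -0.7)
  ident <- compose_links(lk, invert_link(lk))
  expect_equal(c(ident$u, ident$v), c(1, 0), tolerance = 1e-12)
  # ability round trip
  expect_equal(apply_link_theta(apply_link_theta(0.37, lk), invert_link(lk)),
               0.37, tolerance = 1e-12)
  # theta = b degenerate point is preserved under any link
  expect_equal(apply_link_theta(0.6, lk),
               apply_link(tibble::tibble(a = 1, b = 0.6, c = 0), lk)$b)
  # chain of three links equals sequential application
  set.seed(21)
  links <- list(random_link(), random_link(), random_link())
  item <- random_items(1)
  seq_applied <- apply_link(apply_link(apply_link(item, links[[1]]),
                                       links[[2]]), links[[3]])
  chained <- compose_links(compose_links(links[[1]], links[[2]]), links[[3]])
  expect_equal(apply_link(item, chained), seq_applied, tolerance = 1e-12)
})

test_that("one common item identifies the link, source over target", {
  it <- tibble::tibble(a = 1.1, b = 0.3, c = 0.2)
  same <- link_from_one_item(it, it)
  expect_equal(c(same$u, same$v), c(1, 0))
  lk <- link_from_one_item(tibble::tibble(a = 2.612, b = -0.843, c = 0.213),
                           tibble::tibble(a = 2.162, b = -1.725, c = 0.191))
  expect_equal(round(lk$u, 3), 1.208)
  expect_equal(round(lk$v, 3), -0.707)
  # round trip: transform by a known link, then estimate it back
  set.seed(22)
  for (rep in 1:10) {
    item <- random_items(1)
    truth <- random_link()
    est <- link_from_one_item(item, apply_link(item, truth))
    expect_equal(c(est$u, est$v), c(truth$u, truth$v), tolerance = 1e-12)
  }
})

test_that("two common items identify the link through difficulties alone", {
  same <- link_from_two_items_b(c(0, 1), c(0, 1))
  expect_equal(c(same$u, same$v), c(1, 0))
  lk <- link_from_two_items_b(c(-0.843, -0.558), c(-1.725, -1.333))
  expect_equal(round(lk$u, 3), 1.375)
  # with exactly two items the slope makes the two intercept solutions
  # coincide identically, so the cross-check is silent even on estimates
  expect_equal(-1.725 - lk$u * (-0.843), -1.333 - lk$u * (-0.558),
               tolerance = 1e-12)
  set.seed(23)
  for (rep in 1:10) {
    truth <- random_link()
    b1 <- sort(runif(2, -2, 2))
    est <- link_from_two_items_b(b1, truth$u * b1 + truth$v)
    expect_equal(c(est$u, est$v), c(truth$u, truth$v), tolerance = 1e-12)
  }
  expect_error(link_from_two_items_b(c(0.5, 0.5), c(0, 1)),
               class = "irtlink_identifiability_error")
})

test_that("two common persons identify the link; one does not", {
  expect_equal(tidy(link_from_two_persons(c(0, 1), c(0, 1)))$estimate, c(1, 0))
  stretch <- link_from_two_persons(c(-1, 1), c(-2, 2))
  expect_equal(c(stretch$u, stretch$v), c(2, 0))
  set.seed(24)
  for (rep in 1:10) {
    truth <- random_link()
    th <- sort(runif(2, -2, 2))
    est <- link_from_two_persons(th, truth$u * th + truth$v)
    expect_equal(c(est$u, est$v), c(truth$u, truth$v), tolerance = 1e-12)
  }
  expect_error(link_from_two_persons(0.4, 0.9),
               class = "irtlink_identifiability_error")
  expect_error(link_from_two_persons(c(0.4, 0.4), c(0.1, 0.9)),
               class = "irtlink_identifiability_error")
})

test_that("slope-intercept link transforms and identifies from joint designs", {
  items_si <- tibble::tibble(alpha = 1.3, beta = 0.4, c = 0.2)
  ident <- si_apply_link(items_si, 0.7, si_link(0, 1, 1))
  expect_equal(ident$items, items_si)
  expect_equal(ident$vartheta, 0.7)
  expect_equal(ident$residual, 0)
  # c untouched for any link
  any_lk <- si_link(0.4, 1.7, -0.6)
  expect_identical(si_apply_link(items_si, 0.7, any_lk)$items$c, items_si$c)

  # identical calibrations give the identity link
  same <- si_link_from_design(items_si, items_si, 0.7, 0.7)
  expect_equal(c(same$u, same$v, same$w), c(0, 1, 1))

  # scenario built from a known (u, v, w) is recovered exactly and
  # satisfies the invariance identity at the identifying pair
  set.seed(25)
  for (rep in 1:10) {
    truth <- si_link(runif(1, -0.5, 0.5), runif(1, 0.5, 2), runif(1, 0.5, 2))
    src <- tibble::tibble(alpha = runif(1, max(0.1, truth$u + 0.1), 3),
                          beta = runif(1, -1, 1), c = runif(1, 0, 0.3))
    vt1 <- runif(1, max(0.1, truth$u + 0.1), 3)
    tgt <- tibble::tibble(alpha = (src$alpha - truth$u) / truth$v,
                          beta = src$beta + truth$u, c = src$c)
    vt2 <- (vt1 - truth$u) / truth$w
    est <- si_link_from_design(src, tgt, vt1, vt2)
    expect_equal(c(est$u, est$v, est$w), c(truth$u, truth$v, truth$w),
                 tolerance = 1e-12)
    moved <- si_apply_link(src, vt1, est)
    expect_lt(abs(moved$items$alpha * moved$vartheta + moved$items$beta -
                    (tgt$alpha * vt2 + tgt$beta)), 1e-10)
  }

  # item-only or person-only designs are not identified
  expect_error(si_link_from_design(items_si, items_si, NULL, NULL),
               class = "irtlink_identifiability_error")
  expect_error(si_link_from_design(NULL, NULL, 0.5, 0.7),
               class = "irtlink_identifiability_error")
  expect_error(si_link(0, -1, 1), class = "irtlink_validation_error")
  expect_error(si_link(0, 1, 0), class = "irtlink_validation_error")
})
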