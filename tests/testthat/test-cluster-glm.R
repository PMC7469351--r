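test_that("indicator design encodes membership and rejects overlaps", {
  ind <- indicator_matrix(list(1L, c(3L, 4L)), m = 4L)
  expect_equal(ind$z, rbind(c(1L, 0L, 0L, 0L), c(0L, 0L, 1L, 1L)))
  expect_equal(ind$z0, c(0L, 1L, 0L, 0L))

  empty <- indicator_matrix(list(), m = 3L)
  expect_equal(nrow(empty$z), 0L)
  expect_equal(empty$z0, c(1L, 1L, 1L))

  expect_error(indicator_matrix(list(1L, c(1L, 2L)), m = 3L), "disjoint")
})

test_that("null model MLE has the closed-form intercept and likelihood", {
  f1 <- fit_null(case_data(c(2, 2), c(1, 1)))
  expect_equal(f1$alpha, log(2))

  f2 <- fit_null(case_data(c(1, 3), c(2, 2)))
  expect_equal(f2$alpha, 0)

  # pinned against the manual Poisson log-pmf: y = (4,1,1,1), mu0 = 1
  f3 <- fit_null(case_data(c(4, 1, 1, 1), rep(1, 4)))
  expect_equal(f3$loglik, -6.260743314799987, tolerance = 1e-12)

  expect_error(fit_null(case_data(c(0, 0), c(1, 1))), "zero")
})

test_that("multicluster MLE solves the group score equations in closed form", {
  d <- case_data(c(4, 1, 1, 1), rep(1, 4))
  fit <- fit_multicluster(d, list(1L))
  expect_equal(unname(fit$thetas[1]), 4)
  expect_equal(unname(fit$thetas["outside"]), 1)
  expect_equal(unname(fit$betas), log(4))

  # fitted group totals equal observed group totals (score equations)
  set.seed(21)
  for (rep in 1:25) {
    inst <- random_instance(k = 2)
    if (!length(inst$windows)) next
    fit <- suppressWarnings(fit_multicluster(inst$data, inst$windows))
    for (w in inst$windows) {
      expect_equal(sum(fit$fitted[w]), sum(inst$data$observed[w]))
    }
    outside <- setdiff(seq_len(inst$m), unlist(inst$windows))
    expect_equal(sum(fit$fitted[outside]),
                 sum(inst$data$observed[outside]))
  }
})

test_that("window totals equal to expectations give the null fit back", {
  d <- case_data(c(2, 2, 4), c(2, 2, 4))
  fit <- suppressWarnings(fit_multicluster(d, list(1L)))
  expect_equal(unname(fit$betas), 0)
  expect_equal(fit$loglik, fit_null(d)$loglik)
})

test_that("degenerate window sets are rejected", {
  d <- case_data(c(2, 2, 2), c(1, 1, 1))
  expect_error(fit_multicluster(d, list(c(1L, 2L, 3L))), "outside")
  d2 <- case_data(c(2, 2, 0), c(1, 1, 1))
  expect_error(fit_multicluster(d2, list(c(1L, 2L))), "no cases outside")
  # a non-elevated candidate is flagged, not fatal
  d3 <- case_data(c(1, 9, 10), c(5, 5, 5))
  expect_warning(fit_multicluster(d3, list(1L)), "beta <= 0")
})

test_that("closed-form likelihood matches a numeric maximizer", {
  set.seed(33)
  for (rep in 1:40) {
    inst <- random_instance()
    fit <- suppressWarnings(fit_multicluster(inst$data, inst$windows))
    expect_equal(fit$loglik, oracle_loglik(inst$data, inst$windows),
                 tolerance = 1e-8)
  }
})

test_that("single-window likelihood ratio equals the scan LLR on standardized data", {
  set.seed(44)
  for (rep in 1:30) {
    inst <- random_instance(k = 1)
    d <- inst$data
    # standardize expectations to the observed total (conditioning scale)
    d_std <- case_data(d$observed, standardize_expected_for_test(d))
    w <- inst$windows[[1]]
    glm_lr <- loglik_ratio(
      suppressWarnings(fit_multicluster(d_std, list(w))), fit_null(d_std))
    ow <- sum(d_std$observed[w]); ew <- sum(d_std$expected0[w])
    O <- d_std$total_observed
    scan <- poisson_llr(ow, ew, O, O)
    if (ow / ew > (O - ow) / (O - ew)) {
      expect_equal(glm_lr, scan, tolerance = 1e-10)
    } else {
      expect_equal(scan, 0)  # low-rate window suppressed by the scan
      expect_gte(glm_lr, 0)
    }
  }
})

test_that("adding windows never decreases the likelihood (nesting)", {
  set.seed(55)
  for (rep in 1:15) {
    inst <- random_instance(m = 8, k = 2)
    if (length(inst$windows) < 2) next
    d <- inst$data
    l0 <- fit_null(d)$loglik
    l1 <- suppressWarnings(fit_multicluster(d, inst$windows[1]))$loglik
    l2 <- suppressWarnings(fit_multicluster(d, inst$windows))$loglik
    expect_gte(l1, l0 - 1e-12)
    expect_gte(l2, l1 - 1e-12)
  }
})

test_that("planted relative risk is recovered as the theta ratio", {
  set.seed(66)
  map <- synthetic_map(25, "lattice")
  w <- list(c(7L, 8L, 12L, 13L))
  mu0 <- rep(2500, 25)  # window expectation 1e4
  ratios <- replicate(20, {
    rr <- rep(1, 25); rr[w[[1]]] <- 2
    d <- case_data(rpois(25, rr * mu0), mu0)
    fit <- fit_multicluster(d, w)
    unname(fit$thetas[1] / fit$thetas["outside"])
  })
  expect_equal(mean(ratios), 2, tolerance = 0.02)
})

test_that("fit report tabulates per-cluster rates on both scales", {
  d <- case_data(c(8, 2, 2, 2), c(2, 2, 2, 2))
  fit <- fit_multicluster(d, list(1L))
  tab <- fit_report(fit, d)
  expect_equal(tab$observed, 8)
  expect_equal(tab$theta, 4)
  expect_equal(tab$RR, 4)  # theta relative to the outside rate of 1
})
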