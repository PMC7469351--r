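test_that("poisson scan LLR follows the closed form and high-rate rule", {
  # equal inside/outside rates
  expect_equal(poisson_llr(10, 10, 100, 100), 0)
  # low-rate window suppressed
  expect_equal(poisson_llr(5, 10, 100, 100), 0)
  # pinned closed-form value: 20 log 2 + 80 log(80/90)
  expect_equal(poisson_llr(20, 10, 100, 100), 4.440300758688226,
               tolerance = 1e-12)
  # zero-count inside term contributes zero
  expect_equal(poisson_llr(0, 10, 100, 100), 0)
  expect_error(poisson_llr(10, 0, 100, 100), "0 < E_w < E")
  expect_error(poisson_llr(10, 100, 100, 100), "0 < E_w < E")
})

test_that("circular windows enumerate nested distance balls with dedup and cap", {
  map <- toy_map()
  d <- case_data(c(1, 1, 1), c(1, 1, 1))
  wins <- circular_windows(map, d, max_fraction = 0.5)
  keys <- sort(vapply(wins, paste, character(1), collapse = ","))
  # cap 1.5 admits only windows with expected <= 1.5: singletons
  expect_equal(keys, c("1", "2", "3"))

  # brute-force check on distinct distances: centers yield nested prefixes
  map2 <- region_map(c("A", "B", "C", "D"), cbind(c(0, 1, 3, 7), 0))
  d2 <- case_data(rep(1, 4), rep(1, 4))
  wins2 <- circular_windows(map2, d2, max_fraction = 0.5)
  keys2 <- sort(vapply(wins2, paste, character(1), collapse = ","))
  # cap 2 admits singletons and pairs; {A,B}, {B,C}, {C,D} arise and the
  # reverse-direction duplicates are removed
  expect_equal(keys2, sort(c("1", "2", "3", "4", "1,2", "2,3", "3,4")))
})

test_that("flexible windows are the connected subsets of each neighborhood", {
  map <- path_map(3)
  wins <- flexible_windows(map, neighbor_limit = 2L)
  keys <- sort(vapply(wins, paste, character(1), collapse = ","))
  # centers A,B,C with the neighborhoods of size 2 around each
  expect_true(all(c("1", "2", "3", "1,2") %in% keys))

  # neighbor_limit 1: singletons only
  singles <- flexible_windows(map, neighbor_limit = 1L)
  expect_equal(sort(vapply(singles, paste, character(1), collapse = ",")),
               c("1", "2", "3"))

  # center B with a 3-region neighborhood: all connected subsets containing B
  map4 <- path_map(4)
  wins4 <- flexible_windows(map4, neighbor_limit = 3L)
  keys4 <- vapply(wins4, paste, character(1), collapse = ",")
  expect_true(all(c("2", "1,2", "2,3", "1,2,3") %in% keys4))
  # disconnected subset {A, C} never appears
  expect_false("1,3" %in% keys4)

  # vacuous restriction reproduces the unrestricted scan
  d <- case_data(c(2, 2, 2, 2), rep(2, 4))
  unres <- flexible_windows(map4, d, neighbor_limit = 3L)
  res <- flexible_windows(map4, d, neighbor_limit = 3L, restricted = TRUE,
                          alpha1 = 1.0)
  expect_setequal(vapply(res, paste, character(1), collapse = ","),
                  vapply(unres, paste, character(1), collapse = ","))
  expect_error(flexible_windows(map4, neighbor_limit = 4L), "< m")
})

test_that("restricted scan keeps only regions with small Poisson mid-p", {
  map <- path_map(4)
  # region 2 strongly elevated, others at baseline
  d <- case_data(c(5, 40, 5, 5), rep(5, 4))
  wins <- flexible_windows(map, d, neighbor_limit = 3L, restricted = TRUE,
                           alpha1 = 0.05)
  members <- sort(unique(unlist(wins)))
  expect_equal(members, 2L)  # only the elevated region is eligible
})

test_that("most likely cluster maximizes LLR with size-then-order tie breaks", {
  d <- case_data(c(30, 10, 10, 10), c(10, 10, 10, 10))
  mlc <- most_likely_cluster(d, list(1L, 2L, c(3L, 4L)))
  expect_equal(mlc$members, 1L)
  expect_equal(mlc$observed, 30)

  # identical llr for two windows: the smaller wins
  d2 <- case_data(c(20, 10, 10, 20), c(10, 5, 5, 40))
  mlc2 <- most_likely_cluster(d2, list(c(2L, 3L), 1L))
  expect_equal(mlc2$members, 1L)
  expect_error(most_likely_cluster(d, list()), "no admissible")
})

test_that("SCP candidates are disjoint, reproducible, and drop sub-threshold tails", {
  set.seed(31)
  map <- synthetic_map(64, "lattice")
  # two well-separated hotspots in opposite corners of the 8x8 grid
  cl <- list(c(1L, 2L, 9L, 10L), c(55L, 56L, 63L, 64L))
  mu0 <- rep(50, 64)
  rr <- rep(1, 64)
  for (w in cl) rr[w] <- 3
  d <- case_data(rpois(64, rr * mu0), mu0)

  cfg <- scan_config(kmax = 5, replications = 99)
  set.seed(7)
  cands <- scp_candidates(d, map, cfg)
  members <- unlist(lapply(cands$candidates, `[[`, "members"))
  expect_equal(anyDuplicated(members), 0L)  # pairwise disjoint

  # the two planted hotspots come out first, exactly
  got <- lapply(cands$candidates[1:2], `[[`, "members")
  expect_setequal(vapply(got, paste, character(1), collapse = ","),
                  vapply(cl, paste, character(1), collapse = ","))

  # p-values live on the Monte Carlo grid
  ps <- vapply(cands$candidates, `[[`, numeric(1), "p_s")
  expect_true(all(abs(ps * 100 - round(ps * 100)) < 1e-9))
  expect_true(all(ps > 0 & ps <= 1))

  # bit-reproducible under the same seed
  set.seed(7)
  again <- scp_candidates(d, map, cfg)
  expect_identical(cands, again)

  # a strict threshold truncates the sequence at the first exceedance
  cfg2 <- scan_config(kmax = 5, replications = 99, ps_threshold = 0.05)
  set.seed(7)
  trimmed <- scp_candidates(d, map, cfg2)
  expect_lte(length(trimmed$candidates), length(cands$candidates))
  ps2 <- vapply(trimmed$candidates, `[[`, numeric(1), "p_s")
  expect_true(all(ps2 <= 0.05))
})

test_that("null data yields no retained candidates at a strict threshold", {
  set.seed(99)
  map <- synthetic_map(49, "lattice")
  d <- case_data(rpois(49, 30), rep(30, 49))
  cfg <- scan_config(kmax = 3, replications = 99, ps_threshold = 0.05)
  cands <- scp_candidates(d, map, cfg)
  expect_lte(length(cands$candidates), 1L)
})

test_that("window p-values hit the grid ends for extreme statistics", {
  set.seed(5)
  map <- synthetic_map(16, "lattice")
  d <- case_data(rpois(16, 20), rep(20, 16))
  cfg <- scan_config(kmax = 1)
  expect_equal(window_pvalue(1e6, d, map, cfg, R = 19), 1 / 20)
  expect_equal(window_pvalue(-1, d, map, cfg, R = 19), 1)
})

test_that("scan maximization is invariant to an overall rate shift", {
  # doubling all baseline expectations must not change the chosen window
  set.seed(13)
  map <- synthetic_map(36, "lattice")
  cl <- plant_clusters(map, 4, shape = "ball")
  mu0 <- rep(40, 36)
  rr <- rep(1, 36); rr[cl[[1]]] <- 2.5
  y <- rpois(36, rr * mu0)
  c1 <- scp_candidates(case_data(y, mu0), map, scan_config(kmax = 1),
                       compute_ps = FALSE)
  c2 <- scp_candidates(case_data(y, mu0 / 3), map, scan_config(kmax = 1),
                       compute_ps = FALSE)
  expect_equal(c1$candidates[[1]]$members, c2$candidates[[1]]$members)
  expect_equal(c1$candidates[[1]]$llr, c2$candidates[[1]]$llr)
})
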