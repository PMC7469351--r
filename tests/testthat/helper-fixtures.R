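# Shared fixtures: tiny maps, random model instances, and an independent
# numeric maximizer of the multiple-cluster Poisson likelihood used as an
# oracle against the closed-form MLE.

# 3-region toy map: A(0,0) B(1,0) C(0,1), edges A-B, A-C
toy_map <- function() {
  region_map(c("A", "B", "C"), rbind(c(0, 0), c(1, 0), c(0, 1)),
             nbrs = list(c(2L, 3L), 1L, 1L))
}

# path graph A-B-C on a line
path_map <- function(n = 3) {
  ids <- LETTERS[seq_len(n)]
  nbrs <- lapply(seq_len(n), function(i)
    intersect(c(i - 1L, i + 1L), seq_len(n)))
  region_map(ids, cbind(seq_len(n) - 1, 0), nbrs = nbrs)
}

# write a whitespace-separated table to a temp file
write_fixture <- function(lines, ext = ".txt") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# random small model instance: m regions, `k` disjoint windows; counts
# drawn with elevated rates inside windows so fits are non-degenerate
random_instance <- function(m = sample(4:8, 1), k = sample(0:2, 1)) {
  repeat {
    mu0 <- runif(m, 0.8, 4)
    idx <- sample.int(m)
    sizes <- if (k > 0) sample(1:2, k, replace = TRUE) else integer()
    windows <- list()
    at <- 1L
    for (s in sizes) {
      windows <- c(windows, list(sort(idx[at:(at + s - 1L)])))
      at <- at + s
    }
    rate <- rep(1, m)
    for (w in windows) rate[w] <- runif(1, 1.5, 3)
    y <- rpois(m, rate * mu0 + 1)
    data <- case_data(y, mu0)
    outside <- setdiff(seq_len(m), unlist(windows))
    if (length(outside) && sum(y[outside]) > 0 && sum(y) > 0) {
      return(list(data = data, windows = windows, m = m))
    }
  }
}

# Independent numeric maximizer of the model log-likelihood: iteratively
# reweighted least squares via stats::glm with a Poisson family and the
# baseline expectation as offset; never uses the closed-form group MLE.
oracle_loglik <- function(data, windows) {
  K <- length(windows)
  m <- length(data$observed)
  y <- data$observed
  off <- log(data$expected0)
  ctl <- stats::glm.control(epsilon = 1e-13, maxit = 200)
  fit <- if (K == 0) {
    stats::glm(y ~ 1, family = stats::poisson(), offset = off,
               control = ctl)
  } else {
    z <- matrix(0, nrow = m, ncol = K)
    for (j in seq_len(K)) z[windows[[j]], j] <- 1
    stats::glm(y ~ z, family = stats::poisson(), offset = off,
               control = ctl)
  }
  as.numeric(stats::logLik(fit))
}

# conditioning scale used by the scan layer
standardize_expected_for_test <- function(d) {
  d$expected0 * d$total_observed / sum(d$expected0)
}
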