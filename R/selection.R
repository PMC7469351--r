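# Information-criterion selection of the number of clusters K.
#
# C(K) = -2 l(psi_hat | z) + (3K + 1) log m for K >= 1, obtained from a
# Laplace approximation of the marginal likelihood after dropping terms
# below O(1) in m, with window-selection probability h(z) = (1/m)^K.
# The number of clusters maximizes RDC(K) = (C0 - C(K)) / C0, where
# C0 = -2 l(alpha0_hat) + log m is the criterion under the null model
# (K = 0, q = 1, empty selection so the h-term vanishes).

#' Information criterion C(K) for a fitted multiple-cluster model
#'
#' @param fit a `cluster_fit` with `K >= 1` from [fit_multicluster()].
#' @param m number of regions in the study space.
#' @return `-2 * loglik + (3K + 1) * log(m)`.
#' @export
criterion <- function(fit, m) {
  if (m < 2) stop("criterion requires m >= 2")
  if (fit$K < 1L) stop("use criterion_null() for the null model")
  -2 * fit$loglik + (3 * fit$K + 1) * log(m)
}

#' Information criterion under the null model
#'
#' @param null_fit a `cluster_fit` with `K = 0` from [fit_null()].
#' @param m number of regions.
#' @return `-2 * loglik + log(m)`.
#' @export
criterion_null <- function(null_fit, m) {
  stopifnot(null_fit$K == 0L)
  -2 * null_fit$loglik + log(m)
}

#' Relative difference of criterion
#'
#' `RDC(K) = (C0 - C(K)) / C0`, elementwise over a criterion trace.
#'
#' @param c0 criterion under the null model (must be positive).
#' @param c_values vector of `C(K)` values.
#' @return vector of RDC values (may be negative).
#' @export
rdc_trace <- function(c0, c_values) {
  if (!is.finite(c0) || c0 <= 0) {
    stop("C0 must be positive for RDC; got ", format(c0))
  }
  (c0 - c_values) / c0
}

#' Select the number of clusters by maximum RDC
#'
#' Fits the multiple-cluster model on each prefix `w_1*, ..., w_K*` of the
#' SCP candidate ordering (K = 1..length(candidates)), computes `C(K)` and
#' `RDC(K)`, and selects `K_hat = argmax_K RDC(K)` when the maximum is
#' positive, else `K_hat = 0` (no clusters). Ties go to the smaller K.
#' AIC and BIC traces (`-2l + 2q`, `-2l + q log m`, `q = K + 1`) are
#' reported alongside for comparison only.
#'
#' @param candidates a `candidate_seq` from [scp_candidates()], or a list
#'   of disjoint windows.
#' @param data a [case_data()].
#' @param m number of regions (defaults to the data length).
#' @return object of class `selection_result`: `c0`, `c_trace`,
#'   `rdc_trace`, `loglik_trace`, `aic_trace`, `bic_trace`, `k_hat`,
#'   `max_rdc`, `selected` (the first `k_hat` windows), `p_m` (`NA` until
#'   filled by [overall_test()]).
#' @export
select_clusters <- function(candidates, data, m = length(data$observed)) {
  windows <- if (inherits(candidates, "candidate_seq")) {
    window_members(candidates$candidates)
  } else {
    window_members(candidates)
  }
  null_fit <- fit_null(data)
  c0 <- -2 * null_fit$loglik + log(m)
  if (!is.finite(c0) || c0 <= 0) {
    stop("degenerate criterion scale: C0 = ", format(c0))
  }
  Kmax <- length(windows)
  ll <- cc <- aic <- bic <- numeric(Kmax)
  for (K in seq_len(Kmax)) {
    fit <- suppressWarnings(fit_multicluster(data, windows[seq_len(K)]))
    ll[K] <- fit$loglik
    cc[K] <- criterion(fit, m)
    aic[K] <- -2 * fit$loglik + 2 * (K + 1)
    bic[K] <- -2 * fit$loglik + (K + 1) * log(m)
  }
  rdc <- if (Kmax) rdc_trace(c0, cc) else numeric()
  if (Kmax && max(rdc) > 0) {
    k_hat <- which.max(rdc)  # which.max takes the first (smallest K) on ties
    max_rdc <- rdc[k_hat]
  } else {
    k_hat <- 0L
    max_rdc <- if (Kmax) max(rdc) else -Inf
  }
  structure(
    list(c0 = c0, c_trace = cc, rdc_trace = rdc, loglik_trace = ll,
         aic_trace = aic, bic_trace = bic,
         k_hat = as.integer(k_hat), max_rdc = max_rdc,
         selected = windows[seq_len(k_hat)], p_m = NA_real_),
    class = "selection_result"
  )
}

#' @export
print.selection_result <- function(x, ...) {
  cat("<selection_result> K_hat =", x$k_hat,
      " max RDC =", format(x$max_rdc, digits = 4),
      " C0 =", format(x$c0, digits = 6))
  if (!is.na(x$p_m)) cat("  p_M =", format(x$p_m))
  cat("\n")
  invisible(x)
}

#' Criterion trajectory table (one row per K)
#'
#' @param x a `selection_result`.
#' @param ... unused.
#' @return data.frame with columns K, loglik, C, RDC, AIC, BIC,
#'   minus2logL.
#' @export
as.data.frame.selection_result <- function(x, ...) {
  data.frame(K = seq_along(x$c_trace), loglik = x$loglik_trace,
             C = x$c_trace, RDC = x$rdc_trace,
             AIC = x$aic_trace, BIC = x$bic_trace,
             minus2logL = -2 * x$loglik_trace)
}
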