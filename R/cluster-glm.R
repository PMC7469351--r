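# Multiple-cluster Poisson GLM: log mu_i = alpha + sum_k beta_k z_ki +
# log mu_i^0, with z_ki indicating membership of region i in cluster w_k.
# The model is saturated by group (K windows + outside), so the MLE is
# closed form; the full Poisson log-likelihood (including log y_i!) is used
# throughout so criterion values are comparable across K.

#' Cluster membership indicator design
#'
#' Builds the K x m 0/1 indicator matrix `z` for a disjoint window list and
#' the outside indicator `z0` (1 iff a region is in no window).
#'
#' @param windows list of windows (integer index vectors), pairwise
#'   disjoint.
#' @param m number of regions.
#' @return list with matrix `z` (K x m) and vector `z0` (length m).
#' @export
indicator_matrix <- function(windows, m) {
  K <- length(windows)
  z <- matrix(0L, nrow = K, ncol = m)
  for (k in seq_len(K)) {
    w <- windows[[k]]
    if (any(w < 1L | w > m)) stop("window index out of range")
    z[k, w] <- 1L
  }
  if (K && any(colSums(z) > 1L)) stop("candidates must be disjoint")
  list(z = z, z0 = as.integer(if (K) colSums(z) == 0L else rep(1L, m)))
}

# windows may arrive as scored-window lists or bare index vectors
window_members <- function(windows) {
  lapply(windows, function(w) if (is.list(w)) w$members else as.integer(w))
}

#' Fit the null (no-cluster) model
#'
#' `log mu_i = alpha + log mu_i^0`; the MLE is
#' `alpha_hat = log(sum y_i / sum mu_i^0)`.
#'
#' @param data a [case_data()].
#' @return object of class `cluster_fit` with `K = 0`.
#' @export
fit_null <- function(data) {
  O <- data$total_observed
  E <- sum(data$expected0)
  if (O <= 0) stop("all counts are zero; the null rate is degenerate")
  alpha <- log(O / E)
  fitted <- exp(alpha) * data$expected0
  new_cluster_fit(K = 0L, alpha = alpha, betas = numeric(),
                  fitted = fitted, data = data, windows = list())
}

#' Fit the multiple-cluster Poisson model for a disjoint window set
#'
#' The model is saturated by group, so the MLE is closed form:
#' `exp(alpha_hat) = O_out/E_out` and
#' `exp(alpha_hat + beta_hat_k) = O_k/E_k`, where `O_k`, `E_k` are window
#' totals of observed and baseline expected counts. A candidate fitted
#' with `beta_hat_k <= 0` (not elevated) is flagged with a warning, not an
#' error: enforcement of high rates happens upstream in the scan.
#'
#' @param data a [case_data()].
#' @param windows list of disjoint windows (index vectors or scored
#'   windows from [scp_candidates()]).
#' @return object of class `cluster_fit`: `K`, `alpha`, `betas`, `thetas`
#'   (cluster rate multipliers, last element the outside rate), `loglik`
#'   (full Poisson log-likelihood at the MLE), `fitted`, `q = K + 1`.
#' @export
fit_multicluster <- function(data, windows) {
  windows <- window_members(windows)
  K <- length(windows)
  if (K == 0L) return(fit_null(data))
  m <- length(data$observed)
  ind <- indicator_matrix(windows, m)  # validates disjointness
  outside <- which(ind$z0 == 1L)
  if (!length(outside)) stop("at least one region must lie outside all windows")
  Ok <- vapply(windows, function(w) sum(data$observed[w]), numeric(1))
  Ek <- vapply(windows, function(w) sum(data$expected0[w]), numeric(1))
  Oout <- sum(data$observed[outside])
  Eout <- sum(data$expected0[outside])
  if (any(Ek <= 0) || Eout <= 0) stop("zero expected count in a group")
  if (Oout <= 0) stop("no cases outside the windows; outside rate degenerate")
  alpha <- log(Oout / Eout)
  betas <- log(Ok / Ek) - alpha   # -Inf when a window has no cases
  if (any(betas <= 0)) {
    warning(sum(betas <= 0), " candidate window(s) fitted with beta <= 0 ",
            "(rate not elevated)")
  }
  theta <- exp(alpha) * rep(1, m)
  for (k in seq_len(K)) theta[windows[[k]]] <- Ok[k] / Ek[k]
  new_cluster_fit(K = K, alpha = alpha, betas = betas,
                  fitted = theta * data$expected0, data = data,
                  windows = windows)
}

new_cluster_fit <- function(K, alpha, betas, fitted, data, windows) {
  structure(
    list(K = K, alpha = alpha, betas = betas,
         thetas = c(exp(alpha + betas), outside = exp(alpha)),
         loglik = sum(dpois(data$observed, fitted, log = TRUE)),
         fitted = fitted, q = K + 1L, windows = windows),
    class = "cluster_fit"
  )
}

#' @export
print.cluster_fit <- function(x, ...) {
  cat("<cluster_fit> K =", x$K, " loglik =", format(x$loglik), "\n")
  if (x$K > 0) {
    cat("  theta (cluster rate / baseline):",
        paste(format(x$thetas[seq_len(x$K)], digits = 4), collapse = ", "),
        "; outside:", format(exp(x$alpha), digits = 4), "\n")
  }
  invisible(x)
}

#' Log-likelihood ratio between two fits on the same data
#'
#' For a single-window fit against the null this equals the Poisson scan
#' LLR of [poisson_llr()] whenever baseline expectations are internally
#' standardized (`sum mu_i^0 = sum y_i`).
#'
#' @param fit,null_fit `cluster_fit` objects on the same data.
#' @return `fit$loglik - null_fit$loglik` (non-negative by nesting when
#'   `null_fit` is the null model).
#' @export
loglik_ratio <- function(fit, null_fit) {
  fit$loglik - null_fit$loglik
}

#' Per-cluster fit report
#'
#' @param fit a `cluster_fit` from [fit_multicluster()].
#' @param data the [case_data()] it was fitted on.
#' @param map optional [region_map()] for region ids.
#' @return data.frame with per-cluster `k`, `n_regions`, `observed`,
#'   `expected`, `theta` (rate multiplier), `RR` (theta relative to the
#'   outside rate), `beta`, and member regions.
#' @export
fit_report <- function(fit, data, map = NULL) {
  K <- fit$K
  if (K == 0L) return(data.frame())
  Ok <- vapply(fit$windows, function(w) sum(data$observed[w]), numeric(1))
  Ek <- vapply(fit$windows, function(w) sum(data$expected0[w]), numeric(1))
  data.frame(
    k = seq_len(K),
    n_regions = lengths(fit$windows),
    observed = Ok, expected = Ek,
    theta = unname(fit$thetas[seq_len(K)]),
    RR = unname(fit$thetas[seq_len(K)]) / exp(fit$alpha),
    beta = unname(fit$betas),
    region_ids = vapply(fit$windows, function(w)
      if (is.null(map)) paste(w, collapse = ";")
      else paste(map$ids[w], collapse = ";"), character(1))
  )
}
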