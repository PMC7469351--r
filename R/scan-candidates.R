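# Scanning-window enumeration, the Poisson scan statistic, and the
# sequential secondary-cluster procedure (SCP) producing the ordered
# disjoint candidate list w_1*, ..., w_Kmax*.

#' Scan configuration
#'
#' @param method scanning method: `"circular"` (centroid-distance balls),
#'   `"flexible"` (all connected subsets within a neighborhood), or
#'   `"restricted"` (flexible scan restricted to regions with small
#'   one-sided Poisson mid-p).
#' @param max_fraction circular scan: maximum fraction of the total
#'   expected count inside a window (default 0.5).
#' @param neighbor_limit flexible scan: windows are connected subsets of a
#'   region and its `neighbor_limit - 1` nearest regions (default 20).
#' @param alpha1 restricted scan: mid-p eligibility threshold (default 0.2).
#' @param kmax maximum number of SCP candidates (default 20).
#' @param ps_threshold retain candidates while their secondary p-value
#'   `p_s` does not exceed this (default 1, retain all up to `kmax`).
#' @param replications Monte Carlo replicates for `p_s` (default 999).
#' @param emission_cap flexible scan: stop enumerating windows for a center
#'   past this many (guards combinatorial blow-up; truncation is logged).
#' @return a `scan_config` list.
#' @export
scan_config <- function(method = c("circular", "flexible", "restricted"),
                        max_fraction = 0.5, neighbor_limit = 20L,
                        alpha1 = 0.2, kmax = 20L, ps_threshold = 1.0,
                        replications = 999L, emission_cap = 1e5) {
  method <- match.arg(method)
  stopifnot(max_fraction > 0, max_fraction <= 0.5,
            neighbor_limit >= 1L, alpha1 > 0, alpha1 <= 1,
            kmax >= 1L, ps_threshold > 0, ps_threshold <= 1,
            replications >= 1L)
  structure(list(method = method, max_fraction = max_fraction,
                 neighbor_limit = as.integer(neighbor_limit),
                 alpha1 = alpha1, kmax = as.integer(kmax),
                 ps_threshold = ps_threshold,
                 replications = as.integer(replications),
                 emission_cap = emission_cap),
            class = "scan_config")
}

#' Poisson scan log likelihood ratio
#'
#' The standard high-rate Poisson scan statistic for a window with
#' `observed_in` cases against `expected_in` baseline cases, inside a study
#' area with totals `total_observed` and `total_expected`:
#' `O_w log(O_w/E_w) + (O - O_w) log((O - O_w)/(E - E_w))` when the inside
#' rate exceeds the outside rate, else 0. Zero-count terms contribute 0.
#'
#' @param observed_in,expected_in window totals `O_w`, `E_w`.
#' @param total_observed,total_expected study-area totals `O`, `E`.
#' @return non-negative scalar (vectorized over windows).
#' @export
poisson_llr <- function(observed_in, expected_in, total_observed,
                        total_expected) {
  ow <- observed_in; ew <- expected_in
  O <- total_observed; E <- total_expected
  if (any(ew <= 0) || any(ew >= E)) {
    stop("window expected count must satisfy 0 < E_w < E")
  }
  if (any(ow < 0) || any(ow > O)) stop("window observed count outside [0, O]")
  oo <- O - ow
  eo <- E - ew
  xlx <- function(x, r) ifelse(x > 0, x * log(x / r), 0)
  llr <- xlx(ow, ew) + xlx(oo, eo)
  ifelse(ow * eo > oo * ew, llr, 0)
}

# one-sided Poisson mid-p of y against mean mu: P(X > y) + 0.5 P(X = y)
poisson_midp <- function(y, mu) {
  ppois(y, mu, lower.tail = FALSE) + 0.5 * dpois(y, mu)
}

# Precompute the circular-scan geometry: row i of `ord` lists all regions
# by centroid distance from i (self first; ties by lexicographic id).
scan_precompute <- function(map) {
  D <- centroid_distances(map)
  id_rank <- rank(map$ids, ties.method = "first")
  ord <- matrix(0L, map$m, map$m)
  for (i in seq_len(map$m)) {
    o <- order(D[i, ], id_rank)
    ord[i, ] <- c(i, o[o != i])
  }
  ord
}

# Scan maximization conditions on the total count (multinomial null), so
# the scan layer evaluates the LLR against expectations standardized to
# the observed total: mu_i^0 * O / sum(mu^0). This makes the scan LLR
# identical to the multiple-cluster GLM likelihood ratio for the same
# window and keeps the statistic invariant to an overall rate shift.
standardize_expected <- function(data) {
  data$expected0 * data$total_observed / sum(data$expected0)
}

#' Enumerate circular scanning windows
#'
#' For each center region, the nested sets of its 1st, 2nd, ... nearest
#' regions (by centroid distance, ties broken by id) up to the
#' expected-count cap; duplicate member sets are removed.
#'
#' @param map a [region_map()].
#' @param data a [case_data()].
#' @param max_fraction maximum fraction of total expected count per window.
#' @return list of windows (integer vectors of region indices).
#' @export
circular_windows <- function(map, data, max_fraction = 0.5) {
  ord <- scan_precompute(map)
  cap <- max_fraction * sum(data$expected0)
  E <- sum(data$expected0)
  seen <- new.env(hash = TRUE)
  out <- list()
  for (c in seq_len(map$m)) {
    ew <- 0
    for (j in seq_len(map$m)) {
      ew <- ew + data$expected0[ord[c, j]]
      if (ew > cap || ew >= E) break
      w <- sort(ord[c, seq_len(j)])
      key <- paste(w, collapse = ",")
      if (is.null(seen[[key]])) {
        seen[[key]] <- TRUE
        out[[length(out) + 1L]] <- w
      }
    }
  }
  out
}

#' Enumerate flexibly shaped scanning windows
#'
#' For each region i, all connected subsets (under map adjacency) of the
#' set formed by i and its `neighbor_limit - 1` nearest regions, each
#' subset containing i. In restricted mode only regions whose one-sided
#' Poisson mid-p (observed against baseline expectation) falls below
#' `alpha1` are eligible as members (and as centers).
#'
#' @param map a [region_map()] with adjacency.
#' @param data a [case_data()]; required for restricted mode.
#' @param neighbor_limit neighborhood size (maximum window size).
#' @param restricted logical; apply the mid-p restriction.
#' @param alpha1 mid-p eligibility threshold.
#' @param active optional logical mask of regions available for scanning.
#' @param emission_cap per-center enumeration guard.
#' @return list of windows (integer vectors of region indices).
#' @export
flexible_windows <- function(map, data = NULL, neighbor_limit = 20L,
                             restricted = FALSE, alpha1 = 0.2,
                             active = NULL, emission_cap = 1e5) {
  if (is.null(map$nbrs)) stop("flexible scan requires adjacency")
  if (neighbor_limit >= map$m) stop("neighbor_limit must be < m")
  if (is.null(active)) active <- rep(TRUE, map$m)
  eligible <- active
  if (restricted) {
    if (is.null(data)) stop("restricted scan requires case data")
    eligible <- active &
      poisson_midp(data$observed, data$expected0) < alpha1
  }
  D <- centroid_distances(map)
  id_rank <- rank(map$ids, ties.method = "first")
  seen <- new.env(hash = TRUE)
  out <- list()
  truncated <- FALSE
  for (i in which(eligible)) {
    o <- order(D[i, ], id_rank)
    o <- c(i, o[o != i])
    o <- o[eligible[o]]
    allowed <- o[seq_len(min(neighbor_limit, length(o)))]
    subs <- connected_subsets(i, allowed, map$nbrs, emission_cap)
    if (attr(subs, "truncated")) truncated <- TRUE
    for (w in subs) {
      w <- sort(w)
      key <- paste(w, collapse = ",")
      if (is.null(seen[[key]])) {
        seen[[key]] <- TRUE
        out[[length(out) + 1L]] <- w
      }
    }
  }
  if (truncated) {
    message("flexible scan: per-center emission cap reached; ",
            "window list truncated")
  }
  out
}

# All connected subsets of `allowed` containing `root`, enumerated once
# each (grow-with-exclusion), up to `cap` subsets.
connected_subsets <- function(root, allowed, nbrs, cap = 1e5) {
  allowed_set <- rep(FALSE, length(nbrs))
  allowed_set[allowed] <- TRUE
  out <- vector("list", 64L)
  n_out <- 0L
  truncated <- FALSE
  emit <- function(S) {
    if (n_out >= cap) { truncated <<- TRUE; return(FALSE) }
    n_out <<- n_out + 1L
    if (n_out > length(out)) length(out) <<- 2L * n_out
    out[[n_out]] <<- S
    TRUE
  }
  grow <- function(S, ext, excl) {
    if (!emit(S)) return()
    while (length(ext)) {
      v <- ext[1L]
      ext <- ext[-1L]
      nb <- nbrs[[v]]
      nb <- nb[allowed_set[nb]]
      newext <- c(ext, setdiff(nb, c(S, excl, ext, v)))
      grow(c(S, v), newext, excl)
      if (truncated) return()
      excl <- c(excl, v)
    }
  }
  nb0 <- nbrs[[root]]
  grow(root, nb0[allowed_set[nb0]], integer())
  out <- out[seq_len(n_out)]
  attr(out, "truncated") <- truncated
  out
}

# score a list of windows; returns data.frame(ow, ew, llr)
score_windows <- function(data, windows) {
  ow <- vapply(windows, function(w) sum(data$observed[w]), numeric(1))
  ew <- vapply(windows, function(w) sum(data$expected0[w]), numeric(1))
  O <- data$total_observed
  E <- sum(data$expected0)
  data.frame(ow = ow, ew = ew,
             llr = poisson_llr(ow, ew, O, E))
}

#' Most likely cluster among a set of windows
#'
#' Returns the window maximizing the Poisson scan LLR; ties are broken by
#' smaller window size, then by the lexicographically smallest sorted
#' member list in canonical region order.
#'
#' @param data a [case_data()].
#' @param windows list of windows (integer index vectors).
#' @return a scored window: list with `members`, `size`, `observed`,
#'   `expected`, `llr`.
#' @export
most_likely_cluster <- function(data, windows) {
  if (!length(windows)) stop("no admissible scanning window")
  sc <- score_windows(data, windows)
  best <- which(sc$llr == max(sc$llr))
  if (length(best) > 1L) {
    sizes <- lengths(windows[best])
    best <- best[sizes == min(sizes)]
    if (length(best) > 1L) {
      keys <- vapply(windows[best], function(w)
        paste(formatC(sort(w), width = 9, flag = "0"), collapse = ","),
        character(1))
      best <- best[order(keys)]
    }
  }
  b <- best[1L]
  w <- sort(windows[[b]])
  list(members = w, size = length(w), observed = sc$ow[b],
       expected = sc$ew[b], llr = sc$llr[b])
}

# Fast most-likely-cluster for the circular scan over active regions,
# using the compiled kernel on total-standardized expectations.
# Returns NULL when no admissible window.
mlc_circular <- function(ord, y, mu_std, O, cap, active) {
  res <- scan_circular_best(ord, y, mu_std, active, cap, O, O)
  llr <- res$llr
  if (all(llr < 0)) return(NULL)
  top <- max(llr)
  cand <- which(llr == top)
  if (length(cand) > 1L) {  # ties: smaller window first
    sz <- res$size[cand]
    cand <- cand[order(sz, cand)]
  }
  c0 <- cand[1L]
  row <- ord[c0, ]
  members <- sort(row[active[row]][seq_len(res$size[c0])])
  list(members = members, size = length(members),
       observed = sum(y[members]), llr = top)
}

# Null max-LLR replicates for a scan configuration (full active map).
# Expectations are standardized to the conditioning total, so null and
# observed statistics are on the same scale.
null_max_llrs <- function(data, map, config, R) {
  mu_std <- standardize_expected(data)
  O <- data$total_observed
  ymat <- rmultinom(R, O, mu_std / O)
  if (config$method == "circular") {
    ord <- scan_precompute(map)
    scan_circular_max_batch(ord, ymat, mu_std,
                            config$max_fraction * O, O)
  } else if (config$method == "flexible") {
    windows <- flexible_windows(map, data, config$neighbor_limit,
                                emission_cap = config$emission_cap)
    ewv <- vapply(windows, function(w) sum(mu_std[w]), numeric(1))
    memb <- matrix(0, nrow = map$m, ncol = length(windows))
    for (j in seq_along(windows)) memb[windows[[j]], j] <- 1
    vapply(seq_len(R), function(r) {
      y <- ymat[, r]
      ow <- drop(crossprod(memb, y))
      max(poisson_llr(ow, ewv, O, O))
    }, numeric(1))
  } else {
    # restricted scan: mid-p eligibility is data-dependent, so windows are
    # re-enumerated from each replicate's counts
    vapply(seq_len(R), function(r) {
      d <- case_data(ymat[, r], mu_std)
      windows <- flexible_windows(map, d, config$neighbor_limit,
                                  restricted = TRUE, alpha1 = config$alpha1,
                                  emission_cap = config$emission_cap)
      if (!length(windows)) return(0)
      sc <- score_windows(d, windows)
      max(sc$llr)
    }, numeric(1))
  }
}

#' Monte Carlo p-value of an observed scan statistic
#'
#' Generates `R` null datasets by multinomial allocation of the observed
#' total across regions proportional to baseline expectations, recomputes
#' the maximal scan LLR on each, and returns
#' `(1 + #(llr* >= observed_llr)) / (R + 1)`.
#'
#' @param observed_llr the observed window LLR.
#' @param data a [case_data()].
#' @param map a [region_map()].
#' @param config a [scan_config()].
#' @param R number of Monte Carlo replications.
#' @return p-value on the grid `{1/(R+1), ..., 1}`.
#' @export
window_pvalue <- function(observed_llr, data, map, config = scan_config(),
                          R = config$replications) {
  nulls <- null_max_llrs(data, map, config, R)
  (1 + sum(nulls >= observed_llr)) / (R + 1)
}

#' Sequential secondary-cluster candidate generation (SCP)
#'
#' Iteratively finds the most likely cluster among regions not assigned to
#' any previous candidate (previously detected regions are left out of
#' window membership, not removed from the totals), attaches a Monte Carlo
#' secondary p-value `p_s` to each, and stops at `kmax` candidates, when
#' `p_s` exceeds `ps_threshold`, or when no admissible window remains.
#' All candidates share one set of null replicates: each `p_s` compares the
#' candidate's LLR to the null distribution of the full-map scan maximum.
#'
#' @param data a [case_data()].
#' @param map a [region_map()].
#' @param config a [scan_config()].
#' @param compute_ps logical; skip the Monte Carlo `p_s` entirely (used
#'   inside the overall test, where `p_s` does not enter the statistic).
#' @return object of class `candidate_seq`: list with `candidates` (each a
#'   scored window with `members`, `observed`, `expected`, `llr`, `p_s`),
#'   `kmax`, `ps_threshold`, `replications`.
#' @export
scp_candidates <- function(data, map, config = scan_config(),
                           compute_ps = TRUE) {
  stopifnot(inherits(map, "region_map"), inherits(data, "case_data"),
            map$m == length(data$observed))
  cands <- scp_windows(data, map, config)
  if (compute_ps && length(cands)) {
    nulls <- null_max_llrs(data, map, config, config$replications)
    keep <- length(cands)
    for (k in seq_along(cands)) {
      ps <- (1 + sum(nulls >= cands[[k]]$llr)) / (config$replications + 1)
      cands[[k]]$p_s <- ps
      if (ps > config$ps_threshold) { keep <- k - 1L; break }
    }
    cands <- cands[seq_len(keep)]
  }
  structure(list(candidates = cands, kmax = config$kmax,
                 ps_threshold = config$ps_threshold,
                 replications = if (compute_ps) config$replications else 0L,
                 method = config$method),
            class = "candidate_seq")
}

# candidate windows only (no p_s); shared by scp_candidates and the
# overall Monte Carlo test. Previously detected regions are left out of
# window membership; study-area totals are not reduced.
scp_windows <- function(data, map, config) {
  if (data$total_observed <= 0) return(list())
  mu_std <- standardize_expected(data)
  O <- data$total_observed
  data_s <- case_data(data$observed, mu_std)
  active <- rep(TRUE, map$m)
  cands <- list()
  if (config$method == "circular") {
    ord <- scan_precompute(map)
    cap <- config$max_fraction * O
    for (k in seq_len(config$kmax)) {
      if (!any(active)) break
      mlc <- mlc_circular(ord, data$observed, mu_std, O, cap, active)
      if (is.null(mlc)) break
      cands[[k]] <- mlc
      active[mlc$members] <- FALSE
    }
  } else {
    for (k in seq_len(config$kmax)) {
      if (!any(active)) break
      windows <- flexible_windows(
        map, data_s, config$neighbor_limit,
        restricted = (config$method == "restricted"),
        alpha1 = config$alpha1, active = active,
        emission_cap = config$emission_cap)
      if (!length(windows)) break
      mlc <- most_likely_cluster(data_s, windows)
      cands[[k]] <- mlc
      active[mlc$members] <- FALSE
    }
  }
  for (k in seq_along(cands)) {  # report baseline-scale expectations
    cands[[k]]$expected <- sum(data$expected0[cands[[k]]$members])
  }
  cands
}

#' @export
print.candidate_seq <- function(x, ...) {
  cat("<candidate_seq>", length(x$candidates), "candidate cluster(s), ",
      x$method, "scan\n")
  if (length(x$candidates)) print(as.data.frame(x), ...)
  invisible(x)
}

#' Candidate table in secondary-cluster order
#'
#' One row per candidate: rank, number of regions, observed and expected
#' counts, the window SMR (`RR = O_k/E_k`), scan LLR, and `p_s`.
#'
#' @param x a `candidate_seq`.
#' @param map optional [region_map()] used to print member region ids.
#' @param ... unused.
#' @export
as.data.frame.candidate_seq <- function(x, map = NULL, ...) {
  cands <- x$candidates
  data.frame(
    rank = seq_along(cands),
    n_regions = vapply(cands, function(w) w$size, numeric(1)),
    observed = vapply(cands, function(w) w$observed, numeric(1)),
    expected = vapply(cands, function(w) w$expected, numeric(1)),
    RR = vapply(cands, function(w) w$observed / w$expected, numeric(1)),
    llr = vapply(cands, function(w) w$llr, numeric(1)),
    p_s = vapply(cands, function(w)
      if (is.null(w$p_s)) NA_real_ else w$p_s, numeric(1)),
    region_ids = vapply(cands, function(w)
      if (is.null(map)) paste(w$members, collapse = ";")
      else paste(map$ids[w$members], collapse = ";"), character(1))
  )
}
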