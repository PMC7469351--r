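# Data model for the study space: region ids, centroids, adjacency, and
# per-region case / baseline expected counts. Canonical region order is the
# file (construction) order; all downstream vectors are indexed by it.

#' Construct a region map
#'
#' A `region_map` holds the study space: `m` regions identified by opaque
#' string ids, their planar (or geographic) centroids, and an optional
#' symmetric, irreflexive adjacency relation stored as a neighbor list.
#'
#' @param ids character vector of unique region identifiers.
#' @param coords numeric matrix (m x 2) of centroid coordinates; for
#'   geographic data, columns are (latitude, longitude) in degrees.
#' @param nbrs optional list of integer neighbor index vectors (length m);
#'   must be symmetric and contain no self-neighbors.
#' @param geographic logical; if `TRUE`, distances are great-circle.
#' @return object of class `region_map` with elements `ids`, `coords`,
#'   `nbrs`, `m`, `geographic`.
#' @export
region_map <- function(ids, coords, nbrs = NULL, geographic = FALSE) {
  ids <- as.character(ids)
  if (anyDuplicated(ids)) {
    stop("duplicate region id: ", ids[duplicated(ids)][1L])
  }
  m <- length(ids)
  if (m < 2L) stop("a region map needs at least 2 regions")
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  dimnames(coords) <- NULL
  if (nrow(coords) != m || ncol(coords) != 2L) {
    stop("coords must be an m x 2 matrix")
  }
  if (!all(is.finite(coords))) stop("non-finite centroid coordinate")
  if (!is.null(nbrs)) {
    stopifnot(length(nbrs) == m)
    nbrs <- lapply(seq_len(m), function(i) {
      v <- sort(unique(as.integer(nbrs[[i]])))
      if (any(v < 1L | v > m)) stop("neighbor index out of range")
      if (i %in% v) stop("self-adjacency is not allowed (region ", ids[i], ")")
      v
    })
    for (i in seq_len(m)) {
      for (j in nbrs[[i]]) {
        if (!(i %in% nbrs[[j]])) stop("adjacency is not symmetric")
      }
    }
  }
  structure(
    list(ids = ids, coords = coords, nbrs = nbrs, m = m,
         geographic = isTRUE(geographic)),
    class = "region_map"
  )
}

#' @export
print.region_map <- function(x, ...) {
  n_edges <- if (is.null(x$nbrs)) NA_integer_ else sum(lengths(x$nbrs)) %/% 2L
  cat("<region_map> m =", x$m, "regions;",
      if (is.na(n_edges)) "no adjacency" else paste(n_edges, "edges"),
      if (x$geographic) "(geographic coordinates)" else "(planar coordinates)",
      "\n")
  invisible(x)
}

#' Read a coordinates table into a region map
#'
#' Accepts the SaTScan "geo" dialect: whitespace- or comma-separated text
#' with one row per region carrying an id and two coordinates. Row order
#' becomes the canonical region order. Adjacency is left empty; attach it
#' with [read_adjacency()] or [derive_adjacency()].
#'
#' @param path path to the coordinates file.
#' @param id_column,coord_columns column names or positions (defaults:
#'   columns 1, and 2:3).
#' @param header logical; does the file have a header row?
#' @param geographic logical; treat coordinates as (lat, lon) degrees.
#' @return a [region_map()].
#' @export
read_regions <- function(path, id_column = 1L, coord_columns = c(2L, 3L),
                         header = FALSE, geographic = FALSE) {
  tab <- read_table_auto(path, header = header)
  ids <- as.character(tab[[id_column]])
  xy <- tab[coord_columns]
  for (j in 1:2) {
    v <- suppressWarnings(as.numeric(xy[[j]]))
    bad <- which(is.na(v) & !is.na(xy[[j]]))
    if (length(bad)) {
      stop("non-numeric coordinate in row ", bad[1L], " of ", path)
    }
    if (anyNA(v)) stop("missing coordinate in row ", which(is.na(v))[1L])
    xy[[j]] <- v
  }
  region_map(ids, as.matrix(xy), geographic = geographic)
}

# whitespace- or comma-separated tables, auto-detected
read_table_auto <- function(path, header = FALSE) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl(",", first, fixed = TRUE)) "," else ""
  read.table(path, header = header, sep = sep, strip.white = TRUE,
             stringsAsFactors = FALSE, colClasses = "character",
             comment.char = "#")
}

#' Attach adjacency read from a matrix or edge-list file
#'
#' Two dialects: a square 0/1 matrix with region ids as header row and
#' first column, or a two-column edge list of region ids. Input is
#' symmetrized (an edge present in either direction becomes mutual) and the
#' diagonal is ignored.
#'
#' @param path path to the adjacency file.
#' @param map a [region_map()].
#' @return the map with adjacency attached.
#' @export
read_adjacency <- function(path, map) {
  stopifnot(inherits(map, "region_map"))
  tab <- read_table_auto(path, header = FALSE)
  if (ncol(tab) == 2L) {
    edges <- cbind(as.character(tab[[1L]]), as.character(tab[[2L]]))
  } else {
    # matrix dialect: header row of ids, first column of ids
    ids_col <- as.character(tab[[1L]][-1L])
    ids_row <- as.character(unlist(tab[1L, -1L], use.names = FALSE))
    if (length(ids_row) != length(ids_col)) {
      stop("adjacency matrix is not square")
    }
    mat <- as.matrix(tab[-1L, -1L, drop = FALSE])
    storage.mode(mat) <- "numeric"
    hit <- which(mat != 0, arr.ind = TRUE)
    edges <- cbind(ids_col[hit[, 1L]], ids_row[hit[, 2L]])
  }
  attach_edges(map, edges)
}

attach_edges <- function(map, edges) {
  idx <- match(edges, map$ids)
  if (anyNA(idx)) {
    stop("unknown region id in adjacency: ",
         edges[is.na(idx)][1L])
  }
  dim(idx) <- dim(edges)
  nbrs <- rep(list(integer()), map$m)
  keep <- idx[, 1L] != idx[, 2L]
  for (r in which(keep)) {
    i <- idx[r, 1L]; j <- idx[r, 2L]
    nbrs[[i]] <- c(nbrs[[i]], j)
    nbrs[[j]] <- c(nbrs[[j]], i)
  }
  region_map(map$ids, map$coords,
             nbrs = lapply(nbrs, function(v) sort(unique(v))),
             geographic = map$geographic)
}

#' Derive adjacency from centroids as a mutualized k-nearest-neighbor graph
#'
#' An edge joins i and j when j is among the `k_neighbors` nearest centroids
#' of i or vice versa. Distance ties are broken by lexicographic region id,
#' so results are reproducible across platforms.
#'
#' @param map a [region_map()].
#' @param k_neighbors number of nearest neighbors, `1 <= k < m`.
#' @return the map with adjacency attached.
#' @export
derive_adjacency <- function(map, k_neighbors) {
  stopifnot(inherits(map, "region_map"),
            k_neighbors >= 1L, k_neighbors < map$m)
  D <- centroid_distances(map)
  edges <- matrix(character(), ncol = 2L, nrow = 0L)
  out <- vector("list", map$m)
  for (i in seq_len(map$m)) {
    o <- order(D[i, ], rank(map$ids, ties.method = "first"))
    o <- setdiff(o, i)[seq_len(k_neighbors)]
    out[[i]] <- cbind(map$ids[i], map$ids[o])
  }
  res <- attach_edges(map, do.call(rbind, out))
  n_comp <- igraph::components(map_graph(res))$no
  if (n_comp > 1L) {
    warning("derived adjacency graph is disconnected (", n_comp,
            " components); consider a larger k_neighbors")
  }
  res
}

# full pairwise centroid distance matrix (Euclidean or haversine)
centroid_distances <- function(map) {
  if (!map$geographic) {
    return(as.matrix(dist(map$coords)))
  }
  lat <- map$coords[, 1L] * pi / 180
  lon <- map$coords[, 2L] * pi / 180
  R_earth <- 6371.0088
  m <- map$m
  D <- matrix(0, m, m)
  for (i in seq_len(m)) {
    dlat <- lat - lat[i]
    dlon <- lon - lon[i]
    a <- sin(dlat / 2)^2 + cos(lat[i]) * cos(lat) * sin(dlon / 2)^2
    D[i, ] <- 2 * R_earth * asin(pmin(1, sqrt(a)))
  }
  D
}

#' Construct per-region case data
#'
#' @param observed non-negative integer case counts `y_i`, canonical order.
#' @param expected0 positive baseline expected counts `mu_i^0` (cases).
#' @return object of class `case_data` with `observed`, `expected0`,
#'   `total_observed`.
#' @export
case_data <- function(observed, expected0) {
  observed <- as.numeric(observed)
  expected0 <- as.numeric(expected0)
  if (length(observed) != length(expected0)) {
    stop("observed and expected0 must have equal length")
  }
  if (any(observed < 0) || any(observed != round(observed))) {
    stop("observed counts must be non-negative integers")
  }
  if (any(!is.finite(expected0)) || any(expected0 <= 0)) {
    stop("baseline expected counts must be positive; drop zero-expectation ",
         "regions first (see expected_counts)")
  }
  structure(
    list(observed = observed, expected0 = expected0,
         total_observed = sum(observed)),
    class = "case_data"
  )
}

#' @export
print.case_data <- function(x, ...) {
  cat("<case_data>", length(x$observed), "regions; O =", x$total_observed,
      "cases; sum(mu0) =", format(sum(x$expected0)), "\n")
  invisible(x)
}

#' Read a SaTScan-style case file
#'
#' Columns (id, count); rows are matched to the map's canonical order.
#'
#' @param path path to the case file.
#' @param map a [region_map()].
#' @param header logical.
#' @return named numeric vector of counts in canonical region order.
#' @export
read_cases <- function(path, map, header = FALSE) {
  tab <- read_table_auto(path, header = header)
  ids <- as.character(tab[[1L]])
  idx <- match(map$ids, ids)
  if (anyNA(idx)) stop("case file is missing region: ", map$ids[is.na(idx)][1L])
  y <- as.numeric(tab[[2L]])[idx]
  if (anyNA(y)) stop("non-numeric case count in ", path)
  setNames(y, map$ids)
}

#' Baseline expected counts by indirect standardization
#'
#' Allocates the observed case total across regions in proportion to
#' stratum-specific rates: `mu_i^0 = sum_s pop_is * (C_s / P_s)` where
#' `C_s` and `P_s` are stratum case and population totals. With no strata,
#' `mu_i^0 = O * pop_i / P`. The returned vector sums to the case total.
#'
#' Regions with zero population receive `mu_i^0 = 0` and must be removed
#' before analysis (the Poisson likelihood is undefined there); use
#' [drop_zero_expected()], which warns and reduces `m` accordingly.
#'
#' @param population numeric vector (no strata) or matrix (regions x strata)
#'   of person counts.
#' @param cases numeric: total observed cases (scalar, no strata) or vector
#'   of per-stratum case totals.
#' @return numeric vector of `mu_i^0` per region.
#' @export
expected_counts <- function(population, cases) {
  if (is.matrix(population)) {
    if (length(cases) != ncol(population)) {
      stop("per-stratum case totals must align with population strata")
    }
    P_s <- colSums(population)
    if (any(P_s <= 0)) stop("zero total population in a stratum")
    drop(population %*% (cases / P_s))
  } else {
    P <- sum(population)
    if (P <= 0) stop("zero total population")
    sum(cases) * population / P
  }
}

#' Drop regions with zero baseline expectation
#'
#' @param map a [region_map()].
#' @param observed per-region case counts.
#' @param expected0 per-region baseline expectations, possibly with zeros.
#' @return list with the reduced `map` and a [case_data()] on it.
#' @export
drop_zero_expected <- function(map, observed, expected0) {
  bad <- which(expected0 <= 0)
  if (length(bad)) {
    warning("removing ", length(bad), " region(s) with zero baseline ",
            "expectation: ", paste(head(map$ids[bad], 5L), collapse = ", "))
    keep <- setdiff(seq_len(map$m), bad)
    nbrs <- if (!is.null(map$nbrs)) {
      lapply(map$nbrs[keep], function(v) match(setdiff(v, bad), keep))
    }
    map <- region_map(map$ids[keep], map$coords[keep, , drop = FALSE],
                      nbrs = nbrs, geographic = map$geographic)
    observed <- observed[keep]
    expected0 <- expected0[keep]
  }
  list(map = map, data = case_data(observed, expected0))
}
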