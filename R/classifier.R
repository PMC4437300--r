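#' Uniformity filter for clustering features
#'
#' Screens candidate features, retaining exactly those whose empirical
#' distribution rejects uniformity over the feature's observed min-max
#' range (one-sample Kolmogorov-Smirnov against the uniform law, asymptotic
#' p). Constant (zero-range) features are dropped as degenerate. Note the
#' deliberate circularity: the uniform reference range is estimated from
#' the data, which anchors the extremes at 0 and 1 and makes the test
#' slightly conservative.
#'
#' @param x numeric matrix or data frame, cells x features, no missing
#'   values.
#' @param alpha significance level for rejecting uniformity (default 0.05).
#' @return A list: `matrix` (the retained columns) and `report` (data frame
#'   with per-feature statistic, p value and decision).
#' @export
uniformity_filter <- function(x, alpha = 0.05) {
  x <- as.matrix(x)
  if (nrow(x) < 8) .stopf("need at least 8 cells per feature to test uniformity")
  rep_rows <- lapply(colnames(x), function(nm) {
    col <- x[, nm]
    rng <- range(col)
    if (diff(rng) == 0)
      return(data.frame(feature = nm, statistic = NA_real_, p = NA_real_,
                        retained = FALSE, note = "degenerate (zero range)"))
    u <- (col - rng[1]) / diff(rng)
    ks <- suppressWarnings(stats::ks.test(u, "punif", exact = FALSE))
    data.frame(feature = nm, statistic = unname(ks$statistic),
               p = ks$p.value, retained = ks$p.value < alpha, note = "")
  })
  report <- do.call(rbind, rep_rows)
  keep <- report$feature[report$retained]
  if (!length(keep))
    .stopf(paste("all features dropped by the uniformity filter;",
                 "select features manually or raise alpha"))
  list(matrix = x[, keep, drop = FALSE], report = report)
}

#' Min-max normalization
#'
#' Rescales each feature to `(x - min) / (max - min)`, so column minima are
#' 0 and maxima 1. Zero-range columns are an error: filter them first.
#'
#' @param x numeric matrix or data frame, no missing values.
#' @return A matrix of the same shape with values in [0, 1].
#' @export
minmax_normalize <- function(x) {
  x <- as.matrix(x)
  rngs <- apply(x, 2, range)
  if (any(rngs[2, ] == rngs[1, ]))
    .stopf("zero-range column(s): %s; drop before normalizing",
           paste(colnames(x)[rngs[2, ] == rngs[1, ]], collapse = ", "))
  sweep(sweep(x, 2, rngs[1, ]), 2, rngs[2, ] - rngs[1, ], "/")
}

#' Ward's-method agglomerative clustering on squared Euclidean distances
#'
#' The four-step agglomeration: every point starts as its own cluster; at
#' each step the merge that minimizes the increase in total within-cluster
#' error sum of squares (ESS) is performed, via the Lance-Williams update
#' on squared Euclidean distances, until one cluster remains. Merge heights
#' are the ESS increases themselves (not their square roots). Equal-cost
#' ties are broken toward the pair with the lexicographically smallest
#' (oldest) cluster indices, so results are platform-deterministic.
#'
#' @param x numeric matrix or data frame (normally min-max normalized),
#'   n >= 2 rows, no missing values.
#' @return An object of class `ward_dendrogram`: `merge` (hclust
#'   convention: negative entries are singletons), `height` (ESS increase
#'   per merge), `size` (merged cluster sizes), `n`.
#' @export
ward_cluster <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 2) .stopf("need at least 2 points to cluster")
  if (anyNA(x)) .stopf("missing values are not allowed; exclude those cells first")
  # LW distance between singletons = squared Euclidean = 2 * ESS increase
  d <- as.matrix(stats::dist(x))^2
  size <- rep(1L, n)
  id <- -(1:n)                 # hclust convention: negative = singleton
  active <- rep(TRUE, n)
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  msize <- integer(n - 1L)
  for (m in seq_len(n - 1L)) {
    best <- Inf; bi <- 0L; bj <- 0L
    act <- which(active)
    for (ii in seq_len(length(act) - 1L)) {
      i <- act[ii]
      dij <- d[i, act[(ii + 1L):length(act)]]
      w <- which(dij < best)
      if (length(w)) {       # strict < keeps the lexicographically first pair
        k <- w[which.min(dij[w])]
        best <- dij[k]; bi <- i; bj <- act[ii + k]
      }
    }
    merge[m, ] <- c(id[bi], id[bj])
    height[m] <- best / 2      # ESS increase
    # Lance-Williams update for Ward on squared Euclidean distances
    ni <- size[bi]; nj <- size[bj]
    for (k in act) {
      if (k == bi || k == bj) next
      nk <- size[k]
      d[bi, k] <- d[k, bi] <-
        ((ni + nk) * d[bi, k] + (nj + nk) * d[bj, k] - nk * d[bi, bj]) /
        (ni + nj + nk)
    }
    size[bi] <- ni + nj
    active[bj] <- FALSE
    id[bi] <- m
    msize[m] <- size[bi]
  }
  structure(list(merge = merge, height = height, size = msize, n = n),
            class = "ward_dendrogram")
}

#' @export
print.ward_dendrogram <- function(x, ...) {
  cat(sprintf("<ward_dendrogram> %d points, %d merges, heights %g .. %g\n",
              x$n, length(x$height), min(x$height), max(x$height)))
  invisible(x)
}

#' Convert a Ward dendrogram to an `hclust` object
#'
#' Heights are the ESS increases; useful for plotting with
#' [stats::plot.hclust()] or comparing against [stats::hclust()] output.
#'
#' @param tree a [ward_cluster()] result.
#' @param labels optional leaf labels.
#' @return An object of class `hclust`.
#' @export
as_hclust <- function(tree, labels = NULL) {
  stopifnot(inherits(tree, "ward_dendrogram"))
  ord <- integer(0)
  expand <- function(node) {
    if (node < 0) return(-node)
    c(expand(tree$merge[node, 1]), expand(tree$merge[node, 2]))
  }
  structure(list(merge = tree$merge, height = tree$height,
                 order = expand(nrow(tree$merge)),
                 labels = labels, method = "ward (squared Euclidean)",
                 call = match.call(), dist.method = "squared euclidean"),
            class = "hclust")
}

#' Cut a Ward dendrogram into k clusters
#'
#' Applies the first `n - k` merges and labels the resulting components.
#' Labels are numbered by decreasing cluster size, ties broken by first
#' appearance in row order.
#'
#' @param tree a [ward_cluster()] result.
#' @param k desired number of clusters, `1 <= k <= n`.
#' @return Integer vector of cluster labels in `1..k`, one per input row.
#' @export
assign_labels <- function(tree, k) {
  stopifnot(inherits(tree, "ward_dendrogram"))
  n <- tree$n
  if (k < 1 || k > n) .stopf("k must lie in [1, %d]", n)
  members <- c(as.list(1:n), vector("list", n - 1L))
  for (m in seq_len(n - k)) {
    a <- tree$merge[m, 1]; b <- tree$merge[m, 2]
    ma <- if (a < 0) -a else members[[n + a]]
    mb <- if (b < 0) -b else members[[n + b]]
    members[[n + m]] <- c(ma, mb)
  }
  # walk merges newest-first: the first time a point appears, its merged
  # set is a final cluster
  comp <- rep(NA_integer_, n)
  cid <- 0L
  for (m in rev(seq_len(n - k))) {
    idx <- members[[n + m]]
    if (all(is.na(comp[idx]))) { cid <- cid + 1L; comp[idx] <- cid }
  }
  for (i in which(is.na(comp))) { cid <- cid + 1L; comp[i] <- cid }
  # renumber by decreasing size, ties by first-seen row order
  sizes <- table(comp)
  first_seen <- vapply(as.integer(names(sizes)),
                       function(g) min(which(comp == g)), integer(1))
  ord <- order(-as.integer(sizes), first_seen)
  map <- integer(length(sizes))
  map[as.integer(names(sizes))[ord]] <- seq_along(ord)
  map[comp]
}

#' Full classification pipeline
#'
#' Uniformity-filters the feature table (optional), min-max normalizes,
#' Ward-clusters, and cuts at `k`. Cells with any missing retained feature
#' are excluded from clustering and reported.
#'
#' @param features data frame or matrix of candidate features (cells x
#'   features).
#' @param k number of clusters to cut (analyst's choice).
#' @param alpha uniformity-filter significance level.
#' @param filter apply the uniformity filter? (`FALSE` to cluster on all
#'   columns).
#' @return A list: `labels` (NA for excluded cells), `tree`, `report`
#'   (uniformity-filter report or NULL), `excluded` (row indices with
#'   missing retained features).
#' @export
classify_cells <- function(features, k, alpha = 0.05, filter = TRUE) {
  x <- as.matrix(features)
  if (filter) {
    cc <- stats::complete.cases(x)
    uf <- uniformity_filter(x[cc, , drop = FALSE], alpha = alpha)
    x <- x[, colnames(uf$matrix), drop = FALSE]
    report <- uf$report
  } else report <- NULL
  excluded <- which(!stats::complete.cases(x))
  keep <- setdiff(seq_len(nrow(x)), excluded)
  if (length(keep) < 2) .stopf("fewer than 2 complete cells to cluster")
  tree <- ward_cluster(minmax_normalize(x[keep, , drop = FALSE]))
  lab <- rep(NA_integer_, nrow(x))
  lab[keep] <- assign_labels(tree, k)
  list(labels = lab, tree = tree, report = report, excluded = excluded)
}
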