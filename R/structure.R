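# Population stratification: classical (metric) multidimensional scaling of
# the IBS-derived distance matrix, k-means clustering on the leading axes,
# and silhouette-based choice of the cluster count.

#' Classical MDS of an IBS kinship matrix
#'
#' Distances are `D = 1 - IBS`; the doubly centered matrix
#' `B = -1/2 J D^2 J` is eigendecomposed and the top axes scaled by the
#' square root of their eigenvalues (Gower's classical scaling, the
#' `cmdscale` construction). A requested axis with non-positive eigenvalue
#' is zeroed and flagged.
#'
#' @param ibs an [IBSMatrix-class] (or a similarity matrix in `[0, 1]`
#'   with unit diagonal).
#' @param nDims number of axes to return (default 3, matching clustering on
#'   the first three components).
#' @return list with `ids`, `coordinates` (n x nDims, column means zero),
#'   `eigenvalues` (all n), and `zeroed` (logical per returned axis).
#' @export
classicalMds <- function(ibs, nDims = 3) {
  S <- if (is.matrix(ibs)) ibs else kinshipValues(ibs)
  n <- nrow(S)
  if (nDims >= n) stop("nDims must be smaller than the number of individuals")
  if (anyNA(S)) stop("IBS matrix contains NA entries")
  D2 <- (1 - S)^2
  B <- -0.5 * (sweep(sweep(D2, 1, rowMeans(D2)), 2, colMeans(D2)) +
                 mean(D2))
  B <- (B + t(B)) / 2
  eg <- eigen(B, symmetric = TRUE)
  coords <- matrix(0, n, nDims)
  zeroed <- logical(nDims)
  for (k in seq_len(nDims)) {
    if (eg$values[k] > n * .Machine$double.eps * abs(eg$values[1])) {
      coords[, k] <- eg$vectors[, k] * sqrt(eg$values[k])
    } else {
      zeroed[k] <- TRUE
    }
  }
  if (any(zeroed))
    warning("non-positive eigenvalue(s); axis ",
            paste(which(zeroed), collapse = ", "), " zeroed")
  coords <- sweep(coords, 2, colMeans(coords))
  rownames(coords) <- rownames(S)
  list(ids = rownames(S), coordinates = coords, eigenvalues = eg$values,
       zeroed = zeroed)
}

# k-means++ seeding: spread initial centers with probability proportional
# to squared distance from the nearest chosen center.
.kmeansppCenters <- function(x, k) {
  n <- nrow(x)
  idx <- integer(k)
  idx[1] <- sample.int(n, 1)
  if (k > 1) {
    d2 <- rowSums(sweep(x, 2, x[idx[1], ])^2)
    for (j in 2:k) {
      if (sum(d2) <= 0) {
        idx[j] <- sample.int(n, 1)
      } else {
        idx[j] <- sample.int(n, 1, prob = d2)
      }
      d2 <- pmin(d2, rowSums(sweep(x, 2, x[idx[j], ])^2))
    }
  }
  x[idx, , drop = FALSE]
}

#' k-means clustering into subpopulations
#'
#' Lloyd's algorithm seeded by k-means++, best of `nStarts` restarts by
#' within-cluster sum of squares; deterministic under a fixed seed. Starts
#' that converge with an empty cluster are retried.
#'
#' @param coords MDS result from [classicalMds()] or a coordinate matrix.
#' @param k number of clusters (2..n; `k = n` puts every individual in its
#'   own cluster).
#' @param nStarts random restarts (default 50).
#' @param seed integer seed.
#' @return list with `ids`, `cluster` (named integer labels in 1..k), `k`,
#'   `sizes`, and `wcss` (total within-cluster sum of squares).
#' @export
kmeansClusters <- function(coords, k, nStarts = 50, seed = 1) {
  x <- if (is.list(coords) && !is.data.frame(coords)) coords$coordinates
       else as.matrix(coords)
  n <- nrow(x)
  if (k < 1 || k > n) stop("k must lie in 1..n")
  if (!is.null(seed)) set.seed(seed)
  if (k == n) {
    cl <- stats::setNames(seq_len(n), rownames(x))
    return(list(ids = rownames(x), cluster = cl, k = k,
                sizes = rep(1L, n), wcss = 0))
  }
  best <- NULL
  for (s in seq_len(nStarts)) {
    fit <- NULL
    for (try in 1:20) {
      centers <- .kmeansppCenters(x, k)
      fit <- tryCatch(
        suppressWarnings(stats::kmeans(x, centers = centers,
                                       algorithm = "Lloyd",
                                       iter.max = 200)),
        error = function(e) NULL)
      if (!is.null(fit) && length(unique(fit$cluster)) == k) break
      fit <- NULL
    }
    if (is.null(fit)) next
    if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
  }
  if (is.null(best)) stop("k-means failed to produce ", k,
                          " non-empty clusters")
  cl <- stats::setNames(as.integer(best$cluster), rownames(x))
  list(ids = rownames(x), cluster = cl, k = k,
       sizes = as.integer(table(factor(cl, levels = seq_len(k)))),
       wcss = best$tot.withinss)
}

#' Choose the number of subpopulations by mean silhouette
#'
#' Runs [kmeansClusters()] for every candidate `k` and returns the one with
#' the largest mean silhouette width over the coordinate distances; callers
#' may always override `k` explicitly.
#'
#' @param coords MDS result or coordinate matrix.
#' @param kRange candidate cluster counts (default 2:10, clipped to n - 1).
#' @param nStarts restarts per candidate.
#' @param seed integer seed.
#' @return list with `k` (chosen), `diagnostics` (one row per candidate:
#'   k, mean silhouette, WCSS) and `assignments` (the chosen clustering).
#' @export
chooseK <- function(coords, kRange = 2:10, nStarts = 50, seed = 1) {
  x <- if (is.list(coords) && !is.data.frame(coords)) coords$coordinates
       else as.matrix(coords)
  n <- nrow(x)
  kRange <- kRange[kRange >= 2 & kRange <= n - 1]
  if (!length(kRange)) stop("kRange must contain values in [2, n - 1]")
  if (sum(stats::dist(x)) == 0) stop("degenerate coordinates (all identical)")
  dd <- stats::dist(x)
  rows <- vector("list", length(kRange))
  fits <- vector("list", length(kRange))
  for (i in seq_along(kRange)) {
    k <- kRange[i]
    fit <- kmeansClusters(x, k, nStarts = nStarts,
                          seed = deriveSeed(seed, "chooseK", k))
    sil <- cluster::silhouette(fit$cluster, dd)
    rows[[i]] <- data.frame(k = k,
                            mean_silhouette = mean(sil[, "sil_width"]),
                            wcss = fit$wcss)
    fits[[i]] <- fit
  }
  diag <- do.call(rbind, rows)
  bestI <- which.max(diag$mean_silhouette)
  list(k = kRange[bestI], diagnostics = diag, assignment = fits[[bestI]])
}
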