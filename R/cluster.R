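#' Equal-weighted, standardized feature matrix for clustering
#'
#' Builds the clustering input from acoustic feature vectors: each column is
#' standardized to zero mean and unit variance, then multiplied by its feature
#' group's weight. The three groups follow the frequency / duration / contour
#' partition of the acoustic parameters:
#' * `frequency`: `pf_mean`, `pf_min`, `pf_max`, `pf_start`, `pf_end`,
#'   `bandwidth`
#' * `duration`: `duration`
#' * `contour`: `slope`, `sinuosity`, `tonality_mean`, `n_syllables`
#'
#' Standardization precedes weighting so a unit weight gives each group
#' commensurable leverage regardless of physical units. Zero-variance columns
#' are left at 0 after centering.
#'
#' @param features Feature tibble (rows with missing features are dropped).
#' @param weights Named numeric vector of group weights; default all 1.
#' @return A numeric matrix with attribute `"groups"` naming each column's
#'   group; row attribute `"kept"` gives the retained row indices.
#' @export
weighted_feature_matrix <- function(features,
                                    weights = c(frequency = 1, duration = 1,
                                                contour = 1)) {
  groups <- c(
    pf_mean = "frequency", pf_min = "frequency", pf_max = "frequency",
    pf_start = "frequency", pf_end = "frequency", bandwidth = "frequency",
    duration = "duration",
    slope = "contour", sinuosity = "contour", tonality_mean = "contour",
    n_syllables = "contour"
  )
  cols <- intersect(names(groups), names(features))
  if (!length(cols)) stop("no clustering feature columns present")
  x <- as.matrix(features[, cols, drop = FALSE])
  kept <- which(stats::complete.cases(x))
  if (!length(kept)) stop("no complete feature rows to cluster")
  x <- x[kept, , drop = FALSE]
  x <- scale(x)
  x[, attr(x, "scaled:scale") == 0] <- 0   # zero-variance columns stay at 0
  x[is.nan(x)] <- 0
  g <- groups[cols]
  w <- weights[g]
  if (anyNA(w)) stop("weights must name the groups: frequency, duration, contour")
  x <- sweep(x, 2, w, "*")
  attr(x, "scaled:center") <- NULL
  attr(x, "scaled:scale") <- NULL
  attr(x, "groups") <- unname(g)
  attr(x, "kept") <- kept
  x
}

# Best-of-restarts k-means for one k; an optional warm start (previous
# centroids plus the worst-fit point) guarantees inertia(k) <= inertia(k-1).
kmeans_once <- function(x, k, replicates, warm_centers = NULL) {
  if (k >= nrow(x)) {   # every point its own centroid; inertia exactly 0
    return(list(cluster = seq_len(nrow(x)), centers = x,
                tot.withinss = 0, size = rep(1L, nrow(x))))
  }
  best <- stats::kmeans(x, centers = k, nstart = replicates, iter.max = 50)
  if (!is.null(warm_centers)) {
    d2 <- rowSums((x - warm_centers[max.col(-proxy_dist2(x, warm_centers)), ,
                                    drop = FALSE])^2)
    far <- which.max(d2)
    cand <- rbind(warm_centers, x[far, ])
    if (!anyDuplicated(cand)) {
      km2 <- tryCatch(
        stats::kmeans(x, centers = cand, iter.max = 50),
        error = function(e) NULL
      )
      if (!is.null(km2) && km2$tot.withinss < best$tot.withinss) best <- km2
    }
  }
  best
}

proxy_dist2 <- function(x, centers) {
  # squared euclidean distances, n x k
  xx <- rowSums(x^2)
  cc <- rowSums(centers^2)
  outer(xx, cc, "+") - 2 * x %*% t(centers)
}

#' Choose the number of clusters by the elbow method
#'
#' Runs seeded best-of-`replicates` k-means for k = 1..`max_clusters`, records
#' the within-cluster sum of squares (inertia) curve, and returns the k whose
#' point on the curve has maximal perpendicular distance to the chord joining
#' the curve's endpoints -- a standard concretization of the elbow criterion.
#'
#' @param x Feature matrix from [weighted_feature_matrix()].
#' @param max_clusters Largest k to consider (default 50); lowered
#'   automatically when fewer points are available.
#' @param replicates Random restarts per k (default 100).
#' @param seed Integer seed.
#' @return Integer k, with the inertia curve attached as attribute
#'   `"inertia"` (a tibble with columns `k`, `inertia`).
#' @export
choose_k_elbow <- function(x, max_clusters = 50, replicates = 100, seed = 1L) {
  n <- nrow(x)
  if (n < 3L) stop("need at least 3 points to choose a cluster number")
  max_k <- min(max_clusters, n)
  withr::with_seed(as.integer(seed), {
    inertia <- numeric(max_k)
    prev <- NULL
    for (k in seq_len(max_k)) {
      km <- kmeans_once(x, k, replicates, warm_centers = prev)
      inertia[k] <- km$tot.withinss
      prev <- km$centers
    }
  })
  ks <- seq_len(max_k)
  # perpendicular distance of each (k, inertia) point to the endpoint chord
  x1 <- ks[1]; y1 <- inertia[1]; x2 <- ks[max_k]; y2 <- inertia[max_k]
  denom <- sqrt((x2 - x1)^2 + (y2 - y1)^2)
  dist <- abs((y2 - y1) * ks - (x2 - x1) * inertia + x2 * y1 - y2 * x1) /
    max(denom, .Machine$double.eps)
  k_opt <- as.integer(ks[which.max(dist)])
  attr(k_opt, "inertia") <- tibble::tibble(k = ks, inertia = inertia)
  k_opt
}

#' K-means clustering of calls
#'
#' Best-of-`replicates` seeded k-means on a standardized, group-weighted
#' feature matrix. Deterministic given the seed.
#'
#' @param x Feature matrix from [weighted_feature_matrix()].
#' @param k Number of clusters (must not exceed the number of points).
#' @param replicates Random restarts.
#' @param seed Integer seed.
#' @return A `usv_kmeans` object: `k`, `centroids`, `assignments`, `inertia`,
#'   `sizes`, `seed`; if `x` carries the elbow curve (see
#'   [choose_k_elbow()]), pass it via `inertia_curve` to archive it.
#' @param inertia_curve Optional inertia-vs-k tibble to store with the model.
#' @export
kmeans_cluster <- function(x, k, replicates = 100, seed = 1L,
                           inertia_curve = NULL) {
  n <- nrow(x)
  if (k > n) stop("k must not exceed the number of points")
  km <- withr::with_seed(as.integer(seed), kmeans_once(x, k, replicates))
  structure(
    list(
      k = as.integer(k), centroids = km$centers,
      assignments = as.integer(km$cluster),
      inertia = km$tot.withinss, sizes = as.integer(km$size),
      inertia_curve = inertia_curve, seed = as.integer(seed)
    ),
    class = "usv_kmeans"
  )
}

#' @export
print.usv_kmeans <- function(x, ...) {
  cat(sprintf("<usv_kmeans: k = %d, n = %d, inertia = %.2f>\n",
              x$k, length(x$assignments), x$inertia))
  cat("cluster sizes:", paste(x$sizes, collapse = " "), "\n")
  invisible(x)
}

#' Compare clusters with reference call types
#'
#' Cross-tabulates cluster assignments against reference call-type labels,
#' maps every cluster to its majority type, and reports per-cluster purity.
#' Merging clusters by majority type yields the partition used to judge
#' whether the unsupervised categories recover the human-made call types.
#'
#' @param assignments Integer cluster ids.
#' @param true_labels Reference labels, same length.
#' @return A list: `contingency` (tibble cluster x type counts, wide),
#'   `mapping` (tibble: cluster, majority_type, n, purity),
#'   `merged_labels` (majority type per observation), `coverage` (number of
#'   distinct types appearing as a majority).
#' @export
match_clusters_to_types <- function(assignments, true_labels) {
  if (length(assignments) != length(true_labels)) {
    stop("assignments and labels must have equal length")
  }
  tab <- table(cluster = assignments, type = true_labels)
  mapping <- tibble::tibble(
    cluster = as.integer(rownames(tab)),
    majority_type = colnames(tab)[max.col(tab, ties.method = "first")],
    n = as.integer(rowSums(tab))
  )
  mapping$purity <- apply(tab, 1, max) / pmax(rowSums(tab), 1)
  merged <- mapping$majority_type[match(assignments, mapping$cluster)]
  list(
    contingency = tibble::as_tibble(as.data.frame.matrix(unclass(tab)),
                                    rownames = "cluster"),
    mapping = mapping,
    merged_labels = merged,
    coverage = length(unique(mapping$majority_type))
  )
}
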