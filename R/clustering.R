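#' Build the standardized behavioral feature matrix
#'
#' Rows are cells; columns are the four behavioral phenotype features (peak
#' velocity, total distance, lifespan, directionality), z-scored to zero mean
#' and unit variance. Cells with undefined directionality (zero net
#' displacement) or any non-finite feature are excluded and counted.
#'
#' @param metrics data frame from [motility_metrics()].
#' @return numeric matrix with attributes `"states"`, `"conditions"`,
#'   `"cell_ids"` (aligned to rows), `"excluded"` (count) and `"center"`/
#'   `"scale"` from the standardization.
#' @export
build_features <- function(metrics) {
  feats <- c("peak_velocity", "total_distance", "lifespan", "directionality")
  x <- as.matrix(metrics[feats])
  ok <- apply(is.finite(x), 1L, all)
  if (sum(ok) < 2L) stop("fewer than 2 usable rows after exclusions")
  xs <- scale(x[ok, , drop = FALSE])
  structure(xs[, , drop = FALSE],
            states = metrics$state[ok],
            conditions = metrics$condition[ok],
            cell_ids = metrics$cell_id[ok],
            excluded = sum(!ok),
            center = attr(xs, "scaled:center"),
            scale = attr(xs, "scaled:scale"))
}

#' Principal component analysis of the feature matrix
#'
#' Thin wrapper around [stats::prcomp()] (no re-scaling: the input is already
#' standardized) returning scores, orthonormal loadings and variance
#' fractions.
#'
#' @param features matrix from [build_features()].
#' @return list with `scores`, `loadings`, `variance_fraction`.
#' @export
run_pca <- function(features) {
  sds <- apply(features, 2L, stats::sd)
  bad <- !is.finite(sds) | sds == 0 |
    apply(features, 2L, function(x) !all(is.finite(x)))
  if (any(bad))
    stop("constant column(s): ",
         paste(colnames(features)[bad], collapse = ", "))
  p <- stats::prcomp(features, center = FALSE, scale. = FALSE)
  list(scores = p$x, loadings = p$rotation,
       variance_fraction = p$sdev^2 / sum(p$sdev^2))
}

#' Data-driven choice of the number of clusters
#'
#' Builds a Ward-linkage dendrogram of the standardized features and cuts it
#' at every k in `2..k_max`, choosing the k with the largest mean silhouette
#' width (smallest k on ties). Deterministic: no random initialization is
#' involved.
#'
#' @param features matrix from [build_features()] (>= 10 rows).
#' @param k_max largest k considered (default 8).
#' @return a single integer k, with attribute `"silhouette"` holding the
#'   mean widths per candidate k.
#' @export
choose_k <- function(features, k_max = 8L) {
  n <- nrow(features)
  if (n < 10L) stop("need at least 10 rows to select k")
  ks <- 2:min(k_max, n - 1L)
  d <- stats::dist(features)
  hc <- stats::hclust(d, method = "ward.D2")
  sil <- vapply(ks, function(k) {
    cl <- stats::cutree(hc, k = k)
    mean(cluster::silhouette(cl, d)[, "sil_width"])
  }, numeric(1))
  k <- ks[which.max(sil)]
  structure(as.integer(k), silhouette = stats::setNames(sil, ks))
}

#' Seeded k-means partition of the feature matrix
#'
#' Best of 25 random restarts by within-cluster sum of squares, deterministic
#' for a fixed seed.
#'
#' @param features matrix from [build_features()].
#' @param k number of clusters (>= 2).
#' @param seed integer seed.
#' @return integer cluster assignments (length `nrow(features)`), with the
#'   fitted [stats::kmeans()] object in attribute `"fit"`.
#' @export
kmeans_cluster <- function(features, k, seed = 1L) {
  if (k < 2L) stop("k must be >= 2")
  if (k > nrow(features)) stop("k exceeds the number of rows")
  set.seed(seed)
  km <- stats::kmeans(features, centers = k, nstart = 25L, iter.max = 100L)
  structure(km$cluster, fit = km)
}

#' State-by-cluster enrichment table
#'
#' Counts of each cell state per cluster plus row-normalized percentages
#' (each state's rows sum to 100%), with the predominant cluster per state
#' marked. States absent from the data are omitted with a warning.
#'
#' @param assignments integer cluster ids per cell.
#' @param states character state labels aligned with `assignments`.
#' @return list with `counts` and `percent` matrices (rows = states) and
#'   `predominant` (named integer vector).
#' @export
enrichment_table <- function(assignments, states) {
  if (length(assignments) != length(states))
    stop("assignments and states must be aligned")
  present <- unique(states)
  counts <- table(factor(states, levels = present),
                  factor(assignments, levels = sort(unique(assignments))))
  counts <- unclass(as.matrix(counts))
  if (any(rowSums(counts) == 0L)) {
    warning("state(s) without cells omitted: ",
            paste(rownames(counts)[rowSums(counts) == 0L], collapse = ", "))
    counts <- counts[rowSums(counts) > 0L, , drop = FALSE]
  }
  percent <- 100 * counts / rowSums(counts)
  predominant <- apply(percent, 1L, which.max)
  predominant <- stats::setNames(as.integer(colnames(percent)[predominant]),
                                 rownames(percent))
  list(counts = counts, percent = percent, predominant = predominant)
}

#' End-to-end behavioral phenotype clustering
#'
#' Convenience wrapper: feature building, PCA (for reporting), silhouette-
#' guided k selection (unless `k` is given), seeded k-means in feature space
#' and the state enrichment table.
#'
#' @param metrics data frame from [motility_metrics()].
#' @param k optional fixed number of clusters; chosen by [choose_k()] when
#'   `NULL`.
#' @param seed integer seed for the k-means restarts.
#' @param k_max passed to [choose_k()].
#' @return object of class `cluster_report`: list with `features`, `pca`,
#'   `k`, `assignments`, `enrichment`, `excluded`.
#' @export
cluster_phenotypes <- function(metrics, k = NULL, seed = 1L, k_max = 8L) {
  features <- build_features(metrics)
  pca <- run_pca(features)
  if (is.null(k)) k <- choose_k(features, k_max = k_max)
  assignments <- kmeans_cluster(features, k = k, seed = seed)
  enrichment <- enrichment_table(assignments, attr(features, "states"))
  structure(list(features = features, pca = pca, k = as.integer(k),
                 assignments = assignments, enrichment = enrichment,
                 excluded = attr(features, "excluded")),
            class = "cluster_report")
}

#' @export
print.cluster_report <- function(x, ...) {
  cat("<cluster_report> ", nrow(x$features), " cells, k = ", x$k,
      " (", x$excluded, " excluded)\n", sep = "")
  cat("variance explained:",
      paste0(round(100 * x$pca$variance_fraction, 1), "%", collapse = " "),
      "\n")
  cat("state x cluster percentages:\n")
  print(round(x$enrichment$percent, 1))
  invisible(x)
}
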