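# squared Euclidean distances between rows of x (n x d) and rows of c (k x d)
.dist2 <- function(x, centers) {
  outer(rowSums(x^2), rowSums(centers^2), "+") - 2 * x %*% t(centers)
}

# k-means++ seeding (Arthur & Vassilvitskii): spread initial centers with
# probability proportional to squared distance from the chosen set
.kmeanspp_init <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(0, k, ncol(x))
  centers[1, ] <- x[sample.int(n, 1), ]
  d2 <- pmax(.dist2(x, centers[1, , drop = FALSE])[, 1], 0)
  for (j in seq_len(k)[-1]) {
    if (sum(d2) <= 0) {
      centers[j, ] <- x[sample.int(n, 1), ]   # all points coincide
    } else {
      centers[j, ] <- x[sample.int(n, 1, prob = d2), ]
      d2 <- pmin(d2, pmax(.dist2(x, centers[j, , drop = FALSE])[, 1], 0))
    }
  }
  centers
}

# one Lloyd run; returns labels, centers, inertia. Empty clusters are
# re-seeded at the point farthest from its assigned center.
.lloyd <- function(x, centers, max_iter = 100) {
  k <- nrow(centers)
  inertia_prev <- Inf
  labels <- rep(1L, nrow(x))
  for (iter in seq_len(max_iter)) {
    d2 <- .dist2(x, centers)
    labels_new <- max.col(-d2, ties.method = "first")
    pt_d2 <- pmax(d2[cbind(seq_len(nrow(x)), labels_new)], 0)
    empty <- which(tabulate(labels_new, k) == 0)
    if (length(empty)) {
      avail <- pt_d2           # each empty cluster steals a distinct point
      for (j in empty) {
        far <- which.max(avail)
        labels_new[far] <- j
        pt_d2[far] <- 0
        avail[far] <- -Inf
      }
    }
    inertia <- sum(pt_d2)
    # Lloyd's objective is non-increasing; tolerate float round-off only
    stopifnot(inertia <= inertia_prev * (1 + 1e-12) + 1e-12)
    converged <- identical(labels_new, labels) && iter > 1
    labels <- labels_new
    inertia_prev <- inertia
    if (converged) break
    for (j in seq_len(k)) {
      idx <- labels == j
      if (any(idx)) centers[j, ] <- colMeans(x[idx, , drop = FALSE])
    }
  }
  list(labels = labels, centers = centers, inertia = inertia_prev,
       iterations = iter)
}

# order centroids by descending L2 norm, ties by the first differing
# coordinate, so cluster numbering is reproducible across runs and machines
.canonical_order <- function(centers) {
  norms <- sqrt(rowSums(centers^2))
  do.call(order, c(list(-norms), lapply(seq_len(ncol(centers)),
                                        function(j) centers[, j])))
}

# short content fingerprint so transfer assignment can refuse a wrong model
.model_fingerprint <- function(centers) {
  v <- as.numeric(centers)
  sprintf("k%dd%d-%.12e-%.12e", nrow(centers), ncol(centers),
          sum(v), sum(v * seq_along(v)))
}

#' Fit per-channel k-means vector quantization of wavelet features
#'
#' Lloyd's algorithm under squared Euclidean distance with k-means++
#' initialization and `n_init` restarts (best inertia kept). Empty clusters
#' arising during iteration are re-seeded at the farthest point. Centroids
#' are put in a canonical order (descending L2 norm) so cluster numbers are
#' reproducible; the fit is fully determined by `seed`.
#'
#' @param features a [extract_features()] result (or any list with an
#'   `x` matrix and `channel`/`level` fields).
#' @param k number of clusters (8 in the reference analysis).
#' @param seed integer RNG seed.
#' @param n_init number of k-means++ restarts.
#' @param max_iter Lloyd iteration cap per restart.
#' @return Object of class `cluster_model` with `centroids` (`k x d`,
#'   canonical order), `labels` (training assignment), `inertia`,
#'   `channel`, `level`, `k`, `seed`, `fingerprint`.
#' @export
fit_channel_clusters <- function(features, k = 8, seed = 1, n_init = 10,
                                 max_iter = 100) {
  x <- features$x
  stopifnot(is.matrix(x), k >= 1)
  if (nrow(x) < k)
    stop("need at least k = ", k, " events, got ", nrow(x))
  best <- NULL
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  for (r in seq_len(n_init)) {
    fit <- .lloyd(x, .kmeanspp_init(x, k), max_iter)
    if (is.null(best) || fit$inertia < best$inertia) best <- fit
  }
  ord <- .canonical_order(best$centers)
  centers <- best$centers[ord, , drop = FALSE]
  labels <- match(best$labels, ord)
  structure(list(channel = features$channel,
                 level = features$level,
                 k = as.integer(k),
                 centroids = centers,
                 labels = as.integer(labels),
                 inertia = best$inertia,
                 seed = as.integer(seed),
                 n_init = as.integer(n_init),
                 fingerprint = .model_fingerprint(centers)),
            class = "cluster_model")
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
}

#' @export
print.cluster_model <- function(x, ...) {
  cat(sprintf("<cluster_model> channel %s level %d: k = %d, inertia %.4g (seed %d)\n",
              x$channel, x$level, x$k, x$inertia, x$seed))
  invisible(x)
}

#' Assign events to frozen cluster centroids
#'
#' Nearest-centroid assignment under squared Euclidean distance; ties break
#' toward the lower canonical cluster index. This is the transfer mechanism
#' that lets later acquisitions (sorted aliquots, arrest time points) be
#' compared against a reference clustering without refitting.
#'
#' @param features a [extract_features()] result.
#' @param model a [fit_channel_clusters()] model.
#' @return Integer vector of cluster labels in `1..k`.
#' @export
assign_clusters <- function(features, model) {
  x <- features$x
  if (ncol(x) != ncol(model$centroids))
    stop("feature dimension ", ncol(x), " does not match model dimension ",
         ncol(model$centroids))
  max.col(-.dist2(x, model$centroids), ties.method = "first")
}

#' Combine two channels' cluster labels into combined clusters
#'
#' The conjunction of one label per channel indexes a `k_A x k_B`
#' contingency table; combined ids are `(a - 1) * k_B + (b - 1)`, in
#' `[0, k_A * k_B)`. With the reference settings (k = 8 on FSCL and FSCU)
#' this yields the 8 x 8 = 64 combined clusters.
#'
#' @param labels_A,labels_B per-event integer labels of the two channels.
#' @param k_A,k_B cluster counts of the two models.
#' @return Object of class `combined_clustering`: `combined_id` (0-based
#'   per-event id), `labels_A`, `labels_B`, `contingency` (`k_A x k_B`
#'   counts), `k_A`, `k_B`.
#' @export
combine_clusters <- function(labels_A, labels_B, k_A, k_B) {
  if (length(labels_A) != length(labels_B))
    stop("label vectors differ in length")
  stopifnot(all(labels_A %in% seq_len(k_A)), all(labels_B %in% seq_len(k_B)))
  combined <- (labels_A - 1L) * as.integer(k_B) + (labels_B - 1L)
  contingency <- table(factor(labels_A, levels = seq_len(k_A)),
                       factor(labels_B, levels = seq_len(k_B)))
  structure(list(combined_id = as.integer(combined),
                 labels_A = as.integer(labels_A),
                 labels_B = as.integer(labels_B),
                 contingency = unclass(contingency),
                 k_A = as.integer(k_A), k_B = as.integer(k_B)),
            class = "combined_clustering")
}

#' @export
print.combined_clustering <- function(x, ...) {
  cat(sprintf("<combined_clustering> %d x %d = %d combined clusters, %d events\n",
              x$k_A, x$k_B, x$k_A * x$k_B, length(x$combined_id)))
  invisible(x)
}

#' Serialize / restore a cluster model
#'
#' Plain-text JSON with full double precision, so a model fit on a reference
#' acquisition can be applied to later ones on any machine.
#'
#' @param model a `cluster_model`.
#' @param path file path.
#' @return `path` (write) or the restored `cluster_model` (read).
#' @export
write_cluster_model <- function(model, path) {
  stopifnot(inherits(model, "cluster_model"))
  obj <- model
  # %.17g round-trips IEEE doubles exactly; plain JSON numbers may lose the
  # last ulp and break the fingerprint
  obj$centroids <- apply(model$centroids, 1,
                         function(r) sprintf("%.17g", r), simplify = FALSE)
  obj$inertia <- sprintf("%.17g", model$inertia)
  obj$format_version <- 1L
  class(obj) <- NULL
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_cluster_model
#' @export
read_cluster_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$format_version) || obj$format_version != 1L)
    stop("unsupported cluster model format version")
  obj$format_version <- NULL
  cm <- if (is.list(obj$centroids)) do.call(rbind, obj$centroids) else
    obj$centroids
  obj$centroids <- matrix(as.numeric(cm), nrow(cm), ncol(cm))
  obj$inertia <- as.numeric(obj$inertia)
  obj$labels <- as.integer(obj$labels)
  if (!identical(.model_fingerprint(obj$centroids), obj$fingerprint))
    stop("cluster model fingerprint mismatch: file corrupted or edited")
  structure(obj, class = "cluster_model")
}
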