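#' Dynamic time warping distance between two GPS trajectories
#'
#' Dynamic-programming alignment under the symmetric step pattern (diagonal
#' step weight 2, horizontal/vertical weight 1), no window constraint. The
#' local metric between fixes is the haversine distance in meters
#' (timestamps do not enter the local cost). The normalized cost divides by
#' the sum of the two sequence lengths, making costs comparable across
#' tracks of different sampling lengths.
#'
#' @param a,b data frames with `lat`, `lon` columns (or 2-column lat/lon
#'   matrices); for `metric = "abs"`, numeric vectors.
#' @param metric `"haversine"` (default) or `"abs"` (absolute difference of
#'   scalar series, for worked examples).
#' @return named numeric vector `c(cost, normalized_cost)`.
#' @examples
#' dtw_distance(c(0, 0), c(1), metric = "abs")  # cost 2, normalized 2/3
#' @export
dtw_distance <- function(a, b, metric = c("haversine", "abs")) {
  metric <- match.arg(metric)
  if (metric == "abs") {
    a <- as.numeric(a); b <- as.numeric(b)
    if (!length(a) || !length(b)) stop("empty sequence")
    cost <- .dtw_cost_abs_cpp(a, b)
    return(c(cost = cost, normalized_cost = cost / (length(a) + length(b))))
  }
  am <- .coord_matrix(a); bm <- .coord_matrix(b)
  if (!nrow(am) || !nrow(bm)) stop("empty sequence")
  cost <- .dtw_cost_cpp(am, bm)
  c(cost = cost, normalized_cost = cost / (nrow(am) + nrow(bm)))
}

.coord_matrix <- function(x) {
  if (is.data.frame(x)) as.matrix(x[, c("lat", "lon")]) else {
    x <- as.matrix(x)
    stopifnot(ncol(x) == 2)
    x
  }
}

#' Pairwise DTW dissimilarity between participants
#'
#' For every pair of participants, the normalized DTW cost between their
#' walking trajectories is computed per matching track and aggregated over
#' the analyzed tracks (sum by default, so every pair is compared over the
#' same five tracks); the full matrix is then min-max normalized to
#' \[0, 1\] over the off-diagonal entries. Requires the complete-case
#' subsample so that all pairs share the same track set.
#'
#' @param clean_tracks list of `clean_track`s (complete cases).
#' @param aggregate `"sum"` (default) or `"mean"` across tracks.
#' @param normalize min-max normalize the aggregated matrix (default TRUE).
#' @return object of class `dissim_matrix`: symmetric matrix with
#'   participant ids as dimnames, zero diagonal.
#' @export
pairwise_dissimilarity <- function(clean_tracks, aggregate = c("sum", "mean"),
                                   normalize = TRUE) {
  aggregate <- match.arg(aggregate)
  ids <- unique(vapply(clean_tracks, `[[`, character(1), "participant_id"))
  tks <- sort(unique(vapply(clean_tracks, function(x) as.numeric(x$track_id),
                            numeric(1))))
  # index trajectories by participant x track
  traj <- list()
  for (ct in clean_tracks) {
    traj[[paste(ct$participant_id, ct$track_id)]] <-
      .coord_matrix(ct$walking_fixes)
  }
  for (id in ids) for (tk in tks) {
    if (is.null(traj[[paste(id, tk)]])) {
      stop("participant ", id, " is missing track ", tk,
           "; apply complete_case_filter() first")
    }
  }
  n <- length(ids)
  D <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      costs <- vapply(tks, function(tk) {
        a <- traj[[paste(ids[i], tk)]]
        b <- traj[[paste(ids[j], tk)]]
        .dtw_cost_cpp(a, b) / (nrow(a) + nrow(b))
      }, numeric(1))
      D[i, j] <- D[j, i] <- if (aggregate == "sum") sum(costs) else mean(costs)
    }
  }
  if (normalize) D <- minmax_normalize(D)
  structure(D, class = c("dissim_matrix", "matrix"))
}

#' Min-max normalize a dissimilarity matrix
#'
#' Rescales the off-diagonal entries to \[0, 1\]; a degenerate all-equal
#' matrix maps to all zeros, and the diagonal stays zero.
#'
#' @param D symmetric dissimilarity matrix.
#' @return rescaled matrix.
#' @export
minmax_normalize <- function(D) {
  off <- D[row(D) != col(D)]
  if (!length(off)) return(D)
  lo <- min(off); hi <- max(off)
  if (hi == lo) {
    D[row(D) != col(D)] <- 0
    return(D)
  }
  D2 <- (D - lo) / (hi - lo)
  diag(D2) <- 0
  D2
}

#' k-medoids (PAM) clustering of a dissimilarity matrix
#'
#' Partitioning around medoids (BUILD initialization followed by SWAP until
#' no improving swap), as implemented in \pkg{cluster}. Reports per-cluster
#' mean distance to the medoid, the mean silhouette, and, when labels are
#' given, the cluster purity.
#'
#' @param D `dissim_matrix` (or any symmetric dissimilarity matrix).
#' @param k number of clusters, `2 <= k < n`.
#' @param labels optional class labels (same order as rows of `D`).
#' @return object of class `cluster_result`: list with `k`, `assignment`,
#'   `medoids` (row indices), `medoid_ids`, `mean_silhouette`,
#'   `avg_dist_to_medoid` (per cluster), `sizes`, `purity` (or NA).
#' @export
pam_cluster <- function(D, k, labels = NULL) {
  D <- unclass(D)
  n <- nrow(D)
  if (k < 2 || k >= n) stop("need 2 <= k < n")
  fit <- cluster::pam(as.dist(D), k = k, diss = TRUE)
  assignment <- unname(fit$clustering)
  medoids <- match(fit$medoids, rownames(D))
  if (anyNA(medoids)) medoids <- as.integer(fit$id.med)
  avg_d <- vapply(seq_len(k), function(cl) {
    members <- which(assignment == cl)
    mean(D[members, medoids[cl]])
  }, numeric(1))
  structure(list(
    k = k,
    assignment = assignment,
    medoids = medoids,
    medoid_ids = rownames(D)[medoids],
    mean_silhouette = mean_silhouette(D, assignment),
    avg_dist_to_medoid = avg_d,
    sizes = as.integer(table(factor(assignment, levels = seq_len(k)))),
    objective = sum(D[cbind(seq_len(n), medoids[assignment])]),
    purity = if (is.null(labels)) NA_real_ else purity(assignment, labels)
  ), class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("pam: k=%d, sizes=%s, mean silhouette=%.3f%s\n", x$k,
              paste(x$sizes, collapse = "/"), x$mean_silhouette,
              if (is.na(x$purity)) "" else sprintf(", purity=%.3f", x$purity)))
  invisible(x)
}

#' Mean silhouette coefficient
#'
#' For observation i, `s(i) = (b - a) / max(a, b)` where `a` is the mean
#' distance to the other members of its own cluster and `b` the minimum
#' over other clusters of the mean distance to that cluster. Members of
#' singleton clusters get `s = 0`, and a degenerate 0/0 is treated as 0.
#'
#' @param D dissimilarity matrix.
#' @param assignment integer cluster assignment.
#' @return mean silhouette in \[-1, 1\].
#' @export
mean_silhouette <- function(D, assignment) {
  D <- unclass(D)
  n <- nrow(D)
  cl <- unique(assignment)
  if (length(cl) < 2) stop("need at least 2 clusters")
  s <- vapply(seq_len(n), function(i) {
    own <- which(assignment == assignment[i])
    if (length(own) == 1) return(0)
    a <- mean(D[i, setdiff(own, i)])
    b <- min(vapply(setdiff(cl, assignment[i]), function(c2) {
      mean(D[i, assignment == c2])
    }, numeric(1)))
    if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }, numeric(1))
  mean(s)
}

#' Cluster purity against class labels
#'
#' `(1/N) * sum over clusters of the majority class count`, i.e. the share
#' of observations belonging to the most frequent class of their cluster.
#' Accepts either an assignment/label vector pair or a precomputed
#' cluster x class contingency table (matrix).
#'
#' @param assignment cluster assignment vector, or a cluster x class count
#'   matrix.
#' @param labels class labels (ignored when a matrix is given).
#' @return purity in \[max class share, 1\].
#' @examples
#' purity(matrix(c(18, 10, 7, 5, 9, 10, 0, 1, 1), 3, byrow = TRUE))  # 0.475
#' @export
purity <- function(assignment, labels = NULL) {
  if (is.matrix(assignment) || is.table(assignment)) {
    tab <- as.matrix(assignment)
  } else {
    if (is.null(labels) || length(labels) != length(assignment)) {
      stop("assignment and labels must have equal length")
    }
    tab <- table(assignment, labels)
  }
  sum(apply(tab, 1, max)) / sum(tab)
}

#' Silhouette-based selection of the number of clusters
#'
#' Fits [pam_cluster()] for each k in `k_range` and returns the k with the
#' highest mean silhouette (ties broken towards smaller k) together with
#' the full silhouette table.
#'
#' @param D dissimilarity matrix.
#' @param k_range candidate cluster counts, default 3:7.
#' @param labels optional class labels, passed through.
#' @return list with `best_k`, `silhouettes` (data frame `k`, `silhouette`),
#'   `fits` (named list of `cluster_result`s), `best` (the chosen fit).
#' @export
select_k <- function(D, k_range = 3:7, labels = NULL) {
  fits <- lapply(k_range, function(k) pam_cluster(D, k, labels))
  names(fits) <- paste0("k", k_range)
  sil <- vapply(fits, `[[`, numeric(1), "mean_silhouette")
  best_i <- which.max(sil) # which.max takes the first (smallest k) on ties
  list(best_k = k_range[best_i],
       silhouettes = data.frame(k = k_range, silhouette = unname(sil)),
       fits = fits,
       best = fits[[best_i]])
}
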