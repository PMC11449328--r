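test_that("DTW reproduces worked examples and basic identities", {
  # identical sequences align along the diagonal at zero cost
  a <- data.frame(lat = 52.1 + (0:5) * 1e-4, lon = 11.6)
  expect_equal(unname(dtw_distance(a, a)["cost"]), 0)
  # scalar worked example: A = [0,0], B = [1] under |.|
  d <- dtw_distance(c(0, 0), c(1), metric = "abs")
  expect_equal(unname(d["cost"]), 2)
  expect_equal(unname(d["normalized_cost"]), 2 / 3)
  expect_error(dtw_distance(numeric(0), c(1), metric = "abs"), "empty")
})

test_that("DTW equals exhaustive path enumeration on short sequences", {
  set.seed(11)
  for (i in 1:50) {
    n <- sample(1:8, 1); m <- sample(1:8, 1)
    a <- round(runif(n, 0, 5), 2)
    b <- round(runif(m, 0, 5), 2)
    dmat <- abs(outer(a, b, "-"))
    expect_equal(unname(dtw_distance(a, b, metric = "abs")["cost"]),
                 oracle_dtw(dmat), tolerance = 1e-9)
  }
  # and symmetry of the cost
  set.seed(12)
  a <- runif(6); b <- runif(7)
  expect_equal(dtw_distance(a, b, metric = "abs")["cost"],
               dtw_distance(b, a, metric = "abs")["cost"],
               ignore_attr = TRUE)
})

test_that("pairwise dissimilarity has the matrix invariants", {
  coh <- small_cohort(seed = 14)
  ing <- ingest_pipeline(coh)
  D <- pairwise_dissimilarity(ing$complete_tracks)
  expect_equal(unname(diag(unclass(D))), rep(0, nrow(D)))
  expect_equal(unclass(D), t(unclass(D)))
  off <- D[row(D) != col(D)]
  expect_equal(min(off), 0)
  expect_equal(max(off), 1)
  # missing track errors towards the complete-case filter
  expect_error(pairwise_dissimilarity(ing$complete_tracks[-1]),
               "complete_case_filter")
})

test_that("a detour walker is more dissimilar than two direct walkers", {
  rm <- build_route_map()
  direct <- group_behavior("OA", 1.25, 0, p_wrong_turn = 0,
                           stop_rate_per_decision_point = 0,
                           stop_zero_inflation = 0, map_view_rate = 0,
                           gps_noise_sd = 1, sd_log_stop_rate = 0,
                           sd_log_map_rate = 0)
  detour <- direct
  detour$p_wrong_turn <- 0.9
  mk <- function(gb, id, seed) {
    lapply(1:5, function(tk) {
      lg <- simulate_track(gb, rm, tk, seed = seed + tk,
                           participant_id = id, group = "OA")
      extract_walking_phase(lg)
    })
  }
  tracks <- c(mk(direct, "A", 100), mk(direct, "B", 200), mk(detour, "C", 300))
  D <- pairwise_dissimilarity(tracks, normalize = FALSE)
  expect_lt(D["A", "B"], D["A", "C"])
  expect_lt(D["A", "B"], D["B", "C"])
})

test_that("degenerate all-equal dissimilarities normalize to zero", {
  D <- matrix(0.7, 4, 4); diag(D) <- 0
  # identical trajectories: all-zero off-diagonal stays zero
  Z <- matrix(0, 3, 3)
  expect_equal(minmax_normalize(Z), Z)
  N <- minmax_normalize(D)
  expect_true(all(N[row(N) != col(N)] == 0))
})

test_that("PAM recovers separated pairs and matches exhaustive search", {
  # two tight pairs far apart
  pts <- c(0, 0.1, 10, 10.1)
  D <- abs(outer(pts, pts, "-"))
  dimnames(D) <- list(letters[1:4], letters[1:4])
  res <- pam_cluster(D, 2)
  expect_equal(res$assignment[1], res$assignment[2])
  expect_equal(res$assignment[3], res$assignment[4])
  expect_false(res$assignment[1] == res$assignment[3])
  expect_equal(res$objective, oracle_pam_objective(D, 2), tolerance = 1e-12)

  # small clustered instances: BUILD + SWAP lands on the exhaustive
  # optimum when the data carry cluster structure
  set.seed(20)
  for (i in 1:20) {
    k <- sample(2:3, 1)
    n <- sample((2 * k + 2):10, 1)
    centers <- matrix(rnorm(k * 2, sd = 12), k)
    x <- centers[rep_len(seq_len(k), n), ] + matrix(rnorm(n * 2), n)
    D <- as.matrix(dist(x))
    dimnames(D) <- list(paste0("p", 1:n), paste0("p", 1:n))
    res <- pam_cluster(D, k)
    expect_equal(res$objective, oracle_pam_objective(D, k), tolerance = 1e-9)
  }
  # pigeonhole at k = n - 1
  n <- 6
  D <- as.matrix(dist(matrix(rnorm(n * 2), n)))
  dimnames(D) <- list(paste0("p", 1:n), paste0("p", 1:n))
  res <- pam_cluster(D, n - 1)
  expect_equal(sort(res$sizes, decreasing = TRUE)[1], 2)
  expect_error(pam_cluster(D, n), "k < n")
})

test_that("silhouette matches a hand-computed example and cluster::silhouette", {
  # 4 points on a line: {0, 1} and {10, 11}, k = 2
  pts <- c(0, 1, 10, 11)
  D <- abs(outer(pts, pts, "-"))
  assign <- c(1, 1, 2, 2)
  # s(1): a = 1, b = mean(10, 11) = 10.5 -> (10.5 - 1)/10.5; same for all
  expected <- mean(c((10.5 - 1) / 10.5, (9.5 - 1) / 9.5,
                     (9.5 - 1) / 9.5, (10.5 - 1) / 10.5))
  expect_equal(mean_silhouette(D, assign), expected, tolerance = 1e-12)
  # cross-check against the cluster package on a random instance
  set.seed(3)
  x <- matrix(rnorm(30), 15)
  D2 <- as.matrix(dist(x))
  as2 <- sample(1:3, 15, replace = TRUE)
  as2[1:3] <- 1:3 # ensure all clusters present
  sil <- cluster::silhouette(as2, dmatrix = D2)
  expect_equal(mean_silhouette(D2, as2), mean(sil[, "sil_width"]),
               tolerance = 1e-9)
  # identical points: degenerate 0
  Z <- matrix(0, 4, 4)
  expect_equal(mean_silhouette(Z, c(1, 1, 2, 2)), 0)
  expect_error(mean_silhouette(Z, rep(1, 4)), "2 clusters")
})

test_that("purity reproduces the published worked examples", {
  # wayfinding-cluster composition: 29 majority members of 61
  expect_equal(purity(matrix(c(18, 10, 7,
                               5, 9, 10,
                               0, 1, 1), 3, byrow = TRUE)), 29 / 61)
  expect_equal(round(purity(matrix(c(18, 10, 7,
                                     5, 9, 10,
                                     0, 1, 1), 3, byrow = TRUE)), 3), 0.475)
  # performance-profile composition: 38 of 61
  expect_equal(round(purity(matrix(c(18, 5, 2,
                                     5, 14, 10,
                                     0, 1, 6), 3, byrow = TRUE)), 3), 0.623)
  # identity assignment
  labs <- rep(c("a", "b", "c"), times = c(5, 3, 2))
  expect_equal(purity(as.integer(factor(labs)), labs), 1)
  expect_error(purity(1:3, c("a", "b")), "equal length")
})

test_that("purity is invariant to relabeling and joint permutation", {
  set.seed(4)
  assign <- sample(1:3, 40, replace = TRUE)
  labs <- sample(c("x", "y", "z"), 40, replace = TRUE)
  p0 <- purity(assign, labs)
  relabeled <- c(3, 1, 2)[assign]
  expect_equal(purity(relabeled, labs), p0)
  perm <- sample(40)
  expect_equal(purity(assign[perm], labs[perm]), p0)
})

test_that("silhouette-based k selection finds planted structure", {
  set.seed(6)
  centers <- rbind(c(0, 0), c(20, 0), c(0, 20))
  x <- do.call(rbind, lapply(1:3, function(k) {
    sweep(matrix(rnorm(24), 12), 2, centers[k, ], "+")
  }))
  D <- as.matrix(dist(x))
  dimnames(D) <- list(paste0("p", 1:36), paste0("p", 1:36))
  sel <- select_k(D, 3:7)
  expect_equal(sel$best_k, 3)
  expect_equal(nrow(sel$silhouettes), 5)
  expect_equal(sel$silhouettes$k, 3:7)
})
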