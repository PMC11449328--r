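# Independent oracles and small data generators used across the suite.
# Each oracle is a direct, unoptimized statement of the defining
# computation, kept free of the package's own implementation paths.

# plain haversine, written out (R = 6371 km), independent of the package
oracle_hav <- function(lat1, lon1, lat2, lon2) {
  d2r <- pi / 180
  a <- sin((lat2 - lat1) * d2r / 2)^2 +
    cos(lat1 * d2r) * cos(lat2 * d2r) * sin((lon2 - lon1) * d2r / 2)^2
  2 * 6371000 * asin(sqrt(pmin(a, 1)))
}

# exhaustive DTW over all monotone warping paths; symmetric step pattern
# (diagonal weight 2, horizontal/vertical weight 1, origin counted once)
oracle_dtw <- function(dmat) {
  n <- nrow(dmat); m <- ncol(dmat)
  rec <- function(i, j) {
    if (i == 1 && j == 1) return(dmat[1, 1])
    best <- Inf
    if (i > 1 && j > 1) best <- min(best, rec(i - 1, j - 1) + 2 * dmat[i, j])
    if (i > 1) best <- min(best, rec(i - 1, j) + dmat[i, j])
    if (j > 1) best <- min(best, rec(i, j - 1) + dmat[i, j])
    best
  }
  rec(n, m)
}

# greedy left-to-right stay-point scan, written as an explicit double loop
oracle_stay_points <- function(t, lat, lon, d_thresh = 1, t_thresh = 5) {
  n <- length(t)
  if (n < 2) return(0L)
  count <- 0L
  i <- 1
  while (i < n) {
    j <- NA
    for (jj in (i + 1):n) {
      if (oracle_hav(lat[i], lon[i], lat[jj], lon[jj]) > d_thresh) {
        j <- jj
        break
      }
    }
    if (is.na(j)) {
      if (t[n] - t[i] >= t_thresh) count <- count + 1L
      break
    }
    if (t[j - 1] - t[i] >= t_thresh) {
      count <- count + 1L
      i <- j
    } else {
      i <- i + 1
    }
  }
  count
}

# exhaustive k-medoids: minimal total distance to the best medoid set
oracle_pam_objective <- function(D, k) {
  n <- nrow(D)
  best <- Inf
  for (med in utils::combn(n, k, simplify = FALSE)) {
    obj <- sum(apply(D[, med, drop = FALSE], 1, min))
    if (obj < best) best <- obj
  }
  best
}

# AUC as the concordant-pair fraction (ties count 1/2)
oracle_auc <- function(x, y) {
  xp <- x[y == 1]; xn <- x[y == 0]
  cmp <- outer(xp, xn, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# random 2 s-sampled walk in lat/lon with occasional stationary clusters
random_walk_fixes <- function(n_fix, p_pause = 0.3) {
  steps <- ifelse(runif(n_fix - 1) < p_pause, runif(n_fix - 1, 0, 0.4),
                  runif(n_fix - 1, 1.5, 4))
  ang <- cumsum(runif(n_fix - 1, -0.6, 0.6))
  x <- c(0, cumsum(steps * cos(ang)))
  y <- c(0, cumsum(steps * sin(ang)))
  m_per_deg <- pi * 6371000 / 180
  data.frame(t = seq(0, by = 2, length.out = n_fix),
             lat = 52.1 + y / m_per_deg,
             lon = 11.6 + x / (cos(52.1 * pi / 180) * m_per_deg))
}

# zero-inflated Poisson draws
r_zip <- function(n, lambda, pi0) {
  ifelse(runif(n) < pi0, 0L, rpois(n, lambda))
}

# crossed-design ZIP count data with a participant random intercept
sim_zip_design <- function(n_per_group = 50, n_tracks = 5, b0 = 0.2,
                           beta_scd = 0.67, sigma_p = 0.6, pi0 = 0.2,
                           seed = 1) {
  set.seed(seed)
  n <- 2 * n_per_group
  group <- rep(c("OA", "SCD"), each = n_per_group)
  u <- rnorm(n, 0, sigma_p)
  d <- expand.grid(p = seq_len(n), track_id = seq_len(n_tracks))
  eta <- b0 + beta_scd * (group[d$p] == "SCD") + u[d$p]
  d$stops <- r_zip(nrow(d), exp(eta), pi0)
  fam <- round(runif(n, 0, 28))
  data.frame(participant_id = sprintf("P%03d", d$p), group = group[d$p],
             track_id = d$track_id, stops = d$stops,
             familiarity = fam[d$p],
             sex = rep(c("female", "male"), length.out = nrow(d)))
}

# gaussian crossed-design LMM data
sim_lmm_design <- function(n_per_group = 50, n_tracks = 5, b0 = 5,
                           beta_scd = 0.5, sigma_p = 0.3, sigma_t = 0.2,
                           sigma_e = 0.4, seed = 1) {
  set.seed(seed)
  n <- 2 * n_per_group
  group <- rep(c("OA", "SCD"), each = n_per_group)
  u <- rnorm(n, 0, sigma_p)
  v <- rnorm(n_tracks, 0, sigma_t)
  d <- expand.grid(p = seq_len(n), track_id = seq_len(n_tracks))
  d$y <- b0 + beta_scd * (group[d$p] == "SCD") + u[d$p] + v[d$track_id] +
    rnorm(nrow(d), 0, sigma_e)
  fam <- round(runif(n, 0, 28))
  data.frame(participant_id = sprintf("P%03d", d$p), group = group[d$p],
             track_id = d$track_id, y = d$y,
             familiarity = fam[d$p],
             sex = rep(c("female", "male"), length.out = nrow(d)))
}

# mixture draws with profile-separated means for LPA recovery tests
sim_profiles <- function(n = 150, K = 3, d = 5, sep = 3, seed = 1) {
  set.seed(seed)
  mu <- matrix(0, K, d)
  for (k in seq_len(K)) mu[k, ] <- (k - (K + 1) / 2) * sep
  comp <- sample.int(K, n, replace = TRUE)
  list(X = mu[comp, ] + matrix(rnorm(n * d), n, d), truth = comp, means = mu)
}

# tiny complete cohort used by several ingest/cluster tests
small_cohort <- function(seed = 42, n = c(YA = 3, OA = 3, SCD = 3),
                         exclusions = NULL) {
  simulate_cohort(cohort_config(n = n, exclusions = exclusions), seed = seed)
}
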