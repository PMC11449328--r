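#' Default route specification for the wayfinding task
#'
#' Five analyzed walking tracks plus a sixth return track. The analyzed
#' tracks have optimal (most direct) path lengths of 147, 67, 258, 149 and
#' 202 m with 5, 3, 9, 4 and 6 decision points (intersections at which a
#' direction has to be chosen). The return track closes the loop back to
#' the start and is dropped from analyses. Its length is determined by the
#' generated geometry (`NA` in the spec means unconstrained).
#'
#' @return data frame with columns `track_id`, `length_m`, `decision_points`.
#' @export
default_route_spec <- function() {
  data.frame(
    track_id        = 1:6,
    length_m        = c(147, 67, 258, 149, 202, NA),
    decision_points = c(5, 3, 9, 4, 6, 4)
  )
}

#' Build a route map for the wayfinding task
#'
#' Constructs a connected route of point-of-interest (POI) targets and track
#' polylines matching a route specification. Tracks are chained: each starts
#' where the previous one ended, the first starts at the campus origin, and
#' the return track leads back to it. Geometry is laid out in a local
#' tangent frame in meters and converted to WGS84 so that all computations
#' downstream are location-independent.
#'
#' @param spec data frame as [default_route_spec()]; the last row is treated
#'   as the return track and may have `length_m = NA`.
#' @param origin `c(lat, lon)` of the campus start point (also the target of
#'   the return track). The default is arbitrary.
#' @param max_edge_m maximum spacing of polyline vertices; longer segments
#'   are subdivided so polylines stay densely connected.
#' @return an object of class `route_map`: a list with `pois` (data frame
#'   `poi_id`, `lat`, `lon`) and `tracks` (per track: `track_id`, `coords`
#'   lat/lon matrix, `optimal_length_m`, `decision_points`, `decision_nodes`
#'   vertex indices, `target_poi`).
#' @examples
#' rm <- build_route_map()
#' rm$tracks[[3]]$optimal_length_m  # ~258 m, nine decision points
#' @export
build_route_map <- function(spec = default_route_spec(),
                            origin = c(52.10, 11.60),
                            max_edge_m = 45) {
  stopifnot(is.data.frame(spec), nrow(spec) >= 1,
            all(c("track_id", "length_m", "decision_points") %in% names(spec)))
  n_tracks <- nrow(spec)
  lat0 <- origin[1]; lon0 <- origin[2]

  tracks <- vector("list", n_tracks)
  start_xy <- c(0, 0)
  heading <- 80 # degrees, east-ish; rotated per track for a compact loop
  for (i in seq_len(n_tracks)) {
    dp <- spec$decision_points[i]
    len <- spec$length_m[i]
    is_return <- i == n_tracks && is.na(len)
    if (is_return) {
      geom <- .route_return_geom(start_xy, dp, max_edge_m)
    } else {
      geom <- .route_track_geom(start_xy, heading, len, dp, max_edge_m,
                                turn_first = if (i %% 2 == 0) -1 else 1)
    }
    coords <- .from_local(geom$xy[, 1], geom$xy[, 2], lat0, lon0)
    opt_len <- path_length_m(data.frame(lat = coords[, 1], lon = coords[, 2]))
    tracks[[i]] <- list(
      track_id         = spec$track_id[i],
      coords           = coords,
      optimal_length_m = opt_len,
      decision_points  = dp,
      decision_nodes   = geom$nodes,
      target_poi       = if (i == n_tracks) "DZNE" else paste0("POI", i)
    )
    start_xy <- geom$xy[nrow(geom$xy), ]
    heading <- heading - 70 # fold the route back towards the origin
  }

  ends <- t(vapply(tracks, function(tr) tr$coords[nrow(tr$coords), ],
                   numeric(2)))
  pois <- data.frame(
    poi_id = c("DZNE", paste0("POI", seq_len(n_tracks - 1))),
    lat = c(lat0 + 0, ends[-n_tracks, 1]),
    lon = c(lon0 + 0, ends[-n_tracks, 2])
  )
  rm <- structure(list(pois = pois, tracks = tracks), class = "route_map")
  validate_route_map(rm, spec)
  rm
}

# meander with right-angle turns at decision points; corner vertices become
# the decision nodes, long edges are subdivided
.route_track_geom <- function(start_xy, heading, total_len, dp, max_edge_m,
                              turn_first = 1) {
  n_seg <- dp + 1
  w <- 1 + 0.35 * sin(seq_len(n_seg) * 1.7)
  seg_len <- total_len * w / sum(w)
  ang <- heading
  pts <- matrix(start_xy, nrow = 1)
  corner_idx <- integer(0)
  turn <- turn_first
  for (s in seq_len(n_seg)) {
    dir <- c(sin(ang * pi / 180), cos(ang * pi / 180))
    n_sub <- max(1L, ceiling(seg_len[s] / max_edge_m))
    step <- seg_len[s] / n_sub
    for (k in seq_len(n_sub)) {
      pts <- rbind(pts, pts[nrow(pts), ] + dir * step)
    }
    if (s < n_seg) {
      corner_idx <- c(corner_idx, nrow(pts))
      ang <- ang + turn * 90
      turn <- -turn
    }
  }
  list(xy = pts, nodes = corner_idx)
}

# straight return leg to the origin; decision nodes spread over interior
# vertices
.route_return_geom <- function(start_xy, dp, max_edge_m) {
  len <- sqrt(sum(start_xy^2))
  n_sub <- max(dp + 1L, ceiling(len / max_edge_m))
  frac <- seq(0, 1, length.out = n_sub + 1)
  pts <- cbind(start_xy[1] * (1 - frac), start_xy[2] * (1 - frac))
  interior <- 2:n_sub
  nodes <- interior[round(seq(1, length(interior), length.out = dp))]
  list(xy = pts, nodes = as.integer(nodes))
}

#' Validate a route map against its specification
#'
#' Checks polyline connectivity (consecutive vertices closer than 50 m, no
#' duplicated consecutive vertices), agreement between the stored optimal
#' length and the haversine polyline length (1%), agreement with the
#' specified target lengths (5%), and that the decision-point count matches
#' the number of decision nodes.
#'
#' @param rm a `route_map`.
#' @param spec optional route specification with target lengths.
#' @return `rm`, invisibly; errors on violation.
#' @export
validate_route_map <- function(rm, spec = NULL) {
  stopifnot(inherits(rm, "route_map"))
  for (tr in rm$tracks) {
    cc <- tr$coords
    d <- haversine_m(cc[-nrow(cc), 1], cc[-nrow(cc), 2],
                     cc[-1, 1], cc[-1, 2])
    if (any(d == 0)) {
      stop("track ", tr$track_id, ": duplicated consecutive vertices")
    }
    if (any(d >= 50)) {
      stop("track ", tr$track_id, ": polyline not connected (vertex gap >= 50 m)")
    }
    plen <- sum(d)
    if (abs(plen - tr$optimal_length_m) > 0.01 * tr$optimal_length_m) {
      stop("track ", tr$track_id, ": stored optimal length disagrees with polyline")
    }
    if (tr$decision_points != length(tr$decision_nodes)) {
      stop("track ", tr$track_id, ": decision_points != length(decision_nodes)")
    }
    if (!is.null(spec)) {
      target <- spec$length_m[match(tr$track_id, spec$track_id)]
      if (!is.na(target) && abs(plen - target) > 0.05 * target) {
        stop("track ", tr$track_id, ": length ", round(plen, 1),
             " deviates > 5% from specified ", target, " m")
      }
    }
  }
  invisible(rm)
}

#' @export
print.route_map <- function(x, ...) {
  cat("route_map:", length(x$tracks), "tracks,", nrow(x$pois), "POIs\n")
  for (tr in x$tracks) {
    cat(sprintf("  track %d: %.1f m, %d decision points -> %s\n",
                tr$track_id, tr$optimal_length_m, tr$decision_points,
                tr$target_poi))
  }
  invisible(x)
}

#' Write or read a route map as GeoJSON
#'
#' The route map is serialized as a GeoJSON FeatureCollection with Point
#' features for POIs (property `poi_id`) and LineString features for tracks
#' (properties `track_id`, `optimal_length_m`, `decision_points`,
#' `decision_nodes`). GeoJSON coordinate order is (lon, lat).
#'
#' @param rm a `route_map`.
#' @param path file path.
#' @return `write_route_geojson()` returns `path` invisibly;
#'   `read_route_geojson()` returns a `route_map`.
#' @export
write_route_geojson <- function(rm, path) {
  stopifnot(inherits(rm, "route_map"))
  feats <- list()
  for (i in seq_len(nrow(rm$pois))) {
    feats[[length(feats) + 1]] <- list(
      type = "Feature",
      geometry = list(type = "Point",
                      coordinates = c(rm$pois$lon[i], rm$pois$lat[i])),
      properties = list(poi_id = rm$pois$poi_id[i])
    )
  }
  for (tr in rm$tracks) {
    feats[[length(feats) + 1]] <- list(
      type = "Feature",
      geometry = list(type = "LineString",
                      coordinates = unname(cbind(tr$coords[, 2], tr$coords[, 1]))),
      properties = list(track_id = tr$track_id,
                        optimal_length_m = tr$optimal_length_m,
                        decision_points = tr$decision_points,
                        decision_nodes = as.integer(tr$decision_nodes),
                        target_poi = tr$target_poi)
    )
  }
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_route_geojson
#' @export
read_route_geojson <- function(path) {
  gj <- jsonlite::read_json(path, simplifyVector = FALSE)
  stopifnot(identical(gj$type, "FeatureCollection"))
  pois <- list(); tracks <- list()
  for (f in gj$features) {
    if (identical(f$geometry$type, "Point")) {
      cc <- unlist(f$geometry$coordinates)
      pois[[length(pois) + 1]] <- data.frame(
        poi_id = f$properties$poi_id, lat = cc[2], lon = cc[1])
    } else if (identical(f$geometry$type, "LineString")) {
      cc <- do.call(rbind, lapply(f$geometry$coordinates, unlist))
      tracks[[length(tracks) + 1]] <- list(
        track_id = f$properties$track_id,
        coords = cbind(lat = cc[, 2], lon = cc[, 1]),
        optimal_length_m = f$properties$optimal_length_m,
        decision_points = f$properties$decision_points,
        decision_nodes = as.integer(unlist(f$properties$decision_nodes)),
        target_poi = f$properties$target_poi
      )
    }
  }
  tracks <- tracks[order(vapply(tracks, `[[`, numeric(1), "track_id"))]
  structure(list(pois = do.call(rbind, pois), tracks = tracks),
            class = "route_map")
}

# track entry by id, with a clear error
.get_track <- function(rm, track_id) {
  ids <- vapply(rm$tracks, `[[`, numeric(1), "track_id")
  i <- match(track_id, ids)
  if (is.na(i)) stop("track_id ", track_id, " absent from route_map")
  rm$tracks[[i]]
}

# target POI coordinates of a track
.get_target_poi <- function(rm, track_id) {
  tr <- .get_track(rm, track_id)
  i <- match(tr$target_poi, rm$pois$poi_id)
  if (is.na(i)) stop("target POI ", tr$target_poi, " absent from route_map")
  c(lat = rm$pois$lat[i], lon = rm$pois$lon[i])
}
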