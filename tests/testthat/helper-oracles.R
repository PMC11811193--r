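# Independent brute-force oracles. These deliberately avoid the package's
# implementation paths: distances enumerate all 27 periodic images, event
# detection walks the trace frame by frame, and the rotational fit scans an
# angle grid via the closed-form cost.

# minimum-image distance by explicit enumeration of the 27 periodic images
brute_min_image <- function(a, b, box) {
  best <- Inf
  for (i in -1:1) for (j in -1:1) for (k in -1:1) {
    d <- a - (b + c(i, j, k) * box)
    best <- min(best, sqrt(sum(d * d)))
  }
  best
}

# group-group minimum distance by looping over every bead pair
brute_min_pair <- function(ca, cb, box) {
  best <- Inf
  for (i in seq_len(nrow(ca))) for (j in seq_len(nrow(cb))) {
    best <- min(best, brute_min_image(ca[i, ], cb[j, ], box))
  }
  best
}

# double-cutoff event enumeration by a frame-by-frame state walk
brute_events <- function(values, inner, outer, dt) {
  events <- list()
  run_start <- NA_integer_
  dipped <- FALSE
  for (f in seq_along(values)) {
    if (values[f] < outer) {
      if (is.na(run_start)) { run_start <- f; dipped <- FALSE }
      if (values[f] < inner) dipped <- TRUE
    } else {
      if (!is.na(run_start) && dipped) {
        events[[length(events) + 1L]] <- c(run_start, f - 1L)
      }
      run_start <- NA_integer_
    }
  }
  if (!is.na(run_start) && dipped) {
    events[[length(events) + 1L]] <- c(run_start, length(values))
  }
  if (!length(events)) {
    return(data.frame(start_frame = integer(0), end_frame = integer(0),
                      duration_ns = numeric(0)))
  }
  m <- do.call(rbind, events)
  data.frame(start_frame = m[, 1], end_frame = m[, 2],
             duration_ns = (m[, 2] - m[, 1] + 1L) * dt)
}

# point-in-cylinder membership, one point at a time, 9 xy images
brute_in_cylinder <- function(pt, anchor_xy, center_z, radius, half_height,
                              box) {
  rmin <- Inf
  for (i in -1:1) for (j in -1:1) {
    dx <- pt[1] - (anchor_xy[1] + i * box[1])
    dy <- pt[2] - (anchor_xy[2] + j * box[2])
    rmin <- min(rmin, sqrt(dx^2 + dy^2))
  }
  rmin <= radius && abs(pt[3] - center_z) <= half_height
}

# brute-force z-rotation fit: closed-form xy-RMSD cost on a 0.01 deg grid
brute_rot_scan <- function(p_xy, q_xy, step_deg = 0.01) {
  p <- sweep(p_xy, 2, colMeans(p_xy))
  q <- sweep(q_xy, 2, colMeans(q_xy))
  num <- sum(p[, 1] * q[, 2] - p[, 2] * q[, 1])
  den <- sum(p[, 1] * q[, 1] + p[, 2] * q[, 2])
  th <- seq(-180, 180 - step_deg, by = step_deg) * pi / 180
  cost <- -(cos(th) * den + sin(th) * num)
  (th[which.min(cost)]) * 180 / pi
}

# a minimal MembraneFrameRefs built by hand for map tests
manual_refs <- function(phosphate_indices, leaflet, center_z_global,
                        center_z_glycerol = center_z_global) {
  structure(list(
    leaflet_of_index = stats::setNames(rep_len(leaflet,
                                               length(phosphate_indices)),
                                       phosphate_indices),
    leaflet_of_lipid = NULL,
    center_z_global = center_z_global,
    center_z_glycerol = center_z_glycerol),
    class = "MembraneFrameRefs")
}

# single-frame (or repeated-frame) FrameSeries from a coordinate matrix
frames_from_matrix <- function(m, box, n_frames = 1L, dt = 0.5) {
  coords <- array(rep(as.vector(as.matrix(m)), n_frames),
                  dim = c(nrow(m), 3L, n_frames))
  frame_series(coords, box, dt)
}
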