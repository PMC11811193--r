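#' Leaflet-resolved membrane thinning map
#'
#' Accumulates, in lateral bins over the xy plane, the mean absolute
#' distance of one leaflet's lipid backbone phosphates to the global
#' membrane center, over all frames. Bins are `cfg$bin_xy` wide (0.1 nm by
#' default), anchored at the box corner, and a bin is valid only if it
#' received more than `cfg$min_bin_count` phosphate observations. When a
#' protein is present the frames should already be centered and
#' rotationally fitted (see [center_and_rotfit()]).
#'
#' @param frames a `FrameSeries` (centered/rot-fitted when applicable).
#' @param phosphates `BeadSelection` of lipid backbone phosphates.
#' @param leaflet `"top"` or `"bottom"`.
#' @param refs `MembraneFrameRefs` with `center_z_global` filled in.
#' @param cfg an [analysis_config()].
#' @return a `LeafletMap`: list with `thickness` (matrix, nm; NA where
#'   invalid), `count`, `valid`, `x`, `y` (bin centers), `bin_xy`,
#'   `leaflet`, `min_bin_count`.
#' @export
leaflet_thinning_map <- function(frames, phosphates, leaflet = "top",
                                 refs, cfg = analysis_config()) {
  check_selection(phosphates, frames, "phosphate selection")
  keep <- refs$leaflet_of_index[as.character(phosphates$index)] == leaflet
  if (!any(keep, na.rm = TRUE)) {
    stop("selection error: no phosphates in leaflet '", leaflet, "'")
  }
  idx <- phosphates$index[which(keep)]
  box <- frames$box[1, ]
  nx <- max(1L, floor(box[1] / cfg$bin_xy))
  ny <- max(1L, floor(box[2] / cfg$bin_xy))
  nbin <- nx * ny
  ssum_v <- numeric(nbin)
  scount_v <- integer(nbin)
  for (f in seq_len(frames$n_frames)) {
    m <- frames$coords[idx, , f, drop = FALSE][, , 1, drop = FALSE]
    dim(m) <- dim(m)[1:2]
    bx <- frames$box[f, ]
    x <- m[, 1] %% bx[1]; y <- m[, 2] %% bx[2]
    ix <- pmin(nx, floor(x / cfg$bin_xy) + 1L)
    iy <- pmin(ny, floor(y / cfg$bin_xy) + 1L)
    thick <- abs(m[, 3] - refs$center_z_global[f])
    lin <- (iy - 1L) * nx + ix
    scount_v <- scount_v + tabulate(lin, nbins = nbin)
    agg <- rowsum(thick, lin)
    ssum_v[as.integer(rownames(agg))] <-
      ssum_v[as.integer(rownames(agg))] + agg[, 1]
  }
  ssum <- matrix(ssum_v, nx, ny)
  scount <- matrix(scount_v, nx, ny)
  valid <- scount > cfg$min_bin_count
  thickness <- ifelse(valid, ssum / pmax(scount, 1L), NA_real_)
  structure(
    list(thickness = thickness, count = scount, valid = valid,
         x = (seq_len(nx) - 0.5) * cfg$bin_xy,
         y = (seq_len(ny) - 0.5) * cfg$bin_xy,
         bin_xy = cfg$bin_xy, leaflet = leaflet,
         min_bin_count = cfg$min_bin_count),
    class = "LeafletMap")
}

#' Minimum and mean thickness of a leaflet map
#'
#' Summaries are taken over valid bins only; an optional logical `region`
#' mask (same shape as the map) restricts them further.
#'
#' @param map a `LeafletMap`.
#' @param region optional logical matrix mask.
#' @return list `min_nm`, `mean_nm`, `n_bins`.
#' @export
map_summary <- function(map, region = NULL) {
  sel <- map$valid
  if (!is.null(region)) sel <- sel & region
  if (!any(sel)) stop("empty region: no valid bins to summarize")
  v <- map$thickness[sel]
  list(min_nm = min(v), mean_nm = mean(v), n_bins = sum(sel))
}

#' Radial minimum-thickness profile around a protein
#'
#' For the annulus of bins whose centers lie within `annulus` of the
#' protein's xy center, returns the minimum valid thickness in each
#' azimuthal sector and the overall ring minimum. This is the "lowest
#' leaflet value in a circle around the protein" summary.
#'
#' @param map a `LeafletMap`.
#' @param center_xy protein xy center, nm (e.g. box center after rot-fit).
#' @param annulus length-2 inner/outer radius, nm.
#' @param n_sectors number of azimuthal sectors (default 36, i.e. 10 deg).
#' @return list with `profile` (data frame `azimuth_deg`, `min_nm`),
#'   `ring_min_nm`, `ring_min_azimuth_deg`.
#' @export
radial_minimum_profile <- function(map, center_xy, annulus,
                                   n_sectors = 36L) {
  g <- expand.grid(x = map$x, y = map$y)
  dx <- g$x - center_xy[1]; dy <- g$y - center_xy[2]
  r <- sqrt(dx^2 + dy^2)
  in_ring <- r >= annulus[1] & r <= annulus[2] & as.vector(map$valid)
  if (!any(in_ring)) stop("empty region: annulus contains no valid bins")
  az <- (atan2(dy, dx) * 180 / pi) %% 360
  sector <- pmin(n_sectors, floor(az / (360 / n_sectors)) + 1L)
  th <- as.vector(map$thickness)
  mins <- rep(NA_real_, n_sectors)
  for (s in seq_len(n_sectors)) {
    sel <- in_ring & sector == s
    if (any(sel)) mins[s] <- min(th[sel])
  }
  ring_min <- min(th[in_ring])
  ring_az <- az[in_ring][which.min(th[in_ring])]
  list(profile = data.frame(
         azimuth_deg = (seq_len(n_sectors) - 0.5) * 360 / n_sectors,
         min_nm = mins),
       ring_min_nm = ring_min, ring_min_azimuth_deg = ring_az)
}

#' Water-defect count in a protein-anchored cylinder
#'
#' Counts, per frame, the water beads inside a cylinder of radius
#' `cfg$cyl_radius` (xy minimum-image distance to the anchor) spanning
#' `cfg$cyl_half_height` into each leaflet around the global membrane
#' center. The anchor defaults to the protein's per-frame xy geometric
#' center; pass `anchor_xy` for protein-free systems.
#'
#' @param frames a `FrameSeries`.
#' @param waters `BeadSelection` of water beads.
#' @param protein optional `BeadSelection` anchoring the cylinder.
#' @param refs `MembraneFrameRefs` with `center_z_global`.
#' @param cfg an [analysis_config()].
#' @param anchor_xy optional fixed xy anchor, nm.
#' @return a `DefectTrace`: list `counts` (per frame), `mean`, `sem`
#'   (over frames), `radius_nm`, `half_height_nm`.
#' @export
water_defect_count <- function(frames, waters, protein = NULL, refs,
                               cfg = analysis_config(), anchor_xy = NULL) {
  check_selection(waters, frames, "water selection")
  if (is.null(protein) && is.null(anchor_xy)) {
    stop("config error: need a protein selection or an explicit xy anchor")
  }
  counts <- integer(frames$n_frames)
  for (f in seq_len(frames$n_frames)) {
    box <- frames$box[f, ]
    anchor <- if (!is.null(protein)) {
      colMeans(frames$coords[protein$index, 1:2, f, drop = FALSE][, , 1,
                                                                  drop = FALSE])
    } else anchor_xy
    w <- frames$coords[waters$index, , f, drop = FALSE][, , 1, drop = FALSE]
    dim(w) <- dim(w)[1:2]
    rxy <- xy_image_distance(w, anchor, box)
    dz <- abs(w[, 3] - refs$center_z_global[f])
    counts[f] <- sum(rxy <= cfg$cyl_radius & dz <= cfg$cyl_half_height)
  }
  st <- replicate_stats(counts)
  structure(list(counts = counts, mean = st$mean, sem = st$sem,
                 radius_nm = cfg$cyl_radius,
                 half_height_nm = cfg$cyl_half_height),
            class = "DefectTrace")
}

#' Volumetric bead-occupancy grid
#'
#' Grids the box at `cfg$grid_spacing` (0.2 nm = 2 Angstrom default) and
#' records, per cell, the percentage of frames in which at least one
#' selected bead is present. Presence is binary per frame per cell. Beads
#' outside the box after fitting are wrapped by the periodic boundary.
#'
#' @param frames a `FrameSeries` (centered/rot-fitted when applicable).
#' @param beads `BeadSelection` to grid (e.g. phosphates).
#' @param cfg an [analysis_config()].
#' @return an `OccupancyGrid`: list `occupancy` (3-d array, percent),
#'   `spacing`, `origin`, `dims`.
#' @export
occupancy_grid <- function(frames, beads, cfg = analysis_config()) {
  check_selection(beads, frames, "bead selection")
  box <- frames$box[1, ]
  h <- cfg$grid_spacing
  dims <- pmax(1L, floor(box / h))
  present <- array(0L, dim = dims)
  for (f in seq_len(frames$n_frames)) {
    bx <- frames$box[f, ]
    m <- frames$coords[beads$index, , f, drop = FALSE][, , 1, drop = FALSE]
    dim(m) <- dim(m)[1:2]
    ix <- pmin(dims[1], floor((m[, 1] %% bx[1]) / h) + 1L)
    iy <- pmin(dims[2], floor((m[, 2] %% bx[2]) / h) + 1L)
    iz <- pmin(dims[3], floor((m[, 3] %% bx[3]) / h) + 1L)
    cells <- unique(cbind(ix, iy, iz))
    present[cells] <- present[cells] + 1L
  }
  structure(list(occupancy = 100 * present / frames$n_frames,
                 spacing = h, origin = c(0, 0, 0), dims = dims),
            class = "OccupancyGrid")
}

#' Iso-occupancy surface extraction
#'
#' Returns the boolean mask of cells at or above the threshold, plus a
#' triangulated surface built from the exposed faces of the masked voxels
#' (two triangles per face). The mask volume is non-increasing in the
#' threshold.
#'
#' @param grid an `OccupancyGrid`.
#' @param threshold occupancy threshold, percent (default 0.5).
#' @param obj_path optional path; if given the mesh is written as
#'   Wavefront OBJ.
#' @return list `mask` (logical array), `vertices` (`n x 3`, nm),
#'   `faces` (`m x 3` vertex indices), `n_cells`.
#' @export
export_isosurface <- function(grid, threshold = 0.5, obj_path = NULL) {
  if (threshold <= 0 || threshold >= 100) {
    stop("config error: threshold must lie in (0, 100) percent")
  }
  mask <- grid$occupancy >= threshold
  mesh <- voxel_surface_mesh(mask, grid$spacing, grid$origin)
  if (!is.null(obj_path)) {
    con <- file(obj_path, "w")
    on.exit(close(con))
    if (nrow(mesh$vertices)) {
      writeLines(sprintf("v %.5f %.5f %.5f", mesh$vertices[, 1],
                         mesh$vertices[, 2], mesh$vertices[, 3]), con)
      writeLines(sprintf("f %d %d %d", mesh$faces[, 1], mesh$faces[, 2],
                         mesh$faces[, 3]), con)
    }
  }
  list(mask = mask, vertices = mesh$vertices, faces = mesh$faces,
       n_cells = sum(mask))
}

# Boundary mesh of a voxel mask: for every masked cell face adjoining an
# unmasked (or out-of-grid) neighbour, emit the face as two triangles.
voxel_surface_mesh <- function(mask, spacing, origin) {
  idx <- which(mask, arr.ind = TRUE)
  verts <- list(); faces <- list(); nv <- 0L
  if (nrow(idx)) {
    dims <- dim(mask)
    offs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                  c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
    for (r in seq_len(nrow(idx))) {
      c0 <- idx[r, ]
      for (o in seq_len(6)) {
        nb <- c0 + offs[o, ]
        exposed <- any(nb < 1L | nb > dims) || !mask[nb[1], nb[2], nb[3]]
        if (!exposed) next
        fv <- face_corners(c0, offs[o, ], spacing, origin)
        verts[[length(verts) + 1L]] <- fv
        faces[[length(faces) + 1L]] <-
          rbind(nv + c(1L, 2L, 3L), nv + c(1L, 3L, 4L))
        nv <- nv + 4L
      }
    }
  }
  list(vertices = if (length(verts)) do.call(rbind, verts)
                  else matrix(0, 0, 3),
       faces = if (length(faces)) do.call(rbind, faces)
               else matrix(0L, 0, 3))
}

face_corners <- function(cell, normal, spacing, origin) {
  lo <- origin + (cell - 1L) * spacing
  hi <- lo + spacing
  ax <- which(normal != 0)
  fixed <- if (normal[ax] > 0) hi[ax] else lo[ax]
  other <- setdiff(1:3, ax)
  corners <- matrix(0, 4, 3)
  uv <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  for (i in 1:4) {
    p <- numeric(3)
    p[ax] <- fixed
    p[other[1]] <- lo[other[1]] + uv[i, 1] * spacing
    p[other[2]] <- lo[other[2]] + uv[i, 2] * spacing
    corners[i, ] <- p
  }
  corners
}

#' Write an occupancy grid in OpenDX format
#'
#' Plain-text OpenDX scalar field, readable by common molecular viewers.
#' Units are Angstrom in the file, the convention those viewers expect.
#'
#' @param grid an `OccupancyGrid`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_opendx <- function(grid, path) {
  d <- grid$dims
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("object 1 class gridpositions counts %d %d %d", d[1], d[2], d[3]),
    sprintf("origin %.4f %.4f %.4f", grid$origin[1] * 10,
            grid$origin[2] * 10, grid$origin[3] * 10),
    sprintf("delta %.4f 0 0", grid$spacing * 10),
    sprintf("delta 0 %.4f 0", grid$spacing * 10),
    sprintf("delta 0 0 %.4f", grid$spacing * 10),
    sprintf("object 2 class gridconnections counts %d %d %d",
            d[1], d[2], d[3]),
    sprintf("object 3 class array type double rank 0 items %d data follows",
            prod(d))), con)
  # OpenDX runs z fastest
  vals <- aperm(grid$occupancy, c(3, 2, 1))
  vals <- as.vector(vals)
  n3 <- (length(vals) %/% 3) * 3
  if (n3 > 0) {
    m <- matrix(vals[seq_len(n3)], ncol = 3, byrow = TRUE)
    writeLines(sprintf("%.6g %.6g %.6g", m[, 1], m[, 2], m[, 3]), con)
  }
  if (n3 < length(vals)) {
    writeLines(paste(sprintf("%.6g", vals[(n3 + 1):length(vals)]),
                     collapse = " "), con)
  }
  writeLines(c("attribute \"dep\" string \"positions\"",
               "object \"occupancy\" class field",
               "component \"positions\" value 1",
               "component \"connections\" value 2",
               "component \"data\" value 3"), con)
  invisible(path)
}

#' Depth trace of a buried residue relative to the membrane center
#'
#' Per-frame z of the residue's side-chain bead(s) (center of geometry when
#' several) minus the glycerol-based membrane center. Positive values lie
#' in the cytosolic (top) leaflet.
#'
#' @param frames a `FrameSeries`.
#' @param residue_beads `BeadSelection` of the residue's side-chain beads.
#' @param refs `MembraneFrameRefs` with `center_z_glycerol`.
#' @return a `DepthTrace`: list `depth_nm` (per frame), `mean_nm`, `sd_nm`.
#' @export
residue_depth_trace <- function(frames, residue_beads, refs) {
  check_selection(residue_beads, frames, "residue selection")
  z <- matrix(frames$coords[residue_beads$index, 3, , drop = FALSE],
              nrow = nrow(residue_beads), ncol = frames$n_frames)
  zc <- colMeans(z)
  depth <- zc - refs$center_z_glycerol
  structure(list(depth_nm = depth, mean_nm = mean(depth),
                 sd_nm = stats::sd(depth)),
            class = "DepthTrace")
}
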