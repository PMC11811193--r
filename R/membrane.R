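#' Assign lipids to leaflets
#'
#' Each lipid is labelled `"top"` (cytosolic) or `"bottom"` (IMS) by the
#' sign of its phosphate z-position relative to the median phosphate z at a
#' reference frame. Labels are fixed thereafter: coarse-grained lipids do
#' not flip-flop on the timescales these analyses address, so no per-frame
#' reassignment is attempted.
#'
#' @param frames a `FrameSeries`.
#' @param phosphates `BeadSelection` of lipid backbone phosphates (one per
#'   lipid).
#' @param reference_frame frame index used for the split (default 1).
#' @return a `MembraneFrameRefs` list with `leaflet_of_lipid` (named by
#'   residue_id) and `leaflet_of_index` (named by particle index); membrane
#'   centers are filled in by [membrane_centers()].
#' @export
assign_leaflets <- function(frames, phosphates, reference_frame = 1) {
  check_selection(phosphates, frames, "phosphate selection")
  if (nrow(phosphates) < 2L) stop("need at least 2 phosphate beads")
  if (reference_frame < 1L || reference_frame > frames$n_frames) {
    stop("reference_frame out of range")
  }
  z <- frames$coords[phosphates$index, 3, reference_frame]
  if (diff(range(z)) < 1e-9) {
    stop("degenerate membrane: all phosphates at identical z")
  }
  med <- stats::median(z)
  leaflet <- ifelse(z >= med, "top", "bottom")
  # median split can tie for even counts; break ties by z order
  if (all(leaflet == "top") || all(leaflet == "bottom")) {
    leaflet <- ifelse(z > med, "top", "bottom")
  }
  refs <- list(
    leaflet_of_lipid = stats::setNames(leaflet, phosphates$residue_id),
    leaflet_of_index = stats::setNames(leaflet, phosphates$index),
    center_z_glycerol = NULL,
    center_z_global = NULL
  )
  class(refs) <- "MembraneFrameRefs"
  refs
}

#' Per-frame membrane centers
#'
#' Two center definitions are maintained because different stages call for
#' different ones: `center_z_glycerol` is the mean of the two leaflet
#' glycerol centers of geometry (used for buried-residue depth), and
#' `center_z_global` is the center of the whole lipid bead set (used for
#' thinning maps and water defects). Bead weighting for the global center is
#' uniform by default; pass per-bead `masses` to weight it.
#'
#' @param frames a `FrameSeries`.
#' @param glycerols `BeadSelection` of lipid backbone glycerols.
#' @param all_lipid_beads `BeadSelection` covering every lipid bead.
#' @param leaflets `MembraneFrameRefs` from [assign_leaflets()].
#' @param masses optional per-bead masses for `all_lipid_beads`.
#' @return `leaflets` with `center_z_glycerol` and `center_z_global` filled
#'   in (numeric, one per frame).
#' @export
membrane_centers <- function(frames, glycerols, all_lipid_beads, leaflets,
                             masses = NULL) {
  check_selection(glycerols, frames, "glycerol selection")
  check_selection(all_lipid_beads, frames, "lipid selection")
  gl_leaflet <- leaflets$leaflet_of_lipid[as.character(glycerols$residue_id)]
  if (anyNA(gl_leaflet)) {
    stop("glycerol selection contains residues without a leaflet label")
  }
  top <- glycerols$index[gl_leaflet == "top"]
  bot <- glycerols$index[gl_leaflet == "bottom"]
  if (!length(top) || !length(bot)) stop("both leaflets must be non-empty")
  zg_top <- colMeans(frames$coords[top, 3, , drop = FALSE])
  zg_bot <- colMeans(frames$coords[bot, 3, , drop = FALSE])
  leaflets$center_z_glycerol <- as.numeric((zg_top + zg_bot) / 2)
  li <- all_lipid_beads$index
  zl <- frames$coords[li, 3, , drop = FALSE]
  if (is.null(masses)) {
    leaflets$center_z_global <- as.numeric(colMeans(zl))
  } else {
    if (length(masses) != length(li)) {
      stop("masses must match the lipid bead selection")
    }
    w <- masses / sum(masses)
    leaflets$center_z_global <-
      as.numeric(apply(zl, 3, function(m) sum(w * m[, 1])))
  }
  leaflets
}

#' Center the protein in xy and rotationally fit about z
#'
#' Every frame is translated so that the protein's xy geometric center sits
#' at the box xy center, then rotated about the z-axis (through the box xy
#' center) by the angle that minimizes the xy root-mean-square deviation of
#' the protein beads to a common reference. All particles are transformed
#' together, so maps and grids accumulated afterwards share one protein
#' frame of reference. Bead weights in the fit are uniform.
#'
#' @param frames a `FrameSeries`.
#' @param protein `BeadSelection` of the protein beads used for the fit.
#' @param reference_coords `n x 3` matrix of reference protein coordinates
#'   (same bead order as `protein`); defaults to the protein coordinates of
#'   the first frame.
#' @return list with `frames` (transformed `FrameSeries`) and `angle_deg`
#'   (per-frame fitted rotation, degrees).
#' @export
center_and_rotfit <- function(frames, protein, reference_coords = NULL) {
  check_selection(protein, frames, "protein selection")
  if (nrow(protein) < 3L) stop("need at least 3 protein beads to fit")
  if (is.null(reference_coords)) {
    reference_coords <- frames$coords[protein$index, , 1]
  }
  reference_coords <- as.matrix(reference_coords)
  if (nrow(reference_coords) != nrow(protein)) {
    stop("reference has ", nrow(reference_coords),
         " beads, protein selection has ", nrow(protein))
  }
  rc <- reference_coords[, 1:2, drop = FALSE]
  rc <- sweep(rc, 2, colMeans(rc))
  out <- frames$coords
  angles <- numeric(frames$n_frames)
  for (f in seq_len(frames$n_frames)) {
    box <- frames$box[f, ]
    ctr <- box[1:2] / 2
    pxy <- frames$coords[protein$index, 1:2, f, drop = FALSE][, , 1]
    pc <- colMeans(pxy)
    shift <- ctr - pc
    m <- frames$coords[, , f]
    m[, 1] <- m[, 1] + shift[1]
    m[, 2] <- m[, 2] + shift[2]
    # optimal z-rotation (2-D Kabsch): protein beads, centered at box center
    p <- sweep(m[protein$index, 1:2, drop = FALSE], 2, ctr)
    num <- sum(p[, 1] * rc[, 2] - p[, 2] * rc[, 1])
    den <- sum(p[, 1] * rc[, 1] + p[, 2] * rc[, 2])
    th <- atan2(num, den)
    cs <- cos(th); sn <- sin(th)
    xr <- m[, 1] - ctr[1]; yr <- m[, 2] - ctr[2]
    m[, 1] <- cs * xr - sn * yr + ctr[1]
    m[, 2] <- sn * xr + cs * yr + ctr[2]
    out[, , f] <- m
    angles[f] <- th * 180 / pi
  }
  fitted <- frame_series(out, frames$box, frames$dt, frames$origin_format)
  list(frames = fitted, angle_deg = angles)
}

# xy RMSD of a protein selection to reference, after removing both centroids.
protein_xy_rmsd <- function(coords_frame, protein, reference_coords) {
  p <- coords_frame[protein$index, 1:2, drop = FALSE]
  p <- sweep(p, 2, colMeans(p))
  r <- as.matrix(reference_coords)[, 1:2, drop = FALSE]
  r <- sweep(r, 2, colMeans(r))
  sqrt(mean(rowSums((p - r)^2)))
}
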