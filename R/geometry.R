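#' Minimum-image distance under orthorhombic periodic boundaries
#'
#' Distance between points `a` and `b` taking the nearest periodic image in
#' each dimension. `a` and `b` may be single points (length-3 vectors) or
#' matrices of points (rows), in which case they are compared row-wise.
#'
#' @param a,b numeric length-3 vectors or `n x 3` matrices, nm.
#' @param box length-3 box edge lengths, nm.
#' @return numeric vector of distances, nm.
#' @export
minimum_image_distance <- function(a, b, box) {
  a <- rbind(a); b <- rbind(b)
  if (!all(is.finite(a)) || !all(is.finite(b)) || !all(is.finite(box))) {
    stop("positions and box must be finite")
  }
  if (any(box <= 0)) stop("box lengths must be > 0")
  d <- sweep(a - b, 2, box, function(dx, L) dx - L * round(dx / L))
  unname(sqrt(rowSums(d * d)))
}

# All minimum-image pair distances between two coordinate sets for one frame.
# Returns an na x nb matrix. Used by the distance-trace and contact kernels;
# group sizes here are residue-scale (tens of beads), so dense outer
# differences are cheap.
pair_distance_matrix <- function(ca, cb, box) {
  ca <- rbind(ca); cb <- rbind(cb)
  na <- nrow(ca); nb <- nrow(cb)
  d2 <- matrix(0, na, nb)
  for (k in 1:3) {
    dx <- outer(ca[, k], cb[, k], "-")
    dx <- dx - box[k] * round(dx / box[k])
    d2 <- d2 + dx * dx
  }
  sqrt(d2)
}

# Minimum minimum-image distance between two groups for one frame.
min_pair_distance <- function(ca, cb, box) {
  min(pair_distance_matrix(ca, cb, box))
}

# xy minimum-image distance of points to an anchor, one frame.
xy_image_distance <- function(pts, anchor, box) {
  dx <- pts[, 1] - anchor[1]
  dy <- pts[, 2] - anchor[2]
  dx <- dx - box[1] * round(dx / box[1])
  dy <- dy - box[2] * round(dy / box[2])
  sqrt(dx * dx + dy * dy)
}
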