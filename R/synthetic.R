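#' Synthetic coarse-grained trajectory generators
#'
#' Every generator in this file emits geometry with a machine-readable
#' ground-truth record, so each analysis stage can be tested against known
#' answers without a molecular dynamics engine. The generators model the
#' statistical structure the analyses assume -- bead positions, roles and
#' kinetics -- not physics: there are no forces, energies or thermostats.
#'
#' @name synthetic
NULL

# Run code under a given seed without disturbing the caller's RNG stream.
local_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Synthetic bilayer with optional local thinning funnels
#'
#' Builds a two-leaflet bilayer of phosphate/glycerol bead pairs. Leaflet
#' planes sit at +/- `h` with Gaussian z-jitter; lipids random-walk
#' laterally. Each funnel displaces phosphate z toward the membrane center
#' by `depth * exp(-r^2 / (2 width^2))` around its xy center, so the
#' analytic minimum leaflet thickness is `h - depth`. Defaults emulate a
#' pure-POPC patch of 386 lipids with a leaflet thickness of 1.95 nm at a
#' 0.5 ns frame spacing.
#'
#' @param n_per_leaflet lipids per leaflet (default 193).
#' @param box box lengths, nm.
#' @param h leaflet plane height above the membrane center, nm.
#' @param jitter_sd per-frame Gaussian z-jitter SD, nm.
#' @param diff_step lateral random-walk step SD per frame, nm.
#' @param n_frames,dt frames and spacing (ns).
#' @param funnels list of `list(center = c(x, y), depth, width,
#'   leaflet = "top")` entries.
#' @param glycerol_offset distance of the glycerol bead below its
#'   phosphate (toward the center), nm.
#' @param seed optional RNG seed.
#' @return list with `frames` (`FrameSeries`), `phosphates`, `glycerols`,
#'   `lipids` (`BeadSelection`s), and `truth` (leaflet labels, `h`,
#'   funnels, `analytic_min`).
#' @export
make_bilayer <- function(n_per_leaflet = 193, box = c(11.1, 11.1, 9),
                         h = 1.95, jitter_sd = 0.08, diff_step = 0.05,
                         n_frames = 100, dt = 0.5, funnels = list(),
                         glycerol_offset = 0.45, seed = NULL) {
  for (fn in funnels) {
    if (fn$depth >= h) stop("spec error: funnel depth must be < h")
  }
  local_seed(seed, {
    n_lip <- 2L * n_per_leaflet
    leaflet <- rep(c("top", "bottom"), each = n_per_leaflet)
    sgn <- ifelse(leaflet == "top", 1, -1)
    x0 <- stats::runif(n_lip, 0, box[1])
    y0 <- stats::runif(n_lip, 0, box[2])
    n_part <- 2L * n_lip  # phosphate + glycerol per lipid
    coords <- array(NA_real_, dim = c(n_part, 3L, n_frames))
    x <- x0; y <- y0
    for (f in seq_len(n_frames)) {
      if (f > 1L) {
        x <- (x + stats::rnorm(n_lip, 0, diff_step)) %% box[1]
        y <- (y + stats::rnorm(n_lip, 0, diff_step)) %% box[2]
      }
      zdisp <- numeric(n_lip)
      for (fn in funnels) {
        lf <- fn$leaflet %||% "top"
        on_lf <- leaflet == lf
        dx <- x - fn$center[1]; dy <- y - fn$center[2]
        dx <- dx - box[1] * round(dx / box[1])
        dy <- dy - box[2] * round(dy / box[2])
        r2 <- dx^2 + dy^2
        zdisp[on_lf] <- zdisp[on_lf] +
          fn$depth * exp(-r2[on_lf] / (2 * fn$width^2))
      }
      zp <- sgn * (h - zdisp) + stats::rnorm(n_lip, 0, jitter_sd) +
        box[3] / 2
      zg <- zp - sgn * glycerol_offset
      pi_ <- seq(1L, n_part, by = 2L)  # phosphates at odd positions
      gi <- pi_ + 1L
      coords[pi_, 1, f] <- x; coords[pi_, 2, f] <- y; coords[pi_, 3, f] <- zp
      coords[gi, 1, f] <- x; coords[gi, 2, f] <- y; coords[gi, 3, f] <- zg
    }
    frames <- frame_series(coords, box, dt, origin_format = "synthetic")
    pi_ <- seq(1L, n_part, by = 2L)
    phos <- bead_selection(pi_, residue_id = seq_len(n_lip),
                           residue_name = "POPC", bead_name = "PO4",
                           role = "phosphate")
    glyc <- bead_selection(pi_ + 1L, residue_id = seq_len(n_lip),
                           residue_name = "POPC", bead_name = "GL1",
                           role = "glycerol")
    lipids <- bead_selection(seq_len(n_part),
                             residue_id = rep(seq_len(n_lip), each = 2L),
                             residue_name = "POPC",
                             bead_name = rep(c("PO4", "GL1"), n_lip),
                             role = "other")
    depth_max <- if (length(funnels)) max(vapply(funnels, `[[`, 1,
                                                 "depth")) else 0
    list(frames = frames, phosphates = phos, glycerols = glyc,
         lipids = lipids,
         truth = list(leaflet = stats::setNames(leaflet, seq_len(n_lip)),
                      h = h, funnels = funnels,
                      analytic_min = h - depth_max,
                      jitter_sd = jitter_sd, z_center = box[3] / 2))
  })
}

#' Rigid protein-wall bead set with one buried anionic side chain
#'
#' Appends a static cylindrical wall of protein beads spanning the
#' membrane to an existing synthetic system, plus a single side-chain bead
#' tagged as titratable site at a prescribed signed depth from the
#' membrane center, mounted just outside the wall. A stand-in for a
#' beta-barrel with a bilayer-facing glutamate.
#'
#' @param system a list from [make_bilayer()].
#' @param radius wall radius, nm.
#' @param n_per_ring beads per ring.
#' @param ring_z ring z-offsets from the membrane center, nm.
#' @param glu_depth signed z of the buried side chain relative to the
#'   membrane center, nm (positive = cytosolic leaflet).
#' @param glu_azimuth_deg azimuth at which the side chain is mounted.
#' @return the system list, with `frames` extended and `protein`,
#'   `glu` selections and `truth$glu_depth` added.
#' @export
make_protein_wall <- function(system, radius = 1.7, n_per_ring = 24L,
                              ring_z = seq(-2, 2, by = 0.5),
                              glu_depth = 0.4, glu_azimuth_deg = 0) {
  frames <- system$frames
  box <- frames$box[1, ]
  if (radius >= min(box[1:2]) / 2) stop("barrel radius exceeds half box")
  ctr <- c(box[1] / 2, box[2] / 2, box[3] / 2)
  th <- seq(0, 2 * pi, length.out = n_per_ring + 1L)[-(n_per_ring + 1L)]
  wall <- do.call(rbind, lapply(ring_z, function(z) {
    cbind(ctr[1] + radius * cos(th), ctr[2] + radius * sin(th), ctr[3] + z)
  }))
  phi <- glu_azimuth_deg * pi / 180
  glu <- c(ctr[1] + (radius + 0.3) * cos(phi),
           ctr[2] + (radius + 0.3) * sin(phi), ctr[3] + glu_depth)
  extra <- rbind(wall, glu)
  n_old <- frames$n_particles
  n_new <- n_old + nrow(extra)
  coords <- array(NA_real_, dim = c(n_new, 3L, frames$n_frames))
  coords[seq_len(n_old), , ] <- frames$coords
  for (f in seq_len(frames$n_frames)) coords[(n_old + 1L):n_new, , f] <- extra
  system$frames <- frame_series(coords, frames$box, frames$dt, "synthetic")
  wall_idx <- (n_old + 1L):(n_new - 1L)
  system$protein <- bead_selection(
    wall_idx, residue_id = rep(seq_along(ring_z), each = n_per_ring),
    residue_name = "WALL", bead_name = "BB", role = "protein")
  system$glu <- bead_selection(n_new, residue_id = 9999L,
                               residue_name = "GLU", bead_name = "SC1",
                               role = "titratable_site")
  system$truth$glu_depth <- glu_depth
  system$truth$protein_center_xy <- ctr[1:2]
  system$truth$protein_radius <- radius
  system
}

#' Water beads with a controlled defect column
#'
#' Appends water beads: a bulk pool confined to `|z - center| > h` (never
#' inside the membrane core) and a defect pool whose beads enter a column
#' of radius `defect_radius` around `defect_center_xy`, each frame
#' independently with probability `p_in`, at uniform z within
#' `+/- defect_half_height` of the membrane center. The expected in-column
#' count per frame is therefore `n_defect_pool * p_in * enrichment`,
#' capped at the pool size.
#'
#' @param system a list from [make_bilayer()] (optionally with wall).
#' @param n_bulk bulk water beads.
#' @param n_defect_pool defect-pool beads.
#' @param p_in per-frame probability a pool bead is in the column.
#' @param enrichment multiplier on `p_in` (doubling it doubles the
#'   expected count).
#' @param defect_center_xy column center, nm; defaults to the box center.
#' @param defect_radius column radius, nm.
#' @param defect_half_height column half height, nm.
#' @param seed optional RNG seed.
#' @return the system list with `frames` extended, `waters` selection and
#'   `truth$expected_defect_count` added.
#' @export
make_waters <- function(system, n_bulk = 500L, n_defect_pool = 40L,
                        p_in = 0.25, enrichment = 1,
                        defect_center_xy = NULL, defect_radius = 0.8,
                        defect_half_height = 1.2, seed = NULL) {
  frames <- system$frames
  box <- frames$box[1, ]
  zc <- box[3] / 2
  h <- system$truth$h
  if (is.null(defect_center_xy)) defect_center_xy <- box[1:2] / 2
  p_eff <- min(1, p_in * enrichment)
  local_seed(seed, {
    n_w <- n_bulk + n_defect_pool
    n_old <- frames$n_particles
    coords <- array(NA_real_, dim = c(n_old + n_w, 3L, frames$n_frames))
    coords[seq_len(n_old), , ] <- frames$coords
    for (f in seq_len(frames$n_frames)) {
      # bulk: uniform in the two slabs outside the membrane core
      z_bulk <- ifelse(stats::runif(n_bulk) < 0.5,
                       stats::runif(n_bulk, zc + h, box[3]),
                       stats::runif(n_bulk, 0, zc - h))
      bulk <- cbind(stats::runif(n_bulk, 0, box[1]),
                    stats::runif(n_bulk, 0, box[2]), z_bulk)
      inside <- stats::runif(n_defect_pool) < p_eff
      r <- defect_radius * sqrt(stats::runif(n_defect_pool))
      a <- stats::runif(n_defect_pool, 0, 2 * pi)
      dx <- r * cos(a); dy <- r * sin(a)
      zd <- ifelse(inside,
                   zc + stats::runif(n_defect_pool, -defect_half_height,
                                     defect_half_height),
                   ifelse(stats::runif(n_defect_pool) < 0.5,
                          stats::runif(n_defect_pool, zc + h, box[3]),
                          stats::runif(n_defect_pool, 0, zc - h)))
      defect <- cbind((defect_center_xy[1] + dx) %% box[1],
                      (defect_center_xy[2] + dy) %% box[2], zd)
      coords[(n_old + 1L):(n_old + n_w), , f] <- rbind(bulk, defect)
    }
    system$frames <- frame_series(coords, frames$box, frames$dt, "synthetic")
    system$waters <- bead_selection(
      (n_old + 1L):(n_old + n_w),
      residue_id = 100000L + seq_len(n_w),
      residue_name = "W", bead_name = "W", role = "water")
    system$truth$expected_defect_count <- n_defect_pool * p_eff
    system
  })
}

#' Two-state telegraph distance trace with known contact events
#'
#' A bound/unbound Markov chain at rates `k_on`, `k_off` (per ns). Bound
#' frames emit distances Uniform(0.2, 0.55) nm, unbound frames
#' Uniform(1.3, 3.0) nm; with probability `p_excursion` a frame instead
#' emits Uniform(0.62, 0.98) nm, exercising the double-cutoff rule. True
#' events are the maximal bound-state runs.
#'
#' @param n_frames trace length.
#' @param dt frame spacing, ns.
#' @param k_on,k_off transition rates, per ns.
#' @param p_excursion per-frame probability of an intermediate-distance
#'   excursion (default 0).
#' @param seed optional RNG seed.
#' @return list `trace` (`DistanceTrace`), `true_events` (data frame
#'   `start_frame`, `end_frame`, `duration_ns`), `true_prevalence`
#'   (fraction of bound frames), `k_on`, `k_off`.
#' @export
make_contact_trace <- function(n_frames = 4000, dt = 0.5, k_on = 0.02,
                               k_off = 0.1, p_excursion = 0, seed = NULL) {
  stopifnot(k_on > 0, k_off > 0)
  local_seed(seed, {
    p_on <- 1 - exp(-k_on * dt)   # unbound -> bound per frame
    p_off <- 1 - exp(-k_off * dt) # bound -> unbound per frame
    state <- logical(n_frames)
    state[1] <- stats::runif(1) < k_on / (k_on + k_off)
    u <- stats::runif(n_frames)
    for (f in 2:n_frames) {
      state[f] <- if (state[f - 1L]) u[f] >= p_off else u[f] < p_on
    }
    vals <- ifelse(state, stats::runif(n_frames, 0.2, 0.55),
                   stats::runif(n_frames, 1.3, 3.0))
    if (p_excursion > 0) {
      exc <- stats::runif(n_frames) < p_excursion
      vals[exc] <- stats::runif(sum(exc), 0.62, 0.98)
    }
    r <- rle(state)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    keep <- which(r$values)
    true_events <- data.frame(
      start_frame = starts[keep], end_frame = ends[keep],
      duration_ns = (ends[keep] - starts[keep] + 1L) * dt)
    list(trace = distance_trace(vals, dt, "MET1", "GLU"),
         true_events = true_events, true_prevalence = mean(state),
         k_on = k_on, k_off = k_off)
  })
}

#' Exponential-residence desorption trace
#'
#' Distance hovers near `base` nm (clipped jitter, never above 1.3 nm)
#' until an exponentially distributed desorption time, after which it
#' rises linearly at `rise_nm_per_ns`. The analytic first crossing of the
#' 1.4 nm threshold is `tau + (1.4 - base) / rise_nm_per_ns`.
#'
#' @param mean_residence_ns mean of the exponential desorption time.
#' @param n_frames,dt trace length and spacing (ns).
#' @param base adsorbed-state distance, nm.
#' @param jitter adsorbed-state jitter SD, nm.
#' @param rise_nm_per_ns post-desorption rise rate, nm/ns.
#' @param seed optional RNG seed.
#' @return list `trace` (`DistanceTrace`), `tau_ns` (drawn desorption
#'   time), `true_crossing_ns` (analytic 1.4 nm crossing; `Inf` when
#'   beyond the trace), `censored`.
#' @export
make_desorption_trace <- function(mean_residence_ns = 350, n_frames = 4000,
                                  dt = 0.5, base = 0.3, jitter = 0.05,
                                  rise_nm_per_ns = 2.2, seed = NULL) {
  local_seed(seed, {
    tau <- stats::rexp(1, rate = 1 / mean_residence_ns)
    t <- (seq_len(n_frames) - 1) * dt
    vals <- pmin(pmax(stats::rnorm(n_frames, base, jitter), 0.02), 1.3)
    after <- t >= tau
    vals[after] <- base + rise_nm_per_ns * (t[after] - tau)
    crossing <- tau + (1.4 - base) / rise_nm_per_ns
    censored <- !any(vals > 1.4)
    list(trace = distance_trace(vals, dt, "HKI", "MEMB"),
         tau_ns = tau,
         true_crossing_ns = if (censored) Inf else crossing,
         censored = censored)
  })
}

#' Bernoulli proton-binding titration series
#'
#' For every pH on the grid and every replicate, per-frame bound-proton
#' indicators are drawn Bernoulli with deprotonation probability following
#' the Henderson-Hasselbalch curve at the true pKa. Trace length and frame
#' spacing default to a 20 ns run stored every 0.01 ns, so the standard
#' 10 ns analysis window holds 1000 frames.
#'
#' @param true_pka true pKa of the site.
#' @param hill_n Hill coefficient of the generating curve.
#' @param pH_grid pH values (default 3 to 8 in half steps).
#' @param n_replicates independent titration sets (default 3).
#' @param total_ns trace length per pH, ns.
#' @param dt frame spacing, ns.
#' @param seed optional RNG seed.
#' @return list `series` (data frame `pH`, `replicate`, `time_ns`,
#'   `bound_protons`), `true_pka`, `hill_n`.
#' @export
make_titration_series <- function(true_pka = 4.8, hill_n = 1,
                                  pH_grid = seq(3, 8, by = 0.5),
                                  n_replicates = 3, total_ns = 20,
                                  dt = 0.01, seed = NULL) {
  local_seed(seed, {
    t <- seq(dt, total_ns, by = dt)
    rows <- list()
    for (pH in pH_grid) {
      f_deprot <- 1 / (1 + 10^(hill_n * (true_pka - pH)))
      for (rep_ in seq_len(n_replicates)) {
        bound <- as.integer(stats::runif(length(t)) >= f_deprot)
        rows[[length(rows) + 1L]] <- data.frame(
          pH = pH, replicate = rep_, time_ns = t, bound_protons = bound)
      }
    }
    list(series = do.call(rbind, rows), true_pka = true_pka,
         hill_n = hill_n)
  })
}
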