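flat_leaflet_frames <- function(n_phos, n_frames, z, box = c(4, 4, 8),
                                jitter = 0, seed = 1) {
  set.seed(seed)
  coords <- array(NA_real_, dim = c(n_phos, 3, n_frames))
  for (f in seq_len(n_frames)) {
    coords[, 1, f] <- runif(n_phos, 0, box[1])
    coords[, 2, f] <- runif(n_phos, 0, box[2])
    coords[, 3, f] <- z + rnorm(n_phos, 0, jitter)
  }
  frame_series(coords, box, dt = 0.5)
}

test_that("a flat leaflet yields a constant thinning field", {
  fr <- flat_leaflet_frames(200, 60, z = 1.95)
  phos <- bead_selection(1:200, residue_id = 1:200, role = "phosphate")
  refs <- manual_refs(1:200, "top", rep(0, 60))
  map <- leaflet_thinning_map(fr, phos, "top", refs,
                              analysis_config(bin_xy = 0.5))
  vals <- map$thickness[map$valid]
  expect_true(length(vals) > 0)
  expect_true(all(abs(vals - 1.95) < 1e-9))
  s <- map_summary(map)
  expect_equal(s$min_nm, 1.95)
  expect_equal(s$mean_nm, 1.95)
})

test_that("the validity mask requires strictly more than min_bin_count", {
  # one phosphate pinned to one bin: 30 frames -> invalid, 31 -> valid
  for (n in c(30L, 31L)) {
    coords <- array(rep(c(0.05, 0.05, 1.95), n), dim = c(1, 3, n))
    fr <- frame_series(coords, c(2, 2, 6), dt = 0.5)
    phos <- bead_selection(1L, role = "phosphate")
    refs <- manual_refs(1L, "top", rep(0, n))
    map <- leaflet_thinning_map(fr, phos, "top", refs)
    expect_equal(max(map$count), n)
    expect_equal(any(map$valid), n > 30L)
  }
})

test_that("thinning map recovers the funnel depth from generator truth", {
  sys <- make_bilayer(n_frames = 2200,
                      funnels = list(list(center = c(8.3, 5.55),
                                          depth = 1.20, width = 0.7,
                                          leaflet = "top")),
                      seed = 501)
  refs <- assign_leaflets(sys$frames, sys$phosphates)
  refs <- membrane_centers(sys$frames, sys$glycerols, sys$lipids, refs)
  map <- leaflet_thinning_map(sys$frames, sys$phosphates, "top", refs)
  s <- map_summary(map)
  expect_equal(s$min_nm, sys$truth$analytic_min, tolerance = 0.05 / 0.75)
  # a region mask excluding the funnel recovers the plane height
  g <- expand.grid(x = map$x, y = map$y)
  away <- matrix(sqrt((g$x - 8.3)^2 + (g$y - 5.55)^2) > 2.5,
                 nrow = length(map$x))
  s_away <- map_summary(map, region = away)
  expect_equal(s_away$mean_nm, sys$truth$h, tolerance = 0.02 / 1.95)
})

test_that("zero-jitter zero-diffusion bilayer reproduces the analytic field", {
  sys <- make_bilayer(n_per_leaflet = 100, n_frames = 40, jitter_sd = 0,
                      diff_step = 0, seed = 77)
  refs <- assign_leaflets(sys$frames, sys$phosphates)
  refs <- membrane_centers(sys$frames, sys$glycerols, sys$lipids, refs)
  map <- leaflet_thinning_map(sys$frames, sys$phosphates, "top", refs,
                              analysis_config(bin_xy = 1.0, min_bin_count = 1))
  vals <- map$thickness[map$valid]
  expect_true(all(abs(vals - 1.95) < 1e-9))
})

test_that("radial minimum profile locates funnels and their azimuths", {
  # synthetic uniform map with two funnels of different depths dug in by hand
  fr <- flat_leaflet_frames(400, 80, z = 1.95, box = c(10, 10, 8), seed = 4)
  phos <- bead_selection(1:400, residue_id = 1:400, role = "phosphate")
  refs <- manual_refs(1:400, "top", rep(0, 80))
  cfg <- analysis_config(bin_xy = 0.5, min_bin_count = 5)
  base_map <- leaflet_thinning_map(fr, phos, "top", refs, cfg)
  expect_equal(map_summary(base_map)$min_nm, 1.95)

  dig <- function(map, center, value, radius = 0.6) {
    g <- expand.grid(x = map$x, y = map$y)
    hit <- sqrt((g$x - center[1])^2 + (g$y - center[2])^2) < radius
    map$thickness[matrix(hit, nrow = length(map$x)) & map$valid] <- value
    map
  }
  ctr <- c(5, 5)
  # deep funnel east (azimuth 0), shallow funnel north (azimuth 90)
  two <- dig(dig(base_map, c(7, 5), 0.75), c(5, 7), 1.10)
  circ_diff <- function(a, b) {
    d <- abs(a - b) %% 360
    min(d, 360 - d)
  }
  prof <- radial_minimum_profile(two, ctr, annulus = c(1.2, 3.0))
  expect_equal(prof$ring_min_nm, 0.75)
  # ties inside the dug disc are broken arbitrarily; the disc subtends
  # ~ +/-25 degrees at this radius, plus half-bin quantization
  expect_lt(circ_diff(prof$ring_min_azimuth_deg, 0), 35)
  north <- prof$profile$min_nm[abs(prof$profile$azimuth_deg - 90) < 20]
  expect_true(any(abs(north - 1.10) < 1e-9))
  # removing the deeper funnel promotes the shallower to the global minimum
  one <- dig(base_map, c(5, 7), 1.10)
  prof1 <- radial_minimum_profile(one, ctr, annulus = c(1.2, 3.0))
  expect_equal(prof1$ring_min_nm, 1.10)
  expect_lt(circ_diff(prof1$ring_min_azimuth_deg, 90), 35)

  uniform <- radial_minimum_profile(base_map, ctr, annulus = c(1.2, 3.0))
  expect_equal(uniform$ring_min_nm, 1.95)
  expect_true(all(abs(stats::na.omit(uniform$profile$min_nm) - 1.95) < 1e-9))
})

test_that("water defect counting matches hand-placed membership", {
  box <- c(10, 10, 10)
  anchor <- c(5, 5)
  inside <- cbind(runif(7, 4, 6), runif(7, 4, 6), runif(7, 4.2, 5.8))
  outside <- rbind(cbind(runif(3, 0, 1), runif(3, 0, 1), runif(3, 4, 6)),
                   cbind(runif(2, 4, 6), runif(2, 4, 6), runif(2, 8, 9.5)))
  m <- rbind(inside, outside)
  fr <- frames_from_matrix(m, box)
  waters <- bead_selection(1:12, residue_id = 1:12, role = "water")
  refs <- manual_refs(integer(0), character(0), center_z_global = 5)
  d <- water_defect_count(fr, waters, protein = NULL, refs,
                          anchor_xy = anchor)
  expect_equal(d$counts, 7L)
  expect_error(water_defect_count(fr, waters, protein = NULL, refs),
               "config error")
})

test_that("cylinder counts equal the point-in-cylinder brute force", {
  set.seed(8)
  box <- c(12, 12, 10)
  n <- 10000
  m <- cbind(runif(n, 0, 12), runif(n, 0, 12), runif(n, 0, 10))
  fr <- frames_from_matrix(m, box)
  waters <- bead_selection(1:n, residue_id = 1:n, role = "water")
  refs <- manual_refs(integer(0), character(0), center_z_global = 5)
  anchor <- c(1.0, 11.0)  # near the corner so xy wrapping matters
  d <- water_defect_count(fr, waters, protein = NULL, refs,
                          anchor_xy = anchor)
  brute <- sum(vapply(seq_len(n), function(i) {
    brute_in_cylinder(m[i, ], anchor, 5, 2.5, 1.5, box)
  }, logical(1)))
  expect_equal(d$counts, brute)
})

test_that("defect counts are invariant under xy translation of the system", {
  set.seed(9)
  box <- c(8, 8, 8)
  m <- cbind(runif(300, 0, 8), runif(300, 0, 8), runif(300, 0, 8))
  fr <- frames_from_matrix(m, box)
  waters <- bead_selection(1:300, residue_id = 1:300, role = "water")
  refs <- manual_refs(integer(0), character(0), center_z_global = 4)
  shift <- c(2.7, -1.3)
  m2 <- m
  m2[, 1] <- (m[, 1] + shift[1]) %% 8
  m2[, 2] <- (m[, 2] + shift[2]) %% 8
  fr2 <- frames_from_matrix(m2, box)
  a1 <- water_defect_count(fr, waters, NULL, refs, anchor_xy = c(4, 4))
  a2 <- water_defect_count(fr2, waters, NULL, refs,
                           anchor_xy = c(4 + shift[1], 4 + shift[2]))
  expect_equal(a1$counts, a2$counts)
})

test_that("occupancy grid is binary-per-cell and conserves a single bead", {
  box <- c(2, 2, 2)
  # one static bead: its cell 100%, everything else 0
  coords <- array(rep(c(0.5, 0.5, 0.5), 10), dim = c(1, 3, 10))
  fr <- frame_series(coords, box, dt = 0.5)
  sel <- bead_selection(1L, role = "phosphate")
  g <- occupancy_grid(fr, sel)
  expect_equal(max(g$occupancy), 100)
  expect_equal(sum(g$occupancy > 0), 1L)
  expect_equal(sum(g$occupancy) / 100, 1)

  # alternating between two cells on even/odd frames: 50% each
  coords2 <- array(NA_real_, dim = c(1, 3, 10))
  for (f in 1:10) {
    coords2[1, , f] <- if (f %% 2) c(0.5, 0.5, 0.5) else c(1.5, 0.5, 0.5)
  }
  g2 <- occupancy_grid(frame_series(coords2, box, dt = 0.5), sel)
  expect_equal(sort(g2$occupancy[g2$occupancy > 0]), c(50, 50))

  # single-bead conservation for a random walk (incl. wrapping)
  set.seed(12)
  coords3 <- array(c(runif(30, -1, 3)), dim = c(1, 3, 10))
  g3 <- occupancy_grid(frame_series(coords3, box, dt = 0.5), sel)
  expect_equal(sum(g3$occupancy) / 100, 1)
})

test_that("isosurface mask is monotone in threshold and exports OBJ", {
  set.seed(14)
  g <- structure(list(occupancy = array(runif(6 * 6 * 6, 0, 100),
                                        dim = c(6, 6, 6)),
                      spacing = 0.2, origin = c(0, 0, 0),
                      dims = c(6L, 6L, 6L)),
                 class = "OccupancyGrid")
  ths <- sort(runif(6, 1, 99))
  masks <- lapply(ths, function(t) export_isosurface(g, t)$mask)
  for (i in seq_len(length(ths) - 1L)) {
    expect_true(all(masks[[i]] | !masks[[i + 1L]]))  # mask(lo) >= mask(hi)
    expect_gte(sum(masks[[i]]), sum(masks[[i + 1L]]))
  }
  hot <- g
  hot$occupancy[] <- 0
  hot$occupancy[3, 3, 3] <- 100
  iso <- export_isosurface(hot, 0.5)
  expect_equal(sum(iso$mask), 1L)
  expect_equal(nrow(iso$faces), 12L)  # 6 exposed faces, 2 triangles each
  above <- export_isosurface(g, 99.99)
  expect_equal(sum(above$mask), sum(g$occupancy >= 99.99))
  expect_error(export_isosurface(g, 0), "config error")

  obj <- withr::local_tempfile(fileext = ".obj")
  export_isosurface(hot, 0.5, obj_path = obj)
  lines <- readLines(obj)
  expect_equal(sum(startsWith(lines, "v ")), 24L)
  expect_equal(sum(startsWith(lines, "f ")), 12L)
})

test_that("OpenDX export writes a well-formed scalar field", {
  g <- structure(list(occupancy = array(seq(0, 100, length.out = 27),
                                        dim = c(3, 3, 3)),
                      spacing = 0.2, origin = c(0, 0, 0),
                      dims = c(3L, 3L, 3L)),
                 class = "OccupancyGrid")
  path <- withr::local_tempfile(fileext = ".dx")
  write_opendx(g, path)
  lines <- readLines(path)
  expect_match(lines[1], "counts 3 3 3")
  expect_match(lines[3], "delta 2")  # 0.2 nm written as 2 Angstrom
  data_lines <- lines[8:16]
  vals <- scan(text = data_lines, quiet = TRUE)
  expect_equal(length(vals), 27L)
  expect_equal(vals[1], g$occupancy[1, 1, 1], tolerance = 1e-5)
})

test_that("residue depth traces measure z relative to the glycerol center", {
  m <- rbind(c(1, 1, 1.2), c(2, 2, 5))
  fr <- frames_from_matrix(m, box = c(6, 6, 8), n_frames = 4)
  glu <- bead_selection(1L, residue_name = "GLU", role = "titratable_site")
  refs <- manual_refs(integer(0), character(0),
                      center_z_global = rep(0.9, 4),
                      center_z_glycerol = rep(0.9, 4))
  d <- residue_depth_trace(fr, glu, refs)
  expect_equal(d$depth_nm, rep(0.3, 4), tolerance = 1e-12)
  expect_equal(d$mean_nm, 0.3)
  expect_equal(d$sd_nm, 0)

  # buried bead from the generator recovers its prescribed depth
  sys <- make_bilayer(n_per_leaflet = 80, n_frames = 30, seed = 61)
  sys <- make_protein_wall(sys, glu_depth = 0.4)
  refs2 <- assign_leaflets(sys$frames, sys$phosphates)
  refs2 <- membrane_centers(sys$frames, sys$glycerols, sys$lipids, refs2)
  dep <- residue_depth_trace(sys$frames, sys$glu, refs2)
  expect_equal(dep$mean_nm, 0.4, tolerance = 0.05 / 0.4)
  sysf <- make_bilayer(n_per_leaflet = 80, n_frames = 30, seed = 62)
  sysf <- make_protein_wall(sysf, glu_depth = -0.4)
  refsf <- assign_leaflets(sysf$frames, sysf$phosphates)
  refsf <- membrane_centers(sysf$frames, sysf$glycerols, sysf$lipids, refsf)
  depf <- residue_depth_trace(sysf$frames, sysf$glu, refsf)
  expect_equal(depf$mean_nm, -0.4, tolerance = 0.05 / 0.4)
})
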