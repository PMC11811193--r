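make_two_group_frames <- function(separations, box = c(20, 20, 20)) {
  # one bead per group; group b displaced along x by the given separation
  n <- length(separations)
  coords <- array(0, dim = c(2, 3, n))
  for (f in seq_len(n)) {
    coords[1, , f] <- c(1, 1, 1)
    coords[2, , f] <- c(1 + separations[f], 1, 1)
  }
  frame_series(coords, box, dt = 0.5)
}

test_that("contact fraction counts frames below the cutoff", {
  seps <- c(rep(0.4, 40), rep(2.0, 60))
  fr <- make_two_group_frames(seps)
  a <- bead_selection(1L, residue_id = 1L, residue_name = "MET1",
                      role = "protein")
  b <- bead_selection(2L, residue_id = 73L, residue_name = "GLU",
                      role = "protein")
  tab <- residue_contact_fraction(fr, a, b, cutoff = 0.6)
  expect_equal(tab$fraction, 0.40)

  far <- make_two_group_frames(rep(6, 50))
  expect_equal(residue_contact_fraction(far, a, b)$fraction, 0)
  expect_error(residue_contact_fraction(fr, a, a), "overlap")
})

test_that("contact fractions equal an all-pairs brute-force recount", {
  set.seed(13)
  box <- c(6, 6, 6)
  n_frames <- 25
  coords <- array(runif(12 * 3 * n_frames, 0, 6),
                  dim = c(12, 3, n_frames))
  fr <- frame_series(coords, box, dt = 0.5)
  a <- bead_selection(1:6, residue_id = rep(1:2, each = 3),
                      role = "protein")
  b <- bead_selection(7:12, residue_id = rep(3:4, each = 3),
                      role = "protein")
  tab <- residue_contact_fraction(fr, a, b, cutoff = 1.0)
  for (r in seq_len(nrow(tab))) {
    ia <- a$index[a$residue_id == tab$residue_a[r]]
    ib <- b$index[b$residue_id == tab$residue_b[r]]
    hits <- 0L
    for (f in seq_len(n_frames)) {
      if (brute_min_pair(coords[ia, , f], coords[ib, , f], box) < 1.0) {
        hits <- hits + 1L
      }
    }
    expect_equal(tab$fraction[r], hits / n_frames)
  }
  # monotone in cutoff: prevalence at 0.6 <= prevalence at 1.0
  t06 <- residue_contact_fraction(fr, a, b, cutoff = 0.6)
  expect_true(all(t06$fraction <= tab$fraction))
})

test_that("minimum-distance trace echoes separations and matches brute force", {
  seps <- c(0.3, 1.2, 2.5, 0.9)
  fr <- make_two_group_frames(seps)
  a <- bead_selection(1L, role = "protein")
  b <- bead_selection(2L, residue_id = 2L, role = "protein")
  tr <- min_distance_trace(fr, a, b)
  expect_equal(tr$values, seps, tolerance = 1e-12)
  expect_error(min_distance_trace(fr, a, a), "overlap")

  set.seed(5)
  coords <- array(runif(10 * 3 * 10, 0, 5), dim = c(10, 3, 10))
  fr2 <- frame_series(coords, c(5, 5, 5), dt = 0.5)
  ga <- bead_selection(1:4, role = "protein")
  gb <- bead_selection(5:10, residue_id = 2L, role = "protein")
  tr2 <- min_distance_trace(fr2, ga, gb)
  for (f in 1:10) {
    expect_equal(tr2$values[f],
                 brute_min_pair(coords[1:4, , f], coords[5:10, , f],
                                c(5, 5, 5)),
                 tolerance = 1e-12)
  }
})

test_that("double-cutoff event detection follows its definition", {
  tr <- distance_trace(c(1.2, 0.9, 0.5, 0.8, 1.2, 0.9, 0.95, 1.2), dt = 0.5)
  ev <- detect_contact_events(tr, inner = 0.6, outer = 1.0)
  # one event: the run that dips below 0.6; the later 0.9/0.95 run never
  # reaches the inner cutoff and is rejected
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$start_frame, 2L)
  expect_equal(ev$end_frame, 4L)
  expect_equal(ev$duration_ns, 1.5)

  none <- detect_contact_events(distance_trace(rep(1.5, 10), 0.5))
  expect_equal(nrow(none), 0L)

  all_in <- detect_contact_events(distance_trace(rep(0.3, 10), 0.5))
  expect_equal(nrow(all_in), 1L)
  expect_equal(all_in$duration_ns, 5)
  expect_true(all_in$censored)

  expect_error(detect_contact_events(tr, inner = 1.0, outer = 0.6),
               "config error")
})

test_that("detected events satisfy the double-cutoff invariants", {
  set.seed(99)
  for (i in 1:50) {
    v <- runif(300, 0.2, 2.0)
    tr <- distance_trace(v, dt = 0.5)
    ev <- detect_contact_events(tr)
    if (!nrow(ev)) next
    for (r in seq_len(nrow(ev))) {
      run <- v[ev$start_frame[r]:ev$end_frame[r]]
      expect_true(all(run < 1.0))
      expect_true(any(run < 0.6))
    }
    # disjoint, ordered, separated by at least one frame >= outer
    if (nrow(ev) > 1L) {
      expect_true(all(diff(ev$start_frame) > 0))
      expect_true(all(ev$start_frame[-1] > ev$end_frame[-nrow(ev)] + 1L))
    }
    expect_lte(sum(ev$duration_ns), length(v) * 0.5)
  }
})

test_that("lifetime histogram bins mass and normalizes by total time", {
  ev <- data.frame(duration_ns = c(5, 5, 1000))
  h <- lifetime_histogram(ev, total_time = 10000,
                          edges = c(1, 10, 100, 1000, 10000))
  expect_equal(h$normalized, c(0.001, 0, 0, 0.1))
  expect_equal(sum(h$mass_ns), sum(ev$duration_ns))

  empty <- lifetime_histogram(data.frame(duration_ns = numeric(0)),
                              total_time = 100, edges = c(1, 10, 100))
  expect_true(all(empty$mass_ns == 0))

  set.seed(2)
  for (i in 1:20) {
    d <- runif(20, 0.5, 500)
    h <- lifetime_histogram(data.frame(duration_ns = d), total_time = 1e5,
                            edges = 10^seq(-1, 3, by = 0.25))
    expect_equal(sum(h$mass_ns), sum(d), tolerance = 1e-9)
    expect_true(all(h$normalized <= 1))
  }
  expect_error(
    lifetime_histogram(data.frame(duration_ns = 5000), total_time = 1e5,
                       edges = c(1, 10, 100)),
    "binning error")
})

test_that("duration-weighted mean lifetime follows sum(d^2)/sum(d)", {
  expect_equal(weighted_mean_lifetime(c(1, 3))$mean_ns, 2.5)
  one <- weighted_mean_lifetime(c(7))
  expect_equal(one$mean_ns, 7)
  expect_equal(one$sem_ns, 0)
  expect_false(one$sem_defined)
  expect_error(weighted_mean_lifetime(numeric(0)), "empty")

  set.seed(31)
  for (i in 1:200) {
    d <- rexp(sample(2:40, 1), 0.1)
    got <- weighted_mean_lifetime(d)
    expect_equal(got$mean_ns, sum(d^2) / sum(d), tolerance = 1e-12)
    expect_gte(got$sem_ns, 0)
  }
})

test_that("replicate statistics give sd/sqrt(n) and flag single replicas", {
  st <- replicate_stats(c(1, 2, 3))
  expect_equal(st$mean, 2)
  expect_equal(st$sem, 1 / sqrt(3), tolerance = 1e-6)
  expect_equal(round(st$sem, 4), 0.5774)
  expect_equal(replicate_stats(c(4, 4, 4))$sem, 0)
  single <- replicate_stats(17.20)
  expect_equal(single$mean, 17.20)
  expect_false(single$sem_defined)
  expect_error(replicate_stats(numeric(0)), "empty")
})

test_that("telegraph traces recover prevalence and off-rate kinetics", {
  # dwell times (1/k) far above dt so discretization bias is negligible
  k_on <- 0.004; k_off <- 0.02
  sim <- make_contact_trace(n_frames = 60000, dt = 0.5, k_on = k_on,
                            k_off = k_off, seed = 404)
  ev <- detect_contact_events(sim$trace)
  prev <- sum(ev$end_frame - ev$start_frame + 1L) / 60000
  p_stat <- k_on / (k_on + k_off)
  n_ev <- nrow(ev)
  # mean unweighted event duration ~ 1/k_off, MC SE = mean/sqrt(n)
  mean_dur <- mean(ev$duration_ns)
  expect_lt(abs(mean_dur - 1 / k_off), 3 * mean_dur / sqrt(n_ev))
  # variance of the occupied fraction of a two-state Markov process over T:
  # 2 p^2 (1-p)^2 / ((k_on + k_off) T)
  total_ns <- 60000 * 0.5
  se_prev <- sqrt(2 * p_stat^2 * (1 - p_stat)^2 /
                    ((k_on + k_off) * total_ns))
  expect_lt(abs(prev - p_stat), 3 * se_prev)
})
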