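#' Per-frame minimum distance between two bead groups
#'
#' The minimum over all bead pairs of the minimum-image distance, evaluated
#' at every frame. This is the raw series that contact-event detection and
#' residence analysis consume.
#'
#' @param frames a `FrameSeries`.
#' @param group_a,group_b non-empty, disjoint `BeadSelection`s.
#' @return a `DistanceTrace`: list with `values` (nm, one per frame), `dt`
#'   (ns), `group_a`, `group_b` labels.
#' @export
min_distance_trace <- function(frames, group_a, group_b) {
  check_selection(group_a, frames, "group_a")
  check_selection(group_b, frames, "group_b")
  if (length(intersect(group_a$index, group_b$index))) {
    stop("selection error: group_a and group_b overlap")
  }
  vals <- vapply(seq_len(frames$n_frames), function(f) {
    min_pair_distance(frames$coords[group_a$index, , f, drop = FALSE][, , 1],
                      frames$coords[group_b$index, , f, drop = FALSE][, , 1],
                      frames$box[f, ])
  }, numeric(1))
  distance_trace(vals, frames$dt,
                 group_a = group_a$residue_name[1],
                 group_b = group_b$residue_name[1])
}

#' Construct a DistanceTrace from raw values
#' @param values per-frame minimum distances, nm.
#' @param dt frame spacing, ns.
#' @param group_a,group_b labels.
#' @return a `DistanceTrace`.
#' @export
distance_trace <- function(values, dt, group_a = "A", group_b = "B") {
  if (!length(values)) stop("empty distance trace")
  if (any(values < 0) || !all(is.finite(values))) {
    stop("distances must be finite and non-negative")
  }
  structure(list(values = as.numeric(values), dt = dt,
                 group_a = group_a, group_b = group_b),
            class = "DistanceTrace")
}

#' Residue-level contact prevalence
#'
#' For each residue pair (one residue from each group), the fraction of
#' frames in which any bead of the first residue is within `cutoff` of any
#' bead of the second, using minimum-image distances. Two residues are in
#' contact in a frame if they have any particles in contact.
#'
#' @param frames a `FrameSeries`.
#' @param group_a,group_b disjoint `BeadSelection`s; residues are taken from
#'   their `residue_id` columns.
#' @param cutoff contact cutoff, nm (default 0.6).
#' @return data frame with columns `residue_a`, `residue_b`, `name_a`,
#'   `name_b`, `fraction`.
#' @export
residue_contact_fraction <- function(frames, group_a, group_b,
                                     cutoff = 0.6) {
  check_selection(group_a, frames, "group_a")
  check_selection(group_b, frames, "group_b")
  if (length(intersect(group_a$index, group_b$index))) {
    stop("selection error: groups overlap")
  }
  res_a <- unique(group_a$residue_id)
  res_b <- unique(group_b$residue_id)
  grid <- expand.grid(residue_a = res_a, residue_b = res_b)
  counts <- matrix(0L, length(res_a), length(res_b))
  for (f in seq_len(frames$n_frames)) {
    dm <- pair_distance_matrix(
      frames$coords[group_a$index, , f, drop = FALSE][, , 1],
      frames$coords[group_b$index, , f, drop = FALSE][, , 1],
      frames$box[f, ])
    hit <- dm < cutoff
    for (i in seq_along(res_a)) {
      ai <- group_a$residue_id == res_a[i]
      for (j in seq_along(res_b)) {
        bj <- group_b$residue_id == res_b[j]
        if (any(hit[ai, bj])) counts[i, j] <- counts[i, j] + 1L
      }
    }
  }
  grid$name_a <- group_a$residue_name[match(grid$residue_a,
                                            group_a$residue_id)]
  grid$name_b <- group_b$residue_name[match(grid$residue_b,
                                            group_b$residue_id)]
  grid$fraction <- as.vector(counts) / frames$n_frames
  grid
}

#' Detect contact events with the double-cutoff rule
#'
#' A contact event is a maximal run of consecutive frames whose distance
#' stays inside the outer cutoff, kept only if the distance dips below the
#' inner cutoff at least once within the run. The double cutoff suppresses
#' the spurious binding/unbinding frames a single cutoff counts when the
#' distance fluctuates around it, preserving long events intact.
#'
#' @param trace a `DistanceTrace`.
#' @param inner inner (binding) cutoff, nm; default 0.6.
#' @param outer outer (event-continuation) cutoff, nm; default 1.0.
#' @return data frame of events: `start_frame`, `end_frame` (1-based,
#'   inclusive), `duration_ns` (= n_frames_in_event * dt), `censored`
#'   (TRUE if the event touches either trace end).
#' @export
detect_contact_events <- function(trace, inner = 0.6, outer = 1.0) {
  if (inner >= outer) stop("config error: inner cutoff must be < outer")
  v <- trace$values
  inside <- v < outer
  r <- rle(inside)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  rows <- lapply(keep, function(k) {
    s <- starts[k]; e <- ends[k]
    if (min(v[s:e]) < inner) c(s, e) else NULL
  })
  rows <- do.call(rbind, rows)
  if (is.null(rows)) {
    return(data.frame(start_frame = integer(0), end_frame = integer(0),
                      duration_ns = numeric(0), censored = logical(0)))
  }
  data.frame(
    start_frame = rows[, 1], end_frame = rows[, 2],
    duration_ns = (rows[, 2] - rows[, 1] + 1L) * trace$dt,
    censored = rows[, 1] == 1L | rows[, 2] == length(v)
  )
}

#' Duration-weighted logarithmic lifetime histogram
#'
#' Event durations are binned into logarithmic bins; each bin accumulates
#' the summed duration of the events falling in it (half-open bins
#' `[lo, hi)`), then the per-bin mass is normalized by the total simulated
#' time. Default edges run from `dt` to just past `total_time` in decades
#' with 5 bins per decade.
#'
#' @param events event data frame from [detect_contact_events()].
#' @param total_time total simulated time, ns.
#' @param edges optional strictly increasing bin edges, ns.
#' @param dt frame spacing used for default edges, ns.
#' @return data frame `bin_lo`, `bin_hi`, `mass_ns`, `normalized`.
#' @export
lifetime_histogram <- function(events, total_time, edges = NULL, dt = 0.5) {
  if (is.null(edges)) {
    lo <- log10(dt); hi <- log10(total_time * (1 + 1e-9))
    edges <- 10^seq(lo, ceiling(hi * 5) / 5, by = 0.2)
  }
  if (any(diff(edges) <= 0)) stop("bin edges must be strictly increasing")
  d <- events$duration_ns
  if (sum(d) > total_time * (1 + 1e-9)) {
    stop("total_time is smaller than the summed event durations")
  }
  mass <- numeric(length(edges) - 1L)
  if (length(d)) {
    idx <- findInterval(d, edges, left.open = FALSE, rightmost.closed = FALSE)
    if (any(d < edges[1]) || any(d >= edges[length(edges)])) {
      off <- which(d < edges[1] | d >= edges[length(edges)])[1]
      stop("binning error: event of duration ", d[off],
           " ns lies outside the edge span [", edges[1], ", ",
           edges[length(edges)], ")")
    }
    for (i in seq_along(d)) mass[idx[i]] <- mass[idx[i]] + d[i]
  }
  data.frame(bin_lo = edges[-length(edges)], bin_hi = edges[-1],
             mass_ns = mass, normalized = mass / total_time)
}

#' Duration-weighted mean contact lifetime and weighted SEM
#'
#' The mean lifetime weighted by duration is `sum(d^2) / sum(d)` over event
#' durations `d`. Its uncertainty is a weighted SEM with reliability
#' weights `w = d`: `sqrt(Var_w * sum(w^2) / (sum(w))^2)` where `Var_w` is
#' the weighted variance about the weighted mean. With a single event the
#' SEM is reported as 0 and flagged undefined.
#'
#' @param events event data frame (or numeric vector of durations, ns).
#' @return list `mean_ns`, `sem_ns`, `n_events`, `sem_defined`.
#' @export
weighted_mean_lifetime <- function(events) {
  d <- if (is.data.frame(events)) events$duration_ns else as.numeric(events)
  if (!length(d)) stop("empty event list: no lifetimes to average")
  w <- d
  m <- sum(w * d) / sum(w)
  if (length(d) == 1L) {
    return(list(mean_ns = m, sem_ns = 0, n_events = 1L,
                sem_defined = FALSE))
  }
  var_w <- sum(w * (d - m)^2) / sum(w)
  sem <- sqrt(var_w * sum(w^2) / sum(w)^2)
  list(mean_ns = m, sem_ns = sem, n_events = length(d), sem_defined = TRUE)
}

#' Mean and SEM over replicates
#'
#' Plain replicate aggregation: mean and standard error of the mean
#' (sample sd / sqrt(n)). With one replicate the SEM is reported as 0 and
#' flagged undefined.
#'
#' @param values per-replicate numbers.
#' @return list `mean`, `sem`, `n`, `sem_defined`.
#' @export
replicate_stats <- function(values) {
  values <- as.numeric(values)
  if (!length(values)) stop("empty input: no replicate values")
  n <- length(values)
  if (n == 1L) {
    return(list(mean = values, sem = 0, n = 1L, sem_defined = FALSE))
  }
  list(mean = mean(values), sem = stats::sd(values) / sqrt(n), n = n,
       sem_defined = TRUE)
}
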