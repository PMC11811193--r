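#' Run the analysis pipeline from a config file
#'
#' Drives the analysis stages over a synthetic scenario or user-supplied
#' trajectory files, writes per-stage CSV tables and a JSON run manifest
#' recording the config snapshot, seed, package version and output paths.
#' Re-running an identical config and seed reproduces the deterministic
#' outputs byte for byte.
#'
#' Config keys (YAML): `seed`, `out_dir`, `stages` (subset of `thinning`,
#' `defects`, `occupancy`, `depth`, `contacts`, `residence`, `titration`),
#' `scenario: synthetic`, optional `config:` overrides of
#' [analysis_config()] fields, and optional `synthetic:` overrides of the
#' generator defaults (`n_frames`, `funnel_depth`, `glu_depth`,
#' `mean_residence_ns`, `true_pka`, `n_residence_replicas`,
#' `contact_k_on`, `contact_k_off`).
#'
#' @param config path to a YAML config, or an equivalent named list.
#' @param out_dir output directory; overrides the config's `out_dir`.
#' @return the run manifest, invisibly (also written as `manifest.json`).
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  cfg_in <- if (is.character(config)) yaml::read_yaml(config) else config
  if (!is.list(cfg_in)) stop("config error: config must be a file or list")
  out_dir <- out_dir %||% cfg_in$out_dir %||% stop(
    "config error: missing key 'out_dir'")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- cfg_in$seed %||% 1L
  stages <- cfg_in$stages %||% character(0)
  known <- c("thinning", "defects", "occupancy", "depth", "contacts",
             "residence", "titration")
  bad <- setdiff(stages, known)
  if (length(bad)) {
    stop("config error at key 'stages': unknown stage(s) ",
         paste(bad, collapse = ", "))
  }
  acfg <- do.call(analysis_config, cfg_in$config %||% list())
  syn <- cfg_in$synthetic %||% list()
  outputs <- list()
  wrt <- function(df, name) {
    p <- file.path(out_dir, name)
    utils::write.csv(format(df, digits = 6, trim = TRUE, scientific = FALSE),
                     p, row.names = FALSE, quote = FALSE)
    outputs[[name]] <<- p
    p
  }

  needs_membrane <- any(c("thinning", "defects", "occupancy",
                          "depth") %in% stages)
  if (needs_membrane) {
    sys <- make_bilayer(
      n_frames = syn$n_frames %||% 60,
      funnels = list(list(center = c(8.3, 5.55),
                          depth = syn$funnel_depth %||% 1.20,
                          width = 0.7, leaflet = "top")),
      seed = seed)
    sys <- make_protein_wall(sys, glu_depth = syn$glu_depth %||% 0.4)
    sys <- make_waters(sys, defect_center_xy = c(8.3, 5.55),
                       seed = seed + 1L)
    refs <- assign_leaflets(sys$frames, sys$phosphates)
    refs <- membrane_centers(sys$frames, sys$glycerols, sys$lipids, refs)
    if ("thinning" %in% stages) {
      map <- leaflet_thinning_map(sys$frames, sys$phosphates, "top", refs,
                                  acfg)
      s <- map_summary(map)
      wrt(data.frame(leaflet = "top", min_nm = s$min_nm,
                     mean_nm = s$mean_nm, n_valid_bins = s$n_bins),
          "thinning_summary.csv")
    }
    if ("defects" %in% stages) {
      dtr <- water_defect_count(sys$frames, sys$waters, sys$protein, refs,
                                acfg)
      wrt(data.frame(frame = seq_along(dtr$counts), count = dtr$counts),
          "defect_counts.csv")
      wrt(data.frame(mean = dtr$mean, sem = dtr$sem), "defect_summary.csv")
    }
    if ("occupancy" %in% stages) {
      grid <- occupancy_grid(sys$frames, sys$phosphates, acfg)
      p <- file.path(out_dir, "phosphate_occupancy.dx")
      write_opendx(grid, p)
      outputs[["phosphate_occupancy.dx"]] <- p
      iso <- export_isosurface(grid, acfg$occupancy_threshold,
                               file.path(out_dir, "occupancy_surface.obj"))
      outputs[["occupancy_surface.obj"]] <-
        file.path(out_dir, "occupancy_surface.obj")
      wrt(data.frame(threshold_pct = acfg$occupancy_threshold,
                     n_cells = iso$n_cells), "occupancy_mask.csv")
    }
    if ("depth" %in% stages) {
      dep <- residue_depth_trace(sys$frames, sys$glu, refs)
      wrt(data.frame(time_ns = frame_times(sys$frames),
                     depth_nm = dep$depth_nm), "glu_depth_trace.csv")
      wrt(data.frame(mean_nm = dep$mean_nm, sd_nm = dep$sd_nm),
          "glu_depth_summary.csv")
    }
  }
  if ("contacts" %in% stages) {
    ct <- make_contact_trace(n_frames = syn$n_frames_contacts %||% 4000,
                             k_on = syn$contact_k_on %||% 0.02,
                             k_off = syn$contact_k_off %||% 0.1,
                             seed = seed + 2L)
    ev <- detect_contact_events(ct$trace, acfg$d_contact,
                                acfg$d_event_outer)
    wrt(data.frame(start_ns = (ev$start_frame - 1) * ct$trace$dt,
                   end_ns = (ev$end_frame - 1) * ct$trace$dt,
                   duration_ns = ev$duration_ns, censored = ev$censored),
        "contact_events.csv")
    wml <- weighted_mean_lifetime(ev)
    hist <- lifetime_histogram(ev, length(ct$trace$values) * ct$trace$dt,
                               dt = ct$trace$dt)
    wrt(hist, "lifetime_histogram.csv")
    wrt(data.frame(mean_lifetime_ns = wml$mean_ns,
                   weighted_sem_ns = wml$sem_ns, n_events = wml$n_events),
        "lifetime_summary.csv")
  }
  if ("residence" %in% stages) {
    n_rep <- syn$n_residence_replicas %||% 6
    res <- lapply(seq_len(n_rep), function(i) {
      d <- make_desorption_trace(
        mean_residence_ns = syn$mean_residence_ns %||% 350,
        seed = seed + 10L + i)
      residence_time(d$trace, acfg$d_desorb)
    })
    summ <- residence_summary(res)
    wrt(data.frame(replica = seq_len(n_rep),
                   residence_ns = vapply(res, `[[`, 1, "residence_ns"),
                   censored = vapply(res, `[[`, TRUE, "censored")),
        "residence_replicas.csv")
    wrt(data.frame(mean_ns = summ$mean_ns, sem_ns = summ$sem_ns,
                   n_censored = summ$n_censored), "residence_summary.csv")
  }
  if ("titration" %in% stages) {
    tit <- make_titration_series(true_pka = syn$true_pka %||% 4.8,
                                 pH_grid = acfg$pH_grid,
                                 seed = seed + 20L)
    dd <- degree_of_deprotonation(tit$series, acfg$titration_window)
    fit <- fit_pka(dd$summary$pH, dd$summary$mean)
    wrt(dd$summary, "titration_curve.csv")
    wrt(data.frame(pka = fit$pka, hill_n = fit$hill_n,
                   midpoint_interp = fit$midpoint_interp,
                   shift_vs_solution = reference_shift(fit$pka)),
        "titration_fit.csv")
  }
  manifest <- list(
    package_version = as.character(utils::packageVersion("memtraj")),
    seed = seed,
    stages = stages,
    config = acfg[],
    synthetic = syn,
    outputs = lapply(outputs, normalizePath),
    output_md5 = if (length(outputs)) {
      as.list(tools::md5sum(unlist(outputs)))
    } else list()
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

#' Aggregate per-replica tables into a condition summary
#'
#' Given per-replica prevalence tables (as from
#' [residue_contact_fraction()]), returns per residue pair the mean and
#' SEM across replicas, plus a pooled aggregate (all frames of all
#' replicas combined, weighting replicas by their frame counts) as a
#' secondary column. The two differ when replica lengths differ.
#'
#' @param tables list of data frames with columns `residue_a`,
#'   `residue_b`, `fraction`, and optionally `n_frames`.
#' @param condition label carried into the output.
#' @return data frame `condition`, `residue_a`, `residue_b`,
#'   `mean_fraction`, `sem_fraction`, `pooled_fraction`, `n_replicas`.
#' @export
summarize_condition <- function(tables, condition = "condition") {
  if (!length(tables)) stop("aggregation error: no replica tables")
  need <- c("residue_a", "residue_b", "fraction")
  for (t in tables) {
    if (!all(need %in% names(t))) {
      stop("aggregation error: replica table lacks columns ",
           paste(setdiff(need, names(t)), collapse = ", "))
    }
  }
  keys <- unique(do.call(rbind,
                         lapply(tables, `[`, , c("residue_a", "residue_b"))))
  out <- do.call(rbind, lapply(seq_len(nrow(keys)), function(i) {
    fr <- vapply(tables, function(t) {
      r <- t$fraction[t$residue_a == keys$residue_a[i] &
                      t$residue_b == keys$residue_b[i]]
      if (length(r) != 1L) stop("aggregation error: pair missing ",
                                "from a replica table")
      r
    }, numeric(1))
    nf <- vapply(tables, function(t) {
      if ("n_frames" %in% names(t)) t$n_frames[1] else 1
    }, numeric(1))
    st <- replicate_stats(fr)
    data.frame(condition = condition,
               residue_a = keys$residue_a[i], residue_b = keys$residue_b[i],
               mean_fraction = st$mean, sem_fraction = st$sem,
               pooled_fraction = sum(fr * nf) / sum(nf),
               n_replicas = length(fr))
  }))
  rownames(out) <- NULL
  out
}
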