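#' Analysis configuration
#'
#' Bundles the numeric constants shared by the analysis stages. Defaults are
#' the standard values for coarse-grained membrane-protein work: a 0.6 nm
#' residue-contact cutoff, the 0.6/1.0 nm double cutoff for contact events,
#' a 1.4 nm desorption threshold, 0.1 nm lateral bins for leaflet maps with
#' a >30-observation validity mask, a defect cylinder of radius 2.5 nm and
#' total height 3 nm, a 0.2 nm (2 Angstrom) occupancy grid with a 0.5%
#' isosurface threshold, a 10 ns titration analysis window, and a pH grid
#' from 3 to 8 in half-unit steps.
#'
#' @param d_contact residue contact cutoff, nm.
#' @param d_event_outer outer cutoff of the contact-event definition, nm.
#' @param d_desorb desorption threshold for peptide residence, nm.
#' @param bin_xy lateral bin width of leaflet maps, nm.
#' @param min_bin_count a map bin is valid only with more than this many
#'   phosphate observations.
#' @param cyl_radius water-defect cylinder radius, nm.
#' @param cyl_half_height half the defect cylinder height, nm.
#' @param grid_spacing occupancy grid spacing, nm.
#' @param occupancy_threshold isosurface threshold, percent.
#' @param titration_window analysis window at the end of each titration
#'   trace, ns.
#' @param pH_grid pH values of the titration grid.
#' @return an `AnalysisConfig` list.
#' @export
analysis_config <- function(d_contact = 0.6, d_event_outer = 1.0,
                            d_desorb = 1.4, bin_xy = 0.1,
                            min_bin_count = 30, cyl_radius = 2.5,
                            cyl_half_height = 1.5, grid_spacing = 0.2,
                            occupancy_threshold = 0.5,
                            titration_window = 10,
                            pH_grid = seq(3, 8, by = 0.5)) {
  cfg <- list(d_contact = d_contact, d_event_outer = d_event_outer,
              d_desorb = d_desorb, bin_xy = bin_xy,
              min_bin_count = min_bin_count, cyl_radius = cyl_radius,
              cyl_half_height = cyl_half_height,
              grid_spacing = grid_spacing,
              occupancy_threshold = occupancy_threshold,
              titration_window = titration_window, pH_grid = pH_grid)
  lens <- c(cfg$d_contact, cfg$d_event_outer, cfg$d_desorb, cfg$bin_xy,
            cfg$cyl_radius, cfg$cyl_half_height, cfg$grid_spacing,
            cfg$titration_window)
  if (any(lens <= 0)) stop("all lengths and windows must be > 0")
  if (cfg$d_contact >= cfg$d_event_outer) {
    stop("d_contact must be smaller than d_event_outer")
  }
  if (cfg$occupancy_threshold <= 0 || cfg$occupancy_threshold >= 100) {
    stop("occupancy_threshold must lie in (0, 100) percent")
  }
  structure(cfg, class = "AnalysisConfig")
}
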