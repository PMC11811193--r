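#' Bead selections and role maps
#'
#' A `BeadSelection` names a set of particles by (1-based) index together
#' with residue/bead labels and a role tag. Roles follow the coarse-grained
#' bead taxonomy used throughout the package: lipid backbone phosphates and
#' glycerols, water beads, protein beads, free proton particles, and
#' titratable sites.
#'
#' @param indices integer vector of particle indices (1-based).
#' @param residue_id integer vector, recycled.
#' @param residue_name,bead_name character vectors, recycled.
#' @param role one of `"phosphate"`, `"glycerol"`, `"water"`, `"protein"`,
#'   `"proton"`, `"titratable_site"`, `"other"`.
#' @return a `BeadSelection` data frame.
#' @export
bead_selection <- function(indices, residue_id = seq_along(indices),
                           residue_name = "UNK", bead_name = "BB",
                           role = c("phosphate", "glycerol", "water",
                                    "protein", "proton", "titratable_site",
                                    "other")) {
  role <- match.arg(role)
  indices <- as.integer(indices)
  if (anyDuplicated(indices)) stop("selection indices must be unique")
  if (any(indices < 1L)) stop("selection indices must be >= 1 (1-based)")
  out <- data.frame(
    index = indices,
    residue_id = rep_len(as.integer(residue_id), length(indices)),
    residue_name = rep_len(as.character(residue_name), length(indices)),
    bead_name = rep_len(as.character(bead_name), length(indices)),
    role = role,
    stringsAsFactors = FALSE
  )
  class(out) <- c("BeadSelection", "data.frame")
  out
}

check_selection <- function(sel, frames = NULL, what = "selection") {
  if (!nrow(sel)) stop("empty ", what)
  if (!is.null(frames) && any(sel$index > frames$n_particles)) {
    stop(what, " refers to particle indices beyond n_particles")
  }
  invisible(sel)
}

#' Read a role map CSV into a list of BeadSelections
#'
#' The role map is a CSV with columns `index,residue_id,residue_name,
#' bead_name,role`. Particle indices in the file may be 0-based (the common
#' convention of trajectory tooling) or 1-based; they are stored 1-based.
#'
#' @param path CSV path.
#' @param index_base 0 or 1; base of the `index` column in the file.
#' @return named list of `BeadSelection`s, one per role present.
#' @export
read_role_map <- function(path, index_base = 0) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("index", "residue_id", "residue_name", "bead_name", "role")
  if (!all(need %in% names(df))) {
    stop("role map must have columns: ", paste(need, collapse = ", "))
  }
  df$index <- as.integer(df$index) + (1L - as.integer(index_base))
  split_roles <- split(df, df$role)
  lapply(split_roles, function(d) {
    bead_selection(d$index, d$residue_id, d$residue_name, d$bead_name,
                   role = d$role[1])
  })
}

#' Write a role map CSV
#' @param selections named list of `BeadSelection`s (or one selection).
#' @param path output CSV path.
#' @param index_base base to write indices in (default 0).
#' @return `path`, invisibly.
#' @export
write_role_map <- function(selections, path, index_base = 0) {
  if (inherits(selections, "BeadSelection")) selections <- list(selections)
  df <- do.call(rbind, lapply(selections, as.data.frame))
  df$index <- df$index - (1L - as.integer(index_base))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Subset a selection to one residue
#' @param sel a `BeadSelection`.
#' @param residue residue_id to keep.
#' @return a `BeadSelection` restricted to that residue.
#' @export
select_residue <- function(sel, residue) {
  out <- sel[sel$residue_id == residue, , drop = FALSE]
  if (!nrow(out)) stop("residue ", residue, " not present in selection")
  out
}
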