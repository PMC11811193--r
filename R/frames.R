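#' Frame series: time-ordered coarse-grained coordinates
#'
#' A `FrameSeries` holds particle positions for every stored frame of a
#' trajectory, together with the per-frame orthorhombic box and the time
#' spacing between stored frames. All coordinates are in nanometres and all
#' times in nanoseconds, whatever the source format used.
#'
#' @param coords numeric array of dimension `c(n_particles, 3, n_frames)`, nm.
#' @param box numeric matrix `n_frames x 3` of box edge lengths (nm), or a
#'   length-3 vector recycled to every frame.
#' @param dt time between stored frames in ns (default 0.5 ns, the usual
#'   save interval for coarse-grained production runs).
#' @param origin_format tag recording the source format.
#'
#' @return An object of class `FrameSeries`.
#' @export
frame_series <- function(coords, box, dt = 0.5, origin_format = "memory") {
  if (length(dim(coords)) == 2L) {
    coords <- array(coords, dim = c(dim(coords), 1L))
  }
  stopifnot(length(dim(coords)) == 3L, dim(coords)[2] == 3L)
  n_frames <- dim(coords)[3]
  n_particles <- dim(coords)[1]
  if (is.null(dim(box))) {
    box <- matrix(rep(as.numeric(box), length.out = 3L * n_frames),
                  ncol = 3L, byrow = TRUE)
  }
  box <- as.matrix(box)
  if (nrow(box) == 1L && n_frames > 1L) {
    box <- box[rep(1L, n_frames), , drop = FALSE]
  }
  if (!all(is.finite(coords))) stop("coordinates must be finite")
  if (!all(is.finite(box)) || any(box <= 0)) {
    stop("box lengths must be finite and positive")
  }
  if (nrow(box) != n_frames) stop("box must have one row per frame")
  if (!is.numeric(dt) || length(dt) != 1L || dt <= 0) stop("dt must be > 0")
  structure(
    list(coords = coords, box = box, dt = dt,
         n_frames = n_frames, n_particles = n_particles,
         origin_format = origin_format),
    class = "FrameSeries"
  )
}

#' @export
print.FrameSeries <- function(x, ...) {
  cat(sprintf(
    "<FrameSeries> %d frames x %d particles, dt = %g ns, box[1] = %s nm (%s)\n",
    x$n_frames, x$n_particles, x$dt,
    paste(signif(x$box[1, ], 4), collapse = " x "), x$origin_format))
  invisible(x)
}

#' Times of the stored frames
#'
#' Frame `i` (1-based) is reported at time `(i - 1) * dt` ns, so the first
#' stored frame sits at t = 0.
#' @param frames a `FrameSeries`.
#' @return numeric vector of length `n_frames`, ns.
#' @export
frame_times <- function(frames) {
  (seq_len(frames$n_frames) - 1) * frames$dt
}

#' Read a trajectory into a FrameSeries
#'
#' Supported formats: GRO (single- or multi-frame, nm), PDB (single- or
#' multi-MODEL, Angstrom, converted to nm), and a plain-text multi-frame
#' fallback whose first line is `nframes nparticles dt_ns box_x box_y box_z`
#' followed by one `x y z` line per particle per frame (nm). Compressed
#' binary trajectory formats (XTC/TRR/DCD) are not read; convert them to one
#' of the text formats first.
#'
#' @param path file path.
#' @param format one of `"auto"`, `"gro"`, `"pdb"`, `"txt"`.
#' @param dt_override frame spacing in ns for formats that do not store it
#'   (GRO/PDB); ignored for the plain-text format, which carries its own.
#' @return a [frame_series()].
#' @export
read_frames <- function(path, format = c("auto", "gro", "pdb", "txt"),
                        dt_override = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext,
      gro = "gro", pdb = "pdb", txt = "txt", dat = "txt",
      xtc = , trr = , dcd = stop(
        "binary trajectory formats (", ext,
        ") are not supported; supply GRO, PDB or the plain-text format"),
      stop("cannot infer format from extension '", ext,
           "'; pass format= explicitly"))
  }
  switch(format,
    txt = read_frames_txt(path),
    gro = read_frames_gro(path, dt_override %||% 0.5),
    pdb = read_frames_pdb(path, dt_override %||% 0.5))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

read_frames_txt <- function(path) {
  lines <- readLines(path)
  if (!length(lines)) stop("format error in ", path, ": empty file")
  hdr <- suppressWarnings(as.numeric(strsplit(trimws(lines[1]), "\\s+")[[1]]))
  if (length(hdr) != 6L || anyNA(hdr)) {
    stop("format error in ", path, " line 1: expected ",
         "'nframes nparticles dt_ns box_x box_y box_z'")
  }
  n_frames <- as.integer(hdr[1]); n_particles <- as.integer(hdr[2])
  need <- n_frames * n_particles
  body <- lines[-1]
  body <- body[nzchar(trimws(body))]
  if (length(body) != need) {
    stop("structural error in ", path, ": expected ", need,
         " coordinate lines (", n_frames, " frames x ", n_particles,
         " particles), found ", length(body))
  }
  vals <- scan(text = body, quiet = TRUE)
  if (length(vals) != 3L * need) {
    stop("format error in ", path, ": coordinate lines must hold 'x y z'")
  }
  m <- matrix(vals, ncol = 3L, byrow = TRUE)
  coords <- array(NA_real_, dim = c(n_particles, 3L, n_frames))
  for (f in seq_len(n_frames)) {
    coords[, , f] <- m[((f - 1L) * n_particles + 1L):(f * n_particles), ]
  }
  frame_series(coords, box = hdr[4:6], dt = hdr[3], origin_format = "txt")
}

#' Write a FrameSeries in the plain-text multi-frame format
#'
#' The inverse of the `"txt"` branch of [read_frames()]; coordinates are
#' written with enough digits for a round trip well below 1e-4 nm.
#' @param frames a `FrameSeries`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_frames_txt <- function(frames, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%d %d %.10g %.10g %.10g %.10g",
                     frames$n_frames, frames$n_particles, frames$dt,
                     frames$box[1, 1], frames$box[1, 2], frames$box[1, 3]),
             con)
  for (f in seq_len(frames$n_frames)) {
    m <- frames$coords[, , f, drop = FALSE]
    writeLines(sprintf("%.8f %.8f %.8f", m[, 1, 1], m[, 2, 1], m[, 3, 1]),
               con)
  }
  invisible(path)
}

read_frames_gro <- function(path, dt) {
  lines <- readLines(path)
  frames <- list(); boxes <- list(); i <- 1L; n_ref <- NA_integer_
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i])) ) { i <- i + 1L; next }
    if (i + 1L > length(lines)) stop("format error in ", path,
                                     ": truncated GRO header at line ", i)
    natoms <- suppressWarnings(as.integer(trimws(lines[i + 1L])))
    if (is.na(natoms) || natoms < 1L) {
      stop("format error in ", path, " line ", i + 1L,
           ": expected atom count")
    }
    if (!is.na(n_ref) && natoms != n_ref) {
      stop("structural error in ", path, ": frame ", length(frames) + 1L,
           " has ", natoms, " particles, expected ", n_ref)
    }
    n_ref <- natoms
    atom_lines <- lines[(i + 2L):(i + 1L + natoms)]
    # fixed columns: positions occupy chars 21-44 in %8.3f fields
    x <- as.numeric(substr(atom_lines, 21, 28))
    y <- as.numeric(substr(atom_lines, 29, 36))
    z <- as.numeric(substr(atom_lines, 37, 44))
    if (anyNA(x) || anyNA(y) || anyNA(z)) {
      stop("format error in ", path, ": unparseable coordinates in frame ",
           length(frames) + 1L)
    }
    boxv <- suppressWarnings(as.numeric(
      strsplit(trimws(lines[i + 2L + natoms]), "\\s+")[[1]]))
    if (length(boxv) < 3L || anyNA(boxv[1:3])) {
      stop("format error in ", path, ": bad box line after frame ",
           length(frames) + 1L)
    }
    if (length(boxv) > 3L && any(abs(boxv[-(1:3)]) > 1e-9)) {
      stop("triclinic boxes are not supported")
    }
    frames[[length(frames) + 1L]] <- cbind(x, y, z)
    boxes[[length(boxes) + 1L]] <- boxv[1:3]
    i <- i + 3L + natoms
  }
  if (!length(frames)) stop("format error in ", path, ": no frames found")
  coords <- array(unlist(frames), dim = c(n_ref, 3L, length(frames)))
  frame_series(coords, box = do.call(rbind, boxes), dt = dt,
               origin_format = "gro")
}

read_frames_pdb <- function(path, dt) {
  lines <- readLines(path)
  rec <- substr(lines, 1, 6)
  cryst <- lines[startsWith(rec, "CRYST1")]
  box <- c(10, 10, 10)
  if (length(cryst)) {
    a <- as.numeric(substr(cryst[1], 7, 15))
    b <- as.numeric(substr(cryst[1], 16, 24))
    c_ <- as.numeric(substr(cryst[1], 25, 33))
    ang <- c(as.numeric(substr(cryst[1], 34, 40)),
             as.numeric(substr(cryst[1], 41, 47)),
             as.numeric(substr(cryst[1], 48, 54)))
    if (any(abs(ang - 90) > 1e-3)) stop("triclinic boxes are not supported")
    box <- c(a, b, c_) / 10  # Angstrom -> nm
  }
  is_atom <- rec == "ATOM  " | rec == "HETATM"
  model_id <- cumsum(startsWith(rec, "MODEL "))
  if (max(model_id) == 0L) model_id <- rep(1L, length(lines))
  model_of_atom <- model_id[is_atom]
  atom_lines <- lines[is_atom]
  if (!length(atom_lines)) stop("format error in ", path, ": no ATOM records")
  x <- as.numeric(substr(atom_lines, 31, 38)) / 10
  y <- as.numeric(substr(atom_lines, 39, 46)) / 10
  z <- as.numeric(substr(atom_lines, 47, 54)) / 10
  if (anyNA(x) || anyNA(y) || anyNA(z)) {
    stop("format error in ", path, ": unparseable ATOM coordinates")
  }
  counts <- table(model_of_atom)
  if (length(unique(as.integer(counts))) != 1L) {
    stop("structural error in ", path,
         ": particle count varies between MODEL records")
  }
  n_particles <- as.integer(counts[1])
  n_frames <- length(counts)
  coords <- array(NA_real_, dim = c(n_particles, 3L, n_frames))
  ids <- sort(unique(model_of_atom))
  for (f in seq_along(ids)) {
    sel <- model_of_atom == ids[f]
    coords[, , f] <- cbind(x[sel], y[sel], z[sel])
  }
  frame_series(coords, box = box, dt = dt, origin_format = "pdb")
}
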