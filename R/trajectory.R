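# Frames and snapshot ensembles.
#
# Coordinates are stored as an n x 3 x F array (Angstrom) with one
# orthorhombic box length triple per frame.  All frames of an ensemble share
# one topology, which is carried alongside rather than inside the ensemble.

#' Construct a single snapshot
#'
#' @param coordinates n x 3 numeric matrix (Angstrom)
#' @param box length-3 numeric, orthorhombic box lengths (Angstrom)
#' @return object of class `Frame`
#' @export
make_frame <- function(coordinates, box) {
  coordinates <- as.matrix(coordinates)
  if (ncol(coordinates) != 3) stop("coordinates must be n x 3")
  box <- as.numeric(box)
  if (length(box) != 3 || any(!is.finite(box)) || any(box <= 0))
    stop("box must be three positive lengths")
  structure(list(coordinates = coordinates, box = box), class = "Frame")
}

#' Construct a snapshot ensemble
#'
#' @param frames list of [make_frame()] frames (all with the same atom count)
#' @param state_label one of `native`, `extended`, `intermediate1..3`
#' @param replicate_id integer replicate index
#' @param ensemble_kind `"restrained_NPT"` (solute restrained, box may vary)
#'   or `"fixed_NVT"` (all solute atoms fixed, constant volume)
#' @param sampling_interval snapshot spacing in ps
#' @return object of class `TrajectoryEnsemble`
#' @export
make_ensemble <- function(frames, state_label = "native", replicate_id = 1L,
                          ensemble_kind = c("restrained_NPT", "fixed_NVT"),
                          sampling_interval = 2.0) {
  ensemble_kind <- match.arg(ensemble_kind)
  if (!state_label %in% c("native", "extended", "intermediate1",
                          "intermediate2", "intermediate3"))
    stop("unknown state label: ", state_label)
  if (length(frames) == 0) stop("ensemble has no frames")
  n <- nrow(frames[[1]]$coordinates)
  for (f in frames)
    if (nrow(f$coordinates) != n)
      stop("frames disagree on atom count")
  structure(list(
    frames = frames, state_label = state_label,
    replicate_id = as.integer(replicate_id), ensemble_kind = ensemble_kind,
    sampling_interval = sampling_interval
  ), class = "TrajectoryEnsemble")
}

#' @export
print.TrajectoryEnsemble <- function(x, ...) {
  cat(sprintf("TrajectoryEnsemble: state=%s replicate=%d kind=%s %d frames x %d atoms\n",
              x$state_label, x$replicate_id, x$ensemble_kind,
              length(x$frames), nrow(x$frames[[1]]$coordinates)))
  invisible(x)
}

#' Number of frames in an ensemble
#' @param ensemble a `TrajectoryEnsemble`
#' @return integer
#' @export
n_frames <- function(ensemble) length(ensemble$frames)

# ---------------------------------------------------------------------------
# Multi-frame XYZ.  The comment line of each frame carries the box:
#   <natoms>
#   box <Lx> <Ly> <Lz>
#   <element> <x> <y> <z>      (natoms lines)
# ---------------------------------------------------------------------------

#' Read a snapshot ensemble from file
#'
#' Supported formats: the package's multi-frame XYZ (box lengths on each
#' comment line), multi-model PDB, and DCD (via the `bio3d` reader).  XYZ
#' carries per-frame boxes; PDB and DCD inputs take the box from `box`
#' unless CRYST1 records are present.
#'
#' @param path file path
#' @param format `"xyz"`, `"pdb-multi"` or `"dcd"`
#' @param topology optional `Topology`; when given, the per-frame atom count
#'   is checked against it
#' @param box fallback box lengths for formats that do not carry one
#' @param ... passed to [make_ensemble()] (state label etc.)
#' @return a `TrajectoryEnsemble`
#' @export
read_frames <- function(path, format = c("xyz", "pdb-multi", "dcd"),
                        topology = NULL, box = NULL, ...) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("trajectory file not found: ", path)
  frames <- switch(format,
    xyz = .read_xyz_frames(path),
    "pdb-multi" = .read_pdb_frames(path, box),
    dcd = .read_dcd_frames(path, box)
  )
  if (!is.null(topology)) {
    n <- nrow(topology$atoms)
    for (f in frames)
      if (nrow(f$coordinates) != n)
        stop("frame atom count ", nrow(f$coordinates),
             " does not match topology (", n, " atoms)")
  }
  make_ensemble(frames, ...)
}

.read_xyz_frames <- function(path) {
  lines <- readLines(path)
  frames <- list()
  k <- 1L
  while (k <= length(lines)) {
    if (!nzchar(trimws(lines[k]))) { k <- k + 1L; next }
    nat <- suppressWarnings(as.integer(trimws(lines[k])))
    if (is.na(nat)) stop("malformed XYZ atom count at line ", k)
    if (k + 1L + nat > length(lines))
      stop("truncated XYZ file: frame starting at line ", k,
           " declares ", nat, " atoms but the file ends early")
    comment <- strsplit(trimws(lines[k + 1L]), "\\s+")[[1]]
    if (length(comment) < 4 || comment[1] != "box")
      stop("XYZ comment line ", k + 1L,
           " must be 'box Lx Ly Lz' (orthorhombic box lengths)")
    box <- as.numeric(comment[2:4])
    body <- lines[(k + 2L):(k + 1L + nat)]
    f <- strsplit(trimws(body), "\\s+")
    bad <- which(lengths(f) < 4)
    if (length(bad) > 0)
      stop("malformed XYZ coordinate line ", k + 1L + bad[1])
    coords <- matrix(as.numeric(unlist(lapply(f, `[`, 2:4))),
                     ncol = 3, byrow = TRUE)
    frames[[length(frames) + 1L]] <- make_frame(coords, box)
    k <- k + 2L + nat
  }
  if (length(frames) == 0) stop("no frames in XYZ file ", path)
  frames
}

.read_pdb_frames <- function(path, box) {
  lines <- readLines(path)
  cryst <- grep("^CRYST1", lines, value = TRUE)
  if (length(cryst) >= 1) {
    box <- as.numeric(c(substr(cryst[1], 7, 15), substr(cryst[1], 16, 24),
                        substr(cryst[1], 25, 33)))
  }
  if (is.null(box))
    stop("PDB input without CRYST1 record requires an explicit box")
  atom_lines <- grepl("^(ATOM  |HETATM)", lines)
  model_starts <- grep("^MODEL", lines)
  frames <- list()
  parse_block <- function(idx) {
    sel <- lines[idx]
    coords <- cbind(as.numeric(substr(sel, 31, 38)),
                    as.numeric(substr(sel, 39, 46)),
                    as.numeric(substr(sel, 47, 54)))
    make_frame(coords, box)
  }
  if (length(model_starts) == 0) {
    frames[[1]] <- parse_block(which(atom_lines))
  } else {
    model_ends <- grep("^ENDMDL", lines)
    if (length(model_ends) != length(model_starts))
      stop("truncated multi-model PDB: MODEL without matching ENDMDL")
    for (m in seq_along(model_starts)) {
      idx <- which(atom_lines &
                   seq_along(lines) > model_starts[m] &
                   seq_along(lines) < model_ends[m])
      frames[[m]] <- parse_block(idx)
    }
  }
  frames
}

.read_dcd_frames <- function(path, box) {
  if (!requireNamespace("bio3d", quietly = TRUE))
    stop("reading DCD requires the bio3d package")
  traj <- bio3d::read.dcd(path, verbose = FALSE, cell = FALSE)
  if (is.null(box))
    stop("DCD input requires an explicit box")
  lapply(seq_len(nrow(traj)), function(i)
    make_frame(matrix(traj[i, ], ncol = 3, byrow = TRUE), box))
}

#' Write a snapshot ensemble as multi-frame XYZ
#'
#' @param ensemble a `TrajectoryEnsemble`
#' @param topology a `Topology` supplying element symbols
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_frames_xyz <- function(ensemble, topology, path) {
  el <- topology$atoms$element
  con <- file(path, "w")
  on.exit(close(con))
  for (f in ensemble$frames) {
    writeLines(c(as.character(nrow(f$coordinates)),
                 sprintf("box %.10g %.10g %.10g",
                         f$box[1], f$box[2], f$box[3]),
                 sprintf("%s %.10f %.10f %.10f", el,
                         f$coordinates[, 1], f$coordinates[, 2],
                         f$coordinates[, 3])), con)
  }
  invisible(path)
}
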