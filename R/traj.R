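# Trajectory analytics over multi-model PDB: per-frame CA RMSD,
# per-residue RMSF, average structure, inter-residue distance series.
# RMSD/RMSF/averaging are computed after per-frame CA superposition
# onto the initial frame; distance series are superposition-free
# (distances are invariant to the frame).

#' Build a trajectory from a topology and per-frame coordinates
#'
#' @param topology A \code{\link{structure3d}} describing the atoms
#'   (coordinates of the first frame).
#' @param frames List of n_atoms x 3 coordinate matrices, one per
#'   frame; frame 1 must match the topology coordinates.
#' @param time_ps Numeric vector of frame times in picoseconds, or a
#'   single time step (default 1 ps per frame, starting at 0).
#' @return An object of class \code{"trajectory3d"}.
#' @export
trajectory3d <- function(topology, frames, time_ps = 1) {
  stopifnot(inherits(topology, "structure3d"), is.list(frames),
            length(frames) >= 1L)
  n_at <- nrow(topology$atoms)
  for (f in frames)
    if (!is.matrix(f) || nrow(f) != n_at || ncol(f) != 3 ||
        !all(is.finite(f)))
      stop("every frame must be a finite n_atoms x 3 matrix",
           call. = FALSE)
  if (length(time_ps) == 1L)
    time_ps <- (seq_along(frames) - 1) * time_ps
  stopifnot(length(time_ps) == length(frames))
  structure(list(topology = topology, frames = frames,
                 time_ps = as.numeric(time_ps)),
            class = "trajectory3d")
}

#' @export
print.trajectory3d <- function(x, ...) {
  cat(sprintf("<trajectory3d> %d frames x %d atoms, %.0f-%.0f ps\n",
              length(x$frames), nrow(x$topology$atoms),
              min(x$time_ps), max(x$time_ps)))
  invisible(x)
}

#' Build a trajectory from a list of structures
#' @param structures List of topology-identical
#'   \code{\link{structure3d}} objects (ordered frames).
#' @param time_ps As in \code{\link{trajectory3d}}.
#' @return A \code{trajectory3d}.
#' @export
as_trajectory <- function(structures, time_ps = 1) {
  stopifnot(is.list(structures), length(structures) >= 1L)
  topo <- structures[[1]]
  key0 <- paste(topo$atoms$chain, topo$atoms$resno, topo$atoms$elety)
  frames <- lapply(structures, function(s) {
    key <- paste(s$atoms$chain, s$atoms$resno, s$atoms$elety)
    if (!identical(key, key0))
      stop("frames differ in topology", call. = FALSE)
    as.matrix(s$atoms[, c("x", "y", "z")])
  })
  trajectory3d(topo, frames, time_ps)
}

#' Read a multi-model PDB trajectory
#'
#' @param file Path to a PDB file with MODEL/ENDMDL blocks.
#' @param time_ps Frame times (vector) or time step (scalar, ps).
#' @return A \code{\link{trajectory3d}}.
#' @export
read_trajectory <- function(file, time_ps = 1) {
  lines <- readLines(file, warn = FALSE)
  if (!any(grepl("^MODEL ", lines)))
    stop("no MODEL records: use read_structure() for single structures",
         call. = FALSE)
  prescan_pdb_lines(lines)
  pdb <- suppressWarnings(bio3d::read.pdb(file, multi = TRUE,
                                          rm.alt = TRUE, verbose = FALSE))
  df <- bio3d_atoms_to_df(pdb$atom)
  n_at <- nrow(df)
  xyz <- pdb$xyz
  frames <- lapply(seq_len(nrow(xyz)), function(i)
    matrix(xyz[i, ], ncol = 3, byrow = TRUE))
  topo <- df[, setdiff(names(df), "alt")]
  topo$x <- frames[[1]][, 1]; topo$y <- frames[[1]][, 2]
  topo$z <- frames[[1]][, 3]
  trajectory3d(structure3d(topo, id = sub("\\.pdb$", "", basename(file))),
               frames, time_ps)
}

#' Write a trajectory as multi-model PDB
#' @param traj A \code{\link{trajectory3d}}.
#' @param file Output path.
#' @export
write_trajectory <- function(traj, file) {
  s <- traj$topology
  out <- character(0)
  for (i in seq_along(traj$frames)) {
    s$atoms$x <- traj$frames[[i]][, 1]
    s$atoms$y <- traj$frames[[i]][, 2]
    s$atoms$z <- traj$frames[[i]][, 3]
    out <- c(out, sprintf("MODEL     %4d", i), structure_pdb_lines(s),
             "ENDMDL")
  }
  writeLines(c(out, "END"), file)
  invisible(file)
}

ca_index <- function(traj) {
  idx <- which(traj$topology$atoms$elety == "CA")
  if (length(idx) < 3L)
    stop("trajectory topology has fewer than 3 CA atoms", call. = FALSE)
  idx
}

# Superpose each frame onto the reference frame using CA atoms; returns
# the list of fitted full-coordinate frames.
superpose_frames <- function(traj) {
  idx <- ca_index(traj)
  ref <- traj$frames[[1]][idx, , drop = FALSE]
  lapply(seq_along(traj$frames), function(i) {
    f <- traj$frames[[i]]
    fit <- kabsch_fit(f[idx, , drop = FALSE], ref)
    sweep(f %*% fit$rotation, 2, fit$translation, "+")
  })
}

#' Per-frame CA RMSD series against the initial frame
#'
#' Each frame is rigidly superposed (Kabsch on CA) onto the first frame
#' before the RMSD over CA atoms is computed; the first value is 0 by
#' definition.
#'
#' @param traj A \code{\link{trajectory3d}}.
#' @return Numeric vector (Angstrom), one value per frame, with the
#'   frame times as names source via \code{attr(,"time_ps")}.
#' @export
ca_rmsd_series <- function(traj) {
  stopifnot(inherits(traj, "trajectory3d"))
  idx <- ca_index(traj)
  ref <- traj$frames[[1]][idx, , drop = FALSE]
  out <- vapply(seq_along(traj$frames), function(i) {
    if (i == 1L) return(0)
    kabsch_fit(traj$frames[[i]][idx, , drop = FALSE], ref)$rmsd
  }, 0)
  attr(out, "time_ps") <- traj$time_ps
  out
}

#' Per-residue CA fluctuation across a trajectory
#'
#' After superposing every frame onto the initial frame, each residue's
#' value is the root-mean-square deviation of its CA position from the
#' initial position across all frames — the per-residue "averaged
#' movement from the initial structure".
#'
#' @param traj A \code{\link{trajectory3d}} with at least two frames.
#' @return Named numeric vector (Angstrom), names = residue numbers.
#' @export
per_residue_rmsf <- function(traj) {
  stopifnot(inherits(traj, "trajectory3d"))
  if (length(traj$frames) < 2L)
    stop("RMSF needs at least two frames", call. = FALSE)
  idx <- ca_index(traj)
  fitted <- superpose_frames(traj)
  ref <- traj$frames[[1]][idx, , drop = FALSE]
  dev2 <- matrix(0, nrow = length(idx), ncol = length(fitted))
  for (i in seq_along(fitted))
    dev2[, i] <- rowSums((fitted[[i]][idx, , drop = FALSE] - ref)^2)
  out <- sqrt(rowMeans(dev2))
  names(out) <- traj$topology$atoms$resno[idx]
  out
}

#' Average structure over a trajectory
#'
#' Per-atom arithmetic mean of the coordinates after superposing every
#' frame onto the initial frame.
#'
#' @param traj A \code{\link{trajectory3d}}.
#' @return A \code{\link{structure3d}} with the averaged coordinates.
#' @export
average_structure <- function(traj) {
  stopifnot(inherits(traj, "trajectory3d"))
  fitted <- superpose_frames(traj)
  acc <- Reduce(`+`, fitted) / length(fitted)
  s <- traj$topology
  s$atoms$x <- acc[, 1]; s$atoms$y <- acc[, 2]; s$atoms$z <- acc[, 3]
  s$id <- paste0(s$id, "_avg")
  s
}

#' Inter-residue CA distance series
#'
#' Per-frame Euclidean distance between the CA atoms of two residues,
#' without superposition.
#'
#' @param traj A \code{\link{trajectory3d}}.
#' @param res_a,res_b Residue numbers.
#' @param chain Chain identifier (default: first chain).
#' @param elety Atom name (default \code{"CA"}).
#' @return Numeric vector (Angstrom) with \code{attr(,"time_ps")}.
#' @export
residue_distance_series <- function(traj, res_a, res_b, chain = NULL,
                                    elety = "CA") {
  stopifnot(inherits(traj, "trajectory3d"))
  a <- traj$topology$atoms
  if (is.null(chain)) chain <- a$chain[1]
  ia <- which(a$chain == chain & a$resno == res_a & a$elety == elety)
  ib <- which(a$chain == chain & a$resno == res_b & a$elety == elety)
  if (length(ia) != 1L || length(ib) != 1L)
    stop("residue ", if (length(ia) != 1L) res_a else res_b,
         " (", elety, ", chain ", chain, ") not found exactly once",
         call. = FALSE)
  out <- vapply(traj$frames, function(f)
    sqrt(sum((f[ia, ] - f[ib, ])^2)), 0)
  attr(out, "time_ps") <- traj$time_ps
  out
}

#' Write a per-frame series as TSV
#' @param series Numeric vector with \code{attr(,"time_ps")} (as
#'   returned by \code{\link{ca_rmsd_series}} or
#'   \code{\link{residue_distance_series}}).
#' @param path Output path.
#' @param value_name Column name for the values.
#' @export
write_series_tsv <- function(series, path, value_name = "value_A") {
  t_ps <- attr(series, "time_ps")
  if (is.null(t_ps)) t_ps <- seq_along(series) - 1
  df <- data.frame(time_ps = t_ps, value = as.numeric(series))
  names(df)[2] <- value_name
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
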