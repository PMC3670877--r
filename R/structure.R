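# A light atom-table container for single structures, read through
# bio3d with a fixed-width pre-scan for line-numbered diagnostics.
# Coordinates are in Angstrom, residue numbers 1-based, chain "A" by
# default.

#' Build a structure from an atom table
#'
#' @param atoms Data frame with columns \code{type} (ATOM/HETATM),
#'   \code{eleno}, \code{elety} (atom name), \code{resid} (3-letter
#'   residue name), \code{chain}, \code{resno}, \code{x}, \code{y},
#'   \code{z}, and optionally \code{o}, \code{b}, \code{elesy}
#'   (element), \code{charge}.
#' @param id Structure identifier.
#' @return An object of class \code{"structure3d"}.
#' @export
structure3d <- function(atoms, id = "structure") {
  need <- c("elety", "resid", "chain", "resno", "x", "y", "z")
  stopifnot(is.data.frame(atoms), all(need %in% names(atoms)))
  if (nrow(atoms) == 0L) stop("structure has no atoms", call. = FALSE)
  if (is.null(atoms$type)) atoms$type <- "ATOM"
  if (is.null(atoms$eleno)) atoms$eleno <- seq_len(nrow(atoms))
  if (is.null(atoms$o)) atoms$o <- 1
  if (is.null(atoms$b)) atoms$b <- 0
  if (is.null(atoms$elesy)) atoms$elesy <- guess_element(atoms$elety)
  if (is.null(atoms$charge)) atoms$charge <- 0
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  if (!all(is.finite(xyz)))
    stop("non-finite coordinates in structure '", id, "'", call. = FALSE)
  key <- paste(atoms$chain, atoms$resno, atoms$elety)
  if (anyDuplicated(key))
    stop("duplicate (chain, resno, atom name) in structure '", id, "'",
         call. = FALSE)
  rownames(atoms) <- NULL
  structure(list(id = id, atoms = atoms), class = "structure3d")
}

#' @export
print.structure3d <- function(x, ...) {
  cat(sprintf("<structure3d> %s: %d atoms, %d residues, chains [%s]\n",
              x$id, nrow(x$atoms),
              length(unique(paste(x$atoms$chain, x$atoms$resno))),
              paste(unique(x$atoms$chain), collapse = ",")))
  invisible(x)
}

guess_element <- function(elety) {
  e <- toupper(sub("^[0-9]*", "", elety))
  first <- substr(e, 1, 1)
  ifelse(substr(e, 1, 2) %in% c("CL", "BR", "NA", "MG", "ZN", "FE"),
         substr(e, 1, 2), first)
}

#' Extract the coordinate matrix of a structure
#' @param s A \code{structure3d}.
#' @param elety Optional atom-name filter (e.g. \code{"CA"}).
#' @param heavy_only Drop hydrogens.
#' @return Numeric n x 3 matrix.
#' @export
coords <- function(s, elety = NULL, heavy_only = FALSE) {
  a <- s$atoms
  keep <- rep(TRUE, nrow(a))
  if (!is.null(elety)) keep <- keep & a$elety %in% elety
  if (heavy_only) keep <- keep & a$elesy != "H"
  as.matrix(a[keep, c("x", "y", "z")])
}

# Fixed-width pre-scan: report the first malformed ATOM/HETATM record
# with its line number before handing the file to bio3d (which is
# lenient and would silently drop it).
prescan_pdb_lines <- function(lines) {
  rec <- grepl("^(ATOM  |HETATM)", lines)
  for (i in which(rec)) {
    ln <- lines[i]
    if (nchar(ln) < 54)
      stop("PDB parse error at line ", i, ": record shorter than 54 columns",
           call. = FALSE)
    for (fld in list(c(31, 38), c(39, 46), c(47, 54))) {
      v <- suppressWarnings(as.numeric(substr(ln, fld[1], fld[2])))
      if (is.na(v))
        stop("PDB parse error at line ", i, ": non-numeric coordinate field",
             call. = FALSE)
    }
  }
  invisible(TRUE)
}

bio3d_atoms_to_df <- function(atom) {
  data.frame(type = atom$type, eleno = atom$eleno, elety = atom$elety,
             alt = ifelse(is.na(atom$alt), "", atom$alt),
             resid = atom$resid, chain = ifelse(is.na(atom$chain), "A",
                                                atom$chain),
             resno = atom$resno,
             x = atom$x, y = atom$y, z = atom$z,
             o = ifelse(is.na(atom$o), 1, atom$o),
             b = ifelse(is.na(atom$b), 0, atom$b),
             elesy = ifelse(is.na(atom$elesy) | atom$elesy == "",
                            guess_element(atom$elety), atom$elesy),
             charge = 0, stringsAsFactors = FALSE)
}

# Keep, per (chain, resno, atom name), the altloc with the highest
# occupancy; first occurrence wins ties.
select_altloc <- function(df) {
  key <- paste(df$chain, df$resno, df$elety)
  ord <- order(key, -df$o, seq_len(nrow(df)))
  df <- df[ord, ]
  df <- df[!duplicated(paste(df$chain, df$resno, df$elety)), ]
  df[order(df$eleno), setdiff(names(df), "alt")]
}

#' Read a single-model structure from PDB
#'
#' Standard ATOM/HETATM records; when alternate locations are present
#' only the highest-occupancy altloc of each atom is kept.  Files with
#' MODEL records are rejected here — use \code{\link{read_trajectory}}
#' for multi-model files.
#'
#' @param file Path to a PDB file, or \code{NULL} when \code{text} is
#'   given.
#' @param text Character scalar or vector of PDB lines (alternative to
#'   \code{file}).
#' @param id Structure identifier (defaults to the file name).
#' @return A \code{\link{structure3d}}.
#' @export
read_structure <- function(file = NULL, text = NULL, id = NULL) {
  if (is.null(file) && is.null(text))
    stop("either file or text is required", call. = FALSE)
  if (is.null(file)) {
    lines <- unlist(strsplit(text, "\n", fixed = TRUE))
    file <- tempfile(fileext = ".pdb")
    on.exit(unlink(file), add = TRUE)
    writeLines(lines, file)
    if (is.null(id)) id <- "structure"
  } else {
    lines <- readLines(file, warn = FALSE)
    if (is.null(id)) id <- sub("\\.pdb$", "", basename(file))
  }
  if (any(grepl("^MODEL ", lines)))
    stop("multi-model PDB: use read_trajectory()", call. = FALSE)
  prescan_pdb_lines(lines)
  pdb <- suppressWarnings(bio3d::read.pdb(file, rm.alt = FALSE,
                                          verbose = FALSE))
  df <- bio3d_atoms_to_df(pdb$atom)
  structure3d(select_altloc(df), id = id)
}

format_pdb_atom <- function(type, eleno, elety, resid, chain, resno,
                            x, y, z, o, b, elesy) {
  name <- ifelse(nchar(elety) < 4, paste0(" ", elety), elety)
  sprintf("%-6s%5d %-4s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          type, eleno %% 100000L, substr(name, 1, 4), resid, chain, resno,
          x, y, z, o, b, elesy)
}

structure_pdb_lines <- function(s) {
  a <- s$atoms
  format_pdb_atom(a$type, a$eleno, a$elety, a$resid, a$chain, a$resno,
                  a$x, a$y, a$z, a$o, a$b, a$elesy)
}

#' Write a structure as PDB
#' @param s A \code{\link{structure3d}}.
#' @param file Output path.
#' @export
write_structure <- function(s, file) {
  stopifnot(inherits(s, "structure3d"))
  writeLines(c(structure_pdb_lines(s), "END"), file)
  invisible(file)
}

#' Apply a rigid transform to a structure
#'
#' Coordinates are treated as row vectors: \code{x' = x R + t}.
#' @param s A \code{\link{structure3d}}.
#' @param rotation 3x3 rotation matrix.
#' @param translation Length-3 vector (Angstrom).
#' @return The transformed \code{structure3d}.
#' @export
transform_structure <- function(s, rotation = diag(3),
                                translation = c(0, 0, 0)) {
  xyz <- as.matrix(s$atoms[, c("x", "y", "z")]) %*% rotation
  xyz <- sweep(xyz, 2, translation, "+")
  s$atoms$x <- xyz[, 1]; s$atoms$y <- xyz[, 2]; s$atoms$z <- xyz[, 3]
  s
}
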