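# Sequence records, family alignments, pairwise/multiple alignment and
# percent identity.  Pairwise global alignment (Needleman-Wunsch with
# affine gaps) is delegated to Biostrings; the multiple aligner is a
# center-star progressive merge built on those pairwise alignments.

AA_LETTERS <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Create a protein sequence record
#'
#' A minimal container for one protein sequence: an identifier, an
#' optional species tag, and the residues as a string over the twenty
#' canonical amino-acid letters.  Non-canonical letters (including the
#' ambiguity code \code{X}) are rejected, since the downstream
#' residue-class consensus scheme is only defined over the canonical
#' alphabet.
#'
#' @param id Character scalar, sequence identifier (e.g. a UniProt
#'   accession such as \code{"P30556"}).
#' @param residues Character scalar, the amino-acid sequence.
#' @param species Character scalar, species label (optional).
#' @return An object of class \code{"sequence_record"}.
#' @examples
#' sequence_record("toy", "MKTAYIAK", species = "human")
#' @export
sequence_record <- function(id, residues, species = "") {
  stopifnot(is.character(id), length(id) == 1L,
            is.character(residues), length(residues) == 1L)
  residues <- toupper(residues)
  if (nchar(residues) == 0L)
    stop("sequence '", id, "': residues must be non-empty", call. = FALSE)
  bad <- setdiff(unique(strsplit(residues, "")[[1]]), AA_LETTERS)
  if (length(bad) > 0L)
    stop("sequence '", id, "': non-canonical letters: ",
         paste(bad, collapse = ", "), call. = FALSE)
  structure(list(id = id, species = species, residues = residues),
            class = "sequence_record")
}

#' @export
print.sequence_record <- function(x, ...) {
  cat(sprintf("<sequence_record> %s (%s), %d aa\n", x$id,
              if (nzchar(x$species)) x$species else "?", nchar(x$residues)))
  invisible(x)
}

strip_gaps <- function(s) gsub("-", "", s, fixed = TRUE)

#' Create a family alignment
#'
#' An ordered multiple alignment of one receptor family: each member is
#' a \code{\link{sequence_record}} plus its gapped aligned string.  All
#' aligned strings must have the same length and stripping gaps must
#' recover each member's residues exactly.
#'
#' @param family_id Character scalar, e.g. \code{"AT1"}.
#' @param records List of \code{sequence_record}s (at least 2).
#' @param aligned Character vector of gapped strings, parallel to
#'   \code{records}.
#' @return An object of class \code{"family_alignment"} with elements
#'   \code{family_id}, \code{records}, \code{aligned}.
#' @export
family_alignment <- function(family_id, records, aligned) {
  stopifnot(is.list(records), is.character(aligned),
            length(records) == length(aligned))
  if (length(records) < 2L)
    stop("a family alignment needs at least 2 members", call. = FALSE)
  widths <- nchar(aligned)
  if (length(unique(widths)) != 1L || widths[1] < 1L)
    stop("aligned strings must all have the same non-zero length",
         call. = FALSE)
  for (i in seq_along(records)) {
    r <- records[[i]]
    if (!inherits(r, "sequence_record"))
      stop("records[[", i, "]] is not a sequence_record", call. = FALSE)
    if (!identical(strip_gaps(aligned[i]), r$residues))
      stop("member '", r$id,
           "': stripping gaps does not recover the input residues",
           call. = FALSE)
  }
  structure(list(family_id = family_id, records = records,
                 aligned = toupper(aligned)),
            class = "family_alignment")
}

#' @export
print.family_alignment <- function(x, ...) {
  cat(sprintf("<family_alignment> %s: %d members x %d columns\n",
              x$family_id, length(x$records), nchar(x$aligned[1])))
  invisible(x)
}

aln_width <- function(aln) nchar(aln$aligned[1])

aln_matrix <- function(aln) {
  do.call(rbind, strsplit(aln$aligned, ""))
}

resolve_submat <- function(matrix_name) {
  if (is.matrix(matrix_name)) return(matrix_name)
  e <- new.env()
  utils::data(list = matrix_name, package = "Biostrings", envir = e)
  get(matrix_name, envir = e)
}

#' Global pairwise alignment of two protein sequences
#'
#' Needleman-Wunsch global alignment with affine gap penalties, a
#' stand-in for the original ClustalW pairwise step.  A gap of length L
#' costs \code{gap_open + L * gap_extend}.  Defaults follow the ClustalW
#' protein defaults (BLOSUM62, open 10, extend 0.5).
#'
#' @param a,b \code{\link{sequence_record}} objects.
#' @param matrix Substitution matrix: a name known to Biostrings
#'   (e.g. \code{"BLOSUM62"}) or a numeric matrix.
#' @param gap_open,gap_extend Affine gap penalties (positive numbers).
#' @return A 2-member \code{\link{family_alignment}} with attribute
#'   \code{"score"}, the optimal alignment score.
#' @examples
#' a <- sequence_record("a", "HEAGAWGHEE")
#' b <- sequence_record("b", "PAWHEAE")
#' aln <- pairwise_global_align(a, b)
#' attr(aln, "score")
#' @export
pairwise_global_align <- function(a, b, matrix = "BLOSUM62",
                                  gap_open = 10, gap_extend = 0.5) {
  stopifnot(inherits(a, "sequence_record"), inherits(b, "sequence_record"))
  submat <- resolve_submat(matrix)
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a$residues), Biostrings::AAString(b$residues),
    substitutionMatrix = submat, gapOpening = gap_open,
    gapExtension = gap_extend, type = "global")
  out <- family_alignment(
    paste(a$id, b$id, sep = "|"), list(a, b),
    c(as.character(Biostrings::alignedPattern(pa)),
      as.character(Biostrings::alignedSubject(pa))))
  attr(out, "score") <- Biostrings::score(pa)
  out
}

#' Percent identity of a two-member alignment
#'
#' Counts columns where both members carry a residue (columns with a gap
#' in either member are excluded from the denominator) and reports the
#' fraction of those columns with identical letters, as a percentage.
#' This is the conventional reading of a pairwise "% sequence homology"
#' figure.
#'
#' @param aln A \code{\link{family_alignment}} with exactly two members.
#' @return A list of class \code{"identity_result"} with
#'   \code{identical_pairs}, \code{compared_columns}, \code{percent}.
#' @export
percent_identity <- function(aln) {
  stopifnot(inherits(aln, "family_alignment"))
  if (length(aln$records) != 2L)
    stop("percent_identity needs an alignment with exactly two members",
         call. = FALSE)
  x <- strsplit(aln$aligned[1], "")[[1]]
  y <- strsplit(aln$aligned[2], "")[[1]]
  both <- x != "-" & y != "-"
  compared <- sum(both)
  if (compared == 0L)
    stop("no columns where both members have a residue", call. = FALSE)
  ident <- sum(x[both] == y[both])
  structure(list(identical_pairs = ident, compared_columns = compared,
                 percent = 100 * ident / compared),
            class = "identity_result")
}

#' @export
print.identity_result <- function(x, ...) {
  cat(sprintf("%d / %d identical columns = %.2f%%\n",
              x$identical_pairs, x$compared_columns, x$percent))
  invisible(x)
}

# Merge one pairwise alignment (center_pair, seq_pair: gapped strings of
# the center and the new member) into the master alignment (list of
# gapped strings; element 1 is the center).  "Once a gap, always a gap":
# gaps already in the master center are kept, gaps the new pairwise puts
# into the center are inserted into every master row.
merge_into_master <- function(master, center_pair, seq_pair) {
  mc <- strsplit(master[[1]], "")[[1]]
  pc <- strsplit(center_pair, "")[[1]]
  ps <- strsplit(seq_pair, "")[[1]]
  rows <- lapply(master, function(s) strsplit(s, "")[[1]])
  out_rows <- vector("list", length(rows))
  for (k in seq_along(out_rows)) out_rows[[k]] <- character(0)
  out_new <- character(0)
  i <- 1L; j <- 1L
  n_m <- length(mc); n_p <- length(pc)
  while (i <= n_m || j <= n_p) {
    if (i <= n_m && mc[i] == "-") {
      # gap introduced by an earlier merge; new member gets a gap too
      for (k in seq_along(rows)) out_rows[[k]] <- c(out_rows[[k]], rows[[k]][i])
      out_new <- c(out_new, "-")
      i <- i + 1L
    } else if (j <= n_p && pc[j] == "-") {
      # this pairwise alignment gaps the center: insert a gap column
      for (k in seq_along(rows)) out_rows[[k]] <- c(out_rows[[k]], "-")
      out_new <- c(out_new, ps[j])
      j <- j + 1L
    } else if (i <= n_m && j <= n_p) {
      # both carry the same center residue
      for (k in seq_along(rows)) out_rows[[k]] <- c(out_rows[[k]], rows[[k]][i])
      out_new <- c(out_new, ps[j])
      i <- i + 1L; j <- j + 1L
    } else {
      stop("internal error: inconsistent center sequences in merge")
    }
  }
  c(lapply(out_rows, paste, collapse = ""), list(paste(out_new, collapse = "")))
}

#' Build a multiple alignment by center-star merging
#'
#' A small-family progressive stand-in for ClustalW: the center is the
#' sequence maximizing summed pairwise percent identity against all
#' others; every other member is aligned pairwise to the center and the
#' pairwise gap patterns are merged ("once a gap, always a gap").
#'
#' @param records List of at least two \code{\link{sequence_record}}s.
#' @param family_id Family label for the result.
#' @inheritParams pairwise_global_align
#' @return A \code{\link{family_alignment}} whose member order is the
#'   input order.
#' @export
build_msa <- function(records, family_id = "family", matrix = "BLOSUM62",
                      gap_open = 10, gap_extend = 0.5) {
  if (!is.list(records) || length(records) < 2L)
    stop("build_msa needs at least 2 sequences", call. = FALSE)
  n <- length(records)
  if (n == 2L) {
    aln <- pairwise_global_align(records[[1]], records[[2]], matrix,
                                 gap_open, gap_extend)
    return(family_alignment(family_id, records, aln$aligned))
  }
  # pick the center: maximize summed pairwise identity
  pairs <- vector("list", n * n)
  dim(pairs) <- c(n, n)
  idsum <- numeric(n)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    aln <- pairwise_global_align(records[[i]], records[[j]], matrix,
                                 gap_open, gap_extend)
    pid <- percent_identity(aln)$percent
    idsum[i] <- idsum[i] + pid
    idsum[j] <- idsum[j] + pid
    pairs[[i, j]] <- aln
  }
  center <- which.max(idsum)
  others <- setdiff(seq_len(n), center)
  master <- list(records[[center]]$residues)  # center, ungapped to start
  order_added <- center
  for (o in others) {
    aln <- if (center < o) pairs[[center, o]] else pairs[[o, center]]
    if (center < o) {
      cp <- aln$aligned[1]; sp <- aln$aligned[2]
    } else {
      cp <- aln$aligned[2]; sp <- aln$aligned[1]
    }
    master <- merge_into_master(master, cp, sp)
    order_added <- c(order_added, o)
  }
  aligned <- character(n)
  aligned[order_added] <- unlist(master)
  family_alignment(family_id, records, aligned)
}

## ---- file formats -------------------------------------------------------

#' Read protein sequences from a FASTA file
#'
#' @param path Path to a FASTA file.
#' @param species Optional character vector of species labels, recycled.
#' @return A list of \code{\link{sequence_record}}s.
#' @export
read_fasta <- function(path, species = "") {
  ss <- Biostrings::readAAStringSet(path)
  ids <- sub("\\s.*$", "", names(ss))
  species <- rep_len(species, length(ss))
  out <- vector("list", length(ss))
  for (i in seq_along(ss))
    out[[i]] <- sequence_record(ids[i], as.character(ss[[i]]), species[i])
  out
}

#' Write sequence records to a FASTA file
#' @param records List of \code{sequence_record}s.
#' @param path Output path.
#' @export
write_fasta <- function(records, path) {
  ss <- Biostrings::AAStringSet(vapply(records, `[[`, "", "residues"))
  names(ss) <- vapply(records, `[[`, "", "id")
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Read an externally produced alignment
#'
#' Accepts Clustal (\code{.aln}) or aligned ("gapped") FASTA, so that
#' alignments computed elsewhere can bypass the built-in center-star
#' aligner.
#'
#' @param path Path to the alignment file.
#' @param format \code{"clustal"} or \code{"fasta"}.
#' @param family_id Family label.
#' @return A \code{\link{family_alignment}}.
#' @export
read_alignment <- function(path, format = c("fasta", "clustal"),
                           family_id = "family") {
  format <- match.arg(format)
  ma <- Biostrings::readAAMultipleAlignment(path, format = format)
  ss <- as.character(ma)
  ids <- sub("\\s.*$", "", names(ss))
  records <- mapply(function(id, s) sequence_record(id, strip_gaps(s)),
                    ids, ss, SIMPLIFY = FALSE, USE.NAMES = FALSE)
  family_alignment(family_id, records, unname(ss))
}

#' Write a family alignment as aligned FASTA
#' @param aln A \code{\link{family_alignment}}.
#' @param path Output path.
#' @export
write_aligned_fasta <- function(aln, path) {
  ss <- Biostrings::AAStringSet(aln$aligned)
  names(ss) <- vapply(aln$records, `[[`, "", "id")
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}
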