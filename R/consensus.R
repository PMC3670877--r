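# Per-column consensus symbols over a residue-class scheme.
#
# A column that is 100% identical is annotated with that letter; a
# column whose residues all fall inside one physicochemical class is
# annotated with the class symbol; anything else (including any column
# containing a gap) is "." for no conservation.

#' The residue-class scheme used for consensus annotation
#'
#' Five residue classes with one symbol each: hydrophobic
#' \eqn{\alpha} = \{A,V,L,I,F,W,M,P\}, polar acidic \eqn{\beta} =
#' \{D,E\}, polar basic \eqn{\mu} = \{K,R,H\}, aromatic \eqn{\pi} =
#' \{F,W,H,Y\}, and hydroxyl \eqn{\infty} = \{S,T\}.  H is deliberately
#' a member of both the basic and the aromatic class, and F/W of both
#' the hydrophobic and the aromatic class; the classes overlap and a
#' precedence order decides which symbol is reported when a column
#' satisfies several classes (most specific first):
#' \eqn{\beta > \mu > \infty > \pi > \alpha}.
#'
#' @param precedence Character vector giving the class evaluation
#'   order; must be a permutation of the five class names.
#' @return A list of class \code{"residue_class_scheme"} with elements
#'   \code{classes} (named list of letter sets), \code{symbols} (named
#'   character vector of class symbols) and \code{precedence}.
#' @examples
#' residue_class_scheme()$symbols
#' @export
residue_class_scheme <- function(precedence = c("acidic", "basic",
                                                "hydroxyl", "aromatic",
                                                "hydrophobic")) {
  classes <- list(
    hydrophobic = c("A", "V", "L", "I", "F", "W", "M", "P"),
    acidic      = c("D", "E"),
    basic       = c("K", "R", "H"),
    aromatic    = c("F", "W", "H", "Y"),
    hydroxyl    = c("S", "T"))
  symbols <- c(hydrophobic = "\u03b1", acidic = "\u03b2",
               basic = "\u00b5", aromatic = "\u03c0",
               hydroxyl = "\u221e")
  if (!setequal(precedence, names(classes)) ||
      length(precedence) != length(classes))
    stop("precedence must be a permutation of: ",
         paste(names(classes), collapse = ", "), call. = FALSE)
  structure(list(classes = classes, symbols = symbols,
                 precedence = precedence, no_conservation = "."),
            class = "residue_class_scheme")
}

#' Classify one alignment column into a consensus symbol
#'
#' @param residues Character vector of single letters (and \code{"-"}
#'   for gaps), the column contents; treated as a multiset, so member
#'   order is irrelevant.
#' @param scheme A \code{\link{residue_class_scheme}}.
#' @return A single character: a letter when the column is 100%
#'   identical, a class symbol when all residues share that class, or
#'   \code{"."}.  Any gap in the column yields \code{"."}.
#' @examples
#' sch <- residue_class_scheme()
#' classify_column(c("D", "E", "D", "D"), sch)  # beta
#' classify_column(c("K", "R"), sch)            # mu
#' classify_column(c("D", "K"), sch)            # "."
#' @export
classify_column <- function(residues, scheme = residue_class_scheme()) {
  if (length(residues) == 0L)
    stop("empty alignment column", call. = FALSE)
  if (any(residues == "-")) return(scheme$no_conservation)
  u <- unique(residues)
  if (length(u) == 1L) return(u)
  for (cl in scheme$precedence) {
    if (all(u %in% scheme$classes[[cl]])) return(scheme$symbols[[cl]])
  }
  scheme$no_conservation
}

#' Consensus symbol sequence of a family alignment
#'
#' Applies \code{\link{classify_column}} to every column.
#'
#' @param aln A \code{\link{family_alignment}}.
#' @param scheme A \code{\link{residue_class_scheme}}.
#' @return A list of class \code{"consensus_sequence"} with
#'   \code{family_id} and \code{symbols} (single string, one symbol per
#'   alignment column).
#' @export
consensus_sequence <- function(aln, scheme = residue_class_scheme()) {
  stopifnot(inherits(aln, "family_alignment"))
  m <- aln_matrix(aln)
  syms <- vapply(seq_len(ncol(m)),
                 function(j) classify_column(m[, j], scheme), "")
  structure(list(family_id = aln$family_id,
                 symbols = paste(syms, collapse = "")),
            class = "consensus_sequence")
}

#' @export
print.consensus_sequence <- function(x, ...) {
  cat(sprintf("<consensus_sequence> %s (%d columns)\n%s\n", x$family_id,
              nchar(x$symbols), x$symbols))
  invisible(x)
}

#' Write a per-column consensus table as TSV
#'
#' One row per alignment column: column index, the residues of each
#' member, and the consensus symbol.
#'
#' @param aln A \code{\link{family_alignment}}.
#' @param cons Its \code{\link{consensus_sequence}} (recomputed when
#'   missing).
#' @param path Output TSV path.
#' @param scheme Scheme used when recomputing.
#' @export
write_consensus_tsv <- function(aln, path, cons = NULL,
                                scheme = residue_class_scheme()) {
  if (is.null(cons)) cons <- consensus_sequence(aln, scheme)
  m <- aln_matrix(aln)
  df <- data.frame(column = seq_len(ncol(m)),
                   t(m), symbol = strsplit(cons$symbols, "")[[1]],
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[2:(1 + nrow(m))] <- vapply(aln$records, `[[`, "", "id")
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
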