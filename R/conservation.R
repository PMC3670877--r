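# Helix-based consensus numbering and cross-family conservation
# classification.
#
# Consensus numbers label transmembrane positions as 100*helix + offset
# within the helix (101 = first residue of helix 1), so that equivalent
# positions can be compared across receptors whose native numbering
# differs.  Loop residues carry no consensus number.

#' Create a helix-boundary annotation for one receptor
#'
#' @param receptor_id Character scalar.
#' @param helices Data frame with columns \code{helix} (1..7),
#'   \code{start}, \code{end} (1-based receptor residue numbers,
#'   inclusive).  Exactly seven helices, ascending, non-overlapping.
#' @return An object of class \code{"helix_annotation"}.
#' @export
helix_annotation <- function(receptor_id, helices) {
  stopifnot(is.data.frame(helices),
            all(c("helix", "start", "end") %in% names(helices)))
  helices <- helices[order(helices$helix), c("helix", "start", "end")]
  if (nrow(helices) != 7L || !identical(as.integer(helices$helix), 1:7))
    stop("expected exactly seven helices numbered 1..7", call. = FALSE)
  if (any(helices$start > helices$end))
    stop("helix start must be <= end", call. = FALSE)
  if (any(helices$end - helices$start + 1L > 99L))
    stop("a helix longer than 99 residues cannot be consensus-numbered",
         call. = FALSE)
  if (any(helices$start[-1] <= helices$end[-7]))
    stop("helix residue ranges overlap or are out of order", call. = FALSE)
  structure(list(receptor_id = receptor_id, helices = helices),
            class = "helix_annotation")
}

#' Read a helix annotation from TSV
#'
#' Expects columns \code{helix}, \code{start}, \code{end}.
#' @param path TSV path.
#' @param receptor_id Receptor label.
#' @return A \code{\link{helix_annotation}}.
#' @export
read_helix_annotation <- function(path, receptor_id = basename(path)) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  helix_annotation(receptor_id, df)
}

#' Assign helix-based consensus numbers
#'
#' The k-th residue (1-based) of helix h receives consensus number
#' \code{100*h + k}; residues outside every helix receive none.
#'
#' @param ann A \code{\link{helix_annotation}}.
#' @return An object of class \code{"consensus_number_map"}: a data
#'   frame with columns \code{resno} and \code{consensus}, restricted to
#'   helix residues, plus the receptor id as an attribute.
#' @examples
#' ann <- helix_annotation("toy", data.frame(
#'   helix = 1:7, start = c(30, 60, 95, 130, 190, 240, 280),
#'   end   = c(55, 85, 125, 155, 215, 265, 305)))
#' m <- assign_consensus_numbers(ann)
#' residue_to_consensus(m, 30)   # 101
#' @export
assign_consensus_numbers <- function(ann) {
  stopifnot(inherits(ann, "helix_annotation"))
  h <- ann$helices
  rows <- lapply(seq_len(nrow(h)), function(i) {
    resno <- seq.int(h$start[i], h$end[i])
    data.frame(resno = resno,
               consensus = 100L * as.integer(h$helix[i]) +
                 seq_along(resno))
  })
  df <- do.call(rbind, rows)
  structure(df, class = c("consensus_number_map", "data.frame"),
            receptor_id = ann$receptor_id)
}

#' Look up the consensus number of a receptor residue
#'
#' @param map A \code{\link{assign_consensus_numbers}} result.
#' @param resno Receptor residue number(s).
#' @return Integer vector; \code{NA} for loop residues.
#' @export
residue_to_consensus <- function(map, resno) {
  stopifnot(inherits(map, "consensus_number_map"))
  map$consensus[match(resno, map$resno)]
}

#' Look up the receptor residue carrying a consensus number
#'
#' @param map A \code{\link{assign_consensus_numbers}} result.
#' @param consensus Consensus number(s), e.g. \code{512}.
#' @return Integer vector of receptor residue numbers; \code{NA} when
#'   the consensus number does not exist for this receptor.
#' @export
consensus_to_residue <- function(map, consensus) {
  stopifnot(inherits(map, "consensus_number_map"))
  map$resno[match(consensus, map$consensus)]
}

## ---- conservation categories -------------------------------------------

CATEGORY_LEVELS <- c("gpcr_common", "all_conserved", "trio_conserved",
                     "pair_conserved", "unconserved")

# The attribute set of one consensus symbol: for a letter, the letter
# itself plus every class containing it; for a class symbol, that class;
# for ".", nothing.  Two or more symbols "share" conservation when the
# intersection of their attribute sets is non-empty.
symbol_attributes <- function(sym, scheme) {
  if (is.na(sym) || sym == scheme$no_conservation) return(character(0))
  cl_hit <- names(scheme$symbols)[scheme$symbols == sym]
  if (length(cl_hit) == 1L) return(cl_hit)
  if (!sym %in% unlist(scheme$classes) && !sym %in% LETTERS)
    stop("unknown consensus symbol: '", sym, "'", call. = FALSE)
  classes <- names(scheme$classes)[vapply(scheme$classes,
                                          function(s) sym %in% s, NA)]
  c(sym, classes)
}

symbols_share <- function(symbols, scheme) {
  sets <- lapply(symbols, symbol_attributes, scheme = scheme)
  if (any(vapply(sets, length, 0L) == 0L)) return(FALSE)
  length(Reduce(intersect, sets)) > 0L
}

#' Classify one consensus position into a conservation category
#'
#' Categories, in decreasing priority: \code{gpcr_common} (position is
#' in the supplied set of class-A GPCR motif positions),
#' \code{all_conserved} (shared across AT1, AT2, MAS and the outgroup,
#' e.g. rhodopsin), \code{trio_conserved} (shared across the three
#' receptor families only), \code{pair_conserved} (shared by AT1 and
#' AT2 only), else \code{unconserved}.  Two symbols share conservation
#' when they are equal letters, letters of one common class, equal
#' class symbols, or a class symbol plus a letter of that class.
#'
#' @param symbols Named character vector with entries \code{AT1},
#'   \code{AT2}, \code{MAS}: the family consensus symbols at this
#'   aligned position.
#' @param outgroup Single character, the outgroup symbol (a letter,
#'   class symbol, or \code{"."}).
#' @param consensus_number Integer or \code{NA}: the position's
#'   consensus number, checked against \code{gpcr_common}.
#' @param gpcr_common Integer vector of consensus numbers treated as
#'   commonly conserved class-A GPCR positions (user-supplied).
#' @param scheme A \code{\link{residue_class_scheme}}.
#' @return One of \code{"gpcr_common"}, \code{"all_conserved"},
#'   \code{"trio_conserved"}, \code{"pair_conserved"},
#'   \code{"unconserved"}.
#' @examples
#' classify_position(c(AT1 = "K", AT2 = "K", MAS = "I"), outgroup = ".")
#' @export
classify_position <- function(symbols, outgroup,
                              consensus_number = NA_integer_,
                              gpcr_common = integer(0),
                              scheme = residue_class_scheme()) {
  need <- c("AT1", "AT2", "MAS")
  if (is.null(names(symbols)) || !all(need %in% names(symbols)) ||
      anyNA(symbols[need]))
    stop("symbols must carry non-missing entries named AT1, AT2, MAS",
         call. = FALSE)
  if (length(outgroup) != 1L || is.na(outgroup))
    stop("a single outgroup symbol is required", call. = FALSE)
  if (!is.na(consensus_number) && consensus_number %in% gpcr_common)
    return("gpcr_common")
  trio <- as.list(symbols[need])
  if (symbols_share(c(trio, outgroup), scheme)) return("all_conserved")
  if (symbols_share(trio, scheme)) return("trio_conserved")
  if (symbols_share(trio[c("AT1", "AT2")], scheme)) return("pair_conserved")
  "unconserved"
}

#' Read a functional-residue table from TSV
#'
#' Mirrors the layout of a curated functional-residue list: one row per
#' consensus position with the residue found in each receptor, a short
#' effect description and a literature tag.
#'
#' @param path TSV with columns \code{consensus}, \code{AT1},
#'   \code{AT2}, \code{MAS}, \code{effect}, \code{reference}.
#' @return A data frame.
#' @export
read_functional_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, quote = "")
  need <- c("consensus", "AT1", "AT2", "MAS", "effect", "reference")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("functional table misses columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  df
}

#' Cross-receptor divergence report
#'
#' Joins, per consensus position: the family consensus symbols, the
#' conservation category, each receptor's native residue number (via its
#' consensus-number map) and any functional annotation.  Also flags
#' positions where AT1 and AT2 carry aromatic residues while MAS does
#' not — the divergence pattern behind the differential handling of the
#' aromatic C-terminal residue of Ang II.
#'
#' @param positions Data frame with columns \code{consensus},
#'   \code{AT1}, \code{AT2}, \code{MAS}, \code{outgroup} (symbols per
#'   position).
#' @param maps Named list of \code{consensus_number_map}s (names
#'   \code{AT1}, \code{AT2}, \code{MAS}).
#' @param functional Optional functional-residue data frame (see
#'   \code{\link{read_functional_table}}); rows whose consensus number
#'   is absent from \code{positions} are kept as warning rows with
#'   \code{note = "unmapped"}.
#' @param gpcr_common Integer vector of commonly conserved GPCR
#'   consensus numbers.
#' @param scheme A \code{\link{residue_class_scheme}}.
#' @return A data frame sorted by consensus number, one row per
#'   position (plus any unmapped functional rows).
#' @export
divergence_report <- function(positions, maps, functional = NULL,
                              gpcr_common = integer(0),
                              scheme = residue_class_scheme()) {
  need <- c("consensus", "AT1", "AT2", "MAS", "outgroup")
  stopifnot(is.data.frame(positions), all(need %in% names(positions)))
  aromatic <- scheme$classes$aromatic
  rows <- lapply(seq_len(nrow(positions)), function(i) {
    p <- positions[i, ]
    cat_i <- classify_position(
      c(AT1 = p$AT1, AT2 = p$AT2, MAS = p$MAS), p$outgroup,
      consensus_number = p$consensus, gpcr_common = gpcr_common,
      scheme = scheme)
    arom12 <- p$AT1 %in% aromatic && p$AT2 %in% aromatic
    data.frame(
      consensus = p$consensus, AT1 = p$AT1, AT2 = p$AT2, MAS = p$MAS,
      outgroup = p$outgroup,
      AT1_resno = if ("AT1" %in% names(maps))
        consensus_to_residue(maps$AT1, p$consensus) else NA_integer_,
      AT2_resno = if ("AT2" %in% names(maps))
        consensus_to_residue(maps$AT2, p$consensus) else NA_integer_,
      MAS_resno = if ("MAS" %in% names(maps))
        consensus_to_residue(maps$MAS, p$consensus) else NA_integer_,
      category = cat_i,
      aromatic_in_AT1_AT2_only = arom12 && !(p$MAS %in% aromatic),
      effect = NA_character_, reference = NA_character_,
      note = "", stringsAsFactors = FALSE)
  })
  rep_df <- do.call(rbind, rows)
  if (!is.null(functional) && nrow(functional) > 0L) {
    hit <- match(functional$consensus, rep_df$consensus)
    for (k in seq_along(hit)) {
      if (is.na(hit[k])) {
        rep_df <- rbind(rep_df, data.frame(
          consensus = functional$consensus[k],
          AT1 = functional$AT1[k], AT2 = functional$AT2[k],
          MAS = functional$MAS[k], outgroup = NA_character_,
          AT1_resno = NA_integer_, AT2_resno = NA_integer_,
          MAS_resno = NA_integer_, category = NA_character_,
          aromatic_in_AT1_AT2_only = NA,
          effect = functional$effect[k],
          reference = functional$reference[k],
          note = "unmapped", stringsAsFactors = FALSE))
        warning("functional consensus number ", functional$consensus[k],
                " absent from the classified positions", call. = FALSE)
      } else {
        rep_df$effect[hit[k]] <- functional$effect[k]
        rep_df$reference[hit[k]] <- functional$reference[k]
      }
    }
  }
  rep_df <- rep_df[order(rep_df$consensus), ]
  rownames(rep_df) <- NULL
  rep_df
}
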