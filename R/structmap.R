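# CA superposition (Kabsch/SVD), binding-pocket detection, and painting
# of conservation categories onto structures via the B-factor column.

# Core Kabsch: rotation R and translation t minimizing ||P R + t - Q||
# over matched n x 3 coordinate sets (row-vector convention).
kabsch_fit <- function(P, Q) {
  stopifnot(nrow(P) == nrow(Q), ncol(P) == 3, ncol(Q) == 3)
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp); Qc <- sweep(Q, 2, cq)
  M <- crossprod(Pc, Qc)
  sv <- svd(M)
  d <- sign(det(sv$u %*% t(sv$v)))
  R <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  t_vec <- as.numeric(cq - cp %*% R)
  fitted <- sweep(P %*% R, 2, t_vec, "+")
  rmsd <- sqrt(mean(rowSums((fitted - Q)^2)))
  list(rotation = R, translation = t_vec, rmsd = rmsd, fitted = fitted)
}

#' Superpose two structures on matched CA atoms
#'
#' Least-squares rigid superposition (Kabsch, via SVD) of structure
#' \code{a} onto structure \code{b} over a supplied residue mapping.
#' The mapping normally comes from the cross-family sequence alignment,
#' so that equivalent consensus positions are matched; no structural
#' alignment heuristic is applied.
#'
#' @param a,b \code{\link{structure3d}} objects.
#' @param mapping Data frame with columns \code{resno_a},
#'   \code{resno_b} (and optionally \code{chain_a}, \code{chain_b});
#'   when omitted, residues with equal (chain, resno) carrying a CA atom
#'   in both structures are matched.
#' @return A list of class \code{"superposition_result"}:
#'   \code{rotation} (3x3, det +1), \code{translation} (Angstrom),
#'   \code{rmsd} (CA RMSD after the transform), \code{n_matched}.
#'   Applying \code{\link{transform_structure}} with these values moves
#'   \code{a} onto \code{b}.
#' @export
kabsch_superpose <- function(a, b, mapping = NULL) {
  stopifnot(inherits(a, "structure3d"), inherits(b, "structure3d"))
  ca_a <- a$atoms[a$atoms$elety == "CA", ]
  ca_b <- b$atoms[b$atoms$elety == "CA", ]
  if (is.null(mapping)) {
    key_a <- paste(ca_a$chain, ca_a$resno)
    key_b <- paste(ca_b$chain, ca_b$resno)
    common <- intersect(key_a, key_b)
    ia <- match(common, key_a); ib <- match(common, key_b)
  } else {
    stopifnot(all(c("resno_a", "resno_b") %in% names(mapping)))
    ch_a <- if ("chain_a" %in% names(mapping)) mapping$chain_a else
      ca_a$chain[1]
    ch_b <- if ("chain_b" %in% names(mapping)) mapping$chain_b else
      ca_b$chain[1]
    ia <- match(paste(ch_a, mapping$resno_a), paste(ca_a$chain, ca_a$resno))
    ib <- match(paste(ch_b, mapping$resno_b), paste(ca_b$chain, ca_b$resno))
    if (anyNA(ia) || anyNA(ib))
      stop("mapping refers to residues without CA atoms", call. = FALSE)
  }
  if (length(ia) < 3L)
    stop("need at least 3 matched CA pairs for superposition",
         call. = FALSE)
  P <- as.matrix(ca_a[ia, c("x", "y", "z")])
  Q <- as.matrix(ca_b[ib, c("x", "y", "z")])
  if (qr(sweep(P, 2, colMeans(P)))$rank < 2L)
    stop("matched CA atoms are collinear; superposition is degenerate",
         call. = FALSE)
  fit <- kabsch_fit(P, Q)
  structure(list(rotation = fit$rotation, translation = fit$translation,
                 rmsd = fit$rmsd, n_matched = length(ia)),
            class = "superposition_result")
}

#' @export
print.superposition_result <- function(x, ...) {
  cat(sprintf("<superposition> %d CA pairs, RMSD %.4f A\n",
              x$n_matched, x$rmsd))
  invisible(x)
}

cross_dist2 <- function(A, B) {
  # squared distances, |A| x |B|
  a2 <- rowSums(A^2); b2 <- rowSums(B^2)
  d2 <- outer(a2, b2, "+") - 2 * tcrossprod(A, B)
  d2[d2 < 0] <- 0
  d2
}

#' Residues lining a binding pocket
#'
#' All receptor residues with at least one (by default heavy) atom
#' within \code{cutoff} of any probe atom or point.
#'
#' @param receptor A \code{\link{structure3d}}.
#' @param probe A \code{structure3d} (e.g. a ligand pose), an n x 3
#'   coordinate matrix, or a length-3 point.
#' @param cutoff Distance cutoff in Angstrom (default 6).
#' @param heavy_only Consider only non-hydrogen receptor atoms.
#' @return Data frame with columns \code{chain}, \code{resno},
#'   \code{resid}, \code{min_dist}, sorted by residue.
#' @export
pocket_residues <- function(receptor, probe, cutoff = 6,
                            heavy_only = TRUE) {
  stopifnot(inherits(receptor, "structure3d"), cutoff > 0)
  if (inherits(probe, "structure3d")) {
    B <- coords(probe, heavy_only = heavy_only)
  } else {
    B <- rbind(probe)
    storage.mode(B) <- "double"
  }
  if (nrow(B) == 0L) stop("empty probe", call. = FALSE)
  a <- receptor$atoms
  if (heavy_only) a <- a[a$elesy != "H", ]
  A <- as.matrix(a[, c("x", "y", "z")])
  dmin <- sqrt(apply(cross_dist2(A, B), 1, min))
  a$min_dist <- dmin
  hit <- a[a$min_dist <= cutoff, ]
  if (nrow(hit) == 0L)
    return(data.frame(chain = character(0), resno = integer(0),
                      resid = character(0), min_dist = numeric(0)))
  agg <- stats::aggregate(min_dist ~ chain + resno + resid, data = hit,
                          FUN = min)
  agg <- agg[order(agg$chain, agg$resno), ]
  rownames(agg) <- NULL
  agg
}

#' Category codes used in the B-factor column
#'
#' Fixed encoding so annotated PDB outputs are bit-exact:
#' unmapped/absent 0, gpcr_common 1, all_conserved 2, trio_conserved 3,
#' pair_conserved 4, unconserved 5.
#' @return Named numeric vector.
#' @export
category_codes <- function() {
  c(unmapped = 0, gpcr_common = 1, all_conserved = 2,
    trio_conserved = 3, pair_conserved = 4, unconserved = 5)
}

#' Paint conservation categories onto a structure
#'
#' Writes the per-residue category code (see
#' \code{\link{category_codes}}) into the B-factor column of every atom
#' of the residue; residues without a category get code 0.  Optionally
#' writes the annotated PDB and a sidecar TSV.
#'
#' @param receptor A \code{\link{structure3d}}.
#' @param categories Data frame with columns \code{resno} and
#'   \code{category} (and optionally \code{chain}).
#' @param pdb_out,tsv_out Optional output paths.
#' @return The annotated \code{structure3d}, invisibly when writing.
#' @export
annotate_structure <- function(receptor, categories, pdb_out = NULL,
                               tsv_out = NULL) {
  stopifnot(inherits(receptor, "structure3d"),
            all(c("resno", "category") %in% names(categories)))
  codes <- category_codes()
  bad <- setdiff(unique(categories$category), names(codes))
  if (length(bad))
    stop("unknown categories: ", paste(bad, collapse = ", "),
         call. = FALSE)
  a <- receptor$atoms
  chain <- if ("chain" %in% names(categories)) categories$chain else
    a$chain[1]
  key <- paste(chain, categories$resno)
  idx <- match(paste(a$chain, a$resno), key)
  a$b <- ifelse(is.na(idx), codes[["unmapped"]],
                codes[categories$category[idx]])
  receptor$atoms <- a
  sidecar <- unique(data.frame(chain = a$chain, resno = a$resno,
                               resid = a$resid,
                               category = ifelse(is.na(idx), "unmapped",
                                                 categories$category[idx]),
                               code = a$b, stringsAsFactors = FALSE))
  rownames(sidecar) <- NULL
  attr(receptor, "annotation") <- sidecar
  if (!is.null(pdb_out)) write_structure(receptor, pdb_out)
  if (!is.null(tsv_out))
    utils::write.table(sidecar, tsv_out, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  if (is.null(pdb_out) && is.null(tsv_out)) receptor else invisible(receptor)
}
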