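# Pose scoring, ranking and constraint-based placement.
#
# A simplified nonbonded force field (Lennard-Jones 12-6 plus Coulomb
# with a distance-dependent dielectric) replaces the original AMBER03
# energies.  Absolute magnitudes are therefore not comparable with a
# full force field; only orderings and signs of the resulting binding
# energies carry meaning.  Sign convention: binding energy
# BE = E(receptor) + E(ligand) - E(complex), so a MORE POSITIVE BE is
# MORE FAVORABLE, matching the "highest binding energy is best" usage
# of the ranking procedure.

COULOMB_K <- 332.06   # kcal mol^-1 A e^-2

#' Simplified nonbonded force-field parameters
#'
#' Per-element Lennard-Jones radius sigma (Angstrom) and well depth
#' epsilon (kcal/mol), combined with Lorentz-Berthelot mixing; Coulomb
#' term with distance-dependent dielectric D(r) = dielectric_factor * r;
#' interactions beyond \code{cutoff} are ignored.
#'
#' @param sigma,epsilon Named numeric vectors keyed by element symbol.
#' @param dielectric_factor Dimensionless factor in D(r) = f*r
#'   (default 4).
#' @param cutoff Nonbonded cutoff in Angstrom (default 10).
#' @return A list of class \code{"simple_ff_params"}.
#' @export
simple_ff_params <- function(
    sigma = c(C = 3.40, N = 3.25, O = 2.96, S = 3.56, H = 2.50,
              P = 3.74),
    epsilon = c(C = 0.086, N = 0.170, O = 0.210, S = 0.250, H = 0.015,
                P = 0.200),
    dielectric_factor = 4, cutoff = 10) {
  stopifnot(all(sigma > 0), all(epsilon > 0), cutoff > 0,
            dielectric_factor > 0)
  structure(list(sigma = sigma, epsilon = epsilon,
                 dielectric_factor = dielectric_factor, cutoff = cutoff),
            class = "simple_ff_params")
}

atoms_for_energy <- function(x) {
  if (inherits(x, "structure3d")) x <- x$atoms
  stopifnot(is.data.frame(x),
            all(c("x", "y", "z", "elesy") %in% names(x)))
  if (is.null(x$charge)) x$charge <- 0
  x
}

lookup_ff <- function(elements, table, what) {
  v <- table[elements]
  if (anyNA(v)) {
    miss <- unique(elements[is.na(v)])
    stop("no ", what, " parameter for element(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  unname(v)
}

#' Nonbonded interaction energy between two atom sets
#'
#' Sum over all cross pairs within the cutoff of
#' \deqn{4\epsilon[(\sigma/r)^{12} - (\sigma/r)^6] +
#'       332.06 \, q_i q_j / (D(r) \, r)}
#' with Lorentz-Berthelot mixing and D(r) = f r.  A zero interatomic
#' distance raises a clash error.
#'
#' @param a,b \code{\link{structure3d}} objects or atom data frames
#'   (columns x, y, z, elesy, charge); the sets must be disjoint
#'   molecules.
#' @param params A \code{\link{simple_ff_params}}.
#' @return Energy in kcal/mol.
#' @examples
#' at <- function(x) data.frame(x = x, y = 0, z = 0, elesy = "C",
#'                              charge = 0)
#' p <- simple_ff_params()
#' nonbonded_energy(at(0), at(3.40), p)             # 0 at r = sigma
#' nonbonded_energy(at(0), at(2^(1/6) * 3.40), p)   # -epsilon
#' @export
nonbonded_energy <- function(a, b, params = simple_ff_params()) {
  A <- atoms_for_energy(a); B <- atoms_for_energy(b)
  pair_energy_sum(as.matrix(A[, c("x", "y", "z")]),
                  as.matrix(B[, c("x", "y", "z")]),
                  A$elesy, B$elesy, A$charge, B$charge, params)
}

pair_energy_sum <- function(XA, XB, elA, elB, qA, qB, params) {
  d2 <- cross_dist2(XA, XB)
  if (any(d2 < 1e-12))
    stop("atomic clash: zero interatomic distance", call. = FALSE)
  keep <- d2 <= params$cutoff^2
  if (!any(keep)) return(0)
  idx <- which(keep, arr.ind = TRUE)
  r <- sqrt(d2[keep])
  si <- lookup_ff(elA[idx[, 1]], params$sigma, "sigma")
  sj <- lookup_ff(elB[idx[, 2]], params$sigma, "sigma")
  ei <- lookup_ff(elA[idx[, 1]], params$epsilon, "epsilon")
  ej <- lookup_ff(elB[idx[, 2]], params$epsilon, "epsilon")
  sig <- (si + sj) / 2
  eps <- sqrt(ei * ej)
  sr6 <- (sig / r)^6
  lj <- 4 * eps * (sr6^2 - sr6)
  coul <- COULOMB_K * qA[idx[, 1]] * qB[idx[, 2]] /
    (params$dielectric_factor * r * r)
  sum(lj + coul)
}

# Total nonbonded energy within one atom set (unique pairs).
intra_energy <- function(a, params = simple_ff_params()) {
  A <- atoms_for_energy(a)
  n <- nrow(A)
  if (n < 2L) return(0)
  X <- as.matrix(A[, c("x", "y", "z")])
  d2 <- cross_dist2(X, X)
  d2[lower.tri(d2, diag = TRUE)] <- Inf
  keep <- d2 <= params$cutoff^2
  if (!any(keep)) return(0)
  idx <- which(keep, arr.ind = TRUE)
  r <- sqrt(d2[keep])
  if (any(r < 1e-6))
    stop("atomic clash: zero interatomic distance", call. = FALSE)
  si <- lookup_ff(A$elesy[idx[, 1]], params$sigma, "sigma")
  sj <- lookup_ff(A$elesy[idx[, 2]], params$sigma, "sigma")
  ei <- lookup_ff(A$elesy[idx[, 1]], params$epsilon, "epsilon")
  ej <- lookup_ff(A$elesy[idx[, 2]], params$epsilon, "epsilon")
  sig <- (si + sj) / 2
  eps <- sqrt(ei * ej)
  sr6 <- (sig / r)^6
  sum(4 * eps * (sr6^2 - sr6) +
        COULOMB_K * A$charge[idx[, 1]] * A$charge[idx[, 2]] /
        (params$dielectric_factor * r * r))
}

#' Binding energy of a ligand pose
#'
#' \code{BE = E(receptor alone) + E(ligand alone) - E(complex)}.  With
#' a pairwise-additive energy this equals minus the receptor-ligand
#' cross-interaction energy, so a favorable (negative) interaction
#' yields a positive BE.  A ligand entirely beyond the cutoff scores 0;
#' a severely clashed pose scores strongly negative.
#'
#' @param receptor,ligand \code{\link{structure3d}} objects or atom
#'   data frames.
#' @param params A \code{\link{simple_ff_params}}.
#' @return Binding energy in kcal/mol (positive = favorable).
#' @export
binding_energy <- function(receptor, ligand,
                           params = simple_ff_params()) {
  e_rec <- intra_energy(receptor, params)
  e_lig <- intra_energy(ligand, params)
  e_cross <- nonbonded_energy(receptor, ligand, params)
  e_complex <- e_rec + e_lig + e_cross
  e_rec + e_lig - e_complex
}

#' Displacement of a pose from its initial placement
#'
#' Heavy-atom RMSD computed in the shared frame, WITHOUT superposition:
#' this measures how far energy minimization moved the ligand.
#'
#' @param pose,initial \code{\link{structure3d}} objects with identical
#'   topology (same atom names and residue numbers in the same order).
#' @return RMSD in Angstrom.
#' @export
pose_displacement <- function(pose, initial) {
  stopifnot(inherits(pose, "structure3d"),
            inherits(initial, "structure3d"))
  a <- pose$atoms; b <- initial$atoms
  if (nrow(a) != nrow(b) ||
      !identical(paste(a$elety, a$resno), paste(b$elety, b$resno)))
    stop("pose and initial structure differ in topology", call. = FALSE)
  heavy <- a$elesy != "H"
  d <- as.matrix(a[heavy, c("x", "y", "z")]) -
    as.matrix(b[heavy, c("x", "y", "z")])
  sqrt(mean(rowSums(d^2)))
}

## ---- pose sets ----------------------------------------------------------

#' Assemble a scored pose set
#'
#' @param receptor_id,ligand_id Labels.
#' @param poses List of \code{\link{structure3d}} ligand poses.
#' @param receptor The receptor \code{structure3d} used for scoring.
#' @param initial Optional initial pose for displacement (defaults to
#'   each pose itself, i.e. displacement 0).
#' @param params A \code{\link{simple_ff_params}}.
#' @return An object of class \code{"pose_set"}: the poses plus a
#'   \code{scores} data frame with columns \code{pose_index},
#'   \code{pe_receptor}, \code{pe_ligand}, \code{binding_energy},
#'   \code{displacement}.
#' @export
pose_set <- function(receptor_id, ligand_id, poses, receptor,
                     initial = NULL, params = simple_ff_params()) {
  stopifnot(is.list(poses), length(poses) >= 1L)
  pe_rec <- intra_energy(receptor, params)
  scores <- do.call(rbind, lapply(seq_along(poses), function(i) {
    p <- poses[[i]]
    data.frame(pose_index = i,
               pe_receptor = pe_rec,
               pe_ligand = intra_energy(p, params),
               binding_energy = binding_energy(receptor, p, params),
               displacement = if (is.null(initial)) 0 else
                 pose_displacement(p, initial))
  }))
  structure(list(receptor_id = receptor_id, ligand_id = ligand_id,
                 poses = poses, scores = scores),
            class = "pose_set")
}

#' @export
print.pose_set <- function(x, ...) {
  cat(sprintf("<pose_set> %s / %s: %d poses, BE range [%.3f, %.3f]\n",
              x$receptor_id, x$ligand_id, length(x$poses),
              min(x$scores$binding_energy), max(x$scores$binding_energy)))
  invisible(x)
}

#' Rank poses by binding energy and keep the best k
#'
#' Poses are ranked by binding energy in descending order (rank 1 =
#' highest, i.e. most favorable, BE) and the k best rank values are
#' selected; ties are broken by ascending pose index.  This mirrors the
#' compile-ranks-then-keep-three treatment of the ten top docking
#' results per experiment.
#'
#' @param ps A \code{\link{pose_set}}.
#' @param k Number of poses to keep (default 3).
#' @return A \code{pose_set} restricted to the selected poses, with a
#'   \code{rank} column added to \code{scores}, best first.
#' @export
rank_and_select <- function(ps, k = 3) {
  stopifnot(inherits(ps, "pose_set"))
  n <- nrow(ps$scores)
  if (k > n) stop("k = ", k, " exceeds the ", n, " available poses",
                  call. = FALSE)
  ord <- order(-ps$scores$binding_energy, ps$scores$pose_index)
  sel <- ord[seq_len(k)]
  out <- ps
  out$poses <- ps$poses[sel]
  out$scores <- ps$scores[sel, ]
  out$scores$rank <- seq_len(k)
  rownames(out$scores) <- NULL
  out
}

## ---- rigid-body minimization -------------------------------------------

rotation_about_axis <- function(axis, angle) {
  u <- axis / sqrt(sum(axis^2))
  c_ <- cos(angle); s_ <- sin(angle)
  ux <- u[1]; uy <- u[2]; uz <- u[3]
  matrix(c(
    c_ + ux^2 * (1 - c_), ux * uy * (1 - c_) - uz * s_,
    ux * uz * (1 - c_) + uy * s_,
    uy * ux * (1 - c_) + uz * s_, c_ + uy^2 * (1 - c_),
    uy * uz * (1 - c_) - ux * s_,
    uz * ux * (1 - c_) - uy * s_, uz * uy * (1 - c_) + ux * s_,
    c_ + uz^2 * (1 - c_)), 3, 3, byrow = TRUE)
}

move_pose <- function(lig, shift = c(0, 0, 0), axis = NULL, angle = 0) {
  xyz <- as.matrix(lig$atoms[, c("x", "y", "z")])
  if (!is.null(axis) && angle != 0) {
    ctr <- colMeans(xyz)
    xyz <- sweep(sweep(xyz, 2, ctr) %*% rotation_about_axis(axis, angle),
                 2, ctr, "+")
  }
  xyz <- sweep(xyz, 2, shift, "+")
  lig$atoms$x <- xyz[, 1]; lig$atoms$y <- xyz[, 2]; lig$atoms$z <- xyz[, 3]
  lig
}

#' Greedy rigid-body energy minimization of a ligand pose
#'
#' Deterministic pattern search over the six rigid degrees of freedom:
#' at each iteration the twelve candidate moves (+/- translation along
#' x, y, z; +/- rotation about x, y, z through the ligand centroid) are
#' scored and the best accepted if it improves the binding energy; when
#' no move improves, the step sizes are halved.  The ligand is rigid
#' throughout.  The final BE is never below the starting BE.
#'
#' @param receptor,ligand \code{\link{structure3d}} objects.
#' @param params A \code{\link{simple_ff_params}}.
#' @param steps Maximum iterations (default 60); 0 returns the input.
#' @param trans_step Initial translation step, Angstrom (default 0.5).
#' @param rot_step Initial rotation step, radians (default 0.1).
#' @param min_step Stop when the translation step falls below this.
#' @return The minimized ligand \code{structure3d} with attributes
#'   \code{be_initial} and \code{be_final}.
#' @export
rigid_minimize <- function(receptor, ligand, params = simple_ff_params(),
                           steps = 60, trans_step = 0.5, rot_step = 0.1,
                           min_step = 0.01) {
  be0 <- tryCatch(binding_energy(receptor, ligand, params),
                  error = function(e) NaN)
  if (!is.finite(be0))
    stop("non-finite starting energy (clashed pose?)", call. = FALSE)
  if (steps == 0) {
    attr(ligand, "be_initial") <- be0
    attr(ligand, "be_final") <- be0
    return(ligand)
  }
  be_fun <- function(l) tryCatch(binding_energy(receptor, l, params),
                                 error = function(e) -Inf)
  cur <- ligand; be_cur <- be0
  ts <- trans_step; rs <- rot_step
  axes <- list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  for (it in seq_len(steps)) {
    cands <- list()
    for (ax in axes) {
      cands <- c(cands,
                 list(move_pose(cur, shift = ts * ax),
                      move_pose(cur, shift = -ts * ax),
                      move_pose(cur, axis = ax, angle = rs),
                      move_pose(cur, axis = ax, angle = -rs)))
    }
    be_c <- vapply(cands, be_fun, 0)
    best <- which.max(be_c)
    if (be_c[best] > be_cur + 1e-12) {
      cur <- cands[[best]]; be_cur <- be_c[best]
    } else {
      ts <- ts / 2; rs <- rs / 2
      if (ts < min_step) break
    }
  }
  attr(cur, "be_initial") <- be0
  attr(cur, "be_final") <- be_cur
  cur
}

#' Rescore top poses against several receptors
#'
#' Each selected pose is (optionally) rigid-body minimized against each
#' receptor and its binding energy recorded, mirroring the treatment of
#' the top three complexes being re-minimized on AT1, AT2, MAS and
#' rhodopsin.  All receptors must already be in the pose frame; supply
#' \code{transforms} (per-receptor rigid transforms from
#' \code{\link{kabsch_superpose}} of each receptor onto the originating
#' one) to bring the pose into another receptor's frame.
#'
#' @param top A \code{\link{pose_set}} (typically from
#'   \code{\link{rank_and_select}}).
#' @param receptors Named list of \code{\link{structure3d}}.
#' @param params A \code{\link{simple_ff_params}}.
#' @param steps Minimization iterations per pose/receptor (0 = score in
#'   place; on the originating receptor this reproduces the stored BE).
#' @param transforms Optional named list (per receptor) of
#'   \code{list(rotation, translation)} applied to the pose first.
#' @param max_center_sep Frames are declared incompatible when the
#'   pose centroid is farther than this from the receptor centroid
#'   (default 100 Angstrom).
#' @return Numeric matrix of binding energies, poses x receptors.
#' @export
cross_rescore <- function(top, receptors, params = simple_ff_params(),
                          steps = 0, transforms = NULL,
                          max_center_sep = 100) {
  stopifnot(inherits(top, "pose_set"), is.list(receptors),
            length(receptors) >= 1L)
  if (is.null(names(receptors)))
    names(receptors) <- paste0("receptor", seq_along(receptors))
  out <- matrix(NA_real_, nrow = length(top$poses),
                ncol = length(receptors),
                dimnames = list(paste0("pose", top$scores$pose_index),
                                names(receptors)))
  for (j in seq_along(receptors)) {
    rec <- receptors[[j]]
    for (i in seq_along(top$poses)) {
      pose <- top$poses[[i]]
      if (!is.null(transforms) && !is.null(transforms[[names(receptors)[j]]])) {
        tr <- transforms[[names(receptors)[j]]]
        pose <- transform_structure(pose, tr$rotation, tr$translation)
      }
      sep <- sqrt(sum((colMeans(coords(pose)) -
                         colMeans(coords(rec)))^2))
      if (sep > max_center_sep)
        stop("pose and receptor '", names(receptors)[j],
             "' are not in a shared frame (centroid separation ",
             round(sep, 1), " A); supply a transform", call. = FALSE)
      if (steps > 0)
        pose <- rigid_minimize(rec, pose, params, steps = steps)
      out[i, j] <- binding_energy(rec, pose, params)
    }
  }
  out
}

## ---- distance constraints ----------------------------------------------

resolve_selector <- function(s, sel, what) {
  a <- s$atoms
  known <- c("chain", "resno", "resid", "elety", "comment")
  unknown <- setdiff(names(sel), known)
  if (length(unknown))
    stop(what, " selector has unresolved field(s): ",
         paste(unknown, collapse = ", "),
         if ("consensus" %in% unknown)
           " (use resolve_constraint_consensus() first)",
         call. = FALSE)
  keep <- rep(TRUE, nrow(a))
  for (fld in c("chain", "resno", "resid", "elety")) {
    if (!is.null(sel[[fld]])) keep <- keep & a[[fld]] %in% sel[[fld]]
  }
  if (!any(keep))
    stop(what, " selector matches no atoms: ",
         paste(names(sel), unlist(sel), sep = "=", collapse = " "),
         call. = FALSE)
  as.matrix(a[keep, c("x", "y", "z")])
}

#' Check distance constraints of a pose
#'
#' A constraint couples a ligand atom selection to a receptor atom
#' selection with a maximum distance; it is satisfied when the minimum
#' pairwise distance between the selections does not exceed it.  This is
#' how mutagenesis contacts (e.g. the Ang II C-terminus near the
#' consensus-512 lysine) and photolabeling contacts (C-terminus near
#' consensus 725 or 336) are expressed as placement restraints.
#'
#' @param pose,receptor \code{\link{structure3d}} objects.
#' @param spec List of constraints; each is
#'   \code{list(ligand = selector, receptor = selector, max_distance)},
#'   with a selector being a named list over \code{chain}, \code{resno},
#'   \code{resid}, \code{elety}.
#' @return Data frame with one row per constraint: \code{constraint},
#'   \code{min_dist}, \code{max_distance}, \code{satisfied}.
#' @export
check_constraints <- function(pose, receptor, spec) {
  stopifnot(is.list(spec), length(spec) >= 1L)
  rows <- lapply(seq_along(spec), function(i) {
    cs <- spec[[i]]
    if (is.null(cs$max_distance) || cs$max_distance <= 0)
      stop("constraint ", i, ": max_distance must be > 0", call. = FALSE)
    L <- resolve_selector(pose, cs$ligand, paste0("constraint ", i, " ligand"))
    R <- resolve_selector(receptor, cs$receptor,
                          paste0("constraint ", i, " receptor"))
    dmin <- sqrt(min(cross_dist2(L, R)))
    data.frame(constraint = i, min_dist = dmin,
               max_distance = cs$max_distance,
               satisfied = dmin <= cs$max_distance)
  })
  do.call(rbind, rows)
}

#' Read a constraint specification from JSON
#' @param path JSON file: an array of objects with fields
#'   \code{ligand}, \code{receptor} (selector objects) and
#'   \code{max_distance}.
#' @return A constraint list usable by \code{\link{check_constraints}}.
#' @export
read_constraint_spec <- function(path) {
  js <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  lapply(js, function(cs) {
    list(ligand = cs$ligand, receptor = cs$receptor,
         max_distance = as.numeric(cs$max_distance))
  })
}

#' Resolve consensus-number constraint selectors to residue numbers
#'
#' Constraint files express receptor anchors as consensus numbers
#' (e.g. 512, 621, 725, 336) so one specification serves every
#' receptor; this translates them to the receptor's native residue
#' numbers through its consensus-number map.
#'
#' @param spec Constraint list whose receptor selectors may carry a
#'   \code{consensus} field.
#' @param map A \code{consensus_number_map} for the target receptor
#'   (see \code{\link{assign_consensus_numbers}}).
#' @return The constraint list with \code{consensus} fields replaced by
#'   \code{resno}.
#' @export
resolve_constraint_consensus <- function(spec, map) {
  lapply(spec, function(cs) {
    if (!is.null(cs$receptor$consensus)) {
      resno <- consensus_to_residue(map, as.integer(cs$receptor$consensus))
      if (anyNA(resno))
        stop("consensus number ", cs$receptor$consensus,
             " has no residue in this receptor", call. = FALSE)
      cs$receptor$resno <- resno
      cs$receptor$consensus <- NULL
    }
    cs
  })
}

random_rotation <- function() {
  # uniform rotation via a random quaternion
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

#' Generate constraint-satisfying rigid ligand placements
#'
#' Emulates a set of manual dockings: each pose is a random rigid
#' placement (uniform random orientation; the constrained ligand
#' selection dropped near the constrained receptor selection) accepted
#' only when every distance constraint holds and the pose is clash-free
#' with finite energy.  Reproducible for a fixed seed.
#'
#' @param ligand,receptor \code{\link{structure3d}} objects.
#' @param spec Constraint list (see \code{\link{check_constraints}}).
#' @param n Number of poses (default 20, matching a twenty-placement
#'   manual docking set).
#' @param seed Integer RNG seed.
#' @param params A \code{\link{simple_ff_params}}.
#' @param minimize_steps Rigid minimization iterations applied to each
#'   accepted pose (default 0).
#' @param max_attempts Sampling attempts per pose before giving up.
#' @param min_clearance Minimum allowed receptor-ligand atom distance.
#' @return A scored \code{\link{pose_set}}; each member satisfies all
#'   constraints.
#' @export
generate_constrained_poses <- function(ligand, receptor, spec, n = 20,
                                       seed = 1,
                                       params = simple_ff_params(),
                                       minimize_steps = 0,
                                       max_attempts = 2000,
                                       min_clearance = 1.5) {
  stopifnot(inherits(ligand, "structure3d"),
            inherits(receptor, "structure3d"), n >= 1L)
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()),
            add = TRUE)
  }
  set.seed(seed)
  anchor <- spec[[1]]
  rec_anchor <- resolve_selector(receptor, anchor$receptor,
                                 "anchor receptor")
  poses <- vector("list", n)
  viol_count <- integer(length(spec))
  for (i in seq_len(n)) {
    ok <- FALSE
    for (att in seq_len(max_attempts)) {
      lig <- ligand
      xyz <- as.matrix(lig$atoms[, c("x", "y", "z")])
      ctr <- colMeans(xyz)
      xyz <- sweep(xyz, 2, ctr) %*% random_rotation()
      lig$atoms$x <- xyz[, 1]; lig$atoms$y <- xyz[, 2]
      lig$atoms$z <- xyz[, 3]
      # drop the constrained ligand selection near a random anchor atom
      lsel <- resolve_selector(lig, anchor$ligand, "anchor ligand")
      lcen <- colMeans(lsel)
      target_atom <- rec_anchor[sample.int(nrow(rec_anchor), 1L), ]
      dirv <- stats::rnorm(3); dirv <- dirv / sqrt(sum(dirv^2))
      radius <- stats::runif(1, 0, 0.95 * anchor$max_distance)
      target <- target_atom + radius * dirv
      lig <- move_pose(lig, shift = target - lcen)
      chk <- check_constraints(lig, receptor, spec)
      if (!all(chk$satisfied)) {
        viol_count <- viol_count + as.integer(!chk$satisfied)
        next
      }
      dmin <- sqrt(min(cross_dist2(coords(lig), coords(receptor))))
      if (dmin < min_clearance) next
      be <- tryCatch(binding_energy(receptor, lig, params),
                     error = function(e) NaN)
      if (!is.finite(be)) next
      if (minimize_steps > 0)
        lig <- rigid_minimize(receptor, lig, params,
                              steps = minimize_steps)
      poses[[i]] <- lig
      ok <- TRUE
      break
    }
    if (!ok) {
      tightest <- which.max(viol_count)
      stop("no constraint-satisfying placement found after ",
           max_attempts, " attempts; tightest constraint: #", tightest,
           " (max_distance ", spec[[tightest]]$max_distance, " A)",
           call. = FALSE)
    }
  }
  pose_set(receptor$id, ligand$id, poses, receptor, initial = ligand,
           params = params)
}

#' Write pose scores (and ranks) as TSV
#' @param ps A \code{\link{pose_set}}.
#' @param path Output path.
#' @export
write_scores_tsv <- function(ps, path) {
  utils::write.table(ps$scores, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
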