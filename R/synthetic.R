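# Synthetic fixtures with planted, recoverable structure: family
# alignments with a known per-column consensus symbol, ideal 7TM CA
# bundles with matching helix annotations, pose sets with a known
# binding-energy ordering, and trajectories with planted per-residue
# jitter and inter-residue distance drift.  Every generator is a pure
# function of its arguments and seed.

with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

# residue pools guaranteeing that a noise-free column classifies to
# exactly the requested symbol under the default precedence
planted_pool <- function(symbol, scheme) {
  sym <- scheme$symbols
  cls <- scheme$classes
  if (symbol == sym[["acidic"]]) return(cls$acidic)
  if (symbol == sym[["basic"]]) return(cls$basic)
  if (symbol == sym[["hydroxyl"]]) return(cls$hydroxyl)
  if (symbol == sym[["aromatic"]]) return(cls$aromatic)
  if (symbol == sym[["hydrophobic"]])
    return(setdiff(cls$hydrophobic, cls$aromatic))
  if (symbol == scheme$no_conservation) return(c("D", "K", "G"))
  if (symbol %in% AA_LETTERS) return(symbol)
  stop("impossible planted symbol: '", symbol, "'", call. = FALSE)
}

#' Generate a family alignment with planted consensus symbols
#'
#' Builds a gapless alignment of \code{n_species} sequences whose
#' column-wise consensus (at noise 0) is exactly the planted symbol
#' vector: a planted letter gives an identical column, a planted class
#' symbol a column drawn from that class (with at least two distinct
#' members, avoiding residues that would trigger a more specific
#' class), and \code{"."} a column with no shared class.  Substitution
#' noise is applied i.i.d. per cell from outside the planted class.
#'
#' @param n_species Number of member sequences (>= 2).
#' @param length Number of columns; ignored when \code{planted} is
#'   given.
#' @param planted Character vector of per-column symbols (letters,
#'   class symbols, or \code{"."}); \code{NULL} draws a random mix.
#' @param noise Per-cell substitution probability in [0, 1].
#' @param seed Integer seed.
#' @param family_id Family label.
#' @param scheme A \code{\link{residue_class_scheme}}.
#' @return A list: \code{alignment} (a
#'   \code{\link{family_alignment}}), \code{truth} (data frame
#'   \code{column}, \code{planted}).
#' @export
gen_family_alignment <- function(n_species = 6, length = 60,
                                 planted = NULL, noise = 0, seed = 1,
                                 family_id = "FAM",
                                 scheme = residue_class_scheme()) {
  stopifnot(n_species >= 2, noise >= 0, noise <= 1)
  with_seed(seed, {
    if (is.null(planted)) {
      alphabet <- c(AA_LETTERS, unname(scheme$symbols),
                    scheme$no_conservation)
      planted <- sample(alphabet, length, replace = TRUE)
    }
    ncol_ <- base::length(planted)
    m <- matrix("", nrow = n_species, ncol = ncol_)
    for (j in seq_len(ncol_)) {
      pool <- planted_pool(planted[j], scheme)
      if (base::length(pool) == 1L) {
        m[, j] <- pool
      } else {
        col <- sample(pool, n_species, replace = TRUE)
        # force at least two distinct members so the column cannot
        # collapse to a single-letter consensus
        col[1:2] <- sample(pool, 2, replace = FALSE)
        m[, j] <- col
      }
      if (noise > 0) {
        hit <- stats::runif(n_species) < noise
        if (any(hit)) {
          complement <- setdiff(AA_LETTERS, pool)
          m[hit, j] <- sample(complement, sum(hit), replace = TRUE)
        }
      }
    }
    records <- lapply(seq_len(n_species), function(i)
      sequence_record(sprintf("%s_sp%02d", family_id, i),
                      paste(m[i, ], collapse = ""),
                      species = sprintf("species%02d", i)))
    aln <- family_alignment(family_id, records,
                            vapply(records, `[[`, "", "residues"))
    list(alignment = aln,
         truth = data.frame(column = seq_len(ncol_), planted = planted,
                            stringsAsFactors = FALSE))
  })
}

#' Generate an ideal 7TM CA bundle with its helix annotation
#'
#' Seven ideal alpha-helical CA traces (1.5 Angstrom rise, 100 degrees
#' per residue, 2.3 Angstrom helix radius) stand on a circle, axes
#' along z with alternating direction, joined by short interpolated
#' loops.  The returned annotation lists the helix residue ranges, so
#' consensus numbering assigns 101 to the first residue of helix 1.
#'
#' @param helix_lengths Integer vector of 7 helix lengths (>= 8).
#' @param spacing Distance between adjacent helix axes (Angstrom);
#'   must exceed the helix diameter.
#' @param loop_len Number of interpolated loop residues between
#'   consecutive helices.
#' @param jitter Coordinate jitter sigma (Angstrom) making distinct
#'   seeds produce distinct bundles.
#' @param seed Integer seed.
#' @param receptor_id Label for structure and annotation.
#' @return List: \code{structure} (a \code{\link{structure3d}} of CA
#'   atoms, chain A), \code{annotation} (a
#'   \code{\link{helix_annotation}}).
#' @export
gen_7tm_bundle <- function(helix_lengths = rep(24L, 7), spacing = 11,
                           loop_len = 3, jitter = 0.05, seed = 1,
                           receptor_id = "7TM") {
  stopifnot(length(helix_lengths) == 7L, all(helix_lengths >= 8L))
  helix_radius <- 2.3; rise <- 1.5; turn <- 100 * pi / 180
  if (spacing <= 2 * helix_radius)
    stop("helices overlap: spacing must exceed the helix diameter (",
         2 * helix_radius, " A)", call. = FALSE)
  circle_r <- spacing / (2 * sin(pi / 7))
  with_seed(seed, {
    xyz <- NULL
    resno <- integer(0)
    hel_rows <- NULL
    next_res <- 1L
    prev_end_xyz <- NULL
    for (h in 1:7) {
      ang <- 2 * pi * (h - 1) / 7
      cx <- circle_r * cos(ang); cy <- circle_r * sin(ang)
      len <- helix_lengths[h]
      dirz <- if (h %% 2 == 1) 1 else -1
      k <- seq_len(len) - 1
      hx <- cx + helix_radius * cos(turn * k + ang)
      hy <- cy + helix_radius * sin(turn * k + ang)
      hz <- dirz * (rise * k - rise * (len - 1) / 2)
      hxyz <- cbind(hx, hy, hz)
      if (!is.null(prev_end_xyz) && loop_len > 0) {
        # straight interpolated loop between helix ends
        frac <- seq_len(loop_len) / (loop_len + 1)
        lx <- outer(1 - frac, prev_end_xyz[1]) + outer(frac, hxyz[1, 1])
        ly <- outer(1 - frac, prev_end_xyz[2]) + outer(frac, hxyz[1, 2])
        lz <- outer(1 - frac, prev_end_xyz[3]) + outer(frac, hxyz[1, 3])
        xyz <- rbind(xyz, cbind(lx, ly, lz))
        resno <- c(resno, seq.int(next_res, next_res + loop_len - 1L))
        next_res <- next_res + loop_len
      }
      xyz <- rbind(xyz, hxyz)
      hel_rows <- rbind(hel_rows,
                        data.frame(helix = h, start = next_res,
                                   end = next_res + len - 1L))
      resno <- c(resno, seq.int(next_res, next_res + len - 1L))
      next_res <- next_res + len
      prev_end_xyz <- hxyz[nrow(hxyz), ]
    }
    if (jitter > 0)
      xyz <- xyz + matrix(stats::rnorm(length(xyz), sd = jitter),
                          ncol = 3)
    atoms <- data.frame(type = "ATOM", eleno = seq_along(resno),
                        elety = "CA", resid = "ALA", chain = "A",
                        resno = resno, x = xyz[, 1], y = xyz[, 2],
                        z = xyz[, 3], o = 1, b = 0, elesy = "C",
                        charge = 0, stringsAsFactors = FALSE)
    list(structure = structure3d(atoms, id = receptor_id),
         annotation = helix_annotation(receptor_id, hel_rows))
  })
}

# a compact rigid 5-atom toy ligand (HETATM chain L)
toy_ligand <- function(id = "LIG") {
  atoms <- data.frame(
    type = "HETATM", eleno = 1:5,
    elety = c("C1", "C2", "N1", "O1", "C3"),
    resid = "LIG", chain = "L", resno = 1L,
    x = c(0, 1.5, 2.6, 1.7, -1.1),
    y = c(0, 0.4, -0.4, 1.7, 1.0),
    z = c(0, 0, 0.6, -0.3, 0.5),
    o = 1, b = 0, elesy = c("C", "C", "N", "O", "C"), charge = 0,
    stringsAsFactors = FALSE)
  structure3d(atoms, id = id)
}

#' Generate a pose set with a planted binding-energy ordering
#'
#' Places rigid copies of a ligand along the outward axis through the
#' receptor's most exposed atom at increasing separation: under the
#' simplified force field the binding energy decays monotonically with
#' separation, so the pose with planted rank r has the r-th highest
#' binding energy.  The construction is verified after scoring; an
#' arrangement that fails to realize the requested ordering raises an
#' error.
#'
#' @param receptor A \code{\link{structure3d}}.
#' @param ligand Ligand template (default: a built-in 5-atom toy).
#' @param n Number of poses.
#' @param planted_ranking Integer permutation of 1..n;
#'   \code{planted_ranking[i]} is the intended BE rank of pose i.
#' @param seed Integer seed (orientation wobble).
#' @param params A \code{\link{simple_ff_params}}.
#' @param contact_dist Separation of the rank-1 pose from the anchor
#'   atom (Angstrom).
#' @param spacing Extra separation per rank step (Angstrom).
#' @return A scored \code{\link{pose_set}} with attribute
#'   \code{"planted_ranking"}.
#' @export
gen_pose_set <- function(receptor, ligand = toy_ligand(), n = 10,
                         planted_ranking = seq_len(n), seed = 1,
                         params = simple_ff_params(),
                         contact_dist = 5.5, spacing = 0.55) {
  stopifnot(inherits(receptor, "structure3d"),
            setequal(planted_ranking, seq_len(n)))
  with_seed(seed, {
    X <- coords(receptor)
    ctr <- colMeans(X)
    far <- X[which.max(rowSums(sweep(X, 2, ctr)^2)), ]
    u <- (far - ctr) / sqrt(sum((far - ctr)^2))
    poses <- vector("list", n)
    for (i in seq_len(n)) {
      r <- planted_ranking[i]
      lig <- ligand
      # small seeded orientation wobble
      ax <- stats::rnorm(3); ax <- ax / sqrt(sum(ax^2))
      lig <- move_pose(lig, axis = ax, angle = stats::runif(1, -0.03, 0.03))
      lcen <- colMeans(coords(lig))
      target <- far + (contact_dist + (r - 1) * spacing) * u
      poses[[i]] <- move_pose(lig, shift = target - lcen)
    }
    ps <- pose_set(receptor$id, ligand$id, poses, receptor,
                   params = params)
    got <- rank(-ps$scores$binding_energy, ties.method = "first")
    if (!identical(as.integer(got), as.integer(planted_ranking)))
      stop("planted ranking is unsatisfiable at this geometry",
           call. = FALSE)
    attr(ps, "planted_ranking") <- as.integer(planted_ranking)
    ps
  })
}

#' Generate a trajectory with planted jitter and distance drift
#'
#' Frame 1 is the base structure; later frames add i.i.d. Gaussian
#' jitter per atom per axis (no random walk) and, when \code{drift} is
#' given, displace residue \code{res_b} along the a-to-b axis so the
#' CA-CA distance grows linearly by \code{distance} Angstrom over the
#' trajectory.
#'
#' @param base A \code{\link{structure3d}}.
#' @param n_frames Number of frames (>= 1).
#' @param jitter Jitter sigma in Angstrom: a scalar, or a per-atom
#'   vector (e.g. to plant a mobile loop against rigid helices).
#' @param drift \code{NULL} or \code{list(res_a, res_b, distance)}.
#' @param seed Integer seed.
#' @param time_step Frame spacing in ps.
#' @return A \code{\link{trajectory3d}}.
#' @export
gen_trajectory <- function(base, n_frames = 100, jitter = 0.1,
                           drift = NULL, seed = 1, time_step = 1) {
  stopifnot(inherits(base, "structure3d"))
  if (n_frames < 1L) stop("n_frames must be >= 1", call. = FALSE)
  a <- base$atoms
  n_at <- nrow(a)
  sig <- rep_len(jitter, n_at)
  X0 <- as.matrix(a[, c("x", "y", "z")])
  drift_vec <- NULL; drift_rows <- NULL
  if (!is.null(drift)) {
    ia <- which(a$resno == drift$res_a & a$elety == "CA")
    ib <- which(a$resno == drift$res_b & a$elety == "CA")
    if (length(ia) != 1L || length(ib) != 1L)
      stop("drift residues must each carry exactly one CA",
           call. = FALSE)
    u <- X0[ib, ] - X0[ia, ]
    drift_vec <- u / sqrt(sum(u^2)) * drift$distance
    drift_rows <- which(a$resno == drift$res_b)
  }
  with_seed(seed, {
    frames <- vector("list", n_frames)
    frames[[1]] <- X0
    for (f in seq_len(n_frames)[-1]) {
      Xf <- X0 + matrix(stats::rnorm(3 * n_at), ncol = 3) * sig
      if (!is.null(drift_vec)) {
        frac <- (f - 1) / (n_frames - 1)
        Xf[drift_rows, ] <- sweep(Xf[drift_rows, , drop = FALSE], 2,
                                  frac * drift_vec, "+")
      }
      frames[[f]] <- Xf
    }
    trajectory3d(base, frames, time_step)
  })
}
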