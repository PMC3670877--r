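params <- simple_ff_params()

carbon_at <- function(...) {
  xyz <- rbind(...)
  data.frame(x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], elesy = "C",
             charge = 0, stringsAsFactors = FALSE)
}

test_that("the Lennard-Jones term matches its closed forms", {
  sig <- params$sigma[["C"]]
  eps <- params$epsilon[["C"]]
  expect_equal(nonbonded_energy(carbon_at(c(0, 0, 0)),
                                carbon_at(c(sig, 0, 0)), params), 0,
               tolerance = 1e-12)
  expect_equal(nonbonded_energy(carbon_at(c(0, 0, 0)),
                                carbon_at(c(2^(1 / 6) * sig, 0, 0)),
                                params), -eps, tolerance = 1e-12)
  # beyond the cutoff there is no interaction at all
  expect_identical(nonbonded_energy(carbon_at(c(0, 0, 0)),
                                    carbon_at(c(params$cutoff + 0.1, 0, 0)),
                                    params), 0)
  expect_error(nonbonded_energy(carbon_at(c(0, 0, 0)),
                                carbon_at(c(0, 0, 0)), params), "clash")
})

test_that("pair sums, charges and mixing match a hand-rolled oracle", {
  set.seed(41)
  for (k in 1:10) {
    a <- random_structure(5, spread = 4, charges = c(-0.5, 0, 0.3))
    b <- random_structure(4, spread = 4, charges = c(-0.2, 0, 0.4),
                          chain = "L")
    b$atoms[, c("x", "y", "z")] <-
      b$atoms[, c("x", "y", "z")] + 6  # keep the sets apart
    expect_equal(nonbonded_energy(a, b, params),
                 cross_energy_oracle(a, b, params), tolerance = 1e-9)
  }
})

test_that("binding energy equals minus the cross-interaction energy", {
  set.seed(42)
  for (k in 1:20) {
    rec <- random_structure(12, spread = 6,
                            charges = c(-0.4, 0, 0.2))
    lig <- random_structure(5, spread = 3, chain = "L",
                            charges = c(-0.1, 0, 0.3))
    lig$atoms$x <- lig$atoms$x + 14
    be <- binding_energy(rec, lig, params)
    expect_equal(be, -cross_energy_oracle(rec, lig, params),
                 tolerance = 1e-9)
    # symmetry in the two molecules
    expect_equal(binding_energy(lig, rec, params), be,
                 tolerance = 1e-9)
  }
})

test_that("binding energy is invariant under common rigid transforms and signs behave", {
  set.seed(43)
  rec <- random_structure(15, spread = 6)
  lig <- random_structure(4, spread = 2, chain = "L")
  lig$atoms$x <- lig$atoms$x + 11
  be <- binding_energy(rec, lig, params)
  for (k in 1:5) {
    R <- random_rotation_matrix(); t_vec <- stats::runif(3, -30, 30)
    be2 <- binding_energy(transform_structure(rec, R, t_vec),
                          transform_structure(lig, R, t_vec), params)
    expect_equal(be2, be, tolerance = 1e-9)
  }
  far <- lig; far$atoms$x <- far$atoms$x + 500
  expect_identical(binding_energy(rec, far, params), 0)
  # a severely clashed pose is strongly unfavorable (negative BE)
  clashed <- ca_structure(rbind(c(0.4, 0, 0)), chain = "L")
  origin <- ca_structure(rbind(c(0, 0, 0)))
  expect_lt(binding_energy(origin, clashed, params), -1e3)
})

test_that("pose displacement is the unsuperposed heavy-atom RMSD", {
  lig <- random_structure(6, seed = 44, chain = "L")
  expect_equal(pose_displacement(lig, lig), 0)
  shifted <- lig
  shifted$atoms$x <- shifted$atoms$x + 3
  expect_equal(pose_displacement(shifted, lig), 3, tolerance = 1e-12)
  set.seed(45)
  pert <- lig
  d <- matrix(stats::rnorm(18, sd = 0.7), ncol = 3)
  pert$atoms[, c("x", "y", "z")] <- pert$atoms[, c("x", "y", "z")] + d
  expect_equal(pose_displacement(pert, lig),
               sqrt(mean(rowSums(d^2))), tolerance = 1e-12)
  wrong <- lig; wrong$atoms$elety[1] <- "ZZ"
  expect_error(pose_displacement(wrong, lig), "topology")
})

test_that("rigid minimization never worsens the pose and finds the LJ minimum", {
  sig <- params$sigma[["C"]]
  rec1 <- ca_structure(rbind(c(0, 0, 0)))
  lig1 <- ca_structure(rbind(c(4.6, 0, 0)), chain = "L")
  out <- rigid_minimize(rec1, lig1, params, steps = 200)
  r_final <- sqrt(sum(coords(out)^2))
  expect_equal(r_final, 2^(1 / 6) * sig, tolerance = 0.02)
  expect_gte(attr(out, "be_final"), attr(out, "be_initial"))

  # a pose already at the minimum stays there
  at_min <- ca_structure(rbind(c(2^(1 / 6) * sig, 0, 0)), chain = "L")
  stay <- rigid_minimize(rec1, at_min, params, steps = 50)
  expect_equal(attr(stay, "be_final"), attr(stay, "be_initial"),
               tolerance = 1e-6)

  # zero steps returns the input pose untouched
  same <- rigid_minimize(rec1, lig1, params, steps = 0)
  expect_equal(coords(same), coords(lig1), ignore_attr = TRUE)

  # the minimized energy beats the starting energies of random restarts
  set.seed(46)
  rec <- random_structure(10, spread = 5)
  lig <- random_structure(4, spread = 2, chain = "L")
  lig$atoms$x <- lig$atoms$x + 12
  fin <- attr(rigid_minimize(rec, lig, params, steps = 80), "be_final")
  for (k in 1:10) {
    rnd <- lig
    rnd$atoms[, c("x", "y", "z")] <-
      rnd$atoms[, c("x", "y", "z")] +
      matrix(stats::runif(12, -2, 2), ncol = 3)
    be0 <- tryCatch(binding_energy(rec, rnd, params),
                    error = function(e) -Inf)
    expect_gte(fin, be0)
  }
})

test_that("rank-and-select matches a full-sort oracle including ties", {
  bundle <- gen_7tm_bundle(seed = 6)$structure
  base <- gen_pose_set(bundle, n = 10, seed = 7)
  set.seed(47)
  for (k in 1:100) {
    be <- round(stats::runif(10, -5, 5), sample(0:2, 1))  # forces ties
    ps <- with_binding_energies(base, be)
    got <- rank_and_select(ps, 3)$scores$pose_index
    oracle <- order(-be, seq_along(be))[1:3]
    expect_identical(got, oracle)
  }
  tied <- with_binding_energies(base, c(5, 5, rep(0, 8)))
  expect_identical(rank_and_select(tied, 2)$scores$pose_index, c(1L, 2L))
  expect_error(rank_and_select(base, 11), "exceeds")
  # selection is invariant to pose order given the tie rule
  perm <- sample(10)
  shuffled <- base
  shuffled$poses <- base$poses[perm]
  shuffled$scores <- base$scores[perm, ]
  expect_setequal(rank_and_select(shuffled, 3)$scores$pose_index,
                  rank_and_select(base, 3)$scores$pose_index)
})

test_that("cross-rescoring reproduces stored energies and ranks receptors", {
  bundle <- gen_7tm_bundle(seed = 8)$structure
  ps <- gen_pose_set(bundle, n = 6, seed = 9)
  top <- rank_and_select(ps, 3)
  m <- cross_rescore(top, list(orig = bundle), steps = 0)
  expect_equal(unname(m[, "orig"]), top$scores$binding_energy,
               tolerance = 1e-12)

  twins <- cross_rescore(top, list(a = bundle, b = bundle), steps = 0)
  expect_equal(twins[, "a"], twins[, "b"])

  # a receptor with a planted clash at the pose site scores worse
  clash <- bundle
  site <- colMeans(coords(top$poses[[1]]))
  extra <- clash$atoms[1, ]
  extra$eleno <- max(clash$atoms$eleno) + 1L
  extra$resno <- max(clash$atoms$resno) + 10L
  extra$x <- site[1]; extra$y <- site[2]; extra$z <- site[3] + 1.0
  clash$atoms <- rbind(clash$atoms, extra)
  both <- cross_rescore(top, list(clean = bundle, clashed = clash),
                        steps = 0)
  expect_true(all(both[, "clashed"] < both[, "clean"]))

  # frames must be shared unless a transform is supplied
  shifted <- transform_structure(bundle, diag(3), c(500, 0, 0))
  expect_error(cross_rescore(top, list(far = shifted), steps = 0),
               "shared frame")
  back <- cross_rescore(top, list(far = shifted), steps = 0,
                        transforms = list(far = list(
                          rotation = diag(3),
                          translation = c(500, 0, 0))))
  expect_equal(unname(back[, "far"]), top$scores$binding_energy,
               tolerance = 1e-9)
})

test_that("distance constraints evaluate min distances over selections", {
  rec <- ca_structure(rbind(c(0, 0, 0), c(10, 0, 0)))
  lig <- ca_structure(rbind(c(4, 0, 0)), chain = "L")
  spec <- list(list(ligand = list(chain = "L"),
                    receptor = list(resno = 1L), max_distance = 5))
  chk <- check_constraints(lig, rec, spec)
  expect_true(chk$satisfied)
  expect_equal(chk$min_dist, 4)
  spec_tight <- list(list(ligand = list(chain = "L"),
                          receptor = list(resno = 1L),
                          max_distance = 3.9))
  expect_false(check_constraints(lig, rec, spec_tight)$satisfied)

  # multi-atom selections: min over all pairs equals a brute-force scan
  set.seed(48)
  rec2 <- random_structure(20, spread = 8)
  lig2 <- random_structure(5, spread = 3, chain = "L")
  spec2 <- list(list(ligand = list(chain = "L"),
                     receptor = list(resno = 1:20), max_distance = 50))
  got <- check_constraints(lig2, rec2, spec2)$min_dist
  brute <- min(as.matrix(stats::dist(
    rbind(coords(lig2), coords(rec2))))[1:5, 6:25])
  expect_equal(got, brute, tolerance = 1e-12)

  expect_error(check_constraints(lig, rec, list(list(
    ligand = list(chain = "Z"), receptor = list(resno = 1L),
    max_distance = 5))), "matches no atoms")
  expect_error(check_constraints(lig, rec, list(list(
    ligand = list(consensus = 512), receptor = list(resno = 1L),
    max_distance = 5))), "unresolved")
})

test_that("consensus-number constraint selectors resolve per receptor", {
  # 30-residue helices so late-helix positions such as 725 exist
  bundle <- gen_7tm_bundle(helix_lengths = rep(30L, 7), seed = 10)
  map <- assign_consensus_numbers(bundle$annotation)
  spec <- read_constraint_spec(
    system.file("extdata", "constraints_buried_AT1.json",
                package = "angrec"))
  resolved <- resolve_constraint_consensus(spec, map)
  expect_null(resolved[[1]]$receptor$consensus)
  expect_equal(resolved[[1]]$receptor$resno,
               consensus_to_residue(map, 725L))
  expect_error(resolve_constraint_consensus(
    list(list(ligand = list(), receptor = list(consensus = 999),
              max_distance = 5)), map), "999")
})

test_that("constrained pose generation satisfies every constraint reproducibly", {
  bundle <- gen_7tm_bundle(seed = 11)$structure
  lig <- transform_structure(angrec:::toy_ligand(), diag(3),
                             c(60, 0, 0))
  anchor_res <- bundle$atoms$resno[which.max(bundle$atoms$x)]
  spec <- list(list(ligand = list(resno = 1L),
                    receptor = list(resno = anchor_res),
                    max_distance = 8))
  ps <- generate_constrained_poses(lig, bundle, spec, n = 5, seed = 12,
                                   max_attempts = 500)
  expect_length(ps$poses, 5L)
  for (p in ps$poses)
    expect_true(all(check_constraints(p, bundle, spec)$satisfied))
  expect_true(all(ps$scores$displacement > 0))

  again <- generate_constrained_poses(lig, bundle, spec, n = 5,
                                      seed = 12, max_attempts = 500)
  expect_identical(lapply(ps$poses, coords), lapply(again$poses, coords))
  other <- generate_constrained_poses(lig, bundle, spec, n = 5,
                                      seed = 13, max_attempts = 500)
  expect_false(identical(coords(ps$poses[[1]]), coords(other$poses[[1]])))

  impossible <- list(list(ligand = list(resno = 1L),
                          receptor = list(resno = anchor_res),
                          max_distance = 0.5))
  expect_error(generate_constrained_poses(lig, bundle, impossible,
                                          n = 1, seed = 12,
                                          max_attempts = 25),
               "tightest")
})
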