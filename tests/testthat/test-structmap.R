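test_that("PDB parsing keeps coordinates, selects altlocs, flags bad records", {
  one <- read_structure(text = paste0(
    "ATOM      1  CA  ALA A   1      11.104  13.207   2.100  1.00  0.00",
    "           C"))
  expect_equal(nrow(one$atoms), 1L)
  expect_equal(one$atoms$x, 11.104)
  expect_equal(one$atoms$resno, 1L)

  # two altlocs: the higher-occupancy B location must win
  alt <- read_structure(text = c(
    "ATOM      1  CA AALA A   1       0.000   0.000   0.000  0.40  0.00           C",
    "ATOM      2  CA BALA A   1       1.000   0.000   0.000  0.60  0.00           C"))
  expect_equal(nrow(alt$atoms), 1L)
  expect_equal(alt$atoms$x, 1.0)

  expect_error(read_structure(text = c(
    "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00  0.00           C",
    "ATOM      2  CA  ALA A   2       bad-coordinate-here")),
    "line 2")
  expect_error(read_structure(text = c(
    "MODEL     1",
    "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00  0.00           C",
    "ENDMDL")), "read_trajectory")
})

test_that("PDB write/read round-trips coordinates to three decimals", {
  s <- random_structure(25, seed = 9)
  f <- tempfile(fileext = ".pdb")
  write_structure(s, f)
  back <- read_structure(f)
  expect_equal(coords(back), coords(s), tolerance = 1e-3,
               ignore_attr = TRUE)
  expect_identical(back$atoms$elety, s$atoms$elety)
  expect_identical(back$atoms$resno, s$atoms$resno)
})

test_that("superposition removes rigid transforms exactly", {
  set.seed(21)
  bundle <- gen_7tm_bundle(seed = 2)$structure
  self <- kabsch_superpose(bundle, bundle)
  expect_equal(self$rmsd, 0, tolerance = 1e-9)
  for (k in 1:20) {
    R <- random_rotation_matrix()
    t_vec <- stats::runif(3, -20, 20)
    moved <- transform_structure(bundle, R, t_vec)
    sup <- kabsch_superpose(bundle, moved)
    expect_lt(sup$rmsd, 1e-6)
    expect_equal(det(sup$rotation), 1, tolerance = 1e-9)
  }
})

test_that("superposition RMSD matches the quaternion-method oracle", {
  set.seed(22)
  for (k in 1:20) {
    n <- sample(4:10, 1)
    P <- matrix(stats::runif(3 * n, -10, 10), ncol = 3)
    Q <- matrix(stats::runif(3 * n, -10, 10), ncol = 3)
    sup <- kabsch_superpose(ca_structure(P), ca_structure(Q))
    expect_equal(sup$rmsd, quaternion_rmsd(P, Q), tolerance = 1e-6)
    # symmetry of the minimized RMSD
    sup_rev <- kabsch_superpose(ca_structure(Q), ca_structure(P))
    expect_equal(sup$rmsd, sup_rev$rmsd, tolerance = 1e-6)
  }
})

test_that("superposition RMSD is invariant under a common rigid transform", {
  set.seed(23)
  P <- matrix(stats::runif(24, -10, 10), ncol = 3)
  Q <- P + matrix(stats::rnorm(24, sd = 0.6), ncol = 3)
  base <- kabsch_superpose(ca_structure(P), ca_structure(Q))$rmsd
  for (k in 1:5) {
    R <- random_rotation_matrix(); t_vec <- stats::runif(3, -15, 15)
    r2 <- kabsch_superpose(
      transform_structure(ca_structure(P), R, t_vec),
      transform_structure(ca_structure(Q), R, t_vec))$rmsd
    expect_equal(r2, base, tolerance = 1e-9)
  }
})

test_that("superposition rejects degenerate inputs", {
  P <- matrix(c(0, 0, 0, 1, 0, 0, 2, 0, 0, 3, 0, 0), ncol = 3,
              byrow = TRUE)
  expect_error(kabsch_superpose(ca_structure(P), ca_structure(P)),
               "collinear")
  two <- matrix(stats::runif(6), ncol = 3)
  expect_error(kabsch_superpose(ca_structure(two), ca_structure(two)),
               "at least 3")
})

test_that("pocket detection honours the cutoff boundary", {
  rec <- ca_structure(rbind(c(5.9, 0, 0), c(6.1, 0, 0), c(30, 30, 30)))
  hits <- pocket_residues(rec, c(0, 0, 0), cutoff = 6.0)
  expect_equal(hits$resno, 1L)
  expect_equal(hits$min_dist, 5.9, tolerance = 1e-9)
})

test_that("pocket detection equals the brute-force scan and is monotone", {
  rec <- random_structure(60, seed = 31, spread = 15)
  probe <- random_structure(8, seed = 32, spread = 4)
  for (cutoff in c(3, 6, 9)) {
    got <- pocket_residues(rec, probe, cutoff = cutoff)
    expect_identical(sort(paste(got$chain, got$resno)),
                     brute_pocket(rec, probe, cutoff))
  }
  small <- pocket_residues(rec, probe, cutoff = 4)
  large <- pocket_residues(rec, probe, cutoff = 8)
  expect_true(all(paste(small$chain, small$resno) %in%
                    paste(large$chain, large$resno)))
  expect_error(pocket_residues(rec, matrix(0, 0, 3), cutoff = 6),
               "empty probe")
})

test_that("category painting writes fixed codes into the B-factor column", {
  bundle <- gen_7tm_bundle(seed = 4)$structure
  resnos <- unique(bundle$atoms$resno)
  all_un <- annotate_structure(
    bundle, data.frame(resno = resnos, category = "unconserved"))
  expect_true(all(all_un$atoms$b == category_codes()[["unconserved"]]))

  one_trio <- annotate_structure(
    bundle, data.frame(resno = resnos[5], category = "trio_conserved"))
  expect_equal(sum(one_trio$atoms$b ==
                     category_codes()[["trio_conserved"]]), 1L)
  expect_true(all(one_trio$atoms$b[bundle$atoms$resno != resnos[5]] ==
                    category_codes()[["unmapped"]]))

  planted <- data.frame(
    resno = resnos,
    category = rep(c("gpcr_common", "all_conserved", "trio_conserved",
                     "pair_conserved", "unconserved"),
                   length.out = length(resnos)),
    stringsAsFactors = FALSE)
  tsv <- tempfile(fileext = ".tsv")
  pdb <- tempfile(fileext = ".pdb")
  annotate_structure(bundle, planted, pdb_out = pdb, tsv_out = tsv)
  side <- read.table(tsv, header = TRUE, sep = "\t",
                     stringsAsFactors = FALSE)
  expect_identical(side$category[match(planted$resno, side$resno)],
                   planted$category)
  back <- read_structure(pdb)
  expect_identical(back$atoms$b,
                   unname(category_codes()[planted$category[
                     match(back$atoms$resno, planted$resno)]]))
  expect_error(annotate_structure(
    bundle, data.frame(resno = 1, category = "no_such")), "unknown")
})
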