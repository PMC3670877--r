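ann_path <- system.file("extdata", "helix_annotation_synthetic.tsv",
                        package = "angrec")

test_that("consensus numbers follow the 100*helix + offset scheme", {
  ann <- read_helix_annotation(ann_path, "AT1")
  map <- assign_consensus_numbers(ann)
  h <- ann$helices
  # first residue of helix 1 is 101
  expect_equal(residue_to_consensus(map, h$start[1]), 101L)
  # twelfth residue of helix 5 is 512
  expect_equal(residue_to_consensus(map, h$start[5] + 11L), 512L)
  # loop residues have no consensus number
  expect_true(is.na(residue_to_consensus(map, h$end[1] + 1L)))
  expect_true(is.na(residue_to_consensus(map, h$start[1] - 1L)))
  # consecutive helix residues get consecutive numbers
  expect_equal(diff(residue_to_consensus(map, h$start[3]:(h$start[3] + 5L))),
               rep(1L, 5))
})

test_that("consensus numbering is injective and round-trips", {
  ann <- read_helix_annotation(ann_path, "AT1")
  map <- assign_consensus_numbers(ann)
  expect_false(anyDuplicated(map$consensus) > 0)
  expect_equal(consensus_to_residue(map,
                                    residue_to_consensus(map, map$resno)),
               map$resno)
  expect_true(is.na(consensus_to_residue(map, 999L)))
})

test_that("malformed helix annotations are rejected", {
  good <- data.frame(helix = 1:7, start = seq(1, 121, by = 20),
                     end = seq(15, 135, by = 20))
  expect_s3_class(helix_annotation("ok", good), "helix_annotation")
  bad_overlap <- good
  bad_overlap$start[2] <- good$end[1]  # helix 2 starts on helix 1's end
  expect_error(helix_annotation("x", bad_overlap), "overlap")
  expect_error(helix_annotation("x", good[1:6, ]), "seven")
  bad_rev <- good; bad_rev$end[3] <- bad_rev$start[3] - 1L
  expect_error(helix_annotation("x", bad_rev), "<=")
})

test_that("positions classify into the four conservation categories", {
  # equal basic residue in AT1/AT2, hydrophobic in MAS: the pattern at
  # the Lys contact position (consensus 512)
  expect_identical(
    classify_position(c(AT1 = "K", AT2 = "K", MAS = "I"), "."),
    "pair_conserved")
  # Asn in all three receptors but not the outgroup (consensus 725)
  expect_identical(
    classify_position(c(AT1 = "N", AT2 = "N", MAS = "N"), "L"),
    "trio_conserved")
  # identical letter in all four
  expect_identical(
    classify_position(c(AT1 = "F", AT2 = "F", MAS = "F"), "F"),
    "all_conserved")
  # the gpcr-common set overrides everything at that position
  expect_identical(
    classify_position(c(AT1 = "F", AT2 = "F", MAS = "F"), "F",
                      consensus_number = 517L, gpcr_common = c(517L)),
    "gpcr_common")
  expect_identical(
    classify_position(c(AT1 = "D", AT2 = "K", MAS = "G"), "."),
    "unconserved")
})

test_that("class symbols and letters share conservation through classes", {
  sym <- residue_class_scheme()$symbols
  # a family conserved as basic-class shares with a family fixed at Lys
  expect_identical(
    classify_position(c(AT1 = sym[["basic"]], AT2 = "K", MAS = "G"), "."),
    "pair_conserved")
  # aromatic His and aromatic Phe share; Met does not
  expect_identical(
    classify_position(c(AT1 = "H", AT2 = "F", MAS = "M"), "."),
    "pair_conserved")
  # hydrophobic class symbol in all three plus hydrophobic outgroup letter
  expect_identical(
    classify_position(c(AT1 = sym[["hydrophobic"]], AT2 = "L",
                        MAS = "V"), "I"),
    "all_conserved")
})

test_that("classification is invariant to swapping AT1 and AT2", {
  combos <- list(c(AT1 = "K", AT2 = "R", MAS = "G"),
                 c(AT1 = "H", AT2 = "F", MAS = "M"),
                 c(AT1 = "N", AT2 = "N", MAS = "N"))
  for (s in combos) {
    swapped <- c(AT1 = unname(s["AT2"]), AT2 = unname(s["AT1"]),
                 MAS = unname(s["MAS"]))
    expect_identical(classify_position(s, "."),
                     classify_position(swapped, "."))
  }
  expect_error(classify_position(c(AT1 = "K", AT2 = "K"), "."),
               "AT1, AT2, MAS")
})

test_that("the divergence report joins numbering, categories and annotations", {
  ann <- read_helix_annotation(ann_path, "AT1")
  maps <- list(AT1 = assign_consensus_numbers(ann),
               AT2 = assign_consensus_numbers(ann),
               MAS = assign_consensus_numbers(ann))
  positions <- data.frame(
    consensus = c(621L, 512L, 725L, 104L),
    AT1 = c("H", "K", "N", "D"),
    AT2 = c("F", "K", "N", "K"),
    MAS = c("M", "I", "N", "G"),
    outgroup = c(".", ".", "L", "."),
    stringsAsFactors = FALSE)
  functional <- data.frame(
    consensus = c(621L, 999L), AT1 = c("H", "A"), AT2 = c("F", "A"),
    MAS = c("M", "A"),
    effect = c("aromatic contact for the ligand C-terminal Phe", "none"),
    reference = c("curated", "curated"), stringsAsFactors = FALSE)
  expect_warning(
    rep_df <- divergence_report(positions, maps, functional),
    "999")
  expect_equal(rep_df$consensus, sort(rep_df$consensus))
  r621 <- rep_df[rep_df$consensus == 621L & rep_df$note == "", ]
  expect_true(r621$aromatic_in_AT1_AT2_only)
  expect_identical(r621$category, "pair_conserved")
  expect_match(r621$effect, "aromatic contact")
  expect_equal(r621$AT1_resno,
               consensus_to_residue(maps$AT1, 621L))
  r512 <- rep_df[rep_df$consensus == 512L, ]
  expect_identical(r512$category, "pair_conserved")
  expect_false(r512$aromatic_in_AT1_AT2_only)
  expect_identical(rep_df[rep_df$consensus == 725L, "category"],
                   "trio_conserved")
  expect_identical(rep_df[rep_df$consensus == 999L, "note"], "unmapped")
  # empty functional table: category rows only, no warning
  expect_silent(rep2 <- divergence_report(positions, maps))
  expect_equal(nrow(rep2), 4L)
  expect_true(all(rep2$note == ""))
})

test_that("a single planted pair-conserved column yields exactly one such row", {
  positions <- data.frame(
    consensus = c(101L, 102L, 103L),
    AT1 = c("A", "K", "N"), AT2 = c("A", "K", "N"),
    MAS = c("A", "G", "N"), outgroup = c("A", ".", "N"),
    stringsAsFactors = FALSE)
  rep_df <- divergence_report(positions, maps = list())
  expect_equal(sum(rep_df$category == "pair_conserved"), 1L)
  expect_equal(rep_df$consensus[rep_df$category == "pair_conserved"],
               102L)
})
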