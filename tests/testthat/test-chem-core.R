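# MMP fragmentation, series assembly and decomposition.

test_that("toluene and ethylbenzene form a single-site MMP", {
  aset <- analog_set(c("tol", "eb"), c("Cc1ccccc1", "CCc1ccccc1"))
  ed <- fragment_mmp(aset)
  expect_equal(nrow(ed), 1L)
  expect_setequal(c(ed$analog_a, ed$analog_b), c("tol", "eb"))
  expect_setequal(c(ed$substituent_a, ed$substituent_b), c("*C", "*CC"))
})

test_that("the four-analog neighborhood yields exactly the four MMP edges", {
  fx <- fig1_assembled()
  ed <- fragment_mmp(fx$aset)
  pairs <- sort(paste(ed$analog_a, ed$analog_b))
  # A-B and A-C (single-site changes), B-X and C-X; B-C and A-X differ at
  # both sites and must not pair
  expect_equal(pairs, c("A B", "A C", "B X", "C X"))
})

test_that("MMP output is invariant to compound order and matches the oracle", {
  spec <- landscape_spec(n_sites = 2, substituents_per_site = c(5, 2),
                         noise_sd = 0, occupancy = 1, seed = 31)
  fx <- make_series(spec)
  mem <- fx$series$members
  aset <- analog_set(mem$id, mem$smiles, mem$potency)
  ed <- fragment_mmp(aset)
  got <- sort(paste(ed$analog_a, ed$analog_b))
  labs <- fx$series$core$site_labels
  want <- oracle_mmp_pairs(as.matrix(mem[, labs]), mem$id)
  expect_equal(got, want)
  # permuted input: same edge set
  perm <- with_seed(5, sample(nrow(mem)))
  aset2 <- analog_set(mem$id[perm], mem$smiles[perm], mem$potency[perm])
  ed2 <- fragment_mmp(aset2)
  expect_equal(sort(paste(ed2$analog_a, ed2$analog_b)), got)
})

test_that("unparsable structures produce error records, not failures", {
  aset <- analog_set(c("good", "bad", "alsogood"),
                     c("CCO", "C1CC", "CCN"))
  expect_equal(nrow(aset), 2L)
  errs <- attr(aset, "errors")
  expect_length(errs, 1L)
  expect_equal(errs[[1]]$id, "bad")
  expect_equal(nrow(fragment_mmp(analog_set(character(0), character(0)))), 0L)
})

test_that("series assembly separates unrelated scaffolds", {
  spec1 <- landscape_spec(n_sites = 1, substituents_per_site = 4,
                          include_h = FALSE, noise_sd = 0, seed = 41)
  fx1 <- make_series(spec1)
  # second scaffold: cyclohexane-based analogs, no aromatic core
  smi2 <- c("CC1CCCCC1", "CCC1CCCCC1", "CCCC1CCCCC1")
  aset <- analog_set(
    c(fx1$series$members$id, paste0("B", 1:3)),
    c(fx1$series$members$smiles, smi2))
  ed <- fragment_mmp(aset)
  ser <- assemble_series(aset, ed)
  expect_length(ser, 2L)
  groups <- lapply(ser, function(s) sort(s$members$id))
  expect_true(any(vapply(groups, function(g)
    all(startsWith(g, "B")), logical(1))))
  expect_true(any(vapply(groups, function(g)
    all(startsWith(g, "EA")), logical(1))))
})

test_that("the four-analog set assembles into one two-site series", {
  fx <- fig1_assembled()
  expect_length(fx$series$core$site_labels, 2L)
  expect_equal(nrow(fx$series$members), 4L)
  expect_setequal(fx$series$members$id, c("A", "B", "C", "X"))
})

test_that("assembly recovers the generating series membership", {
  seeds <- c(51, 52, 53)
  cores <- c("Cc1ccccn1", "Cc1ccco1", "Cc1cccs1")
  sets <- lapply(seq_along(seeds), function(i)
    make_series(landscape_spec(n_sites = 2, substituents_per_site = 3,
                               include_h = FALSE, noise_sd = 0,
                               core_smiles = cores[i], seed = seeds[i])))
  # make ids unique across the three generators
  all_ids <- character(0); all_smi <- character(0); truth_label <- character(0)
  for (i in seq_along(sets)) {
    mem <- sets[[i]]$series$members
    ids <- paste0("G", i, "_", mem$id)
    all_ids <- c(all_ids, ids); all_smi <- c(all_smi, mem$smiles)
    truth_label <- c(truth_label, rep(paste0("G", i), nrow(mem)))
  }
  aset <- analog_set(all_ids, all_smi)
  ser <- assemble_series(aset, fragment_mmp(aset))
  # generated from one shared grammar: series can merge only if cores
  # coincide, which the per-seed substituent draws make distinct
  got <- lapply(ser, function(s) sort(s$members$id))
  want <- lapply(split(all_ids, truth_label), sort)
  expect_setequal(lapply(got, paste, collapse = ","),
                  lapply(want, paste, collapse = ","))
})

test_that("decompose and recompose are inverse on series members", {
  spec <- landscape_spec(n_sites = 3, substituents_per_site = c(3, 2, 2),
                         noise_sd = 0, occupancy = 1, seed = 61)
  fx <- make_series(spec)
  ser <- fx$series
  for (i in seq_len(nrow(ser$members))) {
    d <- decompose(ser$members$smiles[i], ser)
    expect_named(d, ser$core$site_labels)
    expect_identical(unname(recompose(ser, d)), ser$members$key[i])
    # the recovered table matches the generating assignment
    expect_identical(unname(d),
                     unname(unlist(ser$members[i, ser$core$site_labels])))
  }
  # core equal to the analog itself: all-H decomposition
  dH <- decompose(ser$core$coreH_key, ser)
  expect_true(all(dH == "H"))
  # non-member errors out
  expect_error(decompose("CCCCCCCC", ser), "does not decompose")
})

test_that("every MMP edge differs at exactly the annotated site", {
  fx <- fig1_assembled()
  labs <- fx$series$core$site_labels
  for (r in seq_len(nrow(fx$network))) {
    da <- decompose(with(fx$series$members,
                         smiles[id == fx$network$analog_a[r]]), fx$series)
    db <- decompose(with(fx$series$members,
                         smiles[id == fx$network$analog_b[r]]), fx$series)
    diff_sites <- labs[da != db]
    expect_identical(diff_sites, fx$network$site[r])
  }
})

test_that("file readers round-trip compound sets", {
  dir <- withr::local_tempdir()
  spec <- landscape_spec(n_sites = 2, substituents_per_site = 2,
                         noise_sd = 0, seed = 71)
  fx <- make_series(spec)
  paths <- write_fixture(fx, dir)
  smi <- read_smi(paths[["smi"]])
  expect_equal(nrow(smi), nrow(fx$series$members))
  expect_setequal(smi$key, fx$series$members$key)
  csv <- read_potency_csv(paths[["csv"]])
  expect_equal(csv$potency[match(fx$series$members$id, csv$id)],
               fx$series$members$potency)
  expect_error(read_potency_csv(paths[["smi"]]))
})

test_that("SDF input parses structures and potency tags", {
  # hand-written minimal V2000 record for ethanol
  rec <- c("ethanol", "  test", "",
           "  3  2  0  0  0  0  0  0  0  0999 V2000",
           "    0.0000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
           "    0.0000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
           "    0.0000    0.0000    0.0000 O   0  0  0  0  0  0  0  0  0  0  0  0",
           "  1  2  1  0  0  0  0",
           "  2  3  1  0  0  0  0",
           "M  END",
           "> <potency>", "7.25", "", "$$$$")
  tf <- withr::local_tempfile(fileext = ".sdf")
  writeLines(rec, tf)
  aset <- read_sdf(tf)
  expect_equal(nrow(aset), 1L)
  expect_identical(aset$key, canonical_smiles("CCO"))
  expect_equal(aset$potency, 7.25)
  expect_equal(aset$id, "ethanol")
})
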