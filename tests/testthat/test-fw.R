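# Free-Wilson neighborhoods, analog generation, additive prediction and
# the N score.

test_that("the textbook neighborhood is detected with target X", {
  fx <- fig1_assembled()
  nbhs <- fx$nbhs
  hubA <- nbhs[nbhs$hub == "A", ]
  expect_equal(nrow(hubA), 1L)
  expect_setequal(c(hubA$b, hubA$c), c("B", "C"))
  expect_true(hubA$target_exists)
  expect_equal(hubA$target_id, "X")
  # B and C never pair with each other in any neighborhood role
  expect_false(any(nbhs$hub == "A" & nbhs$b == nbhs$c))
})

test_that("edges at a single site yield no neighborhoods", {
  spec <- landscape_spec(n_sites = 1, substituents_per_site = 4,
                         noise_sd = 0, seed = 3)
  fx <- make_series(spec)
  net <- series_mmp_network(fx$series)
  expect_gt(nrow(net), 0)
  nbhs <- find_fw_nbhs(fx$series, net)
  expect_equal(nrow(nbhs), 0L)
})

test_that("neighborhood enumeration matches the exhaustive triple oracle", {
  for (counts in list(c(3, 3), c(4, 3), c(3, 2, 2))) {
    spec <- landscape_spec(n_sites = length(counts),
                           substituents_per_site = counts,
                           noise_sd = 0, occupancy = 1,
                           seed = 100 + sum(counts))
    fx <- make_series(spec)
    net <- series_mmp_network(fx$series)
    nbhs <- find_fw_nbhs(fx$series, net)
    labs <- fx$series$core$site_labels
    orc <- oracle_fw_nbhs(as.matrix(fx$series$members[, labs]),
                          fx$series$members$id)
    expect_equal(nrow(nbhs), orc$count)
    got <- sort(paste(nbhs$hub, pmin(nbhs$b, nbhs$c), pmax(nbhs$b, nbhs$c)))
    expect_equal(got, orc$keys)
  }
})

test_that("FW VA generation recovers held-out lattice cells exactly", {
  spec <- landscape_spec(n_sites = 2, substituents_per_site = 3,
                         noise_sd = 0, occupancy = 1, seed = 7)
  full <- make_series(spec)
  # drop two non-reference cells from the full lattice
  drop_cells <- c(5L, 9L)
  mem <- full$series$members[-drop_cells, ]
  ser <- full$series; ser$members <- mem
  net <- series_mmp_network(ser)
  nbhs <- find_fw_nbhs(ser, net)
  gen <- generate_fw_vas(ser, nbhs)
  dropped_keys <- full$series$members$key[drop_cells]
  expect_setequal(gen$fw_vas$key, dropped_keys)
  expect_equal(anyDuplicated(gen$fw_vas$key), 0L)
  # every generated VA differs from each of its hubs at exactly two sites
  st <- attr(gen$fw_vas, "substituents")
  labs <- ser$core$site_labels
  for (r in seq_len(nrow(gen$fw_vas))) {
    sig <- paste(unlist(st[r, labs]), collapse = "\r")
    hubs <- nbhs$hub[nbhs$target_sig == sig]
    expect_gte(length(hubs), 1L)
    for (h in hubs) {
      hrow <- unlist(mem[mem$id == h, labs])
      expect_equal(sum(hrow != unlist(st[r, labs])), 2L)
    }
  }
  # FW EAs are the members that occur as existing targets
  expect_setequal(gen$fw_eas$id, unique(nbhs$target_id[nbhs$target_exists]))
})

test_that("FW prediction is additive transfer, averaged over neighborhoods", {
  fx <- fig1_assembled()
  pot <- stats::setNames(fx$aset$potency, fx$aset$id)
  pr <- fw_predict("X", fx$nbhs, pot)
  expect_equal(pr$predicted_potency, 9.3)
  expect_equal(pr$n_nbhs, 1L)
  # zero deltas: prediction equals the hub potency
  pot0 <- c(A = 8.4, B = 8.4, C = 8.4, X = NA)
  pr0 <- fw_predict("X", fx$nbhs, pot0)
  expect_equal(pr0$predicted_potency, 8.4)
  # mean contract over multiple neighborhoods
  nbhs2 <- rbind(fx$nbhs[fx$nbhs$hub == "A", ], fx$nbhs[fx$nbhs$hub == "A", ])
  nbhs2$b[2] <- "C"; nbhs2$c[2] <- "B"  # second NBH with values swapped
  pot2 <- c(A = 8, B = 7.5, C = 7.5)
  pr2 <- fw_predict(nbhs2$target_sig[1], nbhs2, pot2)
  expect_equal(pr2$n_nbhs, 2L)
  expect_equal(pr2$predicted_potency, mean(c(7, 7)))
  # errors: unknown target, missing potency
  expect_error(fw_predict("nope", fx$nbhs, pot), "no Free-Wilson")
  expect_error(fw_predict("X", fx$nbhs, pot[c("A", "B")]), "C")
})

test_that("prediction is symmetric in the two partners", {
  fx <- fig1_assembled()
  pot <- stats::setNames(fx$aset$potency, fx$aset$id)
  sw <- fx$nbhs
  tmp <- sw$b; sw$b <- sw$c; sw$c <- tmp
  for (t in unique(fx$nbhs$target_sig)) {
    expect_equal(fw_predict(t, sw, pot)$predicted_potency,
                 fw_predict(t, fx$nbhs, pot)$predicted_potency)
  }
})

test_that("additive landscapes are reproduced exactly (FW consistency)", {
  for (sd_seed in c(11, 12)) {
    spec <- landscape_spec(n_sites = 3, substituents_per_site = c(3, 3, 2),
                           noise_sd = 0, occupancy = 1, seed = sd_seed)
    fx <- make_series(spec)
    net <- series_mmp_network(fx$series)
    nbhs <- find_fw_nbhs(fx$series, net)
    pred <- virtualize_and_predict_eas(fx$series, nbhs)
    expect_gt(nrow(pred), 0)
    expect_lt(max(abs(pred$true_potency - pred$predicted)), 1e-9)
    expect_equal(r_squared(pred$true_potency, pred$predicted), 1)
  }
})

test_that("generation output has set semantics (order independence)", {
  spec <- landscape_spec(n_sites = 2, substituents_per_site = 3,
                         noise_sd = 0, occupancy = 8 / 9, seed = 7)
  fx <- make_series(spec)
  net <- series_mmp_network(fx$series)
  nbhs <- find_fw_nbhs(fx$series, net)
  perm <- with_seed(2, sample(nrow(nbhs)))
  g1 <- generate_fw_vas(fx$series, nbhs)
  g2 <- generate_fw_vas(fx$series, nbhs[perm, ])
  expect_setequal(g1$fw_vas$key, g2$fw_vas$key)
  expect_setequal(g1$fw_eas$id, g2$fw_eas$id)
})

test_that("the N score follows its definition and limits", {
  expect_equal(score_fw_saturation(3, 3), 0)     # one NBH per FW EA
  expect_equal(score_fw_saturation(2, 4), 0.5)
  expect_true(is.na(score_fw_saturation(0, 0)))
  expect_error(score_fw_saturation(5, 4), "exceeds")
  # multiplicities 1..10: N = 1 - 10 / 55
  expect_equal(score_fw_saturation(10, sum(1:10)), 1 - 10 / 55)
  # monotone in multiplicity at fixed FW EA count
  ns <- vapply(10:20, function(k) score_fw_saturation(10, k), numeric(1))
  expect_true(all(diff(ns) > 0))
  # consistency with a constructed series
  spec <- landscape_spec(n_sites = 2, substituents_per_site = 3,
                         noise_sd = 0, occupancy = 1, seed = 7)
  fx <- make_series(spec)
  nbhs <- find_fw_nbhs(fx$series, series_mmp_network(fx$series))
  n_ea <- length(unique(nbhs$target_id[nbhs$target_exists]))
  n_nbh <- sum(nbhs$target_exists)
  expect_equal(score_fw_saturation(n_ea, n_nbh), 1 - n_ea / n_nbh)
})

test_that("virtual candidates are ranked and the held-out optimum wins", {
  spec <- landscape_spec(n_sites = 2, substituents_per_site = 4,
                         noise_sd = 0, occupancy = 1, seed = 43)
  full <- make_series(spec)
  # hold out the single best lattice cell
  best <- which.max(full$truth$potency)
  ser <- full$series
  ser$members <- ser$members[ser$members$key != full$truth$smiles[best], ]
  net <- series_mmp_network(ser)
  nbhs <- find_fw_nbhs(ser, net)
  cand <- fw_predict_vas(ser, nbhs)
  expect_gt(nrow(cand), 0)
  expect_equal(cand$key[1], full$truth$smiles[best])
  expect_equal(cand$predicted[1], full$truth$potency[best], tolerance = 1e-9)
  expect_true(all(diff(cand$predicted) <= 0))
})
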