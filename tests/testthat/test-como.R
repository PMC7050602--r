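# Diagnostic VA enumeration, reference space, neighborhoods and the
# C / D / S / P scores.

test_that("VA enumeration caps at the achievable unique population", {
  spec <- landscape_spec(n_sites = 1, substituents_per_site = 2,
                         include_h = TRUE, noise_sd = 0, seed = 3)
  fx <- make_series(spec)
  pool <- structure(list(fragments = "*C(=O)NCC(F)(F)F", source_tag = "t"),
                    class = "substituent_pool")
  # one fragment, one site, H frequency 1/2: at most 1 new unique VA
  expect_warning(
    vas <- enumerate_diagnostic_vas(fx$series, pool, n_va = 5, seed = 1),
    "supports only")
  expect_equal(nrow(vas), 1L)
  expect_false(vas$key %in% fx$series$members$key)
})

test_that("hydrogen likelihood at a site tracks the EA frequency", {
  # series with H everywhere at R2
  spec <- landscape_spec(n_sites = 2, substituents_per_site = c(6, 1),
                         include_h = TRUE, noise_sd = 0, seed = 5)
  fx <- make_series(spec)
  expect_true(all(fx$series$members$R2 == "H"))
  pool <- make_pool(40, seed = 9)
  vas <- suppressWarnings(
    enumerate_diagnostic_vas(fx$series, pool, n_va = 60, seed = 2))
  st <- attr(vas, "substituents")
  expect_true(all(st$R2 == "H"))
  # and at a site with zero H frequency, H never appears
  expect_true(all(st$R1 != "H"))
})

test_that("VA enumeration is deterministic given the seed", {
  spec <- landscape_spec(n_sites = 2, substituents_per_site = 3,
                         noise_sd = 0, seed = 7)
  fx <- make_series(spec)
  pool <- make_pool(60, seed = 11)
  v1 <- enumerate_diagnostic_vas(fx$series, pool, n_va = 25, seed = 4)
  v2 <- enumerate_diagnostic_vas(fx$series, pool, n_va = 25, seed = 4)
  expect_identical(v1$key, v2$key)
  v3 <- enumerate_diagnostic_vas(fx$series, pool, n_va = 25, seed = 5)
  expect_false(identical(v1$key, v3$key))
  # never identical to an existing analog
  expect_length(intersect(v1$key, fx$series$members$key), 0L)
})

test_that("reference space is z-normalized over the joint population", {
  spec <- landscape_spec(n_sites = 2, substituents_per_site = 3,
                         noise_sd = 0, seed = 13)
  fx <- make_series(spec)
  eas <- analog_set(fx$series$members$id, fx$series$members$key,
                    fx$series$members$potency)
  pool <- make_pool(60, seed = 11)
  vas <- enumerate_diagnostic_vas(fx$series, pool, n_va = 40, seed = 1)
  sp <- build_reference_space(eas, vas)
  expect_equal(dim(sp$coords), c(nrow(eas) + nrow(vas), 7L))
  expect_equal(unname(colMeans(sp$coords)), rep(0, 7), tolerance = 1e-9)
  expect_equal(unname(apply(sp$coords, 2, stats::var)), rep(1, 7),
               tolerance = 1e-9)
  # duplicate structure: identical coordinates (bypass the analog_set
  # dedup: the space only needs id/key columns)
  dup <- data.frame(id = c("d1", "d2"),
                    key = rep(fx$series$members$key[1], 2))
  sp2 <- build_reference_space(dup, vas)
  expect_equal(sp2$coords[1, ], sp2$coords[2, ])
  # zero-variance descriptor (ring count identical): warned, scale 1
  same <- analog_set(c("a", "b"), c("CCO", "CCN"))
  expect_warning(sp3 <- build_reference_space(same, same[0, ]),
                 "zero-variance")
  expect_true(all(is.finite(sp3$coords)))
})

test_that("NBH membership matches brute-force distance thresholding", {
  spec <- landscape_spec(n_sites = 2, substituents_per_site = 4,
                         noise_sd = 0, seed = 17)
  fx <- make_series(spec)
  eas <- analog_set(fx$series$members$id, fx$series$members$key,
                    fx$series$members$potency)
  pool <- make_pool(80, seed = 19)
  vas <- enumerate_diagnostic_vas(fx$series, pool, n_va = 100, seed = 3)
  sp <- build_reference_space(eas, vas)
  for (radius in c(0.5, 1, 2)) {
    nbh <- compute_nbh(sp, radius)
    ea <- sp$coords[sp$is_ea, , drop = FALSE]
    va <- sp$coords[!sp$is_ea, , drop = FALSE]
    for (i in seq_len(nrow(va))) for (j in seq_len(nrow(ea))) {
      expect_identical(unname(nbh$membership[i, j]),
                       sqrt(sum((va[i, ] - ea[j, ])^2)) <= radius)
    }
  }
  # tiny radius: only exactly-coincident coordinate pairs remain members
  ea <- sp$coords[sp$is_ea, , drop = FALSE]
  va <- sp$coords[!sp$is_ea, , drop = FALSE]
  coincident <- sum(outer(seq_len(nrow(va)), seq_len(nrow(ea)),
                          Vectorize(function(i, j)
                            all(abs(va[i, ] - ea[j, ]) < 1e-15))))
  expect_equal(sum(compute_nbh(sp, 1e-9)$membership), coincident)
  full <- compute_nbh(sp, 1e6)
  expect_true(all(full$membership))
  expect_true(all(full$m == nrow(eas)))
  expect_error(compute_nbh(sp, 0), "positive")
})

test_that("saturation scores follow the defining equations", {
  # constructed membership: 100 VAs, 50 in NBHs, each in exactly 2
  m <- matrix(FALSE, 100, 10)
  for (i in 1:50) m[i, c(1 + (i %% 5), 6 + (i %% 5))] <- TRUE
  nbh <- structure(list(radius = 1, membership = m, m = rowSums(m),
                        n_va = 100, n_ea = 10), class = "nbh_model")
  s <- score_saturation(nbh)
  expect_equal(s$C, 0.5)
  expect_equal(s$d_mean, 2)
  expect_equal(s$D, 0.5)
  expect_equal(s$S, 0.5)
  # empty membership: all zero, d_mean undefined
  nbh0 <- structure(list(radius = 1, membership = m & FALSE, m = rep(0, 100),
                         n_va = 100, n_ea = 10), class = "nbh_model")
  s0 <- score_saturation(nbh0)
  expect_equal(s0$C, 0); expect_equal(s0$S, 0); expect_true(is.na(s0$d_mean))
  # every in-NBH VA in exactly one NBH: D = 0 and S = 0 regardless of C
  m1 <- matrix(FALSE, 10, 4); m1[cbind(1:8, rep(1:4, 2))] <- TRUE
  nbh1 <- structure(list(radius = 1, membership = m1, m = rowSums(m1),
                         n_va = 10, n_ea = 4), class = "nbh_model")
  s1 <- score_saturation(nbh1)
  expect_equal(s1$C, 0.8)
  expect_equal(s1$d_mean, 1); expect_equal(s1$D, 0); expect_equal(s1$S, 0)
})

test_that("progression score follows the defining equations", {
  # one VA shared by two EAs with potencies 6 and 7
  m <- matrix(c(TRUE, TRUE), 1, 2, dimnames = list("VA1", c("E1", "E2")))
  nbh <- structure(list(radius = 1, membership = m, m = 2L,
                        n_va = 1, n_ea = 2), class = "nbh_model")
  p <- score_progression(nbh, c(E1 = 6, E2 = 7))
  expect_equal(p$P, 1)
  # m = 3 with potencies 5, 6, 9: mean pairwise |diff| = 8/3
  m3 <- matrix(TRUE, 1, 3, dimnames = list("VA1", c("E1", "E2", "E3")))
  nbh3 <- structure(list(radius = 1, membership = m3, m = 3L,
                         n_va = 1, n_ea = 3), class = "nbh_model")
  p3 <- score_progression(nbh3, c(E1 = 5, E2 = 6, E3 = 9))
  expect_equal(p3$P, 8 / 3)
  # all multiplicities 1: P undefined, flagged
  ms <- diag(TRUE, 3); dimnames(ms) <- list(paste0("VA", 1:3), paste0("E", 1:3))
  nbhs <- structure(list(radius = 1, membership = ms, m = rowSums(ms),
                         n_va = 3, n_ea = 3), class = "nbh_model")
  ps <- score_progression(nbhs, c(E1 = 5, E2 = 6, E3 = 9))
  expect_true(is.na(ps$P)); expect_false(ps$defined)
  # missing potency for a touched EA errors with its name
  expect_error(score_progression(nbh, c(E1 = 6)), "E2")
})

test_that("score properties hold on randomized fixtures", {
  with_seed(29, {
    for (rep in 1:40) {
      nbh <- random_nbh(n_va = sample(5:40, 1), n_ea = sample(2:8, 1),
                        p = stats::runif(1, 0, 0.5))
      s <- score_saturation(nbh)
      o <- oracle_saturation(nbh$membership)
      expect_equal(s$C, o$C)
      expect_equal(s$D, o$D)
      expect_equal(s$S, o$S)
      expect_true(s$C >= 0 && s$C <= 1)
      expect_true(s$D >= 0 && s$D < 1)
      expect_true(s$S >= 0 && s$S <= 1)
      if (s$C > 0 && s$D > 0) {
        expect_gte(s$S + 1e-12, min(s$C, s$D))
        expect_lte(s$S - 1e-12, max(s$C, s$D))
      }
      pot <- stats::setNames(stats::runif(nbh$n_ea, 4, 10),
                             colnames(nbh$membership))
      p <- score_progression(nbh, pot)
      po <- oracle_progression(nbh$membership, pot)
      if (is.na(po)) expect_true(is.na(p$P)) else expect_equal(p$P, po)
      # P is shift-invariant and scales linearly
      if (!is.na(po)) {
        p_shift <- score_progression(nbh, pot + 3)
        expect_equal(p_shift$P, p$P)
        p_scale <- score_progression(nbh, pot * 2)
        expect_equal(p_scale$P, 2 * p$P)
      }
    }
  })
})

test_that("shrinking the radius never increases coverage", {
  spec <- landscape_spec(n_sites = 2, substituents_per_site = 4,
                         noise_sd = 0, seed = 31)
  fx <- make_series(spec)
  eas <- analog_set(fx$series$members$id, fx$series$members$key,
                    fx$series$members$potency)
  pool <- make_pool(80, seed = 33)
  vas <- enumerate_diagnostic_vas(fx$series, pool, n_va = 80, seed = 6)
  sp <- build_reference_space(eas, vas)
  radii <- c(0.25, 0.5, 1, 2, 4)
  nn <- vapply(radii, function(r) sum(compute_nbh(sp, r)$m >= 1), numeric(1))
  expect_true(all(diff(nn) >= 0))
})

test_that("score_series produces a complete report", {
  spec <- landscape_spec(n_sites = 2, substituents_per_site = 3,
                         noise_sd = 0.1, seed = 37)
  fx <- make_series(spec)
  pool <- make_pool(60, seed = 39)
  rep <- score_series(fx$series, pool, n_va = 50, radius = 1.5, seed = 8)
  expect_s3_class(rep, "score_report")
  expect_equal(rep$counts$n_V, 50)
  expect_equal(rep$parameters$radius, 1.5)
  expect_equal(rep$parameters$seed, 8)
  df <- as.data.frame(rep)
  expect_equal(df$n_EA, 9)
  # harmonic-mean identity on the reported values
  if (rep$C + rep$D > 0)
    expect_equal(rep$S, 2 * rep$C * rep$D / (rep$C + rep$D))
})
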