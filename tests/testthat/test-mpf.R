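# Message-passing updates, five-feature extraction, and normalization.

fx <- fixture_molecules(alkane_lengths = integer(0))

test_that("initial state is all ones at stage 0", {
  st <- init_state(fx$methane)
  expect_identical(st$stage, 0L)
  expect_identical(st$values, rep(1, 5))
  expect_null(st$bond_term)
  expect_identical(init_state(fx$benzene)$values, rep(1, 12))
  expect_identical(init_state(fx$H2)$values, c(1, 1))
})

test_that("updates match hand-computed values on two- and five-atom molecules", {
  # H2: chi = 2.2 both, one single bond
  s1 <- mpf_update(fx$H2, init_state(fx$H2))
  expect_equal(s1$values, c(5.4, 5.4))
  expect_equal(s1$bond_term, c(1, 1))
  expect_equal(s1$atom_term, c(2.2, 2.2))
  expect_equal(s1$self_term, c(2.2, 2.2))
  s2 <- mpf_update(fx$H2, s1)
  expect_equal(s2$values, c(29.16, 29.16))

  # methane: C bonded to four H by single bonds
  m1 <- mpf_update(fx$methane, init_state(fx$methane))
  expect_equal(m1$values, c(15.35, rep(5.75, 4)))
  m2 <- mpf_update(fx$methane, m1)
  expect_equal(m2$values, c(112.7425, rep(67.1425, 4)), tolerance = 1e-12)

  expect_error(mpf_update(fx$H2, init_state(fx$methane)), "dimension")
})

test_that("atoms related by symmetry share values through all stages", {
  st <- init_state(fx$methane)
  for (l in 1:4) {
    st <- mpf_update(fx$methane, st)
    expect_equal(length(unique(st$values[2:5])), 1L)
    expect_false(st$values[1] == st$values[2])
  }
})

test_that("matrix featurizer agrees with the neighbour-walk oracle", {
  for (nm in names(fx)) {
    expect_equal(unclass(featurize(fx[[nm]])), oracle_featurize(fx[[nm]]),
                 tolerance = 1e-12, ignore_attr = TRUE, info = nm)
  }
  g <- make_alkane(10)
  expect_equal(unclass(featurize(g, cutoff = 3)), oracle_featurize(g, 3),
               tolerance = 1e-12, ignore_attr = TRUE)
  # terminal vs mid-chain carbons must differ after 3 rounds
  fm <- featurize(g)
  expect_false(fm[1, "H_bond"] == fm[5, "H_bond"])
})

test_that("H_MNE and H_SEN columns are exact electronegativity summaries", {
  fm <- featurize(fx$methane)
  expect_equal(fm[, "H_MNE"], c(2.20, rep(2.55, 4)))
  expect_equal(fm[, "H_SEN"], c(2.55, rep(2.20, 4)))
  expect_identical(unname(fm[, "H_SEN"]), fx$methane$chi)
  bz <- featurize(fx$benzene)
  expect_equal(max(abs(sweep(bz[1:6, ], 2, bz[1, ]))), 0)   # six C rows identical
  expect_equal(max(abs(sweep(bz[7:12, ], 2, bz[7, ]))), 0)  # six H rows identical
})

test_that("features are local: atoms identical within the cutoff radius match", {
  octane <- make_alkane(8)
  decane <- make_alkane(10)
  # terminal carbon (atom 1) sees identical <=3-bond neighbourhoods
  expect_identical(unclass(featurize(octane))[1, ], unclass(featurize(decane))[1, ])
  # mid-chain carbon of octane (atom 4) vs decane (atom 4): same environment
  expect_identical(unclass(featurize(octane))[4, ], unclass(featurize(decane))[4, ])
  # but once the radius reaches the far-end hydrogens the rows diverge
  expect_false(identical(unclass(featurize(octane, 8))[1, ],
                         unclass(featurize(decane, 8))[1, ]))
})

test_that("featurization rejects isolated atoms and bad cutoffs", {
  expect_error(featurize(molecular_graph("C")), class = "mpf_degenerate_input")
  expect_error(featurize(fx$H2, cutoff = 0))
})

test_that("normalization statistics pool atoms with population moments", {
  f1 <- featurize(fx$methane)
  f2 <- featurize(fx$ethane)
  q1 <- synthetic_charges(fx$methane)
  q2 <- synthetic_charges(fx$ethane)
  st <- fit_norm(list(f1, f2), list(q1, q2))
  expect_identical(st$n_atoms, 13L)

  # independent accumulation over the pooled 13 rows
  pool <- rbind(unclass(f1), unclass(f2))
  for (k in 1:5) {
    expect_equal(st$mean[k], sum(pool[, k]) / 13)
    expect_equal(st$sd[k], sqrt(sum((pool[, k] - st$mean[k])^2) / 13))
  }
  expect_equal(st$q_mean, mean(c(q1, q2)))

  # duplicating the training set leaves the statistics unchanged
  st2 <- fit_norm(list(f1, f2, f1, f2), list(q1, q2, q1, q2))
  expect_equal(st2$mean, st$mean)
  expect_equal(st2$sd, st$sd)
  expect_equal(st2$q_sd, st$q_sd)

  # constant columns are flagged (both H2 atoms are equivalent, so every
  # feature column is constant)
  expect_warning(fit_norm(featurize(fx$H2), synthetic_charges(fx$H2)),
                 "constant feature")
})

test_that("normalize is the exact z-score with a zero-variance guard", {
  f <- list(featurize(fx$ethanol), featurize(fx$acetamide))
  q <- c(synthetic_charges(fx$ethanol), synthetic_charges(fx$acetamide))
  st <- fit_norm(f, q)
  pool <- rbind(unclass(f[[1]]), unclass(f[[2]]))
  z <- normalize_features(pool, st)
  expect_equal(unname(colMeans(z)), rep(0, 5), tolerance = 1e-10)
  expect_equal(unname(apply(z, 2, function(x) sqrt(mean((x - mean(x))^2)))),
               rep(1, 5), tolerance = 1e-10)
  # centring: rows equal to the means map to zero
  expect_equal(unname(normalize_features(rbind(st$mean, st$mean), st)),
               matrix(0, 2, 5))
  # algebraic inverse
  back <- sweep(sweep(z, 2, st$sd, "*"), 2, st$mean, "+")
  expect_equal(unname(back), unname(pool), tolerance = 1e-12)
  # zero-variance column maps to zero, not NaN
  stc <- suppressWarnings(fit_norm(featurize(fx$H2), synthetic_charges(fx$H2)))
  zc <- normalize_features(featurize(fx$H2), stc)
  expect_true(all(is.finite(zc)))
  expect_true(all(zc == 0))
})

test_that("normalization statistics survive a JSON round trip", {
  f <- featurize(fx$ethanol)
  st <- fit_norm(f, synthetic_charges(fx$ethanol))
  path <- withr::local_tempfile(fileext = ".json")
  write_norm_stats(st, path)
  st2 <- read_norm_stats(path)
  expect_identical(st2$mean, st$mean)
  expect_identical(st2$sd, st$sd)
  expect_identical(st2$q_mean, st$q_mean)
  expect_identical(normalize_features(f, st2), normalize_features(f, st))
})
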