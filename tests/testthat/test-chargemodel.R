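# Network training, prediction, persistence, and the accuracy indicators.

fx <- fixture_molecules(alkane_lengths = integer(0))

small_model <- local({
  tr <- synthetic_set(40, synth_spec(6, sigma_noise = 0, seed = 11))
  train_charge_model(tr$graphs, tr$charges,
                     config = train_config(epochs = 10),
                     charge_type = "synthetic")
})

test_that("training is deterministic for fixed seeds", {
  tr <- synthetic_set(10, synth_spec(5, seed = 2))
  cfg <- train_config(epochs = 3, init_seed = 5, shuffle_seed = 9)
  m1 <- train_charge_model(tr$graphs, tr$charges, config = cfg)
  m2 <- train_charge_model(tr$graphs, tr$charges, config = cfg)
  expect_identical(m1$network$W, m2$network$W)
  expect_identical(m1$loss, m2$loss)
  p1 <- predict_charges(m1, fx$ethanol)
  p2 <- predict_charges(m2, fx$ethanol)
  expect_identical(p1$charge, p2$charge)
})

test_that("constant labels collapse to the label mean (zero target spread)", {
  tr <- synthetic_set(8, synth_spec(5, seed = 3))
  const <- lapply(tr$charges, function(q) rep(0.125, length(q)))
  m <- suppressWarnings(
    train_charge_model(tr$graphs, const, config = train_config(epochs = 2)))
  expect_equal(m$norm_stats$q_sd, 0)
  p <- predict_charges(m, fx$benzene)
  expect_equal(p$charge, rep(0.125, 12), tolerance = 1e-12)
})

test_that("denormalization is the exact affine inverse of the target z-score", {
  st <- small_model$norm_stats
  q <- unlist(lapply(fx[c("methane", "ethanol")], synthetic_charges))
  z <- (q - st$q_mean) / st$q_sd
  expect_equal(unname(z * st$q_sd + st$q_mean), unname(q), tolerance = 1e-12)
  # zeroed output layer with bias b predicts b*sd_Q + mean_Q everywhere
  m0 <- small_model
  L <- length(m0$network$W)
  m0$network$W[[L]][] <- 0
  m0$network$b[[L]] <- 0.7
  p <- predict_charges(m0, fx$neopentane)
  expect_equal(p$charge, rep(0.7 * st$q_sd + st$q_mean, 17), tolerance = 1e-12)
})

test_that("automorphic atoms get identical predicted charges", {
  p <- predict_charges(small_model, fx$benzene)
  expect_equal(length(unique(p$charge[1:6])), 1L)
  expect_equal(length(unique(p$charge[7:12])), 1L)
  pn <- predict_charges(small_model, fx$neopentane)
  expect_equal(max(pn$charge[2:5]) - min(pn$charge[2:5]), 0, tolerance = 1e-12)
})

test_that("prediction scales to molecules far larger than any training molecule", {
  big <- make_alkane(500)
  p <- predict_charges(small_model, big)
  expect_identical(nrow(p), big$n_atoms)
  # interior carbons more than 3 bonds from either end are all equivalent
  interior <- p$charge[5:496]
  expect_equal(max(interior) - min(interior), 0, tolerance = 1e-10)
  expect_false(isTRUE(all.equal(p$charge[1], p$charge[250])))
})

test_that("prediction refuses elements unseen in training", {
  sulfurous <- molecular_graph(c("S", "H", "H"),
                               data.frame(i = c(1, 1), j = c(2, 3), type = "single"))
  expect_error(predict_charges(small_model, sulfurous),
               class = "mpf_unsupported_element")
})

test_that("a saved model reloads and predicts bit-identically", {
  path <- withr::local_tempfile(fileext = ".mpf")
  save_charge_model(small_model, path)
  m2 <- load_charge_model(path)
  for (g in fx[c("methane", "benzene", "acetamide")]) {
    expect_identical(predict_charges(m2, g)$charge,
                     predict_charges(small_model, g)$charge)
  }
  expect_identical(m2$cutoff, small_model$cutoff)
  expect_identical(m2$bond_codes, small_model$bond_codes)
})

test_that("corrupted model files and bond-map mismatches are surfaced", {
  path <- withr::local_tempfile(fileext = ".mpf")
  save_charge_model(small_model, path)
  txt <- readLines(path, warn = FALSE)
  writeLines(substr(paste(txt, collapse = ""), 1, 200), path)
  expect_error(load_charge_model(path), class = "mpf_model_file_error")

  save_charge_model(small_model, path)
  other <- c(single = 9, double = 8, triple = 7, amide = 6, aromatic = 5)
  expect_warning(load_charge_model(path, bond_codes = other), "map wins")
  g <- molecular_graph(c("C", rep("H", 4)),
                       data.frame(i = 1, j = 2:5, type = "single"),
                       bond_codes = other)
  expect_warning(p <- predict_charges(small_model, g), "map wins")
  expect_identical(p$charge, predict_charges(small_model, fx$methane)$charge)
})

test_that("the seven indicators match brute-force definitions", {
  truth <- c(0.5, -0.2, 0.1, 0.3, -0.4)
  pred <- truth + c(1, 2, 3, 4, 5)
  tab <- evaluate_charges(pred, truth)
  expect_equal(tab$mae, 3)
  expect_equal(tab$medae, 3)
  expect_equal(tab$tl80ae, 4)  # highest error among the lowest 80% of five
  expect_equal(tab$rmse, sqrt(mean(c(1, 4, 9, 16, 25))))
  expect_equal(tab$r2, 1 - sum(c(1, 4, 9, 16, 25)) / sum((truth - mean(truth))^2))
  pct <- sort(100 * c(1, 2, 3, 4, 5) / abs(truth))
  expect_equal(tab$mdape, pct[3])
  expect_equal(tab$tl80pe, pct[4])

  perfect <- evaluate_charges(truth, truth)
  expect_equal(perfect$mae, 0)
  expect_equal(perfect$rmse, 0)
  expect_equal(perfect$r2, 1)

  shift <- evaluate_charges(truth + 0.1, truth)
  expect_equal(shift$mae, 0.1)
  expect_equal(shift$rmse, 0.1)
  expect_equal(shift$medae, 0.1)

  expect_error(evaluate_charges(1:3, 1:4), "lengths differ")
})

test_that("per-element rows and the zero-truth guard behave", {
  truth <- c(0.2, -0.1, 0, 0.4)
  pred <- truth + 0.01
  tab <- evaluate_charges(pred, truth, elements = c("C", "H", "C", "H"))
  expect_identical(tab$element, c("all", "C", "H"))
  # the zero-truth atom is excluded from percentage metrics only
  expect_equal(tab$n[tab$element == "all"], 4)
  expect_equal(tab$mdape[tab$element == "all"],
               median(100 * 0.01 / abs(truth[truth != 0])))
})
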