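# Dense charge-regression network: a 5-input, five x 50-node tanh hidden
# layer, 1-output MLP trained with Adam on the mean absolute error of
# z-scored charges. Prediction denormalizes with Q = Q_hat * sd_Q + mean_Q.

#' Training configuration
#'
#' Hyperparameters of the charge network. Defaults: Adam with learning rate
#' 0.001, beta1 0.9, beta2 0.999, epsilon 1e-7; MAE loss; 100 epochs; batch
#' size 16 (use 768 for very large training sets).
#'
#' @param epochs Number of passes over the training atoms.
#' @param batch_size Minibatch size.
#' @param lr,beta1,beta2,eps Adam parameters.
#' @param hidden Integer vector of hidden-layer widths.
#' @param init_seed,shuffle_seed Seeds for weight initialization and epoch
#'   shuffling; recorded in the saved model.
#' @return A `train_config` list.
#' @export
train_config <- function(epochs = 100L, batch_size = 16L, lr = 0.001,
                         beta1 = 0.9, beta2 = 0.999, eps = 1e-7,
                         hidden = rep(50L, 5L),
                         init_seed = 1L, shuffle_seed = 1L) {
  cfg <- list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
              lr = lr, beta1 = beta1, beta2 = beta2, eps = eps,
              hidden = as.integer(hidden),
              init_seed = as.integer(init_seed),
              shuffle_seed = as.integer(shuffle_seed))
  stopifnot(cfg$epochs > 0, cfg$batch_size > 0, cfg$lr > 0,
            cfg$beta1 > 0, cfg$beta2 > 0, cfg$eps > 0, all(cfg$hidden > 0))
  structure(cfg, class = "train_config")
}

.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

.init_network <- function(sizes, seed) {
  .with_seed(seed, {
    W <- vector("list", length(sizes) - 1L)
    b <- vector("list", length(sizes) - 1L)
    for (k in seq_along(W)) {
      fan_in <- sizes[k]; fan_out <- sizes[k + 1L]
      lim <- sqrt(6 / (fan_in + fan_out))  # Glorot uniform
      W[[k]] <- matrix(runif(fan_in * fan_out, -lim, lim), fan_in, fan_out)
      b[[k]] <- rep(0, fan_out)
    }
    list(W = W, b = b)
  })
}

# Row-independent forward pass used for prediction: every output element is
# accumulated over ascending input index with a single accumulator, so an
# atom's predicted charge depends only on its own feature row — atoms with
# bitwise-equal rows get bitwise-equal charges regardless of their position
# in the batch. (BLAS GEMM blocks rows and can round identical rows
# differently.)
.forward_det <- function(net, X) {
  n <- nrow(X)
  A <- X
  L <- length(net$W)
  for (k in seq_len(L)) {
    W <- net$W[[k]]
    Z <- matrix(net$b[[k]], n, ncol(W), byrow = TRUE)
    for (p in seq_len(nrow(W))) {
      Z <- Z + A[, p] * matrix(W[p, ], n, ncol(W), byrow = TRUE)
    }
    A <- if (k < L) tanh(Z) else Z
  }
  drop(A)
}

# Forward pass; returns activations per layer (A[[1]] is the input batch).
.forward <- function(net, X) {
  L <- length(net$W)
  A <- vector("list", L + 1L)
  A[[1L]] <- X
  for (k in seq_len(L)) {
    Z <- A[[k]] %*% net$W[[k]]
    Z <- sweep(Z, 2L, net$b[[k]], "+")
    A[[k + 1L]] <- if (k < L) tanh(Z) else Z
  }
  A
}

#' Train the raw regression network
#'
#' Low-level trainer on already-normalized feature rows and z-scored
#' targets: minibatch Adam on the mean absolute error, final-epoch weights
#' kept (no validation split or early stopping). Deterministic for fixed
#' seeds.
#'
#' @param X Numeric matrix, one normalized 5-feature row per atom.
#' @param y Numeric vector of z-scored target charges.
#' @param config A [train_config()].
#' @return List with `W`, `b` (weights), `sizes`, and `loss` (training MAE
#'   per epoch, on the normalized scale).
#' @export
train_network <- function(X, y, config = train_config()) {
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X)
  stopifnot(n >= 1L, length(y) == n)
  if (!all(is.finite(X)) || !all(is.finite(y))) stop("non-finite features or labels")
  sizes <- c(ncol(X), config$hidden, 1L)
  net <- .init_network(sizes, config$init_seed)
  L <- length(net$W)
  mW <- lapply(net$W, function(w) w * 0); vW <- mW
  mb <- lapply(net$b, function(bb) bb * 0); vb <- mb
  t_step <- 0L
  loss <- numeric(config$epochs)
  .with_seed(config$shuffle_seed, {
    for (ep in seq_len(config$epochs)) {
      perm <- sample.int(n)
      abs_sum <- 0
      for (start in seq(1L, n, by = config$batch_size)) {
        idx <- perm[start:min(start + config$batch_size - 1L, n)]
        A <- .forward(net, X[idx, , drop = FALSE])
        err <- drop(A[[L + 1L]]) - y[idx]
        abs_sum <- abs_sum + sum(abs(err))
        # MAE gradient wrt the linear output
        dZ <- matrix(sign(err) / length(idx), ncol = 1L)
        t_step <- t_step + 1L
        corr1 <- 1 - config$beta1^t_step
        corr2 <- 1 - config$beta2^t_step
        for (k in L:1L) {
          dW <- crossprod(A[[k]], dZ)
          db <- colSums(dZ)
          if (k > 1L) {
            dA <- dZ %*% t(net$W[[k]])
            dZ <- dA * (1 - A[[k]]^2)  # tanh'
          }
          mW[[k]] <- config$beta1 * mW[[k]] + (1 - config$beta1) * dW
          vW[[k]] <- config$beta2 * vW[[k]] + (1 - config$beta2) * dW^2
          mb[[k]] <- config$beta1 * mb[[k]] + (1 - config$beta1) * db
          vb[[k]] <- config$beta2 * vb[[k]] + (1 - config$beta2) * db^2
          net$W[[k]] <- net$W[[k]] -
            config$lr * (mW[[k]] / corr1) / (sqrt(vW[[k]] / corr2) + config$eps)
          net$b[[k]] <- net$b[[k]] -
            config$lr * (mb[[k]] / corr1) / (sqrt(vb[[k]] / corr2) + config$eps)
        }
      }
      loss[ep] <- abs_sum / n
    }
  })
  list(W = net$W, b = net$b, sizes = sizes, loss = loss)
}

#' Train a charge model on molecular graphs
#'
#' End-to-end training: featurizes every molecule at `cutoff`, fits the
#' normalization statistics on the pooled training atoms, z-scores features
#' and charges, and trains the dense network. The returned model carries
#' everything needed for prediction on new molecules: weights, normalization
#' statistics, cutoff, bond-code map and the element set seen in training.
#'
#' @param graphs A `molecular_graph` or list of them.
#' @param charges Per-atom charge labels in e: a vector aligned with the
#'   pooled atoms, or a list of vectors parallel to `graphs`. If `NULL`,
#'   charges attached to the graphs (e.g. from a mol2 charge column) are
#'   used.
#' @param cutoff Message-passing cutoff (default 3).
#' @param config A [train_config()].
#' @param charge_type Free-form label for the charge definition the labels
#'   follow (e.g. "Mulliken", "Hirshfeld", "synthetic").
#' @return A `charge_model`.
#' @export
train_charge_model <- function(graphs, charges = NULL, cutoff = 3L,
                               config = train_config(),
                               charge_type = "unspecified") {
  if (inherits(graphs, "molecular_graph")) graphs <- list(graphs)
  stopifnot(length(graphs) >= 1L,
            all(vapply(graphs, inherits, logical(1), "molecular_graph")))
  if (is.null(charges)) {
    charges <- lapply(graphs, `[[`, "charges")
    if (any(vapply(charges, is.null, logical(1)))) {
      stop("no `charges` given and not every graph carries charge labels")
    }
  }
  if (is.list(charges)) charges <- unlist(charges, use.names = FALSE)
  feats <- lapply(graphs, featurize, cutoff = cutoff)
  stats <- fit_norm(feats, charges)
  Xn <- normalize_features(do.call(rbind, lapply(feats, unclass)), stats)
  y <- as.numeric(charges)
  yn <- if (stats$q_sd > 0) (y - stats$q_mean) / stats$q_sd else rep(0, length(y))
  fit <- train_network(Xn, yn, config)
  structure(
    list(format_version = 1L,
         network = fit[c("W", "b", "sizes")],
         loss = fit$loss,
         norm_stats = stats,
         cutoff = as.integer(cutoff),
         bond_codes = graphs[[1L]]$bond_codes,
         elements = sort(unique(unlist(lapply(graphs, `[[`, "elements")))),
         charge_type = charge_type,
         config = unclass(config)),
    class = "charge_model"
  )
}

#' @export
print.charge_model <- function(x, ...) {
  cat(sprintf(
    "<charge_model> %s charges; cutoff %d; elements {%s}; trained on %d atoms (final MAE %.4g)\n",
    x$charge_type, x$cutoff, paste(x$elements, collapse = ", "),
    x$norm_stats$n_atoms, utils::tail(x$loss, 1)))
  invisible(x)
}

# Re-express a graph's topology codes in the model's bond-code map.
.recode_topology <- function(graph, codes) {
  lab <- names(graph$bond_codes)[match(graph$topology, graph$bond_codes)]
  new <- graph$topology
  nz <- !is.na(lab)
  new[nz] <- codes[lab[nz]]
  graph$topology <- new
  graph$bond_codes <- codes
  graph
}

#' Predict per-atom partial charges
#'
#' Featurizes the molecule with the model's stored cutoff and normalization
#' statistics, runs each atom's 5-feature row through the network, and
#' denormalizes the output: `Q = Q_hat * sd_Q + mean_Q`. Molecule size is
#' unlimited; prediction time grows linearly with the number of atoms.
#'
#' @param model A `charge_model`.
#' @param graph A `molecular_graph`. Every element must appear in the
#'   model's training element set (extrapolation to unseen elements is
#'   refused).
#' @return Data frame with columns `atom`, `element`, `q_hat` (normalized
#'   network output) and `charge` (predicted partial charge, units of e).
#' @export
predict_charges <- function(model, graph) {
  stopifnot(inherits(model, "charge_model"), inherits(graph, "molecular_graph"))
  unseen <- setdiff(unique(graph$elements), model$elements)
  if (length(unseen)) {
    stop(errorCondition(
      sprintf("element(s) not in the model's training set: %s",
              paste(unseen, collapse = ", ")),
      class = c("mpf_unsupported_element", "error", "condition")
    ))
  }
  if (!identical(graph$bond_codes[names(model$bond_codes)],
                 model$bond_codes)) {
    warning("graph uses a different bond-code map than the model; the model's map wins")
    graph <- .recode_topology(graph, model$bond_codes)
  }
  fm <- featurize(graph, cutoff = model$cutoff)
  Xn <- normalize_features(fm, model$norm_stats)
  q_hat <- .forward_det(model$network, Xn)
  data.frame(atom = seq_len(graph$n_atoms), element = graph$elements,
             q_hat = q_hat,
             charge = q_hat * model$norm_stats$q_sd + model$norm_stats$q_mean)
}

#' Save / load a charge model
#'
#' The model file is JSON: a metadata header (format version, charge type,
#' cutoff, bond-code map, element set, normalization statistics, training
#' configuration) plus the weight arrays at full precision, so a reloaded
#' model predicts bit-identically.
#'
#' @param model A `charge_model`.
#' @param path File path (conventionally `.mpf`).
#' @return `save_charge_model` returns `path` invisibly; `load_charge_model`
#'   returns the `charge_model`.
#' @export
save_charge_model <- function(model, path) {
  stopifnot(inherits(model, "charge_model"))
  x <- unclass(model)
  x$norm_stats <- unclass(x$norm_stats)
  x$bond_codes <- as.list(x$bond_codes)  # keep names in JSON
  # I(17) significant digits round-trips IEEE doubles exactly
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @param bond_codes Optional session bond-code map to compare against the
#'   model's stored map; on mismatch a warning is issued and the model's own
#'   map wins.
#' @rdname save_charge_model
#' @export
load_charge_model <- function(path, bond_codes = NULL) {
  x <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                error = function(e) NULL)
  if (is.null(x) || !identical(as.integer(x$format_version), 1L) ||
      is.null(x$network) || is.null(x$norm_stats)) {
    stop(errorCondition(
      sprintf("'%s' is not a readable charge-model file", path),
      class = c("mpf_model_file_error", "error", "condition")
    ))
  }
  x$network$W <- lapply(x$network$W, as.matrix)
  x$network$b <- lapply(x$network$b, as.numeric)
  x$norm_stats <- structure(
    x$norm_stats[c("feature_names", "mean", "sd", "q_mean", "q_sd", "n_atoms")],
    class = "norm_stats")
  x$bond_codes <- vapply(x$bond_codes, as.numeric, numeric(1))
  x$norm_stats[c("mean", "sd", "q_mean", "q_sd")] <-
    lapply(x$norm_stats[c("mean", "sd", "q_mean", "q_sd")], as.numeric)
  model <- structure(x, class = "charge_model")
  if (!is.null(bond_codes) &&
      !identical(bond_codes[names(model$bond_codes)], model$bond_codes)) {
    warning("model was trained with a different bond-code map than the session config; the model's own map wins")
  }
  model
}

.tl80 <- function(x) {
  # nearest-rank highest value among the lowest 80%
  x <- sort(x)
  x[max(1L, ceiling(0.8 * length(x)))]
}

.indicator_row <- function(pred, truth) {
  err <- pred - truth
  abs_err <- abs(err)
  keep <- abs(truth) >= 1e-8  # percentage metrics undefined at zero truth
  pct <- 100 * abs_err[keep] / abs(truth[keep])
  ss_tot <- sum((truth - mean(truth))^2)
  data.frame(
    n = length(truth),
    mae = mean(abs_err),
    medae = stats::median(abs_err),
    tl80ae = .tl80(abs_err),
    mdape = if (length(pct)) stats::median(pct) else NA_real_,
    tl80pe = if (length(pct)) .tl80(pct) else NA_real_,
    r2 = if (ss_tot > 0) 1 - sum(err^2) / ss_tot else NA_real_,
    rmse = sqrt(mean(err^2))
  )
}

#' Accuracy indicator table
#'
#' Computes the seven standard indicators — mean absolute error, median
#' absolute error, top-low-80% absolute error (TL80AE: the highest absolute
#' error among the lowest 80% of errors, nearest-rank), median absolute
#' percentage error, top-low-80% percentage error (TL80PE), coefficient of
#' determination R^2, and RMSE — overall and, when `elements` is given, per
#' element. Atoms whose true charge is below 1e-8 e in magnitude are
#' excluded from the percentage metrics only.
#'
#' @param pred,truth Aligned numeric vectors of predicted and reference
#'   charges (e), length >= 2.
#' @param elements Optional character vector of element symbols per atom.
#' @return Data frame with one row per group (first row `"all"`) and columns
#'   `element`, `n`, `mae`, `medae`, `tl80ae`, `mdape`, `tl80pe`, `r2`,
#'   `rmse`.
#' @export
evaluate_charges <- function(pred, truth, elements = NULL) {
  pred <- as.numeric(pred); truth <- as.numeric(truth)
  if (length(pred) != length(truth)) stop("`pred` and `truth` lengths differ")
  if (length(pred) < 2L) stop("need at least 2 atoms")
  out <- cbind(element = "all", .indicator_row(pred, truth))
  if (!is.null(elements)) {
    stopifnot(length(elements) == length(pred))
    for (el in unique(elements)) {
      sel <- elements == el
      if (sum(sel) >= 2L) {
        out <- rbind(out, cbind(element = el, .indicator_row(pred[sel], truth[sel])))
      }
    }
  }
  rownames(out) <- NULL
  out
}
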