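# Timing benchmark on unbranched alkane chains: featurization should scale
# at most quadratically and network prediction linearly with atom count.

# Time one thunk, adaptively repeating until the measurement exceeds
# min_time seconds; returns seconds per single run.
.time_op <- function(fun, min_time = 0.02) {
  reps <- 1L
  repeat {
    t0 <- proc.time()[["elapsed"]]
    for (r in seq_len(reps)) fun()
    dt <- proc.time()[["elapsed"]] - t0
    if (dt >= min_time || reps >= 4096L) return(dt / reps)
    reps <- reps * 4L
  }
}

#' Scaling benchmark on alkane chains
#'
#' For each chain length, measures (averaged over `repeats` runs) the
#' featurization time, the network prediction time (normalization + forward
#' pass + denormalization), the model time (their sum) and, when
#' `include_parse = TRUE` and Open Babel is available, the overall time
#' starting from the SMILES string. Log-log slopes of time against atom
#' count are fitted by least squares.
#'
#' @param lengths Ascending alkane carbon counts.
#' @param repeats Number of timed runs per length; the mean is reported.
#' @param model A `charge_model` used for the prediction timings; by default
#'   a small throwaway model is trained on short alkanes.
#' @param include_parse Also time SMILES parsing (requires `obabel`).
#' @return List with `timings` (data frame: `n_carbons`, `n_atoms` and the
#'   per-phase mean seconds) and `slopes` (named vector: `featurizer`, `nn`,
#'   `model`, and `overall` when parsed).
#' @export
benchmark_scaling <- function(lengths = c(100L, 200L, 400L, 800L, 1600L),
                              repeats = 5L, model = NULL,
                              include_parse = FALSE) {
  stopifnot(!is.unsorted(lengths), repeats >= 1L)
  if (is.null(model)) {
    graphs <- lapply(3:6, make_alkane)
    charges <- lapply(graphs, synthetic_charges)
    model <- train_charge_model(graphs, charges,
                                config = train_config(epochs = 2L),
                                charge_type = "synthetic")
  }
  rows <- vector("list", length(lengths))
  for (k in seq_along(lengths)) {
    g <- make_alkane(lengths[k])
    n_at <- g$n_atoms
    fm <- featurize(g, cutoff = model$cutoff)
    gc(FALSE)
    t_feat <- mean(vapply(seq_len(repeats), function(r)
      .time_op(function() featurize(g, cutoff = model$cutoff)), numeric(1)))
    t_overall <- NA_real_
    if (include_parse) {
      smi <- strrep("C", lengths[k])
      t_overall <- mean(vapply(seq_len(repeats), function(r)
        .time_op(function() predict_charges(model, graph_from_smiles(smi)),
                 min_time = 0), numeric(1)))
    }
    # drop the n x n matrices before timing the network: keeping hundreds of
    # MB live makes the garbage collector, not the forward pass, the cost
    rm(g)
    gc(FALSE)
    t_nn <- mean(vapply(seq_len(repeats), function(r)
      .time_op(function() {
        Xn <- normalize_features(fm, model$norm_stats)
        q_hat <- .forward_det(model$network, Xn)
        q_hat * model$norm_stats$q_sd + model$norm_stats$q_mean
      }), numeric(1)))
    rows[[k]] <- data.frame(n_carbons = lengths[k], n_atoms = n_at,
                            t_featurize = t_feat, t_nn = t_nn,
                            t_model = t_feat + t_nn, t_overall = t_overall)
  }
  timings <- do.call(rbind, rows)
  slope <- function(t) {
    ok <- is.finite(t) & t > 0
    if (sum(ok) < 2L) return(NA_real_)
    unname(stats::coef(stats::lm(log(t[ok]) ~ log(timings$n_atoms[ok])))[2L])
  }
  slopes <- c(featurizer = slope(timings$t_featurize),
              nn = slope(timings$t_nn),
              model = slope(timings$t_model),
              overall = slope(timings$t_overall))
  list(timings = timings, slopes = slopes)
}
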