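# Message-passing featurizer: iterative neighbourhood updates on the bond
# graph, extraction of the five per-atom features, and z-score normalization.
#
# Update model, for stage l -> l+1 (H^(0) = 1 for every atom):
#   H_bond,i = sum_j T_ij * H_j      (bond contribution, through bond codes)
#   H_atom,i = sum_j A_ij * chi_j * H_j   (atom contribution, neighbour types)
#   H_self,i = chi_i * H_i                (self contribution)
#   H_i^(l+1) = H_bond,i + H_atom,i + H_self,i
# After `cutoff` rounds an atom's value encodes its bond-distance <= cutoff
# neighbourhood and nothing beyond it.

# out[i] = sum_j M[i, j] * w[j], accumulated over ascending j
.col_accum <- function(M, w) {
  n <- nrow(M)
  out <- numeric(n)
  for (j in seq_len(n)) out <- out + M[, j] * w[j]
  out
}

#' Initial feature state of a graph
#'
#' Stage-0 state with every atom's feature set to 1, giving all atoms the
#' same weight so that the updates build features in an unbiased way.
#'
#' @param graph A `molecular_graph`.
#' @return A `feature_state` with fields `stage`, `values`, and (unset at
#'   stage 0) `bond_term`, `atom_term`, `self_term`.
#' @export
init_state <- function(graph) {
  stopifnot(inherits(graph, "molecular_graph"))
  structure(
    list(stage = 0L, values = rep(1, graph$n_atoms),
         bond_term = NULL, atom_term = NULL, self_term = NULL),
    class = "feature_state"
  )
}

#' One message-passing update round
#'
#' Advances the state one stage: each atom's value becomes the sum of a bond
#' contribution (neighbour values weighted by the topology codes), an atom
#' contribution (neighbour values weighted by connectivity and the
#' neighbour's electronegativity) and a self contribution (own value times
#' own electronegativity). The three terms of the round are retained.
#'
#' @param graph A `molecular_graph`.
#' @param state A `feature_state` for the same graph.
#' @return The stage `l + 1` `feature_state`.
#' @export
mpf_update <- function(graph, state) {
  stopifnot(inherits(graph, "molecular_graph"), inherits(state, "feature_state"))
  H <- state$values
  n <- graph$n_atoms
  if (length(H) != n) stop("state does not belong to this graph (dimension mismatch)")
  # column-wise accumulation: each row sums its terms in ascending
  # neighbour-index order with one accumulator, so results are reproducible
  # and independent of where the structural zeros sit (BLAS matrix-vector
  # kernels are not: their SIMD lanes make rounding depend on the zero
  # pattern), and no n x n temporary is allocated
  bond <- .col_accum(graph$topology, H)
  atom <- .col_accum(graph$adjacency, graph$chi * H)
  self <- graph$chi * H
  structure(
    list(stage = state$stage + 1L, values = bond + atom + self,
         bond_term = bond, atom_term = atom, self_term = self),
    class = "feature_state"
  )
}

#' Featurize every atom of a molecule
#'
#' Runs `cutoff` update rounds from the all-ones initial state and assembles
#' the n x 5 feature matrix with columns `H_bond`, `H_atom`, `H_self` (the
#' three contribution terms of the final round), `H_MNE` (mean Pauling
#' electronegativity of the bonded neighbours) and `H_SEN` (the atom's own
#' electronegativity). The cutoff equals the bond-distance radius of the
#' neighbourhood encoded in each atom's features.
#'
#' @param graph A `molecular_graph`. Every atom must have at least one bond
#'   (the mean neighbouring electronegativity is undefined for an isolated
#'   atom).
#' @param cutoff Number of update rounds (default 3).
#' @return A `feature_matrix`: numeric matrix with 5 named columns and
#'   attribute `cutoff`.
#' @export
featurize <- function(graph, cutoff = 3L) {
  stopifnot(inherits(graph, "molecular_graph"))
  cutoff <- as.integer(cutoff)
  if (is.na(cutoff) || cutoff < 1L) stop("`cutoff` must be a positive integer")
  deg <- rowSums(graph$adjacency)
  if (any(deg == 0)) {
    stop(errorCondition(
      sprintf("atom %d has no bonds; isolated atoms cannot be featurized",
              which(deg == 0)[1]),
      class = c("mpf_degenerate_input", "error", "condition")
    ))
  }
  st <- init_state(graph)
  for (l in seq_len(cutoff)) st <- mpf_update(graph, st)
  h_mne <- .col_accum(graph$adjacency, graph$chi) / deg
  fm <- cbind(H_bond = st$bond_term, H_atom = st$atom_term,
              H_self = st$self_term, H_MNE = h_mne, H_SEN = graph$chi)
  if (!all(is.finite(fm))) stop("non-finite feature values")
  structure(fm, cutoff = cutoff, class = c("feature_matrix", class(fm)))
}

#' Feature names of the five-column descriptor
#' @return Character vector of the five column names, in order.
#' @export
feature_names <- function() c("H_bond", "H_atom", "H_self", "H_MNE", "H_SEN")

.pooled_features <- function(features) {
  if (is.matrix(features)) features <- list(features)
  stopifnot(is.list(features), length(features) >= 1L)
  pooled <- do.call(rbind, lapply(features, unclass))
  if (ncol(pooled) != 5L) stop("feature matrices must have 5 columns")
  pooled
}

# Population standard deviation: invariant under duplication of the data.
.pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

#' Fit normalization statistics on a training set
#'
#' Pools every atom row of the supplied feature matrices and computes, per
#' feature, the mean and (population) standard deviation, together with the
#' mean and standard deviation of the target charges. Statistics are
#' computed on the post-update features.
#'
#' @param features A `feature_matrix` or list of them (one per molecule).
#' @param charges Numeric vector of per-atom charges (in e) aligned with the
#'   pooled atom rows, or a list of vectors parallel to `features`.
#' @return A `norm_stats` object: feature means/sds, target mean/sd (`q_mean`,
#'   `q_sd`), and the pooled atom count.
#' @export
fit_norm <- function(features, charges) {
  pooled <- .pooled_features(features)
  if (is.list(charges)) charges <- unlist(charges, use.names = FALSE)
  charges <- as.numeric(charges)
  if (length(charges) != nrow(pooled)) {
    stop("`charges` must supply one label per pooled atom row")
  }
  if (nrow(pooled) < 2L) stop("need at least 2 atoms to fit normalization statistics")
  if (!all(is.finite(pooled)) || !all(is.finite(charges))) stop("non-finite inputs")
  mu <- colMeans(pooled)
  sd <- apply(pooled, 2L, .pop_sd)
  if (any(sd == 0)) {
    warning(sprintf("constant feature column(s): %s (normalized to 0)",
                    paste(feature_names()[sd == 0], collapse = ", ")))
  }
  structure(
    list(feature_names = feature_names(), mean = unname(mu), sd = unname(sd),
         q_mean = mean(charges), q_sd = .pop_sd(charges),
         n_atoms = nrow(pooled)),
    class = "norm_stats"
  )
}

#' Normalize a feature matrix
#'
#' Applies the z-score `(H - mean) / sd` per feature column using fitted
#' training statistics. Columns with zero training standard deviation map to
#' 0 (a constant feature carries no information).
#'
#' @param fm A `feature_matrix` (or plain 5-column matrix).
#' @param stats A `norm_stats` from [fit_norm()].
#' @return Numeric matrix of the same shape.
#' @export
normalize_features <- function(fm, stats) {
  stopifnot(inherits(stats, "norm_stats"))
  fm <- .pooled_features(fm)
  sd <- ifelse(stats$sd == 0, 1, stats$sd)
  out <- sweep(sweep(fm, 2L, stats$mean, "-"), 2L, sd, "/")
  out[, stats$sd == 0] <- 0
  colnames(out) <- stats$feature_names
  out
}

#' Save / load normalization statistics as JSON
#'
#' @param stats A `norm_stats`.
#' @param path File path.
#' @return `write_norm_stats` returns `path` invisibly; `read_norm_stats`
#'   returns the `norm_stats`.
#' @export
write_norm_stats <- function(stats, path) {
  stopifnot(inherits(stats, "norm_stats"))
  jsonlite::write_json(unclass(stats), path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname write_norm_stats
#' @export
read_norm_stats <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(x[c("feature_names", "mean", "sd", "q_mean", "q_sd", "n_atoms")],
            class = "norm_stats")
}
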