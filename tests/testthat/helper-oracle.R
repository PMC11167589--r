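# Independent brute-force featurizer: walks explicit neighbour lists in
# ascending index order instead of using matrix algebra. Written from the
# same update-rule transcription as the package code, so a transcription
# error in either surfaces as disagreement on hand-computed small cases.
oracle_featurize <- function(graph, cutoff = 3L) {
  n <- graph$n_atoms
  chi <- graph$chi
  nb <- lapply(seq_len(n), function(i) sort(which(graph$adjacency[i, ] == 1)))
  H <- rep(1, n)
  bond <- atom <- self <- numeric(n)
  for (l in seq_len(cutoff)) {
    for (i in seq_len(n)) {
      sb <- 0
      sa <- 0
      for (j in nb[[i]]) {
        sb <- sb + graph$topology[i, j] * H[j]
        sa <- sa + chi[j] * H[j]
      }
      bond[i] <- sb
      atom[i] <- sa
      self[i] <- chi[i] * H[i]
    }
    H <- bond + atom + self
  }
  mne <- vapply(seq_len(n), function(i) mean(chi[nb[[i]]]), numeric(1))
  out <- cbind(H_bond = bond, H_atom = atom, H_self = self,
               H_MNE = mne, H_SEN = chi)
  rownames(out) <- NULL
  out
}

# Random molecules used across tests: seeds fixed, heavy-atom counts cycled
# so total atom counts stay at or below 29.
random_test_graphs <- function(n_graphs = 50L) {
  lapply(seq_len(n_graphs), function(s) {
    random_molecule(synth_spec(1L + (s %% 9L), seed = 1000L + s))
  })
}
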