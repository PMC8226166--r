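# Shared helpers: tiny frames built in code and independent oracles.

# a bare frame from a coordinate matrix
make_frame <- function(xyz, element = "C", chain_id = "A",
                       residue_index = NULL, atom_name = NULL,
                       residue_name = "GLY") {
  n <- nrow(xyz)
  if (length(element) == 1L) element <- rep(element, n)
  if (is.null(residue_index)) residue_index <- seq_len(n)
  if (length(chain_id) == 1L) chain_id <- rep(chain_id, n)
  if (is.null(atom_name)) atom_name <- element
  structure(list(
    atoms = data.frame(atom_name = atom_name, element = element,
                       residue_index = as.integer(residue_index),
                       residue_name = residue_name, chain_id = chain_id,
                       stringsAsFactors = FALSE),
    xyz = xyz, frame_index = 1L), class = "traj_frame")
}

# a random two-chain frame with n_a + n_b atoms inside a box
random_two_chain_frame <- function(n_a, n_b, box = 15) {
  xyz <- matrix(stats::runif((n_a + n_b) * 3, 0, box), ncol = 3)
  make_frame(xyz,
             element = "C",
             chain_id = c(rep("A", n_a), rep("B", n_b)),
             residue_index = c(seq_len(n_a), seq_len(n_b)))
}

# O(n^2) double-loop close-contact oracle: count of inter-chain atom
# pairs strictly closer than cutoff, plus the residue pairs involved
brute_force_contacts <- function(frame, cutoff = 4.0) {
  ia <- which(frame$atoms$chain_id == sort(unique(frame$atoms$chain_id))[1])
  ib <- which(frame$atoms$chain_id == sort(unique(frame$atoms$chain_id))[2])
  ncc <- 0L
  pairs <- character(0)
  for (i in ia) for (j in ib) {
    d <- sqrt(sum((frame$xyz[i, ] - frame$xyz[j, ])^2))
    if (d < cutoff) {
      ncc <- ncc + 1L
      pairs <- c(pairs, sprintf("A:%d-B:%d", frame$atoms$residue_index[i],
                                frame$atoms$residue_index[j]))
    }
  }
  list(ncc = ncc, pairs = sort(unique(pairs)))
}

# random rigid motion applied to a frame
random_rigid_motion <- function(frame) {
  v <- stats::runif(3, -pi, pi)
  th <- sqrt(sum(v^2)); k <- v / th
  K <- matrix(c(0, k[3], -k[2], -k[3], 0, k[1], k[2], -k[1], 0), 3, 3)
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
  t <- stats::runif(3, -20, 20)
  frame$xyz <- sweep(frame$xyz %*% t(R), 2, t, "+")
  frame
}

# random valid peptide spec for round-trip property tests
random_peptide_spec <- function(n_res = sample(1:15, 1)) {
  aa <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
  residues <- lapply(seq_len(n_res), function(i) {
    base <- sample(aa, 1)
    opts <- "none"
    if (base %in% c("S", "T", "Y")) opts <- c(opts, "ph")
    if (base == "K") opts <- c(opts, "me1", "me2", "me3", "ac")
    if (base == "R") opts <- c(opts, "me1", "me2")
    list(base = base, ptm = sample(opts, 1))
  })
  peptide_spec(residues,
               n_cap = sample(c("free_amine", "ACE"), 1),
               c_cap = sample(c("free_acid", "NMe"), 1))
}
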