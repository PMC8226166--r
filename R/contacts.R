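# Heavy-atom close-contact detection and salt-bridge typing.
#
# A close contact is a pair of heavy atoms strictly less than `cutoff`
# (default 4 A) apart. N_cc counts inter-chain atom pairs, each unordered
# pair once; residue-pair incidence uses the any-atom criterion (>= 1
# heavy-atom pair within cutoff). Neighbour search uses a cell list with
# cells of edge `cutoff`, so only atoms in adjacent cells are compared.

# integer cell key for a coordinate matrix; cells of edge h
.cell_keys <- function(xyz, h) {
  ix <- floor(xyz[, 1] / h); iy <- floor(xyz[, 2] / h); iz <- floor(xyz[, 3] / h)
  list(ix = ix, iy = iy, iz = iz,
       key = paste(ix, iy, iz, sep = ","))
}

# all atom pairs (i in idx_a, j in idx_b) with distance < cutoff, via the
# cell list; returns a data.frame i, j, d
.close_atom_pairs <- function(xyz, idx_a, idx_b, cutoff) {
  ka <- .cell_keys(xyz[idx_a, , drop = FALSE], cutoff)
  kb <- .cell_keys(xyz[idx_b, , drop = FALSE], cutoff)
  lookup <- split(seq_along(idx_b), kb$key)
  out_i <- integer(0); out_j <- integer(0); out_d <- numeric(0)
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  for (a in seq_along(idx_a)) {
    neigh_keys <- paste(ka$ix[a] + offs[, 1], ka$iy[a] + offs[, 2],
                        ka$iz[a] + offs[, 3], sep = ",")
    cand <- unlist(lookup[neigh_keys], use.names = FALSE)
    if (length(cand) == 0L) next
    dv <- xyz[idx_b[cand], , drop = FALSE] -
      matrix(xyz[idx_a[a], ], length(cand), 3, byrow = TRUE)
    d <- sqrt(rowSums(dv * dv))
    hit <- which(d < cutoff)
    if (length(hit)) {
      out_i <- c(out_i, rep.int(a, length(hit)))
      out_j <- c(out_j, cand[hit])
      out_d <- c(out_d, d[hit])
    }
  }
  data.frame(i = idx_a[out_i], j = idx_b[out_j], d = out_d)
}

# canonical residue-pair key; chains sorted lexically, intra pairs i < j
.pair_key <- function(chain_a, res_a, chain_b, res_b) {
  swap <- (chain_a > chain_b) | (chain_a == chain_b & res_a > res_b)
  ca <- ifelse(swap, chain_b, chain_a); ra <- ifelse(swap, res_b, res_a)
  cb <- ifelse(swap, chain_a, chain_b); rb <- ifelse(swap, res_a, res_b)
  sprintf("%s:%d-%s:%d", ca, ra, cb, rb)
}

#' Per-frame heavy-atom close contacts
#'
#' Counts inter-chain heavy-atom pairs strictly closer than `cutoff`
#' (`ncc`) and reports the residue pairs with at least one such atom pair,
#' together with each pair's minimal heavy-atom distance. With
#' `include_intra = TRUE` intra-chain residue pairs are additionally
#' reported (they never contribute to `ncc`, which is an inter-chain
#' statistic).
#'
#' @param frame a two-chain `traj_frame`; hydrogens should already have
#'   been removed (see [heavy_atom_view()]).
#' @param cutoff close-contact cutoff in Angstrom (default 4.0, strict
#'   `<`).
#' @param include_intra also report intra-chain residue-pair contacts.
#' @return list with `ncc` (integer) and `pairs`, a data.frame with
#'   columns `chain_a`, `res_a`, `chain_b`, `res_b`, `min_distance`,
#'   `scope` (`"intermolecular"`/`"intramolecular"`) and `pair` (canonical
#'   key).
#' @export
frame_close_contacts <- function(frame, cutoff = 4.0, include_intra = FALSE) {
  stopifnot(inherits(frame, "traj_frame"), cutoff > 0)
  chains <- sort(unique(frame$atoms$chain_id))
  if (length(chains) != 2L) {
    stop(sprintf("frame must contain exactly two chains, found %d",
                 length(chains)), call. = FALSE)
  }
  idx_a <- which(frame$atoms$chain_id == chains[1])
  idx_b <- which(frame$atoms$chain_id == chains[2])
  hits <- .close_atom_pairs(frame$xyz, idx_a, idx_b, cutoff)
  ncc <- nrow(hits)

  collate <- function(hits, scope) {
    if (nrow(hits) == 0L) {
      return(data.frame(chain_a = character(0), res_a = integer(0),
                        chain_b = character(0), res_b = integer(0),
                        min_distance = numeric(0), scope = character(0),
                        pair = character(0), stringsAsFactors = FALSE))
    }
    ca <- frame$atoms$chain_id[hits$i]; ra <- frame$atoms$residue_index[hits$i]
    cb <- frame$atoms$chain_id[hits$j]; rb <- frame$atoms$residue_index[hits$j]
    key <- .pair_key(ca, ra, cb, rb)
    agg <- tapply(hits$d, key, min)
    parts <- do.call(rbind, strsplit(names(agg), "[-:]"))
    data.frame(chain_a = parts[, 1], res_a = as.integer(parts[, 2]),
               chain_b = parts[, 3], res_b = as.integer(parts[, 4]),
               min_distance = as.numeric(agg), scope = scope,
               pair = names(agg), stringsAsFactors = FALSE)
  }

  pairs <- collate(hits, "intermolecular")
  if (include_intra) {
    for (ch in chains) {
      idx <- which(frame$atoms$chain_id == ch)
      h <- .close_atom_pairs(frame$xyz, idx, idx, cutoff)
      h <- h[h$i < h$j, , drop = FALSE]
      h <- h[frame$atoms$residue_index[h$i] != frame$atoms$residue_index[h$j], ,
             drop = FALSE]
      pairs <- rbind(pairs, collate(h, "intramolecular"))
    }
  }
  rownames(pairs) <- NULL
  list(ncc = as.integer(ncc), pairs = pairs)
}

#' Contact incidence over a whole trajectory
#'
#' Applies [frame_close_contacts()] to every frame and assembles the
#' per-frame atom-pair counts (the N_cc source) plus a frames x pairs
#' incidence matrix at residue granularity.
#'
#' @param traj a two-chain heavy-atom [trajectory()].
#' @param cutoff close-contact cutoff in Angstrom.
#' @param include_intra track intra-chain residue pairs as well (needed
#'   for intramolecular persistence maps).
#' @return object of class `contact_series`: list with `per_frame_ncc`,
#'   `incidence` (logical matrix, one column per residue pair ever in
#'   contact), `pair_info` (data.frame describing the columns), `cutoff`,
#'   `n_frames`.
#' @export
contact_series <- function(traj, cutoff = 4.0, include_intra = TRUE) {
  stopifnot(inherits(traj, "trajectory"))
  nf <- n_frames(traj)
  per_frame <- vector("list", nf)
  ncc <- integer(nf)
  for (f in seq_len(nf)) {
    res <- frame_close_contacts(get_frame(traj, f), cutoff = cutoff,
                                include_intra = include_intra)
    ncc[f] <- res$ncc
    per_frame[[f]] <- res$pairs
  }
  all_pairs <- unique(do.call(rbind, lapply(per_frame, function(p) {
    p[, c("pair", "chain_a", "res_a", "chain_b", "res_b", "scope")]
  })))
  if (is.null(all_pairs)) {
    all_pairs <- data.frame(pair = character(0), chain_a = character(0),
                            res_a = integer(0), chain_b = character(0),
                            res_b = integer(0), scope = character(0))
  }
  rownames(all_pairs) <- NULL
  inc <- matrix(FALSE, nrow = nf, ncol = nrow(all_pairs),
                dimnames = list(NULL, all_pairs$pair))
  for (f in seq_len(nf)) {
    inc[f, per_frame[[f]]$pair] <- TRUE
  }
  structure(list(per_frame_ncc = ncc, incidence = inc,
                 pair_info = all_pairs, cutoff = cutoff, n_frames = nf,
                 topology = traj$topology),
            class = "contact_series")
}

#' @export
print.contact_series <- function(x, ...) {
  cat(sprintf("<contact_series> %d frames, cutoff %.2f A, mean N_cc %.2f, %d residue pairs observed\n",
              x$n_frames, x$cutoff, mean(x$per_frame_ncc),
              ncol(x$incidence)))
  invisible(x)
}

#' Time-averaged number of inter-chain close contacts (N_cc)
#'
#' @param series a [contact_series()].
#' @return arithmetic mean of the per-frame inter-chain heavy-atom
#'   close-contact counts.
#' @export
mean_ncc <- function(series) {
  stopifnot(inherits(series, "contact_series"))
  if (length(series$per_frame_ncc) == 0L) {
    stop("contact series has no frames", call. = FALSE)
  }
  mean(series$per_frame_ncc)
}

#' Type a residue-pair interaction
#'
#' A pair is a salt bridge when one partner carries a phosphate
#' (phospho-Ser/Thr/Tyr) and the other a guanidinium (Arg, any methylation
#' state) or an ammonium/methylammonium (Lys, unless acetylated, which
#' removes the charge). Classification is by residue identity and PTM
#' state; every other combination is `other_contact`.
#'
#' @param res_a,res_b residue records with `base` and `ptm` fields (e.g.
#'   elements of `spec$residues`).
#' @return list with `category` (one of `R_pS_saltbridge`,
#'   `R_pT_saltbridge`, `K_pS_saltbridge`, `K_pT_saltbridge`,
#'   `other_contact`), `donor_modified` (basic partner carries methyl
#'   groups) and `acceptor` (base letter of the phosphorylated partner, or
#'   `NA`).
#' @export
classify_pair <- function(res_a, res_b) {
  is_phos <- function(r) r$ptm == "ph"
  is_basic <- function(r) (r$base == "R") || (r$base == "K" && r$ptm != "ac")
  combo <- NULL
  if (is_phos(res_a) && is_basic(res_b)) combo <- list(p = res_a, b = res_b)
  if (is_phos(res_b) && is_basic(res_a)) combo <- list(p = res_b, b = res_a)
  if (is.null(combo)) {
    return(list(category = "other_contact", donor_modified = FALSE,
                acceptor = NA_character_))
  }
  category <- sprintf("%s_p%s_saltbridge", combo$b$base, combo$p$base)
  list(category = category,
       donor_modified = combo$b$ptm %in% c("me1", "me2", "me3"),
       acceptor = combo$p$base)
}

# resolve a (chain, residue_index) to a residue record, preferring the
# trajectory topology and falling back to the PDB residue name
.resolve_residue <- function(chain, res_index, topology, atoms = NULL) {
  if (!is.null(topology) && chain %in% names(topology)) {
    spec <- topology[[chain]]
    if (res_index >= 1L && res_index <= length(spec$residues)) {
      return(spec$residues[[res_index]])
    }
  }
  if (!is.null(atoms)) {
    hit <- which(atoms$chain_id == chain & atoms$residue_index == res_index)
    if (length(hit)) {
      r <- .resname_to_ptm(atoms$residue_name[hit[1]])
      if (!is.null(r)) return(list(base = r$base, ptm = r$ptm))
    }
  }
  NULL
}
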