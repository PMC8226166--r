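# Ideal peptide chain builder.
#
# Builds a reduced heavy-atom representation of a peptide from standard
# internal coordinates: backbone N, CA, C, O per residue, plus CB and a
# single side-chain "tip" pseudo-atom for non-glycine residues. The tip
# stands in for the side chain's interaction centre; charged groups
# (guanidinium, ammonium, phosphate) get their full reach, neutral side
# chains a compact stub, so that interface contacts in generated dimers
# are carried by the chemistry the analysis cares about.

# standard peptide bond lengths (A) and angles (deg)
.GEOM <- list(
  b_n_ca = 1.458, b_ca_c = 1.525, b_c_n = 1.329, b_c_o = 1.231,
  b_ca_cb = 1.530,
  a_n_ca_c = 111.2, a_ca_c_n = 116.2, a_c_n_ca = 121.7,
  a_ca_c_o = 120.5, a_c_ca_cb = 110.1, a_ca_cb_tip = 114.0,
  d_n_c_ca_cb = 122.55   # improper fixing CB chirality
)

# tip pseudo-atom: bond length from CB (A), atom name, element.
# R/K/phospho tips reach the charged-group centroid; everything else is a
# short stub.
.tip_params <- function(base, ptm) {
  if (ptm == "ph") return(list(len = 4.1, name = "P", elem = "P"))
  if (base == "R") return(list(len = 4.3, name = "NH1", elem = "N"))
  if (base == "K") return(list(len = 4.0, name = "NZ", elem = "N"))
  list(len = 1.2, name = "CG", elem = "C")
}

# place atom d given positions a, b, c with bond |cd|, angle b-c-d (deg)
# and dihedral a-b-c-d (deg); the standard NeRF construction
place_atom <- function(a, b, c, bond, angle, dihedral) {
  ang <- angle * pi / 180
  dih <- dihedral * pi / 180
  bc <- c - b
  bc <- bc / sqrt(sum(bc^2))
  n <- pracma_cross(b - a, bc)
  n <- n / sqrt(sum(n^2))
  m <- pracma_cross(n, bc)
  d2 <- bond * c(-cos(ang), sin(ang) * cos(dih), sin(ang) * sin(dih))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

pracma_cross <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

#' Build an ideal single-chain frame from a peptide specification
#'
#' Places backbone heavy atoms (N, CA, C, O) plus CB and one side-chain
#' tip pseudo-atom per non-glycine residue by internal-coordinate chain
#' building with fixed backbone dihedrals: (phi, psi) = (-57, -47) degrees
#' for `"helical"` (canonical alpha helix) or (-135, 135) degrees for
#' `"extended"` (beta-strand-like). Omega is 180 degrees (trans). The tip
#' atom's element reflects the side-chain chemistry: N for Arg/Lys
#' (guanidinium/ammonium), P for phosphorylated Ser/Thr/Tyr, C otherwise.
#'
#' @param spec a [peptide_spec()].
#' @param conformation `"helical"` or `"extended"`.
#' @param chain_id chain identifier for the emitted atoms.
#' @return a single-chain `traj_frame`.
#' @export
build_ideal_chain <- function(spec, conformation = c("helical", "extended"),
                              chain_id = "A") {
  stopifnot(inherits(spec, "peptide_spec"))
  conformation <- match.arg(conformation)
  pp <- if (conformation == "helical") c(-57, -47) else c(-135, 135)
  phi <- pp[1]; psi <- pp[2]
  g <- .GEOM
  nres <- length(spec$residues)

  name <- character(0); elem <- character(0); ridx <- integer(0)
  rname <- character(0)
  coords <- list()
  add <- function(nm, el, ri, rn, xyz) {
    name <<- c(name, nm); elem <<- c(elem, el)
    ridx <<- c(ridx, ri); rname <<- c(rname, rn)
    coords[[length(coords) + 1L]] <<- xyz
  }

  # residue 1 backbone seeds the frame
  N <- c(0, 0, 0)
  CA <- c(g$b_n_ca, 0, 0)
  ang <- g$a_n_ca_c * pi / 180
  C <- CA + g$b_ca_c * c(-cos(ang), sin(ang), 0)

  prevN <- prevCA <- prevC <- NULL
  for (i in seq_len(nres)) {
    r <- spec$residues[[i]]
    rn <- residue_name_for(r$base, r$ptm)
    if (i > 1L) {
      N <- place_atom(prevN, prevCA, prevC, g$b_c_n, g$a_ca_c_n, psi)
      CA <- place_atom(prevCA, prevC, N, g$b_n_ca, g$a_c_n_ca, 180)
      C <- place_atom(prevC, N, CA, g$b_ca_c, g$a_n_ca_c, phi)
    }
    add("N", "N", i, rn, N)
    add("CA", "C", i, rn, CA)
    add("C", "C", i, rn, C)
    # carbonyl O anti to the next amide N
    O <- place_atom(N, CA, C, g$b_c_o, g$a_ca_c_o, psi + 180)
    add("O", "O", i, rn, O)
    if (r$base != "G") {
      CB <- place_atom(N, C, CA, g$b_ca_cb, g$a_c_ca_cb, g$d_n_c_ca_cb)
      add("CB", "C", i, rn, CB)
      tp <- .tip_params(r$base, r$ptm)
      TIP <- place_atom(N, CA, CB, tp$len, g$a_ca_cb_tip, 180)
      add(tp$name, tp$elem, i, rn, TIP)
    }
    prevN <- N; prevCA <- CA; prevC <- C
  }

  atoms <- data.frame(atom_name = name, element = elem,
                      residue_index = ridx, residue_name = rname,
                      chain_id = chain_id, stringsAsFactors = FALSE)
  structure(list(atoms = atoms, xyz = do.call(rbind, coords),
                 frame_index = 1L),
            class = "traj_frame")
}
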