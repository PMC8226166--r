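# Multi-model PDB reader/writer.
#
# The package's native trajectory format is multi-model PDB: one MODEL /
# ENDMDL block per frame, fixed 80-column records, TER after each chain.
# The reader enforces the container invariants (>= 1 model, exactly two
# chains, identical atom roster in every model) and silently drops solvent
# and counter-ion records with a reported count.

.SOLVENT_RES <- c("HOH", "WAT", "TIP", "TIP3", "SOL", "DOD",
                  "NA", "NA+", "SOD", "CL", "CL-", "CLA", "K", "K+", "MG")

# residue names used for modified residues in PDB output
.MOD_RESNAME <- c(
  "T.ph" = "TPO", "S.ph" = "SEP", "Y.ph" = "PTR",
  "K.me1" = "MLZ", "K.me2" = "MLY", "K.me3" = "M3L", "K.ac" = "ALY",
  "R.me1" = "NMM", "R.me2" = "DA2"
)

.AA3 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS",
          Q = "GLN", E = "GLU", G = "GLY", H = "HIS", I = "ILE",
          L = "LEU", K = "LYS", M = "MET", F = "PHE", P = "PRO",
          S = "SER", T = "THR", W = "TRP", Y = "TYR", V = "VAL")

# inverse: residue_name -> (base, ptm); standard + modified names
.resname_to_ptm <- function(resname) {
  resname <- toupper(trimws(resname))
  hit <- match(resname, .MOD_RESNAME)
  if (!is.na(hit)) {
    key <- strsplit(names(.MOD_RESNAME)[hit], ".", fixed = TRUE)[[1]]
    return(list(base = key[1], ptm = key[2]))
  }
  hit <- match(resname, .AA3)
  if (!is.na(hit)) return(list(base = names(.AA3)[hit], ptm = "none"))
  NULL
}

residue_name_for <- function(base, ptm) {
  if (ptm == "none") return(unname(.AA3[base]))
  key <- paste(base, ptm, sep = ".")
  out <- .MOD_RESNAME[key]
  if (is.na(out)) unname(.AA3[base]) else unname(out)
}

# element inference when columns 77-78 are blank: first alphabetic
# character of the atom name (peptide atoms only: C, N, O, S, P, H)
.infer_element <- function(atom_name) {
  vapply(atom_name, function(nm) {
    ch <- regmatches(nm, regexpr("[A-Za-z]", nm))
    if (length(ch) == 0L) stop(sprintf("cannot infer element for atom '%s'", nm),
                               call. = FALSE)
    toupper(ch)
  }, character(1), USE.NAMES = FALSE)
}

#' Read a two-chain trajectory from a multi-model PDB file
#'
#' Parses `ATOM`/`HETATM` records from every `MODEL`/`ENDMDL` block (a file
#' without MODEL records is treated as a single frame). Water and
#' counter-ion records are dropped (a message reports how many). The file
#' must describe exactly two chains, and every model must carry an
#' identical atom roster; violations raise distinct errors.
#'
#' @param path PDB file path.
#' @param topology optional named list mapping chain id to a
#'   [peptide_spec()] (e.g. from [read_topology()]); stored on the
#'   returned trajectory and used downstream for interaction typing.
#' @return a [trajectory()].
#' @export
read_multimodel_pdb <- function(path, topology = NULL) {
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  is_atom <- rec %in% c("ATOM  ", "HETATM")
  model_starts <- grep("^MODEL", lines)

  if (length(model_starts) == 0L) {
    blocks <- list(which(is_atom))
  } else {
    model_ends <- grep("^ENDMDL", lines)
    if (length(model_ends) != length(model_starts)) {
      stop("malformed PDB: unbalanced MODEL/ENDMDL records", call. = FALSE)
    }
    blocks <- mapply(function(s, e) {
      idx <- s:e
      idx[is_atom[idx]]
    }, model_starts, model_ends, SIMPLIFY = FALSE)
  }
  blocks <- Filter(length, blocks)
  if (length(blocks) == 0L) {
    stop("no models with atom records found in PDB file", call. = FALSE)
  }

  parse_block <- function(idx) {
    ln <- lines[idx]
    atom_name <- trimws(substr(ln, 13, 16))
    resname <- trimws(substr(ln, 18, 20))
    chain <- trimws(substr(ln, 22, 22))
    resseq <- as.integer(substr(ln, 23, 26))
    x <- as.numeric(substr(ln, 31, 38))
    y <- as.numeric(substr(ln, 39, 46))
    z <- as.numeric(substr(ln, 47, 54))
    elem <- toupper(trimws(substr(ln, 77, 78)))
    blank <- elem == "" | is.na(elem)
    if (any(blank)) elem[blank] <- .infer_element(atom_name[blank])
    keep <- !(toupper(resname) %in% .SOLVENT_RES)
    n_dropped <- sum(!keep)
    list(atoms = data.frame(atom_name = atom_name[keep],
                            element = elem[keep],
                            residue_index = resseq[keep],
                            residue_name = resname[keep],
                            chain_id = chain[keep],
                            stringsAsFactors = FALSE),
         xyz = cbind(x, y, z)[keep, , drop = FALSE],
         n_dropped = n_dropped)
  }

  parsed <- lapply(blocks, parse_block)
  dropped <- sum(vapply(parsed, `[[`, numeric(1), "n_dropped"))
  if (dropped > 0L) {
    message(sprintf("read_multimodel_pdb: dropped %d solvent/ion atom records",
                    dropped))
  }

  ref <- parsed[[1]]$atoms
  roster_key <- function(a) {
    paste(a$atom_name, a$residue_name, a$residue_index, a$chain_id, sep = "|")
  }
  ref_key <- roster_key(ref)
  for (m in seq_along(parsed)) {
    key <- roster_key(parsed[[m]]$atoms)
    if (length(key) != length(ref_key) || !all(key == ref_key)) {
      miss <- setdiff(ref_key, key)
      extra <- setdiff(key, ref_key)
      what <- if (length(miss)) miss[1] else extra[1]
      stop(sprintf(
        "atom roster mismatch in MODEL %d: atom '%s' differs from MODEL 1",
        m, gsub("|", " ", what, fixed = TRUE)), call. = FALSE)
    }
  }

  chains <- sort(unique(ref$chain_id))
  if (length(chains) != 2L) {
    stop(sprintf("expected exactly two chains, found %d (%s)",
                 length(chains), paste(chains, collapse = ", ")), call. = FALSE)
  }

  xyz <- array(NA_real_, dim = c(nrow(ref), 3L, length(parsed)))
  for (m in seq_along(parsed)) xyz[, , m] <- parsed[[m]]$xyz
  trajectory(ref, xyz, topology = topology)
}

#' Write a trajectory as a multi-model PDB file
#'
#' One `MODEL`/`ENDMDL` block per frame, `TER` after each chain,
#' coordinates as `%8.3f`, element symbols in columns 77-78.
#'
#' @param traj a [trajectory()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_multimodel_pdb <- function(traj, path) {
  stopifnot(inherits(traj, "trajectory"))
  a <- traj$atoms
  # PDB convention: names of <4 characters start in column 14
  fmt_name <- ifelse(nchar(a$atom_name) >= 4L,
                     substr(a$atom_name, 1, 4),
                     sprintf(" %-3s", a$atom_name))
  chains <- unique(a$chain_id)
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (f in seq_len(n_frames(traj))) {
    xyz <- traj$xyz[, , f, drop = TRUE]
    if (is.null(dim(xyz))) xyz <- matrix(xyz, ncol = 3L)
    writeLines(sprintf("MODEL     %4d", f), con)
    serial <- 0L
    for (ch in chains) {
      idx <- which(a$chain_id == ch)
      serial_block <- serial + seq_along(idx)
      lines <- sprintf(
        "ATOM  %5d %s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        serial_block, fmt_name[idx], a$residue_name[idx], ch,
        a$residue_index[idx], xyz[idx, 1], xyz[idx, 2], xyz[idx, 3],
        1.00, 0.00, a$element[idx])
      writeLines(lines, con)
      serial <- serial + length(idx)
      last <- idx[length(idx)]
      writeLines(sprintf("TER   %5d      %-3s %1s%4d", serial + 1L,
                         a$residue_name[last], ch, a$residue_index[last]), con)
      serial <- serial + 1L
    }
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Read a chain-topology sidecar file
#'
#' The sidecar is a small YAML document mapping chain ids to annotated
#' peptide sequences, with optional `label` and `conformation` fields:
#' ```yaml
#' label: P1M2/P1M2
#' conformation: extended
#' chains:
#'   A: "ART[ph]K[me3]QTAR[me2]KSTG-NME"
#'   B: "ART[ph]K[me3]QTAR[me2]KSTG-NME"
#' ```
#'
#' @param path YAML file path.
#' @return list with `chains` (named list of [peptide_spec()]), `label`
#'   and `conformation` (may be `NULL`).
#' @export
read_topology <- function(path) {
  doc <- yaml::read_yaml(path)
  if (is.null(doc$chains) || length(doc$chains) == 0L) {
    stop("topology file must contain a 'chains' mapping", call. = FALSE)
  }
  chains <- lapply(names(doc$chains), function(id) {
    parse_annotation(doc$chains[[id]], label = id)
  })
  names(chains) <- names(doc$chains)
  list(chains = chains, label = doc$label %||% "",
       conformation = doc$conformation %||% NULL)
}

#' Write a chain-topology sidecar file
#'
#' @param topology named list mapping chain id to [peptide_spec()].
#' @param path output YAML path.
#' @param label free-text dimer label.
#' @param conformation optional conformation tag (`"helical"`/`"extended"`).
#' @return `path`, invisibly.
#' @export
write_topology <- function(topology, path, label = "", conformation = NULL) {
  doc <- list(label = label)
  if (!is.null(conformation)) doc$conformation <- conformation
  doc$chains <- lapply(topology, format_annotation)
  yaml::write_yaml(doc, path)
  invisible(path)
}
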