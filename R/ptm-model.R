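# PTM-aware peptide representation and formal-charge model.
#
# A peptide is an ordered list of residues, each carrying at most one
# post-translational modification (PTM), plus the state of the two termini.
# The formal charge is the pH ~ 7 bookkeeping charge: +1 for a free
# N-terminal amine, -1 for a free C-terminal acid, +1 for Arg/Lys side
# chains (methylation does not remove the charge), 0 for acetyl-Lys,
# -1 for Asp/Glu, 0 for His, and -2 for a fully deprotonated phosphate on
# Ser/Thr/Tyr.

.AA1 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

.PTM_TAGS <- c("ph", "me1", "me2", "me3", "ac")

# which PTMs are chemically admissible on which residue
.PTM_ALLOWED <- list(
  ph  = c("S", "T", "Y"),
  me1 = c("K", "R"),
  me2 = c("K", "R"),   # for R: asymmetric dimethylation
  me3 = "K",
  ac  = "K"
)

# side-chain formal charge at pH ~ 7 given (base, ptm)
.side_chain_charge <- function(base, ptm) {
  if (ptm == "ph") return(-2L)
  if (base == "K") return(if (ptm == "ac") 0L else 1L)
  if (base == "R") return(1L)
  if (base %in% c("D", "E")) return(-1L)
  0L
}

new_residue_ptm <- function(base, ptm = "none", position = NA_integer_) {
  stopifnot(length(base) == 1L, length(ptm) == 1L)
  if (!base %in% .AA1) {
    stop(sprintf("unknown amino-acid code '%s' at position %s", base, position),
         call. = FALSE)
  }
  if (!ptm %in% c("none", .PTM_TAGS)) {
    stop(sprintf("unknown PTM tag '%s' at position %s", ptm, position),
         call. = FALSE)
  }
  if (ptm != "none" && !base %in% .PTM_ALLOWED[[ptm]]) {
    stop(sprintf("PTM '%s' is not admissible on residue '%s' at position %s",
                 ptm, base, position), call. = FALSE)
  }
  list(base = base, ptm = ptm, position = as.integer(position))
}

#' Construct a peptide specification
#'
#' A `peptide_spec` holds an ordered list of residues with their PTM state
#' plus the two terminal groups, and is the unit the charge model and the
#' interaction-typing code operate on.
#'
#' @param residues list of residue records as produced by the annotation
#'   parser; each has `base` (one-letter code), `ptm` (one of `"none"`,
#'   `"ph"`, `"me1"`, `"me2"`, `"me3"`, `"ac"`) and `position` (1-based).
#' @param n_cap `"free_amine"` or `"ACE"` (N-terminal acetyl cap).
#' @param c_cap `"free_acid"` or `"NMe"` (C-terminal N-methyl amide cap).
#' @param label free-text label, e.g. `"P1M2"`.
#' @return an object of class `peptide_spec`.
#' @seealso [parse_annotation()], [compute_formal_charge()]
#' @export
peptide_spec <- function(residues, n_cap = "free_amine", c_cap = "free_acid",
                         label = "") {
  n_cap <- match.arg(n_cap, c("free_amine", "ACE"))
  c_cap <- match.arg(c_cap, c("free_acid", "NMe"))
  if (length(residues) == 0L) {
    stop("a peptide must contain at least one residue", call. = FALSE)
  }
  residues <- lapply(seq_along(residues), function(i) {
    r <- residues[[i]]
    new_residue_ptm(r$base, r$ptm %||% "none", i)
  })
  structure(list(residues = residues, n_cap = n_cap, c_cap = c_cap,
                 label = label),
            class = "peptide_spec")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.peptide_spec <- function(x, ...) {
  cat(sprintf("<peptide_spec> %s  (%d residues, charge %+d)\n",
              if (nzchar(x$label)) x$label else "<unlabelled>",
              length(x$residues), compute_formal_charge(x)))
  cat(" ", format_annotation(x), "\n")
  invisible(x)
}

#' @export
length.peptide_spec <- function(x) length(x$residues)

#' Parse an annotated peptide sequence
#'
#' The annotation grammar is `[ACE-]<residues>[-NME]` where each residue is
#' a one-letter amino-acid code optionally followed by a bracketed PTM tag:
#' `[ph]` (phosphorylation, Ser/Thr/Tyr), `[me1]`/`[me2]`/`[me3]`
#' (methylation; `me1`/`me2` on Lys or Arg, with `me2` on Arg meaning
#' asymmetric dimethylation; `me3` on Lys only) or `[ac]` (Lys
#' acetylation). Example: `"ART[ph]K[me3]QTAR[me2]KSTG-NME"` is the
#' H3(1-12) tail carrying the mitotic phospho-T3 / trimethyl-K4 /
#' dimethyl-R8 mark set.
#'
#' @param text annotation string.
#' @param label optional label stored on the returned spec.
#' @return a [peptide_spec()].
#' @export
parse_annotation <- function(text, label = "") {
  if (!is.character(text) || length(text) != 1L || is.na(text)) {
    stop("annotation must be a single string", call. = FALSE)
  }
  raw <- trimws(text)
  n_cap <- "free_amine"
  c_cap <- "free_acid"
  if (grepl("^ACE-", raw, ignore.case = TRUE)) {
    n_cap <- "ACE"
    raw <- sub("^ACE-", "", raw, ignore.case = TRUE)
  }
  if (grepl("-NME$", raw, ignore.case = TRUE)) {
    c_cap <- "NMe"
    raw <- sub("-NME$", "", raw, ignore.case = TRUE)
  }
  if (!nzchar(raw)) {
    stop("empty sequence: annotation contains no residues", call. = FALSE)
  }
  residues <- list()
  i <- 1L
  pos <- 0L
  chars <- strsplit(raw, "", fixed = TRUE)[[1]]
  while (i <= length(chars)) {
    base <- chars[i]
    pos <- pos + 1L
    if (!base %in% .AA1) {
      stop(sprintf("malformed annotation: unexpected character '%s' at residue position %d",
                   base, pos), call. = FALSE)
    }
    i <- i + 1L
    ptm <- "none"
    if (i <= length(chars) && chars[i] == "[") {
      close <- i
      while (close <= length(chars) && chars[close] != "]") close <- close + 1L
      if (close > length(chars)) {
        stop(sprintf("malformed annotation: unterminated PTM tag at residue position %d",
                     pos), call. = FALSE)
      }
      tag <- paste(chars[(i + 1L):(close - 1L)], collapse = "")
      if (!tag %in% .PTM_TAGS) {
        stop(sprintf("unknown PTM tag '[%s]' at residue position %d", tag, pos),
             call. = FALSE)
      }
      ptm <- tag
      i <- close + 1L
    }
    residues[[pos]] <- list(base = base, ptm = ptm)
  }
  peptide_spec(residues, n_cap = n_cap, c_cap = c_cap, label = label)
}

#' Format a peptide specification back to its annotation string
#'
#' Inverse of [parse_annotation()]: `parse_annotation(format_annotation(s))`
#' reproduces `s`.
#'
#' @param spec a [peptide_spec()].
#' @return annotation string.
#' @export
format_annotation <- function(spec) {
  stopifnot(inherits(spec, "peptide_spec"))
  body <- vapply(spec$residues, function(r) {
    if (r$ptm == "none") r$base else sprintf("%s[%s]", r$base, r$ptm)
  }, character(1))
  out <- paste(body, collapse = "")
  if (spec$n_cap == "ACE") out <- paste0("ACE-", out)
  if (spec$c_cap == "NMe") out <- paste0(out, "-NME")
  out
}

#' Formal net charge of a modified peptide
#'
#' Sums per-group contributions at pH ~ 7: free N-terminal amine +1 (acetyl
#' cap 0), free C-terminal acid -1 (N-methyl amide cap 0), Arg/Lys side
#' chains +1 regardless of methylation state, acetyl-Lys 0, Asp/Glu -1,
#' His 0, and phosphorylated Ser/Thr/Tyr -2 (fully deprotonated phosphate).
#'
#' @param spec a [peptide_spec()].
#' @return integer charge in elementary charge units.
#' @examples
#' compute_formal_charge(parse_annotation("ARTKQTARKSTG-NME"))  # +5
#' @export
compute_formal_charge <- function(spec) {
  stopifnot(inherits(spec, "peptide_spec"))
  side <- vapply(spec$residues, function(r) .side_chain_charge(r$base, r$ptm),
                 integer(1))
  term <- (if (spec$n_cap == "free_amine") 1L else 0L) +
    (if (spec$c_cap == "free_acid") -1L else 0L)
  term + sum(side)
}

#' The four study peptides of the H3(1-12) dimerization analysis
#'
#' Returns the four annotated H3 N-terminal tail peptides used throughout
#' the package examples: the unmodified tail with free amine (`P0M0_ala`,
#' charge +5) or N-terminal acetyl cap (`P0M0_ace`, +4), the tail carrying
#' the mitotic phospho-T3/trimethyl-K4/dimethyl-R8 mark set (`P1M2`, +3)
#' and the fully modified, charge-neutral tail (`P2M4`, 0). All four have
#' a C-terminal N-methyl amide cap.
#'
#' @return named list of four [peptide_spec()] objects.
#' @export
builtin_peptides <- function() {
  defs <- c(
    P0M0_ala = "ARTKQTARKSTG-NME",
    P0M0_ace = "ACE-RTKQTARKSTG-NME",
    P1M2     = "ART[ph]K[me3]QTAR[me2]KSTG-NME",
    P2M4     = "ACE-R[me2]T[ph]K[me3]QTAR[me2]K[me3]S[ph]TG-NME"
  )
  out <- lapply(names(defs), function(nm) parse_annotation(defs[[nm]], label = nm))
  names(out) <- names(defs)
  out
}
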