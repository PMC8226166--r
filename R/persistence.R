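# Interaction-persistence analysis.
#
# Persistence of a residue pair is the fraction of trajectory frames in
# which the pair is in close contact (any-atom criterion). Reported maps
# keep pairs at or above a threshold fraction (default 10%, the lower
# reporting bound), label each entry intra- or intermolecular and type it
# via the salt-bridge classifier. Fractions are exact rationals
# (frame counts over total frames) represented in double precision.

#' Persistence fraction of one residue pair
#'
#' @param series a [contact_series()].
#' @param pair canonical pair key `"<chain>:<res>-<chain>:<res>"` (chains
#'   sorted lexically; see the `pair` column of the series' `pair_info`),
#'   or a length-4 vector `c(chain_a, res_a, chain_b, res_b)`.
#' @return fraction of frames in contact, in `[0, 1]`. Pairs never seen in
#'   contact return 0; a malformed key raises an error.
#' @export
persistence_fraction <- function(series, pair) {
  stopifnot(inherits(series, "contact_series"))
  if (length(pair) == 4L) {
    pair <- .pair_key(pair[1], as.integer(pair[2]), pair[3], as.integer(pair[4]))
  }
  if (!is.character(pair) || length(pair) != 1L ||
      !grepl("^[A-Za-z0-9]+:[0-9]+-[A-Za-z0-9]+:[0-9]+$", pair)) {
    stop("malformed residue-pair key: ", pair, call. = FALSE)
  }
  if (!pair %in% colnames(series$incidence)) return(0)
  sum(series$incidence[, pair]) / series$n_frames
}

#' Build a persistence map from a contact series
#'
#' Computes the persistence fraction of every residue pair observed in the
#' series, keeps those at or above `threshold` (inclusive, so a pair
#' present in exactly 10% of frames is reported at the default), excludes
#' intramolecular pairs closer than `exclusion` residues in sequence
#' (|i - j| <= exclusion; bonded neighbours are trivially in contact), and
#' types every entry via [classify_pair()] using the trajectory topology.
#' Entries are sorted by descending persistence.
#'
#' @param series a [contact_series()] built with `include_intra = TRUE`
#'   if intramolecular entries are wanted.
#' @param topology named list mapping chain id to [peptide_spec()];
#'   defaults to the topology stored on the series.
#' @param threshold minimum reported persistence fraction, in `(0, 1]`.
#' @param exclusion intramolecular sequence-separation exclusion window.
#' @return object of class `persistence_map`: a data.frame with columns
#'   `pair`, `chain_a`, `res_a`, `chain_b`, `res_b`, `scope`,
#'   `persistence`, `category`, `donor_modified`; attributes `threshold`
#'   and `n_frames`.
#' @export
build_interaction_map <- function(series, topology = NULL, threshold = 0.10,
                                  exclusion = 2L) {
  stopifnot(inherits(series, "contact_series"))
  if (!(threshold > 0 && threshold <= 1)) {
    stop("threshold must be in (0, 1]", call. = FALSE)
  }
  if (is.null(topology)) topology <- series$topology
  info <- series$pair_info
  empty <- data.frame(pair = character(0), chain_a = character(0),
                      res_a = integer(0), chain_b = character(0),
                      res_b = integer(0), scope = character(0),
                      persistence = numeric(0), category = character(0),
                      donor_modified = logical(0), stringsAsFactors = FALSE)
  if (nrow(info) == 0L) {
    return(structure(empty, class = c("persistence_map", "data.frame"),
                     threshold = threshold, n_frames = series$n_frames))
  }
  frac <- colSums(series$incidence[, info$pair, drop = FALSE]) / series$n_frames
  keep <- frac >= threshold
  # drop near-diagonal intramolecular pairs
  intra_near <- info$scope == "intramolecular" &
    abs(info$res_a - info$res_b) <= exclusion
  keep <- keep & !intra_near
  info <- info[keep, , drop = FALSE]
  frac <- frac[keep]
  if (nrow(info) == 0L) {
    return(structure(empty, class = c("persistence_map", "data.frame"),
                     threshold = threshold, n_frames = series$n_frames))
  }
  cls <- lapply(seq_len(nrow(info)), function(k) {
    ra <- .resolve_residue(info$chain_a[k], info$res_a[k], topology)
    rb <- .resolve_residue(info$chain_b[k], info$res_b[k], topology)
    if (is.null(ra) || is.null(rb)) {
      list(category = "other_contact", donor_modified = FALSE)
    } else {
      classify_pair(ra, rb)
    }
  })
  out <- data.frame(pair = info$pair, chain_a = info$chain_a,
                    res_a = info$res_a, chain_b = info$chain_b,
                    res_b = info$res_b, scope = info$scope,
                    persistence = as.numeric(frac),
                    category = vapply(cls, `[[`, character(1), "category"),
                    donor_modified = vapply(cls, `[[`, logical(1),
                                            "donor_modified"),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$persistence, out$pair), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("persistence_map", "data.frame"),
            threshold = threshold, n_frames = series$n_frames)
}

#' @export
print.persistence_map <- function(x, ...) {
  cat(sprintf("<persistence_map> %d entries (threshold %.0f%%, %d frames)\n",
              nrow(x), 100 * attr(x, "threshold"), attr(x, "n_frames")))
  if (nrow(x)) print.data.frame(x, digits = 3)
  invisible(x)
}

#' Number of intermolecular entries in a persistence map
#'
#' The `n` statistic of a dimer analysis: how many distinct inter-chain
#' residue pairs stay in contact for at least the threshold fraction of
#' the trajectory.
#'
#' @param map a [build_interaction_map()] result.
#' @return integer count.
#' @export
count_intermolecular <- function(map) {
  stopifnot(inherits(map, "persistence_map"))
  sum(map$scope == "intermolecular")
}

#' Write a persistence map as TSV and JSON
#'
#' The TSV carries one entry per line (pair, scope, fraction, category).
#' The JSON document additionally maps each entry's persistence to a line
#' width for a linear interaction diagram, linearly from the threshold
#' (thinnest) to 0.98 (thickest), following the convention of
#' persistence-scaled contact diagrams.
#'
#' @param map a [build_interaction_map()] result.
#' @param tsv_path,json_path output paths (either may be `NULL` to skip).
#' @return invisibly, the list written to JSON.
#' @export
write_interaction_map <- function(map, tsv_path = NULL, json_path = NULL) {
  stopifnot(inherits(map, "persistence_map"))
  if (!is.null(tsv_path)) {
    utils::write.table(as.data.frame(map), tsv_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  thr <- attr(map, "threshold")
  width <- function(p) {
    span <- max(0.98 - thr, 1e-9)
    0.5 + 4.5 * pmin(1, pmax(0, (p - thr) / span))
  }
  doc <- list(threshold = thr, n_frames = attr(map, "n_frames"),
              entries = lapply(seq_len(nrow(map)), function(k) {
                list(pair = map$pair[k], scope = map$scope[k],
                     persistence = map$persistence[k],
                     category = map$category[k],
                     line_width = width(map$persistence[k]))
              }))
  if (!is.null(json_path)) {
    jsonlite::write_json(doc, json_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(doc)
}
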