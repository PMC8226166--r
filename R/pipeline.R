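# End-to-end analysis pipeline: read -> heavy-atom filter -> contacts ->
# persistence -> SASA -> report files.
#
# Reports are tab-separated UTF-8 with one header line. Summary floats
# mirror the display precision of the motivating study's tables (one
# decimal for N_cc, whole Angstrom^2 for dA); full precision is retained
# in the JSON outputs. No RNG is used anywhere in the analysis path, so
# re-running a configuration reproduces every report byte for byte.

#' Build and validate a run configuration
#'
#' @param trajectory path to a multi-model PDB trajectory.
#' @param topology path to the YAML topology sidecar (see
#'   [read_topology()]).
#' @param out_dir directory for report files (`NULL` to skip writing).
#' @param cutoff close-contact cutoff, A.
#' @param threshold persistence reporting threshold, in `(0, 1]`.
#' @param probe SASA probe radius, A.
#' @param n_points SASA sphere points per atom.
#' @param stride analyse every `stride`-th frame.
#' @param exclusion intramolecular sequence-separation exclusion window.
#' @param label dimer label; defaults to the sidecar's.
#' @return object of class `run_config`.
#' @export
run_config <- function(trajectory, topology, out_dir = NULL,
                       cutoff = 4.0, threshold = 0.10, probe = 1.4,
                       n_points = 960, stride = 1L, exclusion = 2L,
                       label = NULL) {
  if (!file.exists(trajectory)) {
    stop("trajectory file not found: ", trajectory, call. = FALSE)
  }
  if (!file.exists(topology)) {
    stop("topology file not found: ", topology, call. = FALSE)
  }
  stopifnot(cutoff > 0, probe > 0, n_points >= 32, stride >= 1,
            exclusion >= 0)
  if (!(threshold > 0 && threshold <= 1)) {
    stop("threshold must be in (0, 1]", call. = FALSE)
  }
  structure(list(trajectory = trajectory, topology = topology,
                 out_dir = out_dir, cutoff = cutoff, threshold = threshold,
                 probe = probe, n_points = n_points,
                 stride = as.integer(stride), exclusion = as.integer(exclusion),
                 label = label),
            class = "run_config")
}

#' Run the full dimer analysis for one trajectory
#'
#' Reads the trajectory and topology, restricts to heavy atoms, computes
#' per-frame close contacts and the N_cc statistic, the persistence map
#' at the configured threshold, and the buried-surface series
#' `dA = <A1 + A2 - A12>`. When `config$out_dir` is set, writes
#' `summary.tsv` (label, conformation, N_cc, dA), `interaction_map.tsv` /
#' `interaction_map.json`, `contacts.tsv` (per frame and residue pair),
#' `sasa.tsv` (per frame) and `run.log` (parameters, frame counts and the
#' formal charges of the chain peptides).
#'
#' @param config a [run_config()].
#' @return object of class `report_bundle`: list with `label`,
#'   `conformation`, `mean_ncc`, `delta_A`, `n_intermolecular`, `map`,
#'   `contacts` ([contact_series()]), `sasa` ([delta_sasa()] result),
#'   `charges`, `n_frames_analysed`, `files` (paths written, or `NULL`).
#' @export
run_analysis <- function(config) {
  stopifnot(inherits(config, "run_config"))
  stage <- function(what, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", what,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  topo <- stage("topology", read_topology(config$topology))
  traj <- stage("read", read_multimodel_pdb(config$trajectory,
                                            topology = topo$chains))
  n_total <- n_frames(traj)
  traj <- stage("heavy-atom filter", heavy_atom_view(traj))
  traj <- stride_view(traj, config$stride)
  n_used <- n_frames(traj)

  contacts <- stage("contacts",
                    contact_series(traj, cutoff = config$cutoff,
                                   include_intra = TRUE))
  map <- stage("persistence",
               build_interaction_map(contacts, topology = topo$chains,
                                     threshold = config$threshold,
                                     exclusion = config$exclusion))
  sasa <- stage("sasa",
                delta_sasa(traj, probe = config$probe,
                           n_points = config$n_points))

  charges <- vapply(topo$chains, compute_formal_charge, integer(1))
  label <- config$label %||% topo$label
  conformation <- topo$conformation %||% "unspecified"

  bundle <- structure(
    list(label = label, conformation = conformation,
         mean_ncc = mean_ncc(contacts), delta_A = sasa$delta_A,
         n_intermolecular = count_intermolecular(map), map = map,
         contacts = contacts, sasa = sasa, charges = charges,
         n_frames_total = n_total, n_frames_analysed = n_used,
         config = config, files = NULL),
    class = "report_bundle")

  if (!is.null(config$out_dir)) {
    bundle$files <- .write_reports(bundle, config)
  }
  bundle
}

#' @export
print.report_bundle <- function(x, ...) {
  cat(sprintf("<report_bundle> %s (%s): N_cc = %.1f, dA = %.0f A^2, n_inter = %d (%d frames)\n",
              x$label, x$conformation, x$mean_ncc, x$delta_A,
              x$n_intermolecular, x$n_frames_analysed))
  invisible(x)
}

# write the report files; returns named paths
.write_reports <- function(bundle, config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    summary = file.path(config$out_dir, "summary.tsv"),
    map_tsv = file.path(config$out_dir, "interaction_map.tsv"),
    map_json = file.path(config$out_dir, "interaction_map.json"),
    contacts = file.path(config$out_dir, "contacts.tsv"),
    sasa = file.path(config$out_dir, "sasa.tsv"),
    log = file.path(config$out_dir, "run.log")
  )
  summary_df <- data.frame(
    dimer = bundle$label, conformation = bundle$conformation,
    N_cc = sprintf("%.1f", bundle$mean_ncc),
    delta_A = sprintf("%.0f", bundle$delta_A),
    n_intermolecular = bundle$n_intermolecular)
  utils::write.table(summary_df, paths$summary, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_interaction_map(bundle$map, paths$map_tsv, paths$map_json)

  cs <- bundle$contacts
  ct <- .contact_table(cs)
  utils::write.table(ct, paths$contacts, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(
    within(bundle$sasa$per_frame, {
      A1 <- sprintf("%.3f", A1); A2 <- sprintf("%.3f", A2)
      A12 <- sprintf("%.3f", A12); buried <- sprintf("%.3f", buried)
    }),
    paths$sasa, sep = "\t", quote = FALSE, row.names = FALSE)

  log_lines <- c(
    sprintf("trajectory: %s", config$trajectory),
    sprintf("topology: %s", config$topology),
    sprintf("dimer: %s  conformation: %s", bundle$label,
            bundle$conformation),
    sprintf("parameters: cutoff=%.2f A threshold=%.3f probe=%.2f A points=%d stride=%d exclusion=%d",
            config$cutoff, config$threshold, config$probe, config$n_points,
            config$stride, config$exclusion),
    sprintf("frames: %d read, %d analysed", bundle$n_frames_total,
            bundle$n_frames_analysed),
    sprintf("formal charges: %s",
            paste(sprintf("%s=%+d", names(bundle$charges), bundle$charges),
                  collapse = " ")),
    sprintf("mean N_cc: %.4f", bundle$mean_ncc),
    sprintf("delta_A: %.4f A^2", bundle$delta_A),
    sprintf("intermolecular interactions >= threshold: %d",
            bundle$n_intermolecular))
  writeLines(log_lines, paths$log)
  paths
}

# long per-frame contact table: frame, chain/residue pair, min distance,
# category
.contact_table <- function(cs) {
  info <- cs$pair_info[cs$pair_info$scope == "intermolecular", ,
                       drop = FALSE]
  out <- list()
  for (k in seq_len(nrow(info))) {
    frames <- which(cs$incidence[, info$pair[k]])
    if (!length(frames)) next
    ra <- .resolve_residue(info$chain_a[k], info$res_a[k], cs$topology)
    rb <- .resolve_residue(info$chain_b[k], info$res_b[k], cs$topology)
    cat_k <- if (is.null(ra) || is.null(rb)) "other_contact" else
      classify_pair(ra, rb)$category
    out[[length(out) + 1L]] <- data.frame(
      frame = frames,
      chainA_res = sprintf("%s:%d", info$chain_a[k], info$res_a[k]),
      chainB_res = sprintf("%s:%d", info$chain_b[k], info$res_b[k]),
      category = cat_k)
  }
  if (!length(out)) {
    return(data.frame(frame = integer(0), chainA_res = character(0),
                      chainB_res = character(0), category = character(0)))
  }
  out <- do.call(rbind, out)
  out[order(out$frame, out$chainA_res, out$chainB_res), , drop = FALSE]
}

#' Compare several analysed dimers
#'
#' Assembles the per-run headline statistics into one long table keyed by
#' dimer and conformation, the package's analogue of a multi-dimer
#' comparison table (N_cc, dA, number of persistent intermolecular
#' interactions).
#'
#' @param bundles list of [run_analysis()] results (at least two).
#' @return data.frame with columns `dimer`, `conformation`, `N_cc`,
#'   `delta_A`, `n_intermolecular`.
#' @export
compare_runs <- function(bundles) {
  stopifnot(is.list(bundles), length(bundles) >= 2L)
  lapply(bundles, function(b) stopifnot(inherits(b, "report_bundle")))
  out <- do.call(rbind, lapply(bundles, function(b) {
    data.frame(dimer = b$label, conformation = b$conformation,
               N_cc = b$mean_ncc, delta_A = b$delta_A,
               n_intermolecular = b$n_intermolecular,
               stringsAsFactors = FALSE)
  }))
  key <- paste(out$dimer, out$conformation, sep = "/")
  if (anyDuplicated(key)) {
    stop("duplicate (dimer, conformation) keys: ",
         paste(unique(key[duplicated(key)]), collapse = ", "), call. = FALSE)
  }
  rownames(out) <- NULL
  out
}
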