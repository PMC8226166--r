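# Shrake-Rupley solvent-accessible surface area and the buried-area
# statistic dA = <A1 + A2 - A12>.
#
# Test points are placed on a deterministic golden-section spiral lattice
# (no RNG), so SASA values are bit-reproducible. A point on atom i's
# expanded sphere (radius r_i + probe) is accessible when it lies outside
# every other atom's expanded sphere; the atom's SASA is the accessible
# fraction of its expanded-sphere area.

#' Default atomic radius set (Bondi-derived, Angstrom)
#'
#' Van der Waals radii for the elements occurring in peptides. Hydrogens
#' are excluded from SASA by convention in this package (heavy-atom
#' universe); no united-atom inflation is applied.
#'
#' @return named numeric vector of radii.
#' @export
default_atomic_radii <- function() {
  c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80)
}

# deterministic unit-sphere lattice: golden-section spiral
golden_spiral_points <- function(n) {
  stopifnot(n >= 1)
  k <- seq_len(n) - 1L
  z <- 1 - (2 * k + 1) / n
  phi <- k * pi * (3 - sqrt(5))
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Shrake-Rupley solvent-accessible surface area of a frame
#'
#' @param frame a heavy-atom `traj_frame` (one or more chains).
#' @param probe probe radius in Angstrom (1.4, water).
#' @param n_points number of test points per atom (deterministic
#'   golden-spiral lattice; minimum 32).
#' @param radii named atomic-radius table (see
#'   [default_atomic_radii()]).
#' @return list with `total` (A^2) and `per_atom` (A^2 per atom).
#' @export
shrake_rupley <- function(frame, probe = 1.4, n_points = 960,
                          radii = default_atomic_radii()) {
  stopifnot(inherits(frame, "traj_frame"))
  if (n_points < 32) stop("n_points must be at least 32", call. = FALSE)
  elem <- toupper(frame$atoms$element)
  unknown <- setdiff(unique(elem), names(radii))
  if (length(unknown)) {
    stop("no atomic radius for element(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  xyz <- frame$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, ncol = 3L)
  n <- nrow(xyz)
  r <- unname(radii[elem]) + probe
  pts <- golden_spiral_points(n_points)

  # pairwise squared distances between atom centres, for neighbour lists
  if (n > 1L) {
    d2 <- as.matrix(stats::dist(xyz))^2
  }
  per_atom <- numeric(n)
  for (i in seq_len(n)) {
    if (n > 1L) {
      rsum <- r[i] + r[-i]
      nb <- which(d2[i, -i] < rsum^2)
      nb_idx <- seq_len(n)[-i][nb]
      # closest occluders first: they bury the most points, so the
      # surviving set shrinks fastest
      nb_idx <- nb_idx[order(d2[i, nb_idx])]
    } else {
      nb_idx <- integer(0)
    }
    p <- pts * r[i]
    p <- sweep(p, 2, xyz[i, ], "+")
    acc <- rep(TRUE, n_points)
    for (j in nb_idx) {
      live <- which(acc)
      if (length(live) == 0L) break
      dv <- p[live, , drop = FALSE] -
        matrix(xyz[j, ], length(live), 3, byrow = TRUE)
      acc[live[rowSums(dv * dv) < r[j]^2]] <- FALSE
    }
    per_atom[i] <- 4 * pi * r[i]^2 * sum(acc) / n_points
  }
  list(total = sum(per_atom), per_atom = per_atom)
}

#' Buried surface area of a two-chain trajectory
#'
#' For every frame computes `A12` (SASA of the full dimer frame) and `A1`,
#' `A2` (SASA of each chain with the partner deleted, on in-complex
#' coordinates), then averages the per-frame buried area
#' `A1 + A2 - A12` over the trajectory:
#' `dA = <A1 + A2 - A12>`. Splitting a complex can only expose surface,
#' so each per-frame buried area is non-negative up to the lattice
#' resolution.
#'
#' @param traj a two-chain heavy-atom [trajectory()].
#' @param probe probe radius in Angstrom.
#' @param n_points test points per atom.
#' @param radii named atomic-radius table.
#' @param stride analyse every `stride`-th frame.
#' @return object of class `sasa_series`: list with `delta_A` (A^2, the
#'   time average), `per_frame` (data.frame `frame`, `A1`, `A2`, `A12`,
#'   `buried`), `probe_radius`, `n_sphere_points`.
#' @export
delta_sasa <- function(traj, probe = 1.4, n_points = 960,
                       radii = default_atomic_radii(), stride = 1L) {
  stopifnot(inherits(traj, "trajectory"))
  chains <- chain_ids(traj)
  if (length(chains) != 2L) {
    stop("delta_sasa requires a two-chain trajectory", call. = FALSE)
  }
  traj <- stride_view(traj, stride)
  nf <- n_frames(traj)
  A1 <- A2 <- A12 <- numeric(nf)
  for (f in seq_len(nf)) {
    fr <- get_frame(traj, f)
    A12[f] <- shrake_rupley(fr, probe, n_points, radii)$total
    A1[f] <- shrake_rupley(chain_view(fr, chains[1]), probe, n_points, radii)$total
    A2[f] <- shrake_rupley(chain_view(fr, chains[2]), probe, n_points, radii)$total
  }
  buried <- A1 + A2 - A12
  structure(list(delta_A = mean(buried),
                 per_frame = data.frame(frame = seq_len(nf), A1 = A1, A2 = A2,
                                        A12 = A12, buried = buried),
                 probe_radius = probe, n_sphere_points = n_points),
            class = "sasa_series")
}

#' @export
print.sasa_series <- function(x, ...) {
  cat(sprintf("<sasa_series> %d frames, probe %.2f A, %d points, dA = %.1f A^2\n",
              nrow(x$per_frame), x$probe_radius, x$n_sphere_points, x$delta_A))
  invisible(x)
}

#' Exact SASA of a two-sphere system
#'
#' Closed-form accessible area of two spheres of expanded radii `R1`,
#' `R2` whose centres are `d` apart: each sphere loses a spherical cap
#' where it dips inside the other. Used as an analytic oracle for the
#' lattice computation.
#'
#' @param R1,R2 expanded radii (atom radius + probe), Angstrom.
#' @param d centre-centre distance, Angstrom.
#' @return list with `total`, `area1`, `area2` (A^2).
#' @export
two_sphere_sasa_exact <- function(R1, R2, d) {
  stopifnot(d > abs(R1 - R2))  # neither sphere swallowed
  if (d >= R1 + R2) {
    return(list(total = 4 * pi * (R1^2 + R2^2),
                area1 = 4 * pi * R1^2, area2 = 4 * pi * R2^2))
  }
  # distance from centre 1 to the plane of the intersection circle
  x1 <- (d^2 + R1^2 - R2^2) / (2 * d)
  x2 <- d - x1
  cap1 <- 2 * pi * R1 * (R1 - x1)
  cap2 <- 2 * pi * R2 * (R2 - x2)
  list(total = 4 * pi * R1^2 - cap1 + 4 * pi * R2^2 - cap2,
       area1 = 4 * pi * R1^2 - cap1,
       area2 = 4 * pi * R2^2 - cap2)
}
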