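# Default van der Waals radii (Angstrom) by element; overridable in
# shrake_rupley_sasa().
default_vdw_radii <- c(C = 1.7, N = 1.55, O = 1.52, S = 1.8, H = 1.2, P = 1.8)

# Deterministic quasi-uniform points on the unit sphere (golden spiral).
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' Classic sphere-point SASA: each atom's solvent-accessible sphere
#' (vdW radius + probe radius) is sampled with `n_points` quasi-uniform
#' points; the accessible fraction is the fraction of points outside
#' every neighbouring atom's accessible sphere.
#'
#' @param coords `A x 3` coordinates (Angstrom)
#' @param elements element symbol per atom (used to look up radii)
#' @param probe probe radius, Angstrom (water: 1.4)
#' @param n_points sphere points per atom
#' @param radii optional named vector overriding/extending the default
#'   element radii
#' @param topology optional [md_topology()]; when given, per-residue
#'   totals are reported
#' @return list of class `sasa_result`: `atom_sasa` (Angstrom^2 per
#'   atom), `residue_sasa` (named, when a topology is given), `total`
#'   (Angstrom^2) and `total_nm2`
#' @export
shrake_rupley_sasa <- function(coords, elements, probe = 1.4, n_points = 960,
                               radii = NULL, topology = NULL) {
  coords <- matrix(coords, ncol = 3L)
  rtab <- default_vdw_radii
  if (!is.null(radii)) rtab[names(radii)] <- radii
  unknown <- setdiff(unique(elements), names(rtab))
  if (length(unknown)) {
    stop("no vdW radius for element(s): ", paste(unknown, collapse = ", "),
         " (supply via 'radii')")
  }
  r <- rtab[elements] + probe
  n <- nrow(coords)
  pts <- sphere_points(n_points)
  sasa <- numeric(n)
  if (n > 1L) {
    d <- cross_dist(coords, coords)
  }
  for (i in seq_len(n)) {
    p <- pts * r[i]
    p <- sweep(p, 2L, coords[i, ], "+")
    acc <- rep(TRUE, n_points)
    if (n > 1L) {
      nb <- which(d[i, ] < r[i] + r & seq_len(n) != i)
      for (j in nb) {
        if (!any(acc)) break
        dj2 <- rowSums(sweep(p[acc, , drop = FALSE], 2L, coords[j, ])^2)
        # points strictly inside a neighbour are buried; points exactly
        # on the shared boundary are kept by the lower-indexed atom so
        # coincident spheres contribute their surface once
        if (j < i) {
          acc[acc] <- dj2 > r[j]^2 + 1e-6
        } else {
          acc[acc] <- dj2 > r[j]^2 - 1e-6
        }
      }
    }
    sasa[i] <- 4 * pi * r[i]^2 * sum(acc) / n_points
  }
  residue_sasa <- NULL
  if (!is.null(topology)) {
    rs <- tapply(sasa, topology$atoms$residue_id, sum)
    residue_sasa <- as.numeric(rs)
    names(residue_sasa) <- residue_labels(topology, as.integer(names(rs)))
  }
  structure(list(atom_sasa = sasa, residue_sasa = residue_sasa,
                 total = sum(sasa), total_nm2 = sum(sasa) / 100),
            class = "sasa_result")
}

#' @export
print.sasa_result <- function(x, ...) {
  cat(sprintf("sasa_result: total %.1f Angstrom^2 (%.2f nm^2), %d atoms\n",
              x$total, x$total_nm2, length(x$atom_sasa)))
  invisible(x)
}
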