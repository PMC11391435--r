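# Simplified 4-code secondary structure {H, E, T, C}.
#
# Backbone hydrogen bonds are scored with the Kabsch-Sander
# electrostatic model, E = 27.888 * (1/rON + 1/rCH - 1/rOH - 1/rCN)
# kcal/mol (distances in Angstrom), bond iff E < -0.5 kcal/mol.
# i -> i+4 turn ladders give H, bridge patterns give E, isolated
# 3/4/5-turns give T, everything else C. G/I helices and single
# bridges are deliberately folded into H/E/C: only the four coarse
# classes are interpreted downstream.

# NeRF placement: position a new atom given three predecessors and
# internal coordinates (bond Angstrom, angle/torsion degrees).
place_atom <- function(a, b, c, bond, angle, torsion) {
  ang <- angle * pi / 180
  tor <- torsion * pi / 180
  bc <- unit(c - b)
  n <- unit(pracma_cross(b - a, bc))
  m <- pracma_cross(n, bc)
  d2 <- c(-bond * cos(ang), bond * sin(ang) * cos(tor), bond * sin(ang) * sin(tor))
  c + cbind(bc, m, n) %*% d2
}

pracma_cross <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

#' Build an ideal peptide backbone chain
#'
#' Generates N, CA, C, O (and amide H from the second residue on)
#' backbone coordinates for a poly-peptide at fixed backbone dihedrals,
#' using standard bond lengths and angles. An alpha-helix corresponds
#' to roughly `phi = -57`, `psi = -47`; an extended strand to
#' `phi = -139`, `psi = 135`.
#'
#' @param n_res number of residues (>= 2)
#' @param phi,psi backbone dihedrals in degrees (recycled per residue)
#' @param chain chain id
#' @param resid residue name used for all residues
#' @param resno_start first author residue number
#' @return list with `topology` ([md_topology()]) and `coords` (`A x 3`)
#' @export
build_peptide_chain <- function(n_res, phi = -57, psi = -47, chain = "A",
                                resid = "ALA", resno_start = 1L) {
  stopifnot(n_res >= 2L)
  phi <- rep_len(phi, n_res); psi <- rep_len(psi, n_res)
  N <- matrix(0, n_res, 3L); CA <- N; C <- N; O <- N
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(1.458, 0, 0)
  ang <- 111.2 * pi / 180
  C[1, ] <- CA[1, ] + 1.525 * c(-cos(ang), sin(ang), 0)
  for (i in seq_len(n_res - 1L)) {
    N[i + 1, ] <- place_atom(N[i, ], CA[i, ], C[i, ], 1.329, 116.2, psi[i])
    CA[i + 1, ] <- place_atom(CA[i, ], C[i, ], N[i + 1, ], 1.458, 121.7, 180)
    C[i + 1, ] <- place_atom(C[i, ], N[i + 1, ], CA[i + 1, ], 1.525, 111.2,
                             phi[i + 1])
  }
  for (i in seq_len(n_res)) {
    O[i, ] <- place_atom(N[i, ], CA[i, ], C[i, ], 1.231, 120.8, psi[i] + 180)
  }
  atoms <- NULL; coords <- NULL
  for (i in seq_len(n_res)) {
    names_i <- c("N", "CA", "C", "O", "H")
    # first residue has no preceding carbonyl; bisect against its own C
    h <- if (i > 1L) amide_h(N[i, ], CA[i, ], C[i - 1, ]) else
      amide_h(N[1, ], CA[1, ], C[1, ])
    xyz_i <- rbind(N[i, ], CA[i, ], C[i, ], O[i, ], h)
    atoms <- rbind(atoms, data.frame(
      elety = names_i,
      elesy = substr(names_i, 1L, 1L),
      resno = resno_start + i - 1L, resid = resid, chain = chain,
      stringsAsFactors = FALSE))
    coords <- rbind(coords, xyz_i)
  }
  bonds <- infer_h_bonds(atoms, coords)
  list(topology = md_topology(atoms, bonds = bonds), coords = coords)
}

# Amide hydrogen on N along the bisector of N->CA and N->C(prev),
# pointing away from both, at 1.01 Angstrom.
amide_h <- function(n, ca, c_prev) {
  n + 1.01 * unit(-(unit(ca - n) + unit(c_prev - n)))
}

# Backbone atom indices per residue: matrix res x (N, CA, C, O, H);
# NA where missing.
backbone_index <- function(top) {
  res <- top$residues$residue_id
  out <- matrix(NA_integer_, length(res), 5L,
                dimnames = list(NULL, c("N", "CA", "C", "O", "H")))
  a <- top$atoms
  for (k in seq_along(res)) {
    rows <- which(a$residue_id == res[k])
    for (nm in colnames(out)) {
      hit <- rows[a$elety[rows] == nm]
      if (length(hit)) out[k, nm] <- hit[1L]
    }
  }
  out
}

#' Assign simplified secondary structure to one frame
#'
#' @param coords `A x 3` coordinates (Angstrom) of one frame
#' @param topology an [md_topology()]; residues must carry backbone
#'   N, CA, C, O atoms (amide H is reconstructed geometrically when
#'   absent); residues missing a backbone atom are assigned `C` with a
#'   warning
#' @param e_cut hydrogen-bond energy cutoff, kcal/mol
#' @return character vector of codes in `{H, E, T, C}`, one per residue
#' @export
assign_ss <- function(coords, topology, e_cut = -0.5) {
  coords <- matrix(coords, ncol = 3L)
  bb <- backbone_index(topology)
  nres <- nrow(bb)
  chain <- topology$residues$chain
  ok <- !is.na(bb[, "N"]) & !is.na(bb[, "CA"]) & !is.na(bb[, "C"]) & !is.na(bb[, "O"])
  if (any(!ok)) warning(sum(!ok), " residue(s) missing backbone atoms assigned C")

  # donor H position per residue (reconstructed when absent)
  hpos <- matrix(NA_real_, nres, 3L)
  for (i in seq_len(nres)) {
    if (!ok[i]) next
    if (!is.na(bb[i, "H"])) {
      hpos[i, ] <- coords[bb[i, "H"], ]
    } else if (i > 1L && ok[i - 1L] && chain[i - 1L] == chain[i]) {
      hpos[i, ] <- amide_h(coords[bb[i, "N"], ], coords[bb[i, "CA"], ],
                           coords[bb[i - 1L, "C"], ])
    }
  }

  # hb[d, a]: N-H of residue d donates to C=O of residue a
  hb <- matrix(FALSE, nres, nres)
  don <- which(ok & !is.na(hpos[, 1L]))
  acc <- which(ok)
  if (length(don) && length(acc)) {
    dON <- cross_dist(coords[bb[acc, "O"], , drop = FALSE],
                      coords[bb[don, "N"], , drop = FALSE])
    cand <- which(dON < 5.2, arr.ind = TRUE)  # K-S energy is negligible beyond
    for (k in seq_len(nrow(cand))) {
      a <- acc[cand[k, 1L]]; d <- don[cand[k, 2L]]
      if (a == d) next
      if (chain[a] == chain[d] && abs(a - d) <= 1L) next
      rON <- dON[cand[k, 1L], cand[k, 2L]]
      rCH <- vnorm(coords[bb[a, "C"], ] - hpos[d, ])
      rOH <- vnorm(coords[bb[a, "O"], ] - hpos[d, ])
      rCN <- vnorm(coords[bb[a, "C"], ] - coords[bb[d, "N"], ])
      if (min(rON, rCH, rOH, rCN) < 0.5) next
      e <- 27.888 * (1 / rON + 1 / rCH - 1 / rOH - 1 / rCN)
      if (e < e_cut) hb[d, a] <- TRUE
    }
  }

  same_chain_gap <- function(i, j, n) {
    i >= 1L && j >= 1L && i <= nres && j <= nres &&
      chain[i] == chain[j] && abs(i - j) == n
  }
  turn <- function(i, n) {
    j <- i + n
    j <= nres && same_chain_gap(i, j, n) && hb[j, i]
  }

  code <- rep("C", nres)
  # helices: two consecutive i -> i+4 turns mark residues i+1..i+4
  for (i in seq_len(nres)) {
    if (i >= 2L && turn(i - 1L, 4L) && turn(i, 4L)) {
      code[(i + 1L):min(i + 4L, nres)] <- "H"
    }
  }
  # bridges (sequence-separated or cross-chain backbone pairing)
  hbs <- function(d, a) d >= 1L && a >= 1L && d <= nres && a <= nres && hb[d, a]
  for (i in seq_len(nres)) {
    for (j in seq_len(nres)) {
      if (j <= i) next
      if (chain[i] == chain[j] && j - i < 3L) next
      anti <- (hbs(i, j) && hbs(j, i)) ||
        (hbs(i + 1L, j - 1L) && hbs(j + 1L, i - 1L))
      para <- (hbs(i + 1L, j) && hbs(j, i - 1L)) ||
        (hbs(j + 1L, i) && hbs(i, j - 1L))
      if (anti || para) {
        if (code[i] == "C" || code[i] == "T") code[i] <- "E"
        if (code[j] == "C" || code[j] == "T") code[j] <- "E"
      }
    }
  }
  # isolated turns
  for (n in 3:5) {
    for (i in seq_len(nres)) {
      if (turn(i, n)) {
        span <- (i + 1L):(i + n - 1L)
        span <- span[span <= nres & code[span] == "C"]
        code[span] <- "T"
      }
    }
  }
  code[!ok] <- "C"
  names(code) <- residue_labels(topology)
  code
}

#' Per-residue secondary-structure fractions over a frame sample
#'
#' Assigns the simplified code to every frame and reports, per residue,
#' the percentage of frames carrying each code. Rows sum to 100.
#'
#' @param traj_sample an [md_trajectory()] (typically produced by
#'   [window_frames()] / [concatenate_trajectories()])
#' @return data.frame of class `ss_profile` with columns `residue`,
#'   `H`, `E`, `T`, `C` (percent of frames)
#' @export
ss_fractions <- function(traj_sample) {
  nf <- n_frames(traj_sample)
  top <- traj_sample$topology
  codes <- c("H", "E", "T", "C")
  counts <- matrix(0, nrow(top$residues), 4L, dimnames = list(NULL, codes))
  for (f in seq_len(nf)) {
    ss <- assign_ss(traj_sample$coords[, , f], top)
    for (cd in codes) counts[, cd] <- counts[, cd] + (ss == cd)
  }
  out <- data.frame(residue = residue_labels(top),
                    100 * counts / nf,
                    stringsAsFactors = FALSE, check.names = FALSE)
  class(out) <- c("ss_profile", "data.frame")
  out
}
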