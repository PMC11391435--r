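#' Geometric hydrogen-bond criteria
#'
#' Defaults follow the common trajectory-analysis convention: donor to
#' acceptor heavy-atom distance at most 3.5 Angstrom, and the angle
#' between the donor-to-hydrogen bond vector and the donor-to-acceptor
#' vector (the out-of-linearity angle) at most 30 degrees, restricted
#' to polar atoms.
#'
#' @param d_DA_max maximum donor-acceptor distance, Angstrom
#' @param angle_max maximum D-H / D-A angle, degrees (0 < angle < 90)
#' @param polar_only restrict donors/acceptors to polar atoms
#' @return list of class `hbond_criteria`
#' @export
hbond_criteria <- function(d_DA_max = 3.5, angle_max = 30, polar_only = TRUE) {
  stopifnot_scalar_num(d_DA_max, "d_DA_max", positive = TRUE)
  stopifnot_scalar_num(angle_max, "angle_max")
  if (angle_max <= 0 || angle_max >= 90) stop("angle_max must be in (0, 90)")
  structure(list(d_DA_max = d_DA_max, angle_max = angle_max,
                 polar_only = isTRUE(polar_only)),
            class = "hbond_criteria")
}

# Donor heavy atoms with their bonded hydrogens from the topology bond
# list. Returns data.frame (donor, hydrogen).
donor_hydrogens <- function(top, donors) {
  b <- top$bonds
  if (is.null(b) || !nrow(b)) {
    return(data.frame(donor = integer(0), hydrogen = integer(0)))
  }
  h <- top$atoms$elesy == "H"
  dh <- rbind(
    data.frame(donor = b[, 2L], hydrogen = b[, 1L])[h[b[, 1L]] & !h[b[, 2L]], ],
    data.frame(donor = b[, 1L], hydrogen = b[, 2L])[h[b[, 2L]] & !h[b[, 1L]], ]
  )
  dh[dh$donor %in% donors, , drop = FALSE]
}

#' Detect hydrogen bonds in one frame
#'
#' A triple (D, H, A) is reported iff `dist(D, A) <= d_DA_max` and the
#' angle between D->H and D->A is at most `angle_max`. Donors must be
#' heavy atoms carrying at least one bonded hydrogen (donors with no
#' bonded hydrogen are skipped with a warning); intra-residue pairs are
#' excluded by default.
#'
#' @param coords `A x 3` frame coordinates (Angstrom)
#' @param topology an [md_topology()] with a hydrogen bond list
#' @param criteria an [hbond_criteria()]
#' @param donors,acceptors candidate heavy-atom indices; default: all
#'   polar heavy atoms (per `criteria$polar_only`)
#' @param exclude_intra drop donor/acceptor pairs within one residue
#' @return data.frame with atom indices `donor`, `hydrogen`, `acceptor`,
#'   their labels, `d_DA` (Angstrom) and `angle` (degrees)
#' @export
detect_hbonds <- function(coords, topology, criteria = hbond_criteria(),
                          donors = NULL, acceptors = NULL,
                          exclude_intra = TRUE) {
  coords <- matrix(coords, ncol = 3L)
  a <- topology$atoms
  heavy_polar <- which(a$elesy != "H" & (if (criteria$polar_only) a$is_polar else TRUE))
  donors_given <- !is.null(donors)
  if (is.null(donors)) donors <- heavy_polar
  if (is.null(acceptors)) acceptors <- heavy_polar
  donors <- setdiff(donors, which(a$elesy == "H"))
  acceptors <- setdiff(acceptors, which(a$elesy == "H"))
  dh <- donor_hydrogens(topology, donors)
  no_h <- setdiff(donors, dh$donor)
  if (length(no_h) && donors_given) {
    warning(length(no_h), " donor atom(s) without a bonded hydrogen skipped")
  }
  empty <- data.frame(donor = integer(0), hydrogen = integer(0),
                      acceptor = integer(0), donor_label = character(0),
                      acceptor_label = character(0), d_DA = numeric(0),
                      angle = numeric(0), stringsAsFactors = FALSE)
  if (!nrow(dh) || !length(acceptors)) return(empty)
  dmat <- cross_dist(coords[dh$donor, , drop = FALSE],
                     coords[acceptors, , drop = FALSE])
  hits <- which(dmat <= criteria$d_DA_max, arr.ind = TRUE)
  if (!nrow(hits)) return(empty)
  out <- NULL
  for (k in seq_len(nrow(hits))) {
    di <- hits[k, 1L]; ai <- acceptors[hits[k, 2L]]
    D <- dh$donor[di]; H <- dh$hydrogen[di]
    if (ai == D || ai == H) next
    if (exclude_intra && a$residue_id[ai] == a$residue_id[D]) next
    vDH <- coords[H, ] - coords[D, ]
    vDA <- coords[ai, ] - coords[D, ]
    cosang <- sum(vDH * vDA) / (vnorm(vDH) * vnorm(vDA))
    ang <- acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
    if (ang <= criteria$angle_max) {
      out <- rbind(out, data.frame(
        donor = D, hydrogen = H, acceptor = ai,
        donor_label = atom_label(topology, D),
        acceptor_label = atom_label(topology, ai),
        d_DA = dmat[di, hits[k, 2L]], angle = ang,
        stringsAsFactors = FALSE))
    }
  }
  if (is.null(out)) empty else out
}

atom_label <- function(top, i) {
  a <- top$atoms[i, ]
  sprintf("%s:%s %d %s", a$chain, a$resid, a$resno, a$elety)
}

#' Hydrogen-bond occupancy over a trajectory
#'
#' Occupancy of a (donor, hydrogen, acceptor) triple is the percentage
#' of frames in which it satisfies the geometric criteria. The
#' denominator is the frame count of the supplied (already windowed)
#' trajectory. Pairs never observed are absent from the table (0%).
#'
#' @param traj an [md_trajectory()], windowed to the analysis span
#' @param criteria an [hbond_criteria()]
#' @param donors,acceptors candidate heavy-atom index sets (must be
#'   non-empty if supplied)
#' @param exclude_intra drop intra-residue pairs
#' @return data.frame of class `hbond_table`: key columns (`donor`,
#'   `hydrogen`, `acceptor`, labels) plus `occupancy` (percent)
#' @export
hbond_occupancy <- function(traj, criteria = hbond_criteria(),
                            donors = NULL, acceptors = NULL,
                            exclude_intra = TRUE) {
  if ((!is.null(donors) && !length(donors)) ||
      (!is.null(acceptors) && !length(acceptors))) {
    stop("empty atom selection")
  }
  nf <- n_frames(traj)
  counts <- new.env(parent = emptyenv())
  meta <- new.env(parent = emptyenv())
  for (f in seq_len(nf)) {
    hb <- detect_hbonds(traj$coords[, , f], traj$topology, criteria,
                        donors = donors, acceptors = acceptors,
                        exclude_intra = exclude_intra)
    if (!nrow(hb)) next
    keys <- paste(hb$donor, hb$hydrogen, hb$acceptor)
    for (k in seq_along(keys)) {
      key <- keys[k]
      counts[[key]] <- (counts[[key]] %||% 0L) + 1L
      if (is.null(meta[[key]])) meta[[key]] <- hb[k, c("donor", "hydrogen",
                                                       "acceptor", "donor_label",
                                                       "acceptor_label")]
    }
  }
  keys <- ls(counts)
  if (!length(keys)) {
    out <- data.frame(donor = integer(0), hydrogen = integer(0),
                      acceptor = integer(0), donor_label = character(0),
                      acceptor_label = character(0), occupancy = numeric(0))
  } else {
    out <- do.call(rbind, lapply(keys, function(k) meta[[k]]))
    out$occupancy <- 100 * vapply(keys, function(k) counts[[k]], numeric(1)) / nf
    out <- out[order(-out$occupancy), ]
    rownames(out) <- NULL
  }
  class(out) <- c("hbond_table", "data.frame")
  out
}

#' Filter occupancy tables across replicates and states
#'
#' Aligns per-replicate occupancy tables on the (donor, hydrogen,
#' acceptor) key and keeps a row iff its occupancy reaches `min_pct`
#' (inclusive) in at least one replicate of either state. Sub-threshold
#' cells are retained; cells below 1% are flagged in the `faint`
#' attribute so reports can grey them out.
#'
#' @param tables named list of `hbond_table`s (one per replicate;
#'   names like `"holo_rep1"` become occupancy columns)
#' @param min_pct occupancy threshold in percent (default 10)
#' @return data.frame of class `hbond_table` with one occupancy column
#'   per input table; attribute `faint` is a logical matrix marking
#'   cells below 1%
#' @export
filter_occupancy <- function(tables, min_pct = 10) {
  stopifnot(length(tables) >= 1L)
  if (is.null(names(tables))) names(tables) <- paste0("rep", seq_along(tables))
  keyed <- lapply(tables, function(t) {
    t$key <- paste(t$donor, t$hydrogen, t$acceptor)
    t
  })
  all_keys <- unique(unlist(lapply(keyed, `[[`, "key")))
  if (!length(all_keys)) {
    out <- data.frame(donor_label = character(0), acceptor_label = character(0))
    class(out) <- c("hbond_table", "data.frame")
    return(out)
  }
  occ <- sapply(keyed, function(t) {
    t$occupancy[match(all_keys, t$key)]
  })
  occ <- matrix(occ, nrow = length(all_keys),
                dimnames = list(NULL, names(tables)))
  occ[is.na(occ)] <- 0
  first_seen <- do.call(rbind, lapply(all_keys, function(k) {
    for (t in keyed) {
      hit <- which(t$key == k)
      if (length(hit)) return(t[hit[1L], c("donor_label", "acceptor_label")])
    }
  }))
  keep <- apply(occ, 1L, max) >= min_pct
  out <- cbind(first_seen[keep, , drop = FALSE],
               as.data.frame(occ[keep, , drop = FALSE]))
  rownames(out) <- NULL
  attr(out, "faint") <- occ[keep, , drop = FALSE] < 1
  class(out) <- c("hbond_table", "data.frame")
  out
}

#' Scan for ligand-water-protein bridges
#'
#' A bridge exists in a frame when one water molecule is hydrogen
#' bonded (in either donor/acceptor role) to both a ligand atom and a
#' protein atom. Waters are identified by residue name
#' (HOH/SOL/WAT/TIP3).
#'
#' @param traj_sample an [md_trajectory()] (typically a modest evenly
#'   spaced frame sample)
#' @param ligand_sel,protein_sel heavy-atom index sets for the two
#'   bridged partners
#' @param criteria an [hbond_criteria()]
#' @return list of class `water_bridges`: `records` (one row per
#'   frame/water/ligand-atom/protein-atom bridge) and `summary`
#'   (distinct bridged ligand-protein atom pairs with the fraction of
#'   frames bridged)
#' @export
water_bridges <- function(traj_sample, ligand_sel, protein_sel,
                          criteria = hbond_criteria()) {
  top <- traj_sample$topology
  wat_res <- top$atoms$resid %in% c("HOH", "SOL", "WAT", "TIP3")
  water_sel <- which(wat_res & top$atoms$elesy != "H")
  if (!length(water_sel)) {
    warning("no water residues in topology; empty result")
    return(structure(list(records = NULL,
                          summary = data.frame(ligand_atom = character(0),
                                               protein_atom = character(0),
                                               frequency = numeric(0))),
                     class = "water_bridges"))
  }
  nf <- n_frames(traj_sample)
  recs <- NULL
  for (f in seq_len(nf)) {
    xyz <- traj_sample$coords[, , f]
    leg <- function(sel) {
      sel_don <- intersect(sel, donor_hydrogens(top, sel)$donor)
      hb1 <- detect_hbonds(xyz, top, criteria, donors = water_sel, acceptors = sel)
      hb2 <- detect_hbonds(xyz, top, criteria, donors = sel_don,
                           acceptors = water_sel)
      rbind(
        if (nrow(hb1)) data.frame(water = top$atoms$residue_id[hb1$donor],
                                  partner = hb1$acceptor, hb1),
        if (nrow(hb2)) data.frame(water = top$atoms$residue_id[hb2$acceptor],
                                  partner = hb2$donor, hb2)
      )
    }
    lw <- leg(ligand_sel)
    pw <- leg(protein_sel)
    if (is.null(lw) || is.null(pw) || !nrow(lw) || !nrow(pw)) next
    shared <- intersect(lw$water, pw$water)
    for (w in shared) {
      li <- lw[lw$water == w, ]
      pi_ <- pw[pw$water == w, ]
      for (i in seq_len(nrow(li))) for (j in seq_len(nrow(pi_))) {
        recs <- rbind(recs, data.frame(
          frame = f, water = w,
          ligand_atom = atom_label(top, li$partner[i]),
          protein_atom = atom_label(top, pi_$partner[j]),
          d_ligand = li$d_DA[i], angle_ligand = li$angle[i],
          d_protein = pi_$d_DA[j], angle_protein = pi_$angle[j],
          stringsAsFactors = FALSE))
      }
    }
  }
  if (is.null(recs)) {
    summary <- data.frame(ligand_atom = character(0),
                          protein_atom = character(0), frequency = numeric(0))
  } else {
    key <- paste(recs$ligand_atom, recs$protein_atom, sep = " | ")
    nfr <- tapply(recs$frame, key, function(fr) length(unique(fr)))
    parts <- strsplit(names(nfr), " \\| ")
    summary <- data.frame(
      ligand_atom = vapply(parts, `[`, "", 1L),
      protein_atom = vapply(parts, `[`, "", 2L),
      frequency = as.numeric(nfr) / nf, stringsAsFactors = FALSE)
  }
  structure(list(records = recs, summary = summary), class = "water_bridges")
}

#' @export
print.water_bridges <- function(x, ...) {
  cat(sprintf("water_bridges: %d bridge events, %d distinct atom pairs\n",
              if (is.null(x$records)) 0L else nrow(x$records),
              nrow(x$summary)))
  invisible(x)
}

#' Per-frame distances for fixed atom pairs
#'
#' @param traj an [md_trajectory()]
#' @param atom_pairs two-column matrix of atom indices, or list of
#'   length-2 vectors
#' @return data.frame of class `distance_series` in long-by-pair wide
#'   format: one column per pair (named by atom labels) plus `time`;
#'   attribute `means` holds per-pair means (feeding replicate-level
#'   Mann-Whitney comparisons)
#' @export
pair_distance_series <- function(traj, atom_pairs) {
  if (is.list(atom_pairs)) atom_pairs <- do.call(rbind, atom_pairs)
  atom_pairs <- matrix(as.integer(atom_pairs), ncol = 2L)
  na <- n_atoms(traj$topology)
  if (any(atom_pairs < 1L) || any(atom_pairs > na)) stop("unknown atom in pair list")
  nf <- n_frames(traj)
  out <- matrix(0, nf, nrow(atom_pairs))
  for (f in seq_len(nf)) {
    xyz <- traj$coords[, , f]
    for (p in seq_len(nrow(atom_pairs))) {
      out[f, p] <- vnorm(xyz[atom_pairs[p, 1L], ] - xyz[atom_pairs[p, 2L], ])
    }
  }
  labels <- apply(atom_pairs, 1L, function(p) {
    paste(atom_label(traj$topology, p[1L]), "-", atom_label(traj$topology, p[2L]))
  })
  colnames(out) <- labels
  df <- data.frame(time = traj$times, out, check.names = FALSE)
  attr(df, "means") <- colMeans(out)
  class(df) <- c("distance_series", "data.frame")
  df
}
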