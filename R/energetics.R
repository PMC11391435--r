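# Coulomb constant f = 138.935458 kJ mol^-1 nm e^-2, i.e. 1389.35458 on
# the Angstrom scale used throughout the package.
COULOMB_KJ_A <- 1389.35458

# Pairwise Coulomb and LJ energy matrices (na x nb) between two atom
# groups on one frame. Lorentz-Berthelot combining; no cutoff.
pair_energy_matrices <- function(coords, group_a, group_b, atoms, eps_r = 1) {
  need <- c(group_a, group_b)
  bad <- need[is.na(atoms$charge[need]) | is.na(atoms$sigma[need]) |
                is.na(atoms$epsilon[need])]
  if (length(bad)) {
    stop("missing charge/LJ parameters for atom(s): ",
         paste(paste0(atoms$chain[bad], ":", atoms$resid[bad],
                      atoms$resno[bad], " ", atoms$elety[bad])[seq_len(min(5, length(bad)))],
               collapse = ", "))
  }
  r <- cross_dist(coords[group_a, , drop = FALSE], coords[group_b, , drop = FALSE])
  if (any(r < 1e-6)) stop("singularity: overlapping atoms (r < 1e-6 Angstrom)")
  qq <- outer(atoms$charge[group_a], atoms$charge[group_b])
  coulomb <- COULOMB_KJ_A * qq / (eps_r * r)
  sij <- outer(atoms$sigma[group_a], atoms$sigma[group_b], function(a, b) (a + b) / 2)
  eij <- sqrt(outer(atoms$epsilon[group_a], atoms$epsilon[group_b]))
  sr6 <- (sij / r)^6
  lj <- 4 * eij * (sr6^2 - sr6)
  list(coulomb = coulomb, lj = lj)
}

#' Coulomb and Lennard-Jones interaction energy between two groups
#'
#' Explicit pair sum (no cutoff) of the electrostatic term
#' `f * qi * qj / (eps_r * r)` with `f = 138.935458` kJ mol^-1 nm e^-2
#' and the 12-6 LJ term `4*eps_ij*((sig_ij/r)^12 - (sig_ij/r)^6)` with
#' Lorentz-Berthelot combining. Charges are in elementary charge units,
#' sigma in Angstrom, epsilon in kJ/mol.
#'
#' @param coords `A x 3` frame coordinates (Angstrom)
#' @param group_a,group_b disjoint atom index sets
#' @param topology an [md_topology()] carrying `charge`, `sigma`,
#'   `epsilon` for all interacting atoms
#' @param eps_r relative dielectric constant (default 1)
#' @return named numeric `c(coulomb =, lj =)` in kJ/mol
#' @export
coulomb_lj_energy <- function(coords, group_a, group_b, topology, eps_r = 1) {
  if (length(intersect(group_a, group_b))) stop("groups must be disjoint")
  m <- pair_energy_matrices(matrix(coords, ncol = 3L), group_a, group_b,
                            topology$atoms, eps_r)
  c(coulomb = sum(m$coulomb), lj = sum(m$lj))
}

#' SASA-based nonpolar solvation term for binding
#'
#' Linear surface-area model `g = gamma * SASA + b` per species:
#' `dG_nonpolar = gamma * (SASA_complex - SASA_a - SASA_b) - b` under
#' the per-species convention (each of the three species carries its
#' own offset `b`, leaving `-b` in the difference), or the bare area
#' term under `convention = "difference"`.
#'
#' @param coords `A x 3` frame coordinates
#' @param topology an [md_topology()]
#' @param part_a,part_b atom index sets of the two binding partners;
#'   the complex is their union
#' @param gamma surface tension coefficient, kJ mol^-1 Angstrom^-2
#' @param b offset, kJ/mol
#' @param convention `"per_species"` (default) or `"difference"`
#' @param probe,n_points passed to [shrake_rupley_sasa()]
#' @return list with `dg_nonpolar` (kJ/mol), `area_term` (kJ/mol),
#'   `dsasa` (Angstrom^2, negative when area is buried) and the three
#'   species SASA results
#' @export
nonpolar_term <- function(coords, topology, part_a, part_b,
                          gamma = 0.0226778, b = 3.84928,
                          convention = c("per_species", "difference"),
                          probe = 1.4, n_points = 960) {
  convention <- match.arg(convention)
  coords <- matrix(coords, ncol = 3L)
  el <- topology$atoms$elesy
  cx <- sort(c(part_a, part_b))
  s_cx <- shrake_rupley_sasa(coords[cx, , drop = FALSE], el[cx], probe, n_points)
  s_a <- shrake_rupley_sasa(coords[part_a, , drop = FALSE], el[part_a], probe, n_points)
  s_b <- shrake_rupley_sasa(coords[part_b, , drop = FALSE], el[part_b], probe, n_points)
  dsasa <- s_cx$total - s_a$total - s_b$total
  area <- gamma * dsasa
  dg <- if (convention == "per_species") area - b else area
  list(dg_nonpolar = dg, area_term = area, dsasa = dsasa,
       sasa_complex = s_cx, sasa_a = s_a, sasa_b = s_b)
}

resolve_polar <- function(polar_source, nf) {
  if (is.null(polar_source)) {
    message("polar solvation source is 'none': dG_polar = 0 for all frames")
    return(numeric(nf))
  }
  if (is.numeric(polar_source) && length(polar_source) == 1L) {
    return(rep(polar_source, nf))
  }
  if (is.numeric(polar_source)) {
    if (length(polar_source) != nf) {
      stop("alignment error: per-frame polar table has ", length(polar_source),
           " entries for ", nf, " frames")
    }
    return(polar_source)
  }
  if (inherits(polar_source, "decomposition_table")) {
    return(rep(sum(polar_source$g_polar), nf))
  }
  stop("unsupported polar_source")
}

#' Binding interaction energy over a frame sample
#'
#' Single-trajectory end-state convention: complex, receptor and ligand
#' conformations are taken from the same frame, so the molecular
#' mechanics part reduces to the explicit cross-group Coulomb + LJ
#' interaction energy. Per frame,
#' `dG_total = dE_MM + dG_polar + dG_nonpolar`; the polar term is
#' ingested (external solver output) or zero.
#'
#' @param sample an [md_trajectory()] (typically an evenly spaced
#'   sample, e.g. 500 frames from the final portion of a replicate)
#' @param part_a,part_b atom index sets of the two partners (e.g. the
#'   two chains, or receptor and ligand)
#' @param polar_source `NULL` (none; logged), a single number, a
#'   per-frame numeric vector, or a `decomposition_table` whose
#'   `g_polar` column is summed
#' @param eps_r relative dielectric constant
#' @param gamma,b,nonpolar_convention passed to [nonpolar_term()]
#' @param sasa_n_points sphere points for the SASA evaluations
#' @return object of class `bfe_result`: data.frame `frames` with
#'   per-frame `e_mm` (+ `coulomb`, `lj`), `g_polar`, `g_nonpolar`,
#'   `g_total`, and summary `mean`/`sd` over frames
#' @export
binding_energy <- function(sample, part_a, part_b, polar_source = NULL,
                           eps_r = 1, gamma = 0.0226778, b = 3.84928,
                           nonpolar_convention = "per_species",
                           sasa_n_points = 240) {
  nf <- n_frames(sample)
  gp <- resolve_polar(polar_source, nf)
  at <- sample$topology$atoms
  rows <- vector("list", nf)
  for (f in seq_len(nf)) {
    xyz <- sample$coords[, , f]
    m <- pair_energy_matrices(xyz, part_a, part_b, at, eps_r)
    np <- nonpolar_term(xyz, sample$topology, part_a, part_b, gamma, b,
                        nonpolar_convention, n_points = sasa_n_points)
    rows[[f]] <- data.frame(coulomb = sum(m$coulomb), lj = sum(m$lj),
                            g_nonpolar = np$dg_nonpolar)
  }
  fr <- do.call(rbind, rows)
  fr$e_mm <- fr$coulomb + fr$lj
  fr$g_polar <- gp
  fr$g_total <- fr$e_mm + fr$g_polar + fr$g_nonpolar
  structure(list(frames = fr, mean = mean(fr$g_total), sd = stats::sd(fr$g_total),
                 components = colMeans(fr[c("e_mm", "g_polar", "g_nonpolar",
                                            "g_total")])),
            class = "bfe_result")
}

#' @export
print.bfe_result <- function(x, ...) {
  cat(sprintf("bfe_result: %d frames, dG_total %.1f +/- %.1f kJ/mol\n",
              nrow(x$frames), x$mean, x$sd))
  cat(sprintf("  components (mean): E_MM %.1f, G_polar %.1f, G_nonpolar %.1f\n",
              x$components["e_mm"], x$components["g_polar"],
              x$components["g_nonpolar"]))
  invisible(x)
}

#' Per-residue decomposition of the binding energy
#'
#' Each cross-group atom pair's Coulomb/LJ energy is attributed half to
#' the residue of each of its two atoms, so summing the residue MM
#' contributions over all residues recovers the total exactly. The
#' nonpolar part is attributed per residue as `gamma` times the
#' residue's buried area (complex SASA minus its SASA in the isolated
#' partner); the per-species offset `-b` is reported separately in the
#' `nonpolar_offset` attribute. Ingested per-residue polar shares are
#' merged by residue label when supplied as a `decomposition_table`.
#'
#' @inheritParams binding_energy
#' @return data.frame of class `decomposition_table` with per-residue
#'   frame-mean `e_mm`, `g_polar`, `g_nonpolar`, `g_total` (kJ/mol)
#' @export
per_residue_decomposition <- function(sample, part_a, part_b,
                                      polar_source = NULL, eps_r = 1,
                                      gamma = 0.0226778, b = 3.84928,
                                      nonpolar_convention = "per_species",
                                      sasa_n_points = 240) {
  top <- sample$topology
  at <- top$atoms
  nf <- n_frames(sample)
  rid <- at$residue_id
  ids <- sort(unique(rid[c(part_a, part_b)]))
  mm <- matrix(0, length(ids), nf)
  np <- matrix(0, length(ids), nf)
  el <- at$elesy
  cx <- sort(c(part_a, part_b))
  for (f in seq_len(nf)) {
    xyz <- sample$coords[, , f]
    m <- pair_energy_matrices(xyz, part_a, part_b, at, eps_r)
    pairsum <- m$coulomb + m$lj
    row_res <- rowsum(pairsum, rid[part_a])          # by residue of A atoms
    col_res <- rowsum(t(pairsum), rid[part_b])       # by residue of B atoms
    a_tot <- rowSums(row_res); b_tot <- rowSums(col_res)
    mm[match(as.integer(names(a_tot)), ids), f] <-
      mm[match(as.integer(names(a_tot)), ids), f] + a_tot / 2
    mm[match(as.integer(names(b_tot)), ids), f] <-
      mm[match(as.integer(names(b_tot)), ids), f] + b_tot / 2
    s_cx <- shrake_rupley_sasa(xyz[cx, , drop = FALSE], el[cx],
                               n_points = sasa_n_points)
    s_a <- shrake_rupley_sasa(xyz[part_a, , drop = FALSE], el[part_a],
                              n_points = sasa_n_points)
    s_b <- shrake_rupley_sasa(xyz[part_b, , drop = FALSE], el[part_b],
                              n_points = sasa_n_points)
    res_cx <- tapply(s_cx$atom_sasa, rid[cx], sum)
    res_iso <- c(tapply(s_a$atom_sasa, rid[part_a], sum),
                 tapply(s_b$atom_sasa, rid[part_b], sum))
    dres <- res_cx - res_iso[names(res_cx)]
    np[match(as.integer(names(dres)), ids), f] <- gamma * dres
  }
  out <- data.frame(residue = residue_labels(top, ids),
                    e_mm = rowMeans(mm),
                    g_polar = 0,
                    g_nonpolar = rowMeans(np),
                    stringsAsFactors = FALSE)
  if (inherits(polar_source, "decomposition_table")) {
    hit <- match(out$residue, polar_source$residue)
    out$g_polar[!is.na(hit)] <- polar_source$g_polar[hit[!is.na(hit)]]
  } else if (is.numeric(polar_source) && length(polar_source) == nrow(out)) {
    out$g_polar <- polar_source
  }
  out$g_total <- out$e_mm + out$g_polar + out$g_nonpolar
  attr(out, "nonpolar_offset") <- if (nonpolar_convention == "per_species") -b else 0
  class(out) <- c("decomposition_table", "data.frame")
  out
}

#' Read a per-residue decomposition table
#'
#' Two dialects are supported. The native dialect is a delimited table
#' (comma or whitespace) with header columns `residue`, `e_mm`,
#' `g_polar`, `g_nonpolar`, `g_total`; rows failing
#' `g_total = e_mm + g_polar + g_nonpolar` beyond `tol` trigger a
#' validation warning. The g_mmpbsa contribution dialect
#' (`dialect = "gmmpbsa"`) is the per-frame energy-contribution layout
#' written by that tool: `#`-prefixed header naming one column per
#' residue, then one row per frame; column means are returned as the
#' residue `g_total` contributions.
#'
#' @param path input file
#' @param dialect `"native"` or `"gmmpbsa"`
#' @param tol consistency tolerance, kJ/mol
#' @return data.frame of class `decomposition_table`
#' @export
read_decomposition <- function(path, dialect = c("native", "gmmpbsa"),
                               tol = 1e-3) {
  dialect <- match.arg(dialect)
  if (dialect == "gmmpbsa") {
    lines <- readLines(path)
    hdr <- grep("^#", lines, value = TRUE)
    if (!length(hdr)) stop("g_mmpbsa dialect requires a '#' header line")
    resnames <- strsplit(sub("^#\\s*", "", hdr[length(hdr)]), "\\s+")[[1L]]
    dat <- utils::read.table(text = lines[!grepl("^#", lines)])
    if (ncol(dat) == length(resnames) + 1L) dat <- dat[, -1L, drop = FALSE]  # time col
    if (tolower(resnames[1L]) == "time" && ncol(dat) == length(resnames)) {
      resnames <- resnames[-1L]
      dat <- dat[, -1L, drop = FALSE]
    }
    if (ncol(dat) != length(resnames)) {
      stop("g_mmpbsa table has ", ncol(dat), " columns for ",
           length(resnames), " residues")
    }
    out <- data.frame(residue = resnames, e_mm = NA_real_, g_polar = NA_real_,
                      g_nonpolar = NA_real_, g_total = colMeans(dat),
                      stringsAsFactors = FALSE)
    class(out) <- c("decomposition_table", "data.frame")
    return(out)
  }
  first <- readLines(path, n = 1L)
  sep <- if (grepl(",", first)) "," else ""
  out <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  req <- c("residue", "e_mm", "g_polar", "g_nonpolar", "g_total")
  miss <- setdiff(req, names(out))
  if (length(miss)) stop("decomposition table missing columns: ",
                         paste(miss, collapse = ", "))
  bad <- abs(out$g_total - (out$e_mm + out$g_polar + out$g_nonpolar)) > tol
  if (any(bad)) {
    warning(sum(bad), " row(s) violate g_total = e_mm + g_polar + g_nonpolar",
            " beyond ", tol, " kJ/mol")
  }
  class(out) <- c("decomposition_table", "data.frame")
  out
}

#' Write a per-residue decomposition table (native CSV dialect)
#' @param table a `decomposition_table`
#' @param path output CSV path
#' @return `path`, invisibly
#' @export
write_decomposition <- function(table, path) {
  utils::write.csv(as.data.frame(table)[c("residue", "e_mm", "g_polar",
                                          "g_nonpolar", "g_total")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Summarize binding free energies across replicates and states
#'
#' Per state: mean and sample standard deviation (n-1 denominator) over
#' the replicate means. State differences are reported under two
#' conventions: `delta_rounded` differences the means after rounding to
#' one decimal (the convention that reproduces printed summary tables),
#' `delta_raw` differences the raw means.
#'
#' @param values_by_state named list: state label -> numeric vector of
#'   per-replicate mean binding energies (kJ/mol), at least 2 each
#' @param pairs list of length-2 character vectors
#'   `c(reference, modified)` to difference; default: first state vs
#'   each other state
#' @return object of class `bfe_summary` with `states` (per-state mean,
#'   sd, rounded mean, n) and `deltas` (per pair, both conventions)
#' @export
summarize_bfe <- function(values_by_state, pairs = NULL) {
  stopifnot(length(values_by_state) >= 1L, !is.null(names(values_by_state)))
  n_reps <- lengths(values_by_state)
  if (any(n_reps < 2L)) stop("each state needs >= 2 replicates")
  if (length(unique(n_reps)) > 1L) {
    message("replicate counts differ across states: ",
            paste(n_reps, collapse = ", "))
  }
  states <- data.frame(
    state = names(values_by_state),
    n = as.integer(n_reps),
    mean = vapply(values_by_state, mean, numeric(1)),
    sd = vapply(values_by_state, stats::sd, numeric(1)),
    stringsAsFactors = FALSE)
  states$rounded_mean <- round1(states$mean)
  if (is.null(pairs) && length(values_by_state) > 1L) {
    ref <- names(values_by_state)[1L]
    pairs <- lapply(names(values_by_state)[-1L], function(s) c(ref, s))
  }
  deltas <- NULL
  for (p in pairs) {
    a <- states[states$state == p[1L], ]; b <- states[states$state == p[2L], ]
    if (!nrow(a) || !nrow(b)) stop("unknown state in pair: ", paste(p, collapse = " vs "))
    deltas <- rbind(deltas, data.frame(
      reference = p[1L], modified = p[2L],
      delta_rounded = b$rounded_mean - a$rounded_mean,
      delta_raw = b$mean - a$mean, stringsAsFactors = FALSE))
  }
  structure(list(states = states, deltas = deltas), class = "bfe_summary")
}

#' @export
print.bfe_summary <- function(x, ...) {
  cat("Binding free energy summary (kJ/mol)\n")
  for (i in seq_len(nrow(x$states))) {
    s <- x$states[i, ]
    cat(sprintf("  %-14s mean %8.1f +/- %6.1f  (n = %d)\n",
                s$state, s$mean, s$sd, s$n))
  }
  if (!is.null(x$deltas)) {
    for (i in seq_len(nrow(x$deltas))) {
      d <- x$deltas[i, ]
      cat(sprintf("  Delta %s -> %s: %8.1f (rounded-mean convention; raw %.2f)\n",
                  d$reference, d$modified, d$delta_rounded, d$delta_raw))
    }
  }
  invisible(x)
}

#' Per-residue binding free energy difference between two states
#'
#' `delta_bfe = mean(modified) - mean(reference)` per residue, over the
#' `g_total` column of two decomposition tables aligned by residue
#' label, ranked by absolute magnitude.
#'
#' @param decomp_ref,decomp_mod `decomposition_table`s for the
#'   reference and modified states
#' @return data.frame with `residue`, `delta_bfe` (kJ/mol), sorted by
#'   decreasing `abs(delta_bfe)`
#' @export
residue_delta_bfe <- function(decomp_ref, decomp_mod) {
  hit <- match(decomp_ref$residue, decomp_mod$residue)
  if (anyNA(hit)) warning(sum(is.na(hit)), " residue(s) missing from modified table")
  out <- data.frame(residue = decomp_ref$residue,
                    delta_bfe = decomp_mod$g_total[hit] - decomp_ref$g_total,
                    stringsAsFactors = FALSE)
  out[order(-abs(out$delta_bfe)), , drop = FALSE]
}
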