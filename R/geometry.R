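#' Least-squares (Kabsch) superposition
#'
#' Finds the proper rotation and translation minimizing the RMSD of
#' `mobile` onto `reference` over a selected atom subset, by singular
#' value decomposition of the cross-covariance matrix with the usual
#' reflection correction.
#'
#' @param mobile,reference `A x 3` coordinate matrices (Angstrom)
#' @param selection atom indices used for the fit (default all); must
#'   contain at least 3 non-collinear atoms
#' @return list of class `superposition` with `rotation` (3x3, det +1),
#'   `translation` (length 3) and `rmsd` over the selection, such that
#'   the fitted coordinates are `mobile %*% t(rotation) + translation`
#'   (rows)
#' @export
kabsch_fit <- function(mobile, reference, selection = NULL) {
  mobile <- matrix(mobile, ncol = 3L)
  reference <- matrix(reference, ncol = 3L)
  if (is.null(selection)) selection <- seq_len(nrow(mobile))
  if (length(selection) < 3L) stop("selection must contain at least 3 atoms")
  m <- mobile[selection, , drop = FALSE]
  r <- reference[selection, , drop = FALSE]
  cm <- colMeans(m); cr <- colMeans(r)
  m0 <- sweep(m, 2L, cm); r0 <- sweep(r, 2L, cr)
  h <- crossprod(m0, r0)
  sv <- svd(h)
  if (sv$d[2] < 1e-10 * max(sv$d[1], 1)) {
    stop("numerical degeneracy: selection is collinear or coincident")
  }
  d <- sign(det(sv$v %*% t(sv$u)))
  rot <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  trans <- cr - as.numeric(rot %*% cm)
  fitted <- m %*% t(rot) + matrix(trans, nrow(m), 3L, byrow = TRUE)
  rmsd <- sqrt(mean(rowSums((fitted - r)^2)))
  structure(list(rotation = rot, translation = trans, rmsd = rmsd),
            class = "superposition")
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("superposition: rmsd = %.4f Angstrom\n", x$rmsd))
  invisible(x)
}

apply_fit <- function(coords, fit) {
  coords %*% t(fit$rotation) +
    matrix(fit$translation, nrow(coords), 3L, byrow = TRUE)
}

#' Per-frame RMSD after backbone fitting
#'
#' Each frame is least-squares fitted to the reference on
#' `fit_selection`, then RMSD is measured on `measure_selection`. The
#' two selections may differ, as for ligand RMSD after a backbone fit.
#'
#' @param traj an [md_trajectory()]
#' @param reference `A x 3` reference coordinates
#' @param fit_selection atom indices used for superposition
#' @param measure_selection atom indices RMSD is computed over
#' @return list of class `rmsd_series`: `rmsd` (per frame, Angstrom),
#'   `mean`, `sd`, `times`
#' @export
rmsd_series <- function(traj, reference,
                        fit_selection = NULL,
                        measure_selection = NULL) {
  reference <- matrix(reference, ncol = 3L)
  if (is.null(fit_selection)) fit_selection <- seq_len(n_atoms(traj$topology))
  if (is.null(measure_selection)) measure_selection <- fit_selection
  if (!length(fit_selection) || !length(measure_selection)) {
    stop("empty atom selection")
  }
  nf <- n_frames(traj)
  out <- numeric(nf)
  refm <- reference[measure_selection, , drop = FALSE]
  for (f in seq_len(nf)) {
    x <- traj$coords[, , f]
    fit <- kabsch_fit(x, reference, fit_selection)
    xm <- apply_fit(x[measure_selection, , drop = FALSE], fit)
    out[f] <- sqrt(mean(rowSums((xm - refm)^2)))
  }
  structure(list(rmsd = out, mean = mean(out), sd = stats::sd(out),
                 times = traj$times),
            class = "rmsd_series")
}

#' @export
print.rmsd_series <- function(x, ...) {
  cat(sprintf("rmsd_series: %d frames, mean %.3f +/- %.3f Angstrom\n",
              length(x$rmsd), x$mean, x$sd))
  invisible(x)
}

#' C-alpha RMSF profile against a fixed reference
#'
#' Per-residue root-mean-square fluctuation of the selected atoms,
#' measured as deviation from the fixed reference structure (not from
#' the trajectory mean): `rmsf_i = sqrt(mean_f |x_{f,i} - x_{ref,i}|^2)`
#' after least-squares fitting each frame to the reference on
#' `fit_selection`. A `mode = "mean"` option measures deviation from the
#' time-averaged position instead.
#'
#' @param traj an [md_trajectory()]
#' @param reference `A x 3` reference coordinates (Angstrom)
#' @param selection atom indices to profile; default all CA atoms.
#'   Residues without a selected atom are omitted with a warning.
#' @param fit_selection atoms used for the per-frame superposition
#'   (default: the profiled selection); `NULL` with `fit = FALSE` skips
#'   fitting for pre-aligned frames
#' @param fit logical; superpose each frame first (default `TRUE`)
#' @param mode `"reference"` (default) or `"mean"`
#' @return data.frame of class `flex_profile` with columns `residue`
#'   (label), `chain`, `resno`, `rmsf` (Angstrom); attribute
#'   `reference_id` records the mode
#' @export
rmsf_profile <- function(traj, reference, selection = NULL,
                         fit_selection = selection, fit = TRUE,
                         mode = c("reference", "mean")) {
  mode <- match.arg(mode)
  top <- traj$topology
  reference <- matrix(reference, ncol = 3L)
  if (is.null(selection)) {
    selection <- select_atoms(top, elety = "CA")
    has_ca <- top$residues$residue_id %in% top$atoms$residue_id[selection]
    if (!all(has_ca)) {
      warning(sum(!has_ca), " residue(s) without a CA atom omitted from the profile")
    }
  }
  if (!length(selection)) stop("empty atom selection")
  nf <- n_frames(traj)
  ref_sel <- reference[selection, , drop = FALSE]
  dev2 <- matrix(0, length(selection), nf)
  pos <- array(0, dim = c(length(selection), 3L, nf))
  for (f in seq_len(nf)) {
    x <- traj$coords[, , f]
    if (fit && !is.null(fit_selection)) {
      ft <- kabsch_fit(x, reference, fit_selection)
      x <- apply_fit(x, ft)
    }
    pos[, , f] <- x[selection, , drop = FALSE]
  }
  centre <- if (mode == "reference") ref_sel else apply(pos, c(1L, 2L), mean)
  for (f in seq_len(nf)) dev2[, f] <- rowSums((pos[, , f] - centre)^2)
  rmsf_atom <- sqrt(rowMeans(dev2))
  rid <- top$atoms$residue_id[selection]
  rmsf_res <- tapply(rmsf_atom, rid, mean)
  ids <- as.integer(names(rmsf_res))
  out <- data.frame(residue = residue_labels(top, ids),
                    chain = top$residues$chain[match(ids, top$residues$residue_id)],
                    resno = top$residues$resno[match(ids, top$residues$residue_id)],
                    rmsf = as.numeric(rmsf_res),
                    stringsAsFactors = FALSE)
  attr(out, "reference_id") <- mode
  class(out) <- c("flex_profile", "data.frame")
  out
}

#' Flag residues with large RMSF differences between two states
#'
#' Differences two flexibility profiles and flags residues whose
#' absolute RMSF change meets the order-dependent threshold: >= 1
#' Angstrom for ordered residues, >= 3 Angstrom for disordered ones
#' (both inclusive). Maximal runs of flagged residues are reported as
#' contiguous regions.
#'
#' @param profile_a,profile_b [rmsf_profile()] outputs over the same
#'   residue set (a = reference state); `delta_rmsf = b - a`
#' @param order_mask named character vector (`"ordered"`/`"disordered"`)
#'   per residue label, e.g. from [order_mask()]; residues absent from
#'   the mask are treated as ordered
#' @param thresholds named numeric: Angstrom thresholds per order class
#' @return `flex_profile` data.frame with `rmsf_a`, `rmsf_b`,
#'   `delta_rmsf`, `flag`; attribute `regions` is a data.frame of
#'   contiguous flagged runs (`chain`, `start`, `end`, `max_abs_delta`)
#' @export
flag_flexible_regions <- function(profile_a, profile_b, order_mask = NULL,
                                  thresholds = c(ordered = 1, disordered = 3)) {
  if (!identical(profile_a$residue, profile_b$residue)) {
    stop("profiles cover different residue sets")
  }
  delta <- profile_b$rmsf - profile_a$rmsf
  cls <- rep("ordered", nrow(profile_a))
  if (!is.null(order_mask)) {
    hit <- match(profile_a$residue, names(order_mask))
    cls[!is.na(hit)] <- order_mask[hit[!is.na(hit)]]
  }
  thr <- thresholds[cls]
  flag <- abs(delta) >= thr
  out <- data.frame(residue = profile_a$residue, chain = profile_a$chain,
                    resno = profile_a$resno, rmsf_a = profile_a$rmsf,
                    rmsf_b = profile_b$rmsf, delta_rmsf = delta,
                    order = cls, flag = flag, stringsAsFactors = FALSE)
  runs <- rle(flag)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep <- which(runs$values)
  regions <- do.call(rbind, lapply(keep, function(k) {
    i <- starts[k]:ends[k]
    data.frame(chain = out$chain[i[1L]], start = out$resno[i[1L]],
               end = out$resno[i[length(i)]],
               max_abs_delta = max(abs(delta[i])), stringsAsFactors = FALSE)
  }))
  attr(out, "regions") <- regions
  class(out) <- c("flex_profile", "data.frame")
  out
}

#' Write a flexibility profile as CSV and its regions as BED-like TSV
#' @param profile a `flex_profile`
#' @param path CSV output path; regions (if any) go to
#'   `sub(".csv", "_regions.tsv", path)`
#' @return `path`, invisibly
#' @export
write_flex_profile <- function(profile, path) {
  utils::write.csv(as.data.frame(profile), path, row.names = FALSE)
  reg <- attr(profile, "regions")
  if (!is.null(reg) && nrow(reg)) {
    utils::write.table(reg, sub("\\.csv$", "_regions.tsv", path),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}
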