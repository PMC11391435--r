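#' Construct a molecular topology
#'
#' A topology holds the static atom table of a system: names, elements,
#' residue membership, chain ids, polarity flags and (optionally)
#' force-field parameters (partial charges in elementary charge units,
#' Lennard-Jones sigma in Angstrom and epsilon in kJ/mol). Residue
#' numbering from the source structure (`resno`) is preserved and used
#' in every report; an internal 1-based ordinal (`residue_id`) indexes
#' residues across chains.
#'
#' @param atoms data.frame with columns `elety` (atom name), `elesy`
#'   (element symbol), `resno` (author residue number), `resid`
#'   (3-letter residue name), `chain` (chain id) and optionally
#'   `charge`, `sigma`, `epsilon`.
#' @param bonds integer matrix with two columns of 1-based atom row
#'   indices, or `NULL` to infer hydrogen-to-heavy-atom bonds from
#'   reference coordinates (see [infer_h_bonds()]).
#'
#' @return An object of class `md_topology`: a list with elements
#'   `atoms` (atom table augmented with `residue_id` and `is_polar`),
#'   `residues` (one row per residue) and `bonds`.
#' @export
md_topology <- function(atoms, bonds = NULL) {
  req <- c("elety", "elesy", "resno", "resid", "chain")
  miss <- setdiff(req, names(atoms))
  if (length(miss)) stop("atoms is missing columns: ", paste(miss, collapse = ", "))
  if (nrow(atoms) == 0L) stop("empty atom table")
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  key <- paste(atoms$chain, atoms$resno, atoms$resid, sep = "|")
  atoms$residue_id <- match(key, unique(key))
  for (col in c("charge", "sigma", "epsilon")) {
    if (is.null(atoms[[col]])) atoms[[col]] <- NA_real_
  }
  if (any(!is.na(atoms$sigma) & atoms$sigma <= 0)) stop("lj sigma must be > 0")
  if (any(!is.na(atoms$epsilon) & atoms$epsilon < 0)) stop("lj epsilon must be >= 0")
  if (!is.null(bonds)) {
    bonds <- matrix(as.integer(bonds), ncol = 2L)
    if (any(bonds < 1L) || any(bonds > nrow(atoms))) {
      stop("bond indices reference atoms outside the topology")
    }
  }
  ridx <- !duplicated(atoms$residue_id)
  residues <- data.frame(
    residue_id = atoms$residue_id[ridx],
    resno = atoms$resno[ridx],
    resid = atoms$resid[ridx],
    chain = atoms$chain[ridx],
    stringsAsFactors = FALSE
  )
  atoms$is_polar <- polar_flags(atoms, bonds)
  structure(list(atoms = atoms, residues = residues, bonds = bonds),
            class = "md_topology")
}

# Polar atoms: N, O, S, P heavy atoms plus hydrogens bonded to one of them.
polar_flags <- function(atoms, bonds) {
  polar_heavy <- atoms$elesy %in% c("N", "O", "S", "P")
  flags <- polar_heavy
  if (!is.null(bonds) && nrow(bonds)) {
    h <- atoms$elesy == "H"
    for (k in seq_len(nrow(bonds))) {
      i <- bonds[k, 1L]; j <- bonds[k, 2L]
      if (h[i] && polar_heavy[j]) flags[i] <- TRUE
      if (h[j] && polar_heavy[i]) flags[j] <- TRUE
    }
  }
  flags
}

#' Pair each hydrogen with its nearest heavy atom
#'
#' Builds an explicit hydrogen-to-heavy bond list by distance: every
#' hydrogen is bonded to the nearest heavy atom within `cutoff`
#' Angstrom. No heavy-heavy bond perception is attempted.
#'
#' @param atoms atom table (needs `elesy`)
#' @param coords A x 3 coordinate matrix in Angstrom
#' @param cutoff maximum H-heavy bond length, Angstrom
#' @return two-column integer matrix of (hydrogen, heavy) atom indices
#' @export
infer_h_bonds <- function(atoms, coords, cutoff = 1.3) {
  h <- which(atoms$elesy == "H")
  heavy <- which(atoms$elesy != "H")
  if (!length(h) || !length(heavy)) return(matrix(integer(0), ncol = 2L))
  d <- cross_dist(coords[h, , drop = FALSE], coords[heavy, , drop = FALSE])
  j <- heavy[apply(d, 1L, which.min)]
  ok <- apply(d, 1L, min) <= cutoff
  cbind(h[ok], j[ok])
}

#' @export
print.md_topology <- function(x, ...) {
  cat(sprintf("md_topology: %d atoms, %d residues, %d chains\n",
              nrow(x$atoms), nrow(x$residues),
              length(unique(x$atoms$chain))))
  invisible(x)
}

#' Number of atoms in a topology
#' @param top an `md_topology`
#' @return integer atom count
#' @export
n_atoms <- function(top) nrow(top$atoms)

#' Human-readable residue labels (e.g. "A:GLY 323")
#' @param top an `md_topology`
#' @param residue_id internal residue ids (default all)
#' @return character vector of labels in the structure's own numbering
#' @export
residue_labels <- function(top, residue_id = top$residues$residue_id) {
  r <- top$residues[match(residue_id, top$residues$residue_id), ]
  sprintf("%s:%s %d", r$chain, r$resid, r$resno)
}

#' Select atoms from a topology
#'
#' @param top an `md_topology`
#' @param elety,chain,resno,resid optional filters (vectors)
#' @param heavy if `TRUE`, keep non-hydrogen atoms only
#' @param polar if `TRUE`, keep polar atoms only
#' @return integer vector of atom indices
#' @export
select_atoms <- function(top, elety = NULL, chain = NULL, resno = NULL,
                         resid = NULL, heavy = FALSE, polar = FALSE) {
  a <- top$atoms
  keep <- rep(TRUE, nrow(a))
  if (!is.null(elety)) keep <- keep & a$elety %in% elety
  if (!is.null(chain)) keep <- keep & a$chain %in% chain
  if (!is.null(resno)) keep <- keep & a$resno %in% resno
  if (!is.null(resid)) keep <- keep & a$resid %in% resid
  if (heavy) keep <- keep & a$elesy != "H"
  if (polar) keep <- keep & a$is_polar
  which(keep)
}
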