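#' Specification for a synthetic two-chain ensemble
#'
#' Defines a toy two-chain helical complex and two state-labelled
#' replicate ensembles with planted, recoverable signal: state-separable
#' interfacial contact distances, per-residue fluctuation amplitudes,
#' and hydrogen bonds with controlled occupancy. Defaults mirror the
#' replicate structure of the study design this package targets: five
#' replicates per state with Gaussian positional noise on every
#' residue.
#'
#' @param residues_per_chain residues per chain (>= 4)
#' @param replicates_per_state replicates per state (>= 2; default 5)
#' @param frames_per_replicate frames per replicate (default 1000)
#' @param base_sigma default per-axis positional jitter sd, Angstrom
#'   (default 0.6, i.e. a realistic C-alpha RMSF of about 1 Angstrom)
#' @param separation distance between the two helix axes, Angstrom
#' @param planted_contacts data.frame(`resno_a`, `resno_b`, `mean_a`,
#'   `mean_b`, `jitter`): CA-CA distance of the (chain A, chain B)
#'   residue pair is drawn Normal(state mean, jitter) per frame. A
#'   residue may appear in at most one planted constraint.
#' @param planted_fluctuations data.frame(`chain`, `resno`, `sigma_a`,
#'   `sigma_b`): per-axis jitter sd per state for selected residues
#' @param planted_hbonds data.frame(`donor_resno`, `acceptor_resno`,
#'   `occupancy`): chain A backbone N-H donates to chain B backbone O
#'   in a Bernoulli(occupancy) fraction of frames
#' @param n_waters isolated 3-atom HOH residues placed near the
#'   interface (0 = none)
#' @param state_labels labels of the two states
#' @param dt frame spacing, ns
#' @param seed base RNG seed
#' @return object of class `synthetic_spec`
#' @export
synthetic_spec <- function(residues_per_chain = 16,
                           replicates_per_state = 5,
                           frames_per_replicate = 1000,
                           base_sigma = 0.6,
                           separation = 9.5,
                           planted_contacts = NULL,
                           planted_fluctuations = NULL,
                           planted_hbonds = NULL,
                           n_waters = 0,
                           state_labels = c("stateA", "stateB"),
                           dt = 0.1,
                           seed = 1L) {
  if (residues_per_chain < 4L) stop("residues_per_chain must be >= 4")
  if (replicates_per_state < 2L) stop("replicates_per_state must be >= 2")
  if (frames_per_replicate < 1L) stop("frames_per_replicate must be >= 1")
  if (!is.null(planted_contacts)) {
    pc <- planted_contacts
    if (any(c(pc$mean_a, pc$mean_b, pc$jitter) <= 0)) {
      stop("planted contact distances and jitter must be > 0")
    }
    if (anyDuplicated(pc$resno_a) || anyDuplicated(pc$resno_b)) {
      stop("spec error: a residue appears in more than one planted contact")
    }
  }
  if (!is.null(planted_hbonds)) {
    ph <- planted_hbonds
    if (any(ph$occupancy < 0 | ph$occupancy > 1)) {
      stop("planted occupancies must lie in [0, 1]")
    }
    if (!is.null(planted_contacts)) {
      clash <- intersect(c(ph$donor_resno, ph$acceptor_resno),
                         c(planted_contacts$resno_a, planted_contacts$resno_b))
      if (length(clash)) {
        stop("spec error: residue(s) ", paste(clash, collapse = ", "),
             " appear in both planted contacts and planted H-bonds")
      }
    }
  }
  structure(list(residues_per_chain = as.integer(residues_per_chain),
                 replicates_per_state = as.integer(replicates_per_state),
                 frames_per_replicate = as.integer(frames_per_replicate),
                 base_sigma = base_sigma, separation = separation,
                 planted_contacts = planted_contacts,
                 planted_fluctuations = planted_fluctuations,
                 planted_hbonds = planted_hbonds,
                 n_waters = as.integer(n_waters),
                 state_labels = state_labels, dt = dt,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

# Backbone force-field toy parameters: per-residue neutral charge set
# and element-based LJ terms.
toy_params <- function(atoms) {
  q <- c(N = -0.35, H = 0.25, CA = 0.10, C = 0.51, O = -0.51,
         OW = -0.834, HW1 = 0.417, HW2 = 0.417)
  s <- c(N = 3.25, H = 1.1, CA = 3.4, C = 3.4, O = 2.96,
         OW = 3.15, HW1 = 1.0, HW2 = 1.0)
  e <- c(N = 0.711, H = 0.065, CA = 0.36, C = 0.36, O = 0.88,
         OW = 0.636, HW1 = 0.01, HW2 = 0.01)
  atoms$charge <- unname(q[atoms$elety])
  atoms$sigma <- unname(s[atoms$elety])
  atoms$epsilon <- unname(e[atoms$elety])
  atoms
}

#' Build the toy two-chain complex topology
#'
#' Two backbone-only chains (N, CA, C, O and amide H per residue) in
#' ideal alpha-helical geometry run side by side, separated across a
#' flat interface; optional isolated waters sit near the interface
#' midpoint. Polar flags, toy partial charges and element-based LJ
#' parameters are assigned to every atom.
#'
#' @param spec a [synthetic_spec()]
#' @return list with `topology` ([md_topology()]) and `coords`
#'   (reference `A x 3`, Angstrom)
#' @export
build_toy_topology <- function(spec) {
  n <- spec$residues_per_chain
  a <- build_peptide_chain(n, chain = "A", resno_start = 1L)
  # chain B: the same helix translated across the interface normal
  ca_idx <- which(a$topology$atoms$elety == "CA")
  ca <- a$coords[ca_idx, , drop = FALSE]
  axis <- svd(scale(ca, scale = FALSE))$v[, 1L]
  normal <- svd(scale(ca, scale = FALSE))$v[, 3L]
  offset <- spec$separation * normal
  b <- build_peptide_chain(n, chain = "B", resno_start = 101L)
  atoms <- rbind(a$topology$atoms[setdiff(names(a$topology$atoms),
                                          c("residue_id", "is_polar", "charge",
                                            "sigma", "epsilon"))],
                 b$topology$atoms[setdiff(names(b$topology$atoms),
                                          c("residue_id", "is_polar", "charge",
                                            "sigma", "epsilon"))])
  coords <- rbind(a$coords, sweep(b$coords, 2L, offset, "+"))
  if (spec$n_waters > 0L) {
    mid <- colMeans(ca) + offset / 2
    for (w in seq_len(spec$n_waters)) {
      base <- mid + 3 * (w - (spec$n_waters + 1) / 2) * axis
      wat <- rbind(base,
                   base + c(0.76, 0.59, 0),
                   base + c(-0.76, 0.59, 0))
      atoms <- rbind(atoms, data.frame(
        elety = c("OW", "HW1", "HW2"), elesy = c("O", "H", "H"),
        resno = 900L + w, resid = "HOH", chain = "W",
        stringsAsFactors = FALSE))
      coords <- rbind(coords, wat)
    }
  }
  atoms <- toy_params(atoms)
  bonds <- infer_h_bonds(atoms, coords)
  list(topology = md_topology(atoms, bonds = bonds), coords = coords)
}

# one frame: reference coords + per-residue rigid jitter + planted
# contacts/hbond geometry
synth_frame <- function(ref, top, sigma_res, contacts, hbonds, atom_res) {
  nres <- length(sigma_res)
  disp <- matrix(stats::rnorm(3L * nres, 0, rep(sigma_res, 3L)), nres, 3L)
  xyz <- ref + disp[atom_res, , drop = FALSE]
  if (!is.null(contacts)) {
    # both residues of a planted pair share the displacement
    # symmetrically, so each carries the pair's distance signal
    for (k in seq_len(nrow(contacts))) {
      cc <- contacts[k, ]
      d <- stats::rnorm(1L, cc$mean_target, cc$jitter)
      ia_atoms <- cc$atoms_a[[1L]]; ib_atoms <- cc$atoms_b[[1L]]
      u <- unit(ref[cc$ca_b, ] - ref[cc$ca_a, ])
      m <- (xyz[cc$ca_a, ] + xyz[cc$ca_b, ]) / 2
      shift_a <- (m - (d / 2) * u) - xyz[cc$ca_a, ]
      shift_b <- (m + (d / 2) * u) - xyz[cc$ca_b, ]
      xyz[ia_atoms, ] <- xyz[ia_atoms, , drop = FALSE] +
        matrix(shift_a, length(ia_atoms), 3L, byrow = TRUE)
      xyz[ib_atoms, ] <- xyz[ib_atoms, , drop = FALSE] +
        matrix(shift_b, length(ib_atoms), 3L, byrow = TRUE)
    }
  }
  if (!is.null(hbonds)) {
    for (k in seq_len(nrow(hbonds))) {
      hh <- hbonds[k, ]
      on <- stats::runif(1L) < hh$occupancy
      dvec <- unit(xyz[hh$h_atom, ] - xyz[hh$d_atom, ])
      dist <- if (on) 2.9 else 5.5
      xyz[hh$a_atom, ] <- xyz[hh$d_atom, ] + dist * dvec
    }
  }
  xyz
}

#' Generate the two state ensembles with planted ground truth
#'
#' Per frame, every residue receives an independent rigid Gaussian
#' displacement of its atoms (so backbone and hydrogen-bond geometry
#' survive the noise); planted contact pairs are positioned so their
#' CA-CA distance is Normal(state mean, jitter); planted hydrogen-bond
#' acceptors are moved inside the geometric criteria in a
#' Bernoulli(occupancy) fraction of frames and well outside otherwise.
#' Replicates differ only by their RNG stream; the same seed gives
#' bit-identical ensembles.
#'
#' @param spec a [synthetic_spec()]
#' @return list with `ensemble_a`, `ensemble_b` ([md_ensemble()]s),
#'   `truth` (see [ground_truth()]), `topology` and `ref_coords`
#' @export
generate_ensembles <- function(spec) {
  built <- build_toy_topology(spec)
  top <- built$topology; ref <- built$coords
  nres <- nrow(top$residues)
  atom_res <- top$atoms$residue_id

  contacts <- NULL
  if (!is.null(spec$planted_contacts)) {
    pc <- spec$planted_contacts
    contacts <- do.call(rbind, lapply(seq_len(nrow(pc)), function(k) {
      ca_a <- select_atoms(top, chain = "A", resno = pc$resno_a[k], elety = "CA")
      ca_b <- select_atoms(top, chain = "B", resno = pc$resno_b[k], elety = "CA")
      if (!length(ca_a) || !length(ca_b)) {
        stop("planted contact references unknown residue")
      }
      rid_a <- top$atoms$residue_id[ca_a[1L]]
      rid_b <- top$atoms$residue_id[ca_b[1L]]
      data.frame(ca_a = ca_a[1L], ca_b = ca_b[1L],
                 atoms_a = I(list(which(atom_res == rid_a))),
                 atoms_b = I(list(which(atom_res == rid_b))),
                 mean_a = pc$mean_a[k], mean_b = pc$mean_b[k],
                 jitter = pc$jitter[k])
    }))
  }
  hbonds <- NULL
  if (!is.null(spec$planted_hbonds)) {
    ph <- spec$planted_hbonds
    hbonds <- do.call(rbind, lapply(seq_len(nrow(ph)), function(k) {
      d <- select_atoms(top, chain = "A", resno = ph$donor_resno[k], elety = "N")
      h <- select_atoms(top, chain = "A", resno = ph$donor_resno[k], elety = "H")
      a <- select_atoms(top, chain = "B", resno = ph$acceptor_resno[k], elety = "O")
      if (!length(d) || !length(h) || !length(a)) {
        stop("planted H-bond references a residue without the needed atoms")
      }
      data.frame(d_atom = d[1L], h_atom = h[1L], a_atom = a[1L],
                 occupancy = ph$occupancy[k])
    }))
  }

  sigma_state <- function(state) {
    s <- rep(spec$base_sigma, nres)
    pf <- spec$planted_fluctuations
    if (!is.null(pf)) {
      for (k in seq_len(nrow(pf))) {
        i <- which(top$residues$chain == pf$chain[k] &
                     top$residues$resno == pf$resno[k])
        s[i] <- if (state == 1L) pf$sigma_a[k] else pf$sigma_b[k]
      }
    }
    s
  }

  make_state <- function(state) {
    sig <- sigma_state(state)
    ctt <- contacts
    if (!is.null(ctt)) {
      ctt$mean_target <- if (state == 1L) ctt$mean_a else ctt$mean_b
    }
    reps <- lapply(seq_len(spec$replicates_per_state), function(r) {
      with_seed(spec$seed + 1000L * state + r, {
        nf <- spec$frames_per_replicate
        coords <- array(0, dim = c(nrow(top$atoms), 3L, nf))
        for (f in seq_len(nf)) {
          coords[, , f] <- synth_frame(ref, top, sig, ctt, hbonds, atom_res)
        }
        md_trajectory(top, coords, dt = spec$dt)
      })
    })
    md_ensemble(spec$state_labels[state], reps)
  }

  list(ensemble_a = make_state(1L), ensemble_b = make_state(2L),
       truth = ground_truth(spec), topology = top, ref_coords = ref)
}

#' Deterministic ground truth of a synthetic specification
#'
#' @param spec a [synthetic_spec()]
#' @return list of class `ground_truth`: `important_residues` (labels
#'   of residues in planted state-separable contacts),
#'   `expected_drmsf` (per planted-fluctuation residue,
#'   `sqrt(3) * |sigma_b - sigma_a|`; approximate, fitting and
#'   residue-averaging shift it slightly), `expected_occupancy`
#'   (echoes the planted fractions), `expected_contacts` (planted pair
#'   list with state means) and `reference_pair_energies` (Coulomb/LJ
#'   energy of each planted residue pair on the reference geometry)
#' @export
ground_truth <- function(spec) {
  built <- build_toy_topology(spec)
  top <- built$topology
  important <- character(0)
  ref_energies <- NULL
  if (!is.null(spec$planted_contacts)) {
    pc <- spec$planted_contacts
    sep <- abs(pc$mean_a - pc$mean_b) > 1e-9
    la <- sprintf("A:ALA %d", pc$resno_a)
    lb <- sprintf("B:ALA %d", pc$resno_b)
    important <- c(la[sep], lb[sep])
    ref_energies <- do.call(rbind, lapply(seq_len(nrow(pc)), function(k) {
      ga <- select_atoms(top, chain = "A", resno = pc$resno_a[k])
      gb <- select_atoms(top, chain = "B", resno = pc$resno_b[k])
      e <- coulomb_lj_energy(built$coords, ga, gb, top)
      data.frame(res_a = la[k], res_b = lb[k],
                 coulomb = e["coulomb"], lj = e["lj"], row.names = NULL)
    }))
  }
  drmsf <- NULL
  if (!is.null(spec$planted_fluctuations)) {
    pf <- spec$planted_fluctuations
    drmsf <- data.frame(chain = pf$chain, resno = pf$resno,
                        expected_drmsf = sqrt(3) * abs(pf$sigma_b - pf$sigma_a),
                        approximate = TRUE, stringsAsFactors = FALSE)
  }
  occ <- NULL
  if (!is.null(spec$planted_hbonds)) {
    occ <- data.frame(donor = sprintf("A:ALA %d N", spec$planted_hbonds$donor_resno),
                      acceptor = sprintf("B:ALA %d O", spec$planted_hbonds$acceptor_resno),
                      occupancy = spec$planted_hbonds$occupancy,
                      stringsAsFactors = FALSE)
  }
  structure(list(important_residues = important,
                 expected_drmsf = drmsf,
                 expected_occupancy = occ,
                 expected_contacts = spec$planted_contacts,
                 reference_pair_energies = ref_energies),
            class = "ground_truth")
}

#' Domain map of the toy two-chain complex
#'
#' One domain per helix and a single interface (id 1) between them,
#' matching the residue numbering of [build_toy_topology()].
#'
#' @param spec a [synthetic_spec()]
#' @param disordered optional list of `list(chain, start, end)` ranges
#'   to flag as disordered
#' @return a `domain_map`
#' @export
toy_domain_map <- function(spec, disordered = NULL) {
  n <- spec$residues_per_chain
  load_domain_map(list(
    domains = list(
      A_helix = list(chain = "A", start = 1L, end = n),
      B_helix = list(chain = "B", start = 101L, end = 100L + n)),
    interfaces = list(list(id = 1L, a = "A_helix", b = "B_helix")),
    disordered = disordered))
}

#' Write a synthetic ensemble pair to disk
#'
#' Emits one multi-model PDB per replicate, the per-atom parameter
#' table, and the ground truth as JSON - the on-disk layout the rest of
#' the pipeline ingests.
#'
#' @param generated a [generate_ensembles()] result
#' @param dir output directory (created if needed)
#' @return the directory, invisibly
#' @export
write_synthetic_ensembles <- function(generated, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (ens in list(generated$ensemble_a, generated$ensemble_b)) {
    lab <- gsub("[^A-Za-z0-9._-]", "_", ens$state_label)
    for (r in seq_along(ens$replicates)) {
      write_trajectory_pdb(ens$replicates[[r]],
                           file.path(dir, sprintf("%s_rep%d.pdb", lab, r)))
    }
  }
  write_param_table(generated$topology, file.path(dir, "params.csv"))
  jsonlite::write_json(
    lapply(unclass(generated$truth), function(x) x),
    file.path(dir, "ground_truth.json"),
    auto_unbox = TRUE, digits = NA, na = "null", force = TRUE)
  invisible(dir)
}
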