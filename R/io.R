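#' Read a structure from a PDB file
#'
#' Parses a (single-model) PDB file via bio3d, preserving atom order,
#' chain ids and hydrogens, and returns the topology together with the
#' first model's coordinates. Hydrogen-heavy bonds are inferred by
#' distance ([infer_h_bonds()]) unless an explicit bond list is given.
#'
#' @param path PDB file
#' @param bonds optional explicit bond matrix (two columns of atom indices)
#' @return list with `topology` (an [md_topology()]) and `coords`
#'   (`A x 3` matrix, Angstrom)
#' @export
read_structure <- function(path, bonds = NULL) {
  pdb <- tryCatch(bio3d::read.pdb(path, multi = FALSE, verbose = FALSE),
                  error = function(e) stop("PDB parse error in '", path, "': ",
                                           conditionMessage(e)))
  if (nrow(pdb$atom) == 0L) stop("empty input: no atoms in '", path, "'")
  top_from_bio3d(pdb, bonds = bonds)
}

top_from_bio3d <- function(pdb, bonds = NULL) {
  a <- pdb$atom
  elesy <- a$elesy
  fix <- is.na(elesy) | elesy == ""
  if (any(fix)) elesy[fix] <- element_from_name(a$elety[fix])
  atoms <- data.frame(elety = a$elety, elesy = elesy, resno = a$resno,
                      resid = a$resid, chain = ifelse(is.na(a$chain), "A", a$chain),
                      stringsAsFactors = FALSE)
  coords <- matrix(pdb$xyz[1, ], ncol = 3L, byrow = TRUE)
  if (is.null(bonds)) bonds <- infer_h_bonds(atoms, coords)
  list(topology = md_topology(atoms, bonds = bonds), coords = coords)
}

# Element symbol from a PDB atom name (first alphabetic character,
# two-letter symbols for common hetero elements).
element_from_name <- function(name) {
  vapply(name, function(nm) {
    nm2 <- gsub("[^A-Za-z]", "", nm)
    if (nm2 %in% c("CL", "Cl", "BR", "Br", "FE", "Fe", "ZN", "Zn", "MG", "Mg", "NA")) {
      return(paste0(substr(nm2, 1, 1), tolower(substr(nm2, 2, 2))))
    }
    substr(nm2, 1L, 1L)
  }, character(1), USE.NAMES = FALSE)
}

#' Read a trajectory from a multi-model PDB file
#'
#' All MODELs are read in file order. PDB carries no time axis, so
#' frame times are synthesized from a configured frame spacing.
#'
#' @param path multi-model PDB
#' @param topology optional [md_topology()] to bind the frames to; its
#'   atom count must match the file (topology-mismatch error otherwise).
#'   When `NULL` the topology is built from the file itself.
#' @param dt frame spacing in ns (default 0.1)
#' @return an [md_trajectory()]
#' @export
read_trajectory <- function(path, topology = NULL, dt = 0.1) {
  pdb <- tryCatch(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE),
                  error = function(e) stop("PDB parse error in '", path, "': ",
                                           conditionMessage(e)))
  if (nrow(pdb$atom) == 0L || is.null(pdb$xyz) || nrow(pdb$xyz) == 0L) {
    stop("empty input: no frames in '", path, "'")
  }
  na_file <- nrow(pdb$atom)
  if (is.null(topology)) {
    topology <- top_from_bio3d(pdb)$topology
  } else if (n_atoms(topology) != na_file) {
    stop(sprintf("topology mismatch: file has %d atoms, topology %d",
                 na_file, n_atoms(topology)))
  }
  nf <- nrow(pdb$xyz)
  coords <- array(0, dim = c(na_file, 3L, nf))
  for (f in seq_len(nf)) coords[, , f] <- matrix(pdb$xyz[f, ], ncol = 3L, byrow = TRUE)
  md_trajectory(topology, coords, dt = dt)
}

#' Write a trajectory as a multi-model PDB file
#'
#' @param traj an [md_trajectory()]
#' @param path output file
#' @return `path`, invisibly
#' @export
write_trajectory_pdb <- function(traj, path) {
  a <- traj$topology$atoms
  nf <- n_frames(traj)
  xyz <- matrix(0, nrow = nf, ncol = 3L * nrow(a))
  for (f in seq_len(nf)) xyz[f, ] <- as.numeric(t(traj$coords[, , f]))
  bio3d::write.pdb(file = path, xyz = xyz, type = rep("ATOM", nrow(a)),
                   resno = a$resno, resid = a$resid, eleno = seq_len(nrow(a)),
                   elety = a$elety, chain = a$chain, elesy = a$elesy)
  invisible(path)
}

#' Read a per-atom force-field parameter table
#'
#' Whitespace- or comma-delimited columns: `chain`, `resno`,
#' `atom_name`, `charge_e`, `sigma_A`, `epsilon_kJmol`. Parameters are
#' matched onto the topology by (chain, residue number, atom name).
#'
#' @param path parameter table file
#' @param topology [md_topology()] to decorate
#' @return the topology with `charge`, `sigma`, `epsilon` filled in
#' @export
read_param_table <- function(path, topology) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl(",", first)) "," else ""
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  req <- c("chain", "resno", "atom_name", "charge_e", "sigma_A", "epsilon_kJmol")
  miss <- setdiff(req, names(tab))
  if (length(miss)) stop("parameter table missing columns: ",
                         paste(miss, collapse = ", "))
  a <- topology$atoms
  key_top <- paste(a$chain, a$resno, a$elety)
  key_tab <- paste(tab$chain, tab$resno, tab$atom_name)
  hit <- match(key_top, key_tab)
  ok <- !is.na(hit)
  a$charge[ok] <- tab$charge_e[hit[ok]]
  a$sigma[ok] <- tab$sigma_A[hit[ok]]
  a$epsilon[ok] <- tab$epsilon_kJmol[hit[ok]]
  topology$atoms <- a
  topology
}

#' Write the per-atom parameter table of a topology
#' @param topology [md_topology()] carrying charges and LJ parameters
#' @param path output file (comma-delimited)
#' @return `path`, invisibly
#' @export
write_param_table <- function(topology, path) {
  a <- topology$atoms
  utils::write.csv(data.frame(chain = a$chain, resno = a$resno,
                              atom_name = a$elety, charge_e = a$charge,
                              sigma_A = a$sigma, epsilon_kJmol = a$epsilon),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Load a domain/interface map
#'
#' The map names domains as inclusive residue ranges on a chain, flags
#' disordered stretches, and declares the interfaces (pairs of domains)
#' to analyze. A template for the HIF-2a:ARNT architecture with its six
#' critical interfaces ships with the package
#' (`system.file("extdata", "hif2a_arnt_domains.yaml", package = "mdcompare")`).
#'
#' @param config path to a YAML file, or an equivalent list with
#'   elements `domains` (name -> chain/start/end), optional
#'   `disordered` (list of chain/start/end ranges) and `interfaces`
#'   (list of id/a/b referencing domain names)
#' @return object of class `domain_map`
#' @export
load_domain_map <- function(config) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  if (is.null(cfg$domains) || !length(cfg$domains)) stop("config lists no domains")
  dom <- do.call(rbind, lapply(names(cfg$domains), function(nm) {
    d <- cfg$domains[[nm]]
    if (is.null(d$chain) || is.null(d$start) || is.null(d$end)) {
      stop("domain '", nm, "' needs chain, start, end")
    }
    if (d$start > d$end) stop("domain '", nm, "' has start > end")
    data.frame(name = nm, chain = d$chain, start = as.integer(d$start),
               end = as.integer(d$end), stringsAsFactors = FALSE)
  }))
  # reject overlapping domains on one chain
  for (ch in unique(dom$chain)) {
    dd <- dom[dom$chain == ch, ]
    if (nrow(dd) > 1L) {
      dd <- dd[order(dd$start), ]
      if (any(dd$start[-1L] <= dd$end[-nrow(dd)])) {
        stop("overlapping domain definitions on chain ", ch)
      }
    }
  }
  ifc <- cfg$interfaces %||% list()
  interfaces <- do.call(rbind, lapply(ifc, function(i) {
    if (!(i$a %in% dom$name) || !(i$b %in% dom$name)) {
      stop("interface ", i$id %||% "?", " references an unknown domain")
    }
    data.frame(id = as.integer(i$id), a = i$a, b = i$b,
               stringsAsFactors = FALSE)
  }))
  if (!is.null(interfaces) && anyDuplicated(interfaces$id)) {
    stop("interface ids must be distinct")
  }
  dis <- cfg$disordered %||% list()
  disordered <- do.call(rbind, lapply(dis, function(d) {
    data.frame(chain = d$chain, start = as.integer(d$start),
               end = as.integer(d$end), stringsAsFactors = FALSE)
  }))
  structure(list(domains = dom, interfaces = interfaces,
                 disordered = disordered),
            class = "domain_map")
}

#' @export
print.domain_map <- function(x, ...) {
  cat(sprintf("domain_map: %d domains, %d interfaces\n",
              nrow(x$domains), if (is.null(x$interfaces)) 0L else nrow(x$interfaces)))
  invisible(x)
}

#' Residue numbers belonging to a named domain
#' @param map a `domain_map`
#' @param name domain name
#' @return list with `chain` and integer `resno` vector
#' @export
domain_residues <- function(map, name) {
  d <- map$domains[map$domains$name == name, ]
  if (nrow(d) != 1L) stop("unknown domain '", name, "'")
  list(chain = d$chain, resno = seq(d$start, d$end))
}

#' Per-residue order mask from a domain map
#'
#' @param map a `domain_map`
#' @param topology an [md_topology()]
#' @return character vector over residues of the topology,
#'   `"ordered"`/`"disordered"` (residues inside a declared disordered
#'   range are disordered)
#' @export
order_mask <- function(map, topology) {
  r <- topology$residues
  mask <- rep("ordered", nrow(r))
  if (!is.null(map$disordered)) {
    for (k in seq_len(nrow(map$disordered))) {
      d <- map$disordered[k, ]
      mask[r$chain == d$chain & r$resno >= d$start & r$resno <= d$end] <- "disordered"
    }
  }
  names(mask) <- residue_labels(topology)
  mask
}
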