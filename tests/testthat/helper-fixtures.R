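# shared fixture builders (all generated in code, no files)

# minimal topology of free atoms with explicit parameters
ion_topology <- function(n, elesy = rep("N", n), charge = rep(0, n),
                         sigma = rep(3, n), epsilon = rep(0.5, n),
                         chain = rep(c("A", "B"), length.out = n)) {
  md_topology(data.frame(
    elety = paste0("X", seq_len(n)), elesy = elesy,
    resno = seq_len(n), resid = "ION", chain = chain,
    charge = charge, sigma = sigma, epsilon = epsilon,
    stringsAsFactors = FALSE))
}

# small synthetic spec used across tests (fast)
tiny_spec <- function(...) {
  args <- utils::modifyList(list(residues_per_chain = 8,
                                 replicates_per_state = 2,
                                 frames_per_replicate = 30), list(...))
  do.call(synthetic_spec, args)
}

# independent superposition oracle: best RMSD over random rotations,
# refined by direct minimization over Euler angles
grid_best_rmsd <- function(mobile, reference, n_grid = 10000) {
  cm <- scale(mobile, scale = FALSE)
  cr <- scale(reference, scale = FALSE)
  euler <- function(a) {
    cz <- cos(a[1]); sz <- sin(a[1]); cy <- cos(a[2]); sy <- sin(a[2])
    cx <- cos(a[3]); sx <- sin(a[3])
    matrix(c(cz * cy, cz * sy * sx - sz * cx, cz * sy * cx + sz * sx,
             sz * cy, sz * sy * sx + cz * cx, sz * sy * cx - cz * sx,
             -sy, cy * sx, cy * cx), 3, 3, byrow = TRUE)
  }
  f <- function(a) sqrt(mean(rowSums((cm %*% t(euler(a)) - cr)^2)))
  best <- c(0, 0, 0); best_val <- f(best)
  for (k in seq_len(n_grid)) {
    a <- stats::runif(3, -pi, pi)
    v <- f(a)
    if (v < best_val) { best <- a; best_val <- v }
  }
  stats::optim(best, f, method = "Nelder-Mead",
               control = list(reltol = 1e-12, maxit = 2000))$value
}

# trajectory from an explicit list of A x 3 frames
traj_from_frames <- function(top, frames, dt = 0.1) {
  coords <- array(0, dim = c(nrow(frames[[1]]), 3, length(frames)))
  for (f in seq_along(frames)) coords[, , f] <- frames[[f]]
  md_trajectory(top, coords, dt = dt)
}

random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  a <- q[1]; b <- q[2]; c <- q[3]; d <- q[4]
  matrix(c(a^2 + b^2 - c^2 - d^2, 2 * (b * c - a * d), 2 * (b * d + a * c),
           2 * (b * c + a * d), a^2 - b^2 + c^2 - d^2, 2 * (c * d - a * b),
           2 * (b * d - a * c), 2 * (c * d + a * b), a^2 - b^2 - c^2 + d^2),
         3, 3, byrow = TRUE)
}

# donor-hydrogen-acceptor toy: N-H on residue 1/chain A, O on residue
# 2/chain B, acceptor placed at distance d and angle theta (degrees)
# from the D -> H direction
dha_fixture <- function(d, theta) {
  top <- md_topology(
    data.frame(elety = c("N", "H", "O"), elesy = c("N", "H", "O"),
               resno = c(1, 1, 2), resid = c("ALA", "ALA", "SER"),
               chain = c("A", "A", "B"), stringsAsFactors = FALSE),
    bonds = cbind(2L, 1L))
  th <- theta * pi / 180
  coords <- rbind(c(0, 0, 0), c(1.01, 0, 0), d * c(cos(th), sin(th), 0))
  list(topology = top, coords = coords)
}

table1_path <- system.file("extdata", "table1_protein_protein_bfe.csv",
                           package = "mdcompare")
table2_path <- system.file("extdata", "table2_belzutifan_bfe.csv",
                           package = "mdcompare")
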