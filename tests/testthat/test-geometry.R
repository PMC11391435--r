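test_that("Kabsch superposition recovers rigid motions exactly", {
  set.seed(11)
  ref <- matrix(rnorm(30), 10)
  self <- kabsch_fit(ref, ref)
  expect_equal(self$rmsd, 0, tolerance = 1e-10)
  expect_equal(self$rotation, diag(3), tolerance = 1e-8)

  th <- pi / 2
  Rz <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3)
  mob <- ref %*% t(Rz) + matrix(c(4, -2, 7), 10, 3, byrow = TRUE)
  fit <- kabsch_fit(mob, ref)
  expect_equal(fit$rmsd, 0, tolerance = 1e-9)
  expect_equal(crossprod(fit$rotation), diag(3), tolerance = 1e-8)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-8)

  # collinear selection is degenerate
  line <- cbind(1:5, 0, 0)
  expect_error(kabsch_fit(line + 0, line), "degenera")
})

test_that("Kabsch RMSD matches a rotation-grid search oracle on asymmetric points", {
  set.seed(21)
  ref <- matrix(c(0, 0, 0, 3, 0, 0, 0, 2, 0, 1, 1, 4), 4, 3, byrow = TRUE)
  mob <- ref + matrix(rnorm(12, sd = 0.3), 4)
  fit <- kabsch_fit(mob, ref)

  # oracle: best RMSD over a random rotation grid with local
  # refinement, independent of the analytic solution
  best <- grid_best_rmsd(mob, ref)
  expect_lte(fit$rmsd, best + 1e-9)
  expect_lt(best - fit$rmsd, 1e-4)
})

test_that("RMSD series separates fit and measure selections", {
  g <- build_toy_topology(tiny_spec())
  top <- g$topology
  ref <- g$coords
  nf <- 5
  # static trajectory: all zeros
  tr <- traj_from_frames(top, replicate(nf, ref, simplify = FALSE))
  rs <- rmsd_series(tr, ref)
  expect_equal(rs$rmsd, rep(0, nf), tolerance = 1e-9)

  # frames are rigid motions of the reference: still zero
  set.seed(3)
  frames <- lapply(1:nf, function(i) {
    ref %*% t(random_rotation()) + matrix(rnorm(3, sd = 5), nrow(ref), 3,
                                          byrow = TRUE)
  })
  rs2 <- rmsd_series(traj_from_frames(top, frames), ref)
  expect_equal(rs2$rmsd, rep(0, nf), tolerance = 1e-8)

  # planted "ligand" displacement of d with an exact backbone match
  chain_a <- select_atoms(top, chain = "A")
  chain_b <- select_atoms(top, chain = "B")
  d <- 2.5
  moved <- ref
  moved[chain_b, 1] <- ref[chain_b, 1] + d
  tr3 <- traj_from_frames(top, replicate(nf, moved, simplify = FALSE))
  rs3 <- rmsd_series(tr3, ref, fit_selection = chain_a,
                     measure_selection = chain_b)
  expect_equal(rs3$rmsd, rep(d, nf), tolerance = 1e-9)

  expect_error(rmsd_series(tr, ref, fit_selection = integer(0)), "empty")
})

test_that("RMSF profiles match the brute-force per-frame oracle and separate planted groups", {
  spec <- tiny_spec(
    frames_per_replicate = 200, seed = 17,
    planted_fluctuations = data.frame(chain = "A", resno = c(3, 4),
                                      sigma_a = 0.2, sigma_b = 1.2))
  g <- generate_ensembles(spec)
  top <- g$topology
  ca <- select_atoms(top, elety = "CA")
  tr <- g$ensemble_b$replicates[[1]]

  # static trajectory: all zero
  st <- traj_from_frames(top, list(g$ref_coords, g$ref_coords))
  p0 <- rmsf_profile(st, g$ref_coords, selection = ca)
  expect_equal(p0$rmsf, rep(0, nrow(p0)), tolerance = 1e-9)

  # oracle: direct per-frame computation without fitting
  prof <- rmsf_profile(tr, g$ref_coords, selection = ca, fit = FALSE)
  dev2 <- sapply(seq_len(n_frames(tr)), function(f) {
    rowSums((tr$coords[ca, , f] - g$ref_coords[ca, ])^2)
  })
  expect_equal(prof$rmsf, unname(sqrt(rowMeans(dev2))), tolerance = 1e-12)

  # planted amplitude groups separate
  hi <- prof$rmsf[prof$chain == "A" & prof$resno %in% c(3, 4)]
  lo <- prof$rmsf[!(prof$chain == "A" & prof$resno %in% c(3, 4))]
  expect_gt(min(hi), max(lo))
})

test_that("RMSF and RMSD are invariant under a global rigid motion of frames and reference", {
  g <- build_toy_topology(tiny_spec())
  set.seed(9)
  frames <- lapply(1:4, function(i) g$coords + rnorm(length(g$coords), sd = 0.3))
  tr <- traj_from_frames(g$topology, frames)
  ca <- select_atoms(g$topology, elety = "CA")
  p1 <- rmsf_profile(tr, g$coords, selection = ca, fit_selection = ca)
  R <- random_rotation(); t0 <- c(10, -4, 2)
  move <- function(x) x %*% t(R) + matrix(t0, nrow(x), 3, byrow = TRUE)
  tr2 <- traj_from_frames(g$topology, lapply(frames, move))
  p2 <- rmsf_profile(tr2, move(g$coords), selection = ca, fit_selection = ca)
  expect_equal(p1$rmsf, p2$rmsf, tolerance = 1e-8)
})

test_that("flexibility flags apply inclusive order-dependent thresholds", {
  prof <- function(rmsf) {
    out <- data.frame(residue = sprintf("A:ALA %d", 1:6), chain = "A",
                      resno = 1:6, rmsf = rmsf, stringsAsFactors = FALSE)
    class(out) <- c("flex_profile", "data.frame")
    out
  }
  a <- prof(rep(1, 6))
  expect_equal(sum(flag_flexible_regions(a, a)$flag), 0L)

  b <- prof(c(2.0, 1.5, 3.5, 1.2, 4.0, 1.0))   # deltas 1.0 0.5 2.5 0.2 3.0 0.0
  mask <- setNames(rep("ordered", 6), a$residue)
  mask[3] <- "disordered"; mask[5] <- "disordered"
  fl <- flag_flexible_regions(a, b, mask)
  # ordered delta = 1.0 flagged (inclusive); disordered 2.5 not; 3.0 yes
  expect_equal(fl$flag, c(TRUE, FALSE, FALSE, FALSE, TRUE, FALSE))
  reg <- attr(fl, "regions")
  expect_equal(nrow(reg), 2L)
  expect_equal(reg$start, c(1, 5))

  b2 <- data.frame(residue = sprintf("A:ALA %d", 1:5), chain = "A",
                   resno = 1:5, rmsf = 1, stringsAsFactors = FALSE)
  class(b2) <- c("flex_profile", "data.frame")
  expect_error(flag_flexible_regions(a, b2), "different residue sets")
})
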