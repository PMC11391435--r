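test_that("geometric criteria gate detection on distance and angle", {
  crit <- hbond_criteria()
  inside <- dha_fixture(2.9, 10)
  hit <- detect_hbonds(inside$coords, inside$topology, crit)
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$donor_label, "A:ALA 1 N")
  expect_equal(hit$acceptor_label, "B:SER 2 O")

  too_far <- dha_fixture(3.6, 10)
  expect_equal(nrow(detect_hbonds(too_far$coords, too_far$topology, crit)), 0L)

  bad_angle <- dha_fixture(3.4, 35)
  expect_equal(nrow(detect_hbonds(bad_angle$coords, bad_angle$topology, crit)), 0L)

  # detection is invariant under a global rigid motion
  set.seed(4)
  R <- random_rotation()
  moved <- inside$coords %*% t(R) + matrix(c(3, -8, 1), 3, 3, byrow = TRUE)
  expect_equal(nrow(detect_hbonds(moved, inside$topology, crit)), 1L)

  expect_error(hbond_criteria(angle_max = 95), "angle_max")
  expect_error(hbond_criteria(d_DA_max = -1), "d_DA_max")
})

test_that("widening either cutoff never loses detections", {
  g <- generate_ensembles(tiny_spec(frames_per_replicate = 10, seed = 23))
  tr <- g$ensemble_a$replicates[[1]]
  narrow <- hbond_occupancy(tr, hbond_criteria(3.2, 20))
  wide <- hbond_occupancy(tr, hbond_criteria(3.5, 30))
  key <- function(t) paste(t$donor, t$hydrogen, t$acceptor)
  for (k in seq_len(nrow(narrow))) {
    i <- match(key(narrow)[k], key(wide))
    expect_false(is.na(i))
    expect_gte(wide$occupancy[i], narrow$occupancy[k])
  }
})

test_that("occupancy recovers a planted Bernoulli rate within binomial error", {
  q <- 0.30; nf <- 2000
  spec <- synthetic_spec(residues_per_chain = 6, replicates_per_state = 2,
                         frames_per_replicate = nf,
                         planted_hbonds = data.frame(donor_resno = 3,
                                                     acceptor_resno = 104,
                                                     occupancy = q),
                         seed = 31)
  g <- generate_ensembles(spec)
  occ <- hbond_occupancy(g$ensemble_a$replicates[[1]])
  row <- occ[occ$donor_label == "A:ALA 3 N" & occ$acceptor_label == "B:ALA 104 O", ]
  expect_equal(nrow(row), 1L)
  se <- sqrt(q * (1 - q) / nf)
  expect_lt(abs(row$occupancy / 100 - q), 3 * se)

  # occupancy equals brute-force per-frame re-evaluation
  tr <- g$ensemble_a$replicates[[1]]
  short <- window_frames(tr, c(0, tr$times[25]), 25)
  occ_s <- hbond_occupancy(short)
  counts <- integer(nrow(occ_s))
  for (f in 1:25) {
    hb <- detect_hbonds(short$coords[, , f], short$topology)
    keys <- paste(hb$donor, hb$hydrogen, hb$acceptor)
    counts <- counts + paste(occ_s$donor, occ_s$hydrogen, occ_s$acceptor) %in% keys
  }
  expect_equal(occ_s$occupancy, 100 * counts / 25)
})

test_that("the occupancy filter keeps rows at or above threshold in any replicate", {
  mk <- function(occ) {
    out <- data.frame(donor = 1:3, hydrogen = 4:6, acceptor = 7:9,
                      donor_label = paste("D", 1:3),
                      acceptor_label = paste("A", 1:3),
                      occupancy = occ, stringsAsFactors = FALSE)
    class(out) <- c("hbond_table", "data.frame")
    out
  }
  filt <- filter_occupancy(list(rep1 = mk(c(95, 12, 4)), rep2 = mk(c(90, 3, 0.5))))
  expect_equal(nrow(filt), 2L)

  filt2 <- filter_occupancy(list(r1 = mk(c(9.9, 10.0, 5))))
  expect_equal(nrow(filt2), 1L)   # 9.9 dropped, 10.0 kept (inclusive)
  expect_equal(filt2$r1, 10.0)

  faint <- attr(filter_occupancy(list(r1 = mk(c(95, 12, 4)),
                                      r2 = mk(c(0.5, 12, 4)))), "faint")
  expect_true(faint[1, "r2"])
  expect_false(faint[1, "r1"])
})

test_that("water bridges require both legs in the same frame", {
  atoms <- data.frame(
    elety = c("N", "H", "O1", "OW", "HW1", "HW2"),
    elesy = c("N", "H", "O", "O", "H", "H"),
    resno = c(1, 1, 50, 900, 900, 900),
    resid = c("ALA", "ALA", "LIG", "HOH", "HOH", "HOH"),
    chain = c("A", "A", "L", "W", "W", "W"), stringsAsFactors = FALSE)
  # protein N-H donates to water O; water O-HW1 donates to ligand O1
  base <- rbind(c(-2.9, 0, 0),                       # N
                c(-2.9 + 1.01, 0, 0),                # H toward water
                c(2.9, 0, 0),                        # ligand O1
                c(0, 0, 0),                          # water O
                c(0.96, 0, 0),                       # HW1 toward ligand
                c(-0.3, 0.9, 0))                     # HW2 elsewhere
  top <- md_topology(atoms, bonds = infer_h_bonds(atoms, base))
  away <- base; away[3, ] <- c(40, 40, 40)           # ligand out of reach

  tr <- traj_from_frames(top, c(replicate(4, base, simplify = FALSE),
                                replicate(6, away, simplify = FALSE)))
  wb <- water_bridges(tr, ligand_sel = 3L, protein_sel = 1:2)
  expect_equal(nrow(wb$summary), 1L)
  expect_equal(wb$summary$frequency, 0.4)
  expect_equal(unique(wb$records$frame), 1:4)

  # water bonded to the ligand only: no bridge
  only <- base; only[1, ] <- c(-40, 0, 0); only[2, ] <- c(-39, 0, 0)
  wb2 <- water_bridges(traj_from_frames(top, list(only)), 3L, 1:2)
  expect_equal(nrow(wb2$summary), 0L)

  # no waters at all: empty result with a warning
  dry <- md_topology(atoms[1:3, ], bonds = cbind(2L, 1L))
  expect_warning(
    wb3 <- water_bridges(traj_from_frames(dry, list(base[1:3, ])), 3L, 1:2),
    "no water")
  expect_equal(nrow(wb3$summary), 0L)
})

test_that("pair distance series report per-frame geometry and replicate means", {
  top <- ion_topology(2)
  fixed <- rbind(c(0, 0, 0), c(5, 0, 0))
  tr <- traj_from_frames(top, replicate(6, fixed, simplify = FALSE))
  ds <- pair_distance_series(tr, cbind(1L, 2L))
  expect_equal(ds[[2]], rep(5, 6))
  expect_equal(unname(attr(ds, "means")), 5)

  # planted bimodal mixture: weighted mean
  near <- fixed; near[2, 1] <- 3.4
  far <- fixed; far[2, 1] <- 8
  tr2 <- traj_from_frames(top, c(replicate(6, near, simplify = FALSE),
                                 replicate(4, far, simplify = FALSE)))
  ds2 <- pair_distance_series(tr2, cbind(1L, 2L))
  expect_equal(unname(attr(ds2, "means")), 0.6 * 3.4 + 0.4 * 8)

  # rigid motion leaves distances unchanged
  set.seed(5)
  R <- random_rotation()
  moved <- lapply(seq_len(n_frames(tr2)), function(f) {
    tr2$coords[, , f] %*% t(R) + matrix(c(1, 2, 3), 2, 3, byrow = TRUE)
  })
  ds3 <- pair_distance_series(traj_from_frames(top, moved), cbind(1L, 2L))
  expect_equal(ds3[[2]], ds2[[2]], tolerance = 1e-9)

  expect_error(pair_distance_series(tr, cbind(1L, 99L)), "unknown atom")
})
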