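test_that("Coulomb and LJ terms match closed forms and a brute-force pair sum", {
  top <- ion_topology(2, charge = c(1, -1), sigma = c(3, 3), epsilon = c(0.5, 0.5))
  xyz <- rbind(c(0, 0, 0), c(10, 0, 0))
  e <- coulomb_lj_energy(xyz, 1L, 2L, top)
  expect_equal(unname(e["coulomb"]), -138.935458, tolerance = 1e-6)

  # LJ vanishes at r = sigma_ij
  e2 <- coulomb_lj_energy(rbind(c(0, 0, 0), c(3, 0, 0)), 1L, 2L,
                          ion_topology(2, charge = c(0, 0)))
  expect_equal(unname(e2["lj"]), 0, tolerance = 1e-10)

  # 3 vs 2 atoms: brute-force double loop
  set.seed(8)
  top5 <- ion_topology(5, charge = runif(5, -1, 1), sigma = runif(5, 2.5, 3.5),
                       epsilon = runif(5, 0.1, 1))
  xyz5 <- matrix(runif(15, 0, 8), 5)
  got <- coulomb_lj_energy(xyz5, 1:3, 4:5, top5)
  cexp <- 0; ljexp <- 0
  for (i in 1:3) for (j in 4:5) {
    r <- sqrt(sum((xyz5[i, ] - xyz5[j, ])^2))
    qi <- top5$atoms$charge[i]; qj <- top5$atoms$charge[j]
    cexp <- cexp + 1389.35458 * qi * qj / r
    sij <- (top5$atoms$sigma[i] + top5$atoms$sigma[j]) / 2
    eij <- sqrt(top5$atoms$epsilon[i] * top5$atoms$epsilon[j])
    ljexp <- ljexp + 4 * eij * ((sij / r)^12 - (sij / r)^6)
  }
  expect_equal(unname(got["coulomb"]), cexp, tolerance = 1e-9)
  expect_equal(unname(got["lj"]), ljexp, tolerance = 1e-9)

  # symmetry under group exchange and rigid motion; charge scaling
  swapped <- coulomb_lj_energy(xyz5, 4:5, 1:3, top5)
  expect_equal(got, swapped, tolerance = 1e-10)
  R <- random_rotation()
  moved <- xyz5 %*% t(R) + matrix(c(5, -1, 2), 5, 3, byrow = TRUE)
  expect_equal(coulomb_lj_energy(moved, 1:3, 4:5, top5), got, tolerance = 1e-8)
  top2x <- top5; top2x$atoms$charge <- 2 * top5$atoms$charge
  got2x <- coulomb_lj_energy(xyz5, 1:3, 4:5, top2x)
  expect_equal(unname(got2x["coulomb"]), 4 * cexp, tolerance = 1e-9)

  expect_error(coulomb_lj_energy(rbind(c(0, 0, 0), c(0, 0, 0)), 1L, 2L, top),
               "singular")
  top_na <- top; top_na$atoms$charge[2] <- NA
  expect_error(coulomb_lj_energy(xyz, 1L, 2L, top_na), "missing charge")
  expect_error(coulomb_lj_energy(xyz, 1:2, 2L, top), "disjoint")
})

test_that("the nonpolar term follows the linear surface-area model", {
  top <- ion_topology(2, elesy = c("C", "C"))
  far <- rbind(c(0, 0, 0), c(60, 0, 0))
  np <- nonpolar_term(far, top, 1L, 2L)
  expect_equal(np$dsasa, 0, tolerance = 1e-9)
  expect_equal(np$dg_nonpolar, -3.84928, tolerance = 1e-9)
  expect_equal(nonpolar_term(far, top, 1L, 2L, convention = "difference")$dg_nonpolar,
               0, tolerance = 1e-9)

  near <- rbind(c(0, 0, 0), c(2.5, 0, 0))
  np1 <- nonpolar_term(near, top, 1L, 2L, convention = "difference")
  expect_lt(np1$dsasa, 0)
  expect_equal(np1$dg_nonpolar, 0.0226778 * np1$dsasa, tolerance = 1e-12)
  # doubling gamma doubles the area term
  np2 <- nonpolar_term(near, top, 1L, 2L, gamma = 2 * 0.0226778,
                       convention = "difference")
  expect_equal(np2$dg_nonpolar, 2 * np1$dg_nonpolar, tolerance = 1e-9)
})

test_that("binding energy sums components and honors an ingested polar term", {
  set.seed(12)
  top <- ion_topology(4, charge = c(0.4, -0.4, 0.3, -0.3))
  frames <- replicate(3, matrix(runif(12, 0, 6), 4), simplify = FALSE)
  tr <- traj_from_frames(top, frames)
  expect_message(b0 <- binding_energy(tr, 1:2, 3:4), "polar")
  expect_equal(b0$frames$g_total,
               b0$frames$e_mm + b0$frames$g_nonpolar, tolerance = 1e-9)

  b10 <- suppressMessages(binding_energy(tr, 1:2, 3:4, polar_source = -10))
  expect_equal(b10$frames$g_total, b0$frames$g_total - 10, tolerance = 1e-9)

  # per-frame totals equal component-wise brute force
  for (f in 1:3) {
    mm <- coulomb_lj_energy(frames[[f]], 1:2, 3:4, top)
    np <- nonpolar_term(frames[[f]], top, 1:2, 3:4, n_points = 240)
    expect_equal(b0$frames$g_total[f], sum(mm) + np$dg_nonpolar,
                 tolerance = 1e-9)
  }

  # rigid non-interacting groups: both terms near zero
  quiet <- ion_topology(4, charge = c(1, -1, 1, -1))
  farxyz <- rbind(c(0, 0, 0), c(3, 0, 0), c(500, 0, 0), c(503, 0, 0))
  bfar <- suppressMessages(binding_energy(traj_from_frames(quiet, list(farxyz)),
                                          1:2, 3:4,
                                          nonpolar_convention = "difference"))
  expect_lt(abs(bfar$frames$e_mm), 0.02)
  expect_equal(bfar$frames$g_nonpolar, 0, tolerance = 1e-9)
})

test_that("per-residue decomposition conserves the totals and matches brute force", {
  set.seed(13)
  # 5 residues: 3 in chain A, 2 in chain B, one atom each
  top <- ion_topology(5, charge = runif(5, -0.5, 0.5),
                      chain = c("A", "A", "A", "B", "B"))
  xyz <- matrix(runif(15, 0, 7), 5)
  tr <- traj_from_frames(top, list(xyz))
  dec <- suppressMessages(
    per_residue_decomposition(tr, 1:3, 4:5, nonpolar_convention = "difference"))
  tot <- suppressMessages(
    binding_energy(tr, 1:3, 4:5, nonpolar_convention = "difference"))

  # conservation: residue sums reproduce the totals
  expect_equal(sum(dec$e_mm), tot$frames$e_mm, tolerance = 1e-6)
  expect_equal(sum(dec$g_nonpolar), tot$frames$g_nonpolar, tolerance = 1e-6)
  expect_equal(attr(dec, "nonpolar_offset"), 0)
  expect_equal(sum(dec$g_total), tot$frames$g_total, tolerance = 1e-6)

  # brute-force half-share attribution per residue
  for (i in 1:5) {
    own <- 0
    for (a in 1:3) for (b in 4:5) {
      if (a != i && b != i) next
      r <- sqrt(sum((xyz[a, ] - xyz[b, ])^2))
      qq <- 1389.35458 * top$atoms$charge[a] * top$atoms$charge[b] / r
      sij <- (top$atoms$sigma[a] + top$atoms$sigma[b]) / 2
      eij <- sqrt(top$atoms$epsilon[a] * top$atoms$epsilon[b])
      lj <- 4 * eij * ((sij / r)^12 - (sij / r)^6)
      own <- own + (qq + lj) / 2
    }
    expect_equal(dec$e_mm[i], own, tolerance = 1e-9)
  }

  # a single interacting residue on one side carries that side's total
  top2 <- ion_topology(3, charge = c(0.5, -0.3, -0.2),
                       chain = c("A", "B", "B"))
  xyz2 <- rbind(c(0, 0, 0), c(4, 0, 0), c(0, 4.5, 0))
  dec2 <- suppressMessages(
    per_residue_decomposition(traj_from_frames(top2, list(xyz2)), 1L, 2:3,
                              nonpolar_convention = "difference"))
  tot2 <- suppressMessages(
    binding_energy(traj_from_frames(top2, list(xyz2)), 1L, 2:3,
                   nonpolar_convention = "difference"))
  expect_equal(dec2$e_mm[dec2$residue == "A:ION 1"], tot2$frames$e_mm / 2,
               tolerance = 1e-9)
})

test_that("decomposition tables round-trip and validate their totals", {
  tab <- data.frame(residue = c("A:GLY 323", "A:THR 324", "B:ARG 100"),
                    e_mm = c(-12.5, -3.1, 4.2), g_polar = c(2.0, 1.0, -0.5),
                    g_nonpolar = c(-0.8, -0.2, -0.1),
                    g_total = c(-11.3, -2.3, 3.6), stringsAsFactors = FALSE)
  class(tab) <- c("decomposition_table", "data.frame")
  f <- withr::local_tempfile(fileext = ".csv")
  write_decomposition(tab, f)
  back <- read_decomposition(f)
  expect_equal(back$g_total, tab$g_total)

  bad <- tab; bad$g_total[2] <- 99
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_decomposition(bad, f2)
  expect_warning(read_decomposition(f2), "violate")

  # g_mmpbsa contribution dialect: '#' header, one column per residue
  f3 <- withr::local_tempfile(fileext = ".dat")
  writeLines(c("# Time GLY-323 THR-324",
               "0.0 -10.0 -2.0",
               "1.0 -14.0 -4.0"), f3)
  gm <- read_decomposition(f3, dialect = "gmmpbsa")
  expect_equal(gm$residue, c("GLY-323", "THR-324"))
  expect_equal(gm$g_total, c(-12, -3))
})

test_that("replicate summaries and deltas reproduce printed-table conventions", {
  vals <- utils::read.csv(table2_path, check.names = FALSE)
  s <- summarize_bfe(as.list(vals))
  expect_equal(s$states$rounded_mean, c(-124.4, -72.7, -101.0))
  expect_equal(s$deltas$delta_rounded, c(51.7, 23.4))

  same <- summarize_bfe(list(a = vals[[1]], b = vals[[1]]))
  expect_equal(same$deltas$delta_rounded, 0)
  expect_error(summarize_bfe(list(a = 1)), "2 replicates")

  dd <- residue_delta_bfe(
    structure(data.frame(residue = c("r1", "r2"), g_total = c(-5, -1)),
              class = c("decomposition_table", "data.frame")),
    structure(data.frame(residue = c("r1", "r2"), g_total = c(-2, -9)),
              class = c("decomposition_table", "data.frame")))
  expect_equal(dd$delta_bfe[dd$residue == "r2"], -8)
  expect_equal(dd$residue[1], "r2")   # ranked by |delta|
})
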