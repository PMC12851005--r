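test_that("superposition of a model onto itself is the identity", {
  set.seed(11)
  P <- matrix(rnorm(30), 10, 3)
  fit <- superpose_kabsch(P, P)
  expect_equal(fit$rmsd, 0, tolerance = 1e-10)
  expect_equal(fit$rotation, diag(3), tolerance = 1e-10)
  expect_equal(fit$n_atoms, 10)
})

test_that("rigid motions are removed exactly", {
  set.seed(12)
  P <- matrix(rnorm(24), 8, 3)
  Rz <- matrix(c(0, -1, 0, 1, 0, 0, 0, 0, 1), 3, byrow = TRUE)  # 90 deg
  fit <- superpose_kabsch(sweep(P %*% t(Rz), 2, c(3, -2, 7), `+`), P)
  expect_lt(fit$rmsd, 1e-8)
  for (i in 1:10) {
    R <- random_rotation(); t <- rnorm(3, sd = 10)
    f <- superpose_kabsch(sweep(P %*% t(R), 2, t, `+`), P)
    expect_lt(f$rmsd, 1e-8)
    expect_equal(crossprod(f$rotation), diag(3), tolerance = 1e-8)
    expect_equal(det(f$rotation), 1, tolerance = 1e-8)
  }
})

test_that("kabsch rmsd matches a brute-force rotation-grid oracle", {
  # planar points with in-plane perturbation: the optimal rotation is
  # about z, so a fine 1-D angle grid is an exhaustive oracle
  set.seed(13)
  P <- cbind(matrix(rnorm(10, sd = 3), 5, 2), 0)
  Q <- P + cbind(matrix(rnorm(10, sd = 0.3), 5, 2), 0)
  grid_min <- min(vapply(seq(0, 2 * pi, length.out = 72001), function(th) {
    R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3,
                byrow = TRUE)
    Pc <- sweep(P, 2, colMeans(P)); Qc <- sweep(Q, 2, colMeans(Q))
    sqrt(mean(rowSums((Pc %*% t(R) - Qc)^2)))
  }, 0))
  fit <- superpose_kabsch(P, Q)
  expect_equal(fit$rmsd, grid_min, tolerance = 1e-6)
  expect_lte(fit$rmsd, grid_min + 1e-12)  # never worse than the oracle
})

test_that("superposition never increases the rmsd and rejects bad input", {
  set.seed(14)
  for (i in 1:5) {
    P <- matrix(rnorm(21), 7, 3); Q <- matrix(rnorm(21), 7, 3)
    before <- sqrt(mean(rowSums((P - Q)^2)))
    expect_lte(superpose_kabsch(P, Q)$rmsd, before + 1e-12)
  }
  expect_error(superpose_kabsch(matrix(0, 4, 3), matrix(0, 5, 3)),
               "4 mobile vs 5")
  collinear <- cbind(1:5, 2 * (1:5), -(1:5))
  expect_error(superpose_kabsch(collinear, collinear + 0.1), "collinear")
  expect_error(superpose_kabsch(matrix(rnorm(6), 2, 3),
                                matrix(rnorm(6), 2, 3)), "at least 3")
})

test_that("coordination statistics give per-ligand and mean distances", {
  m100 <- fixture_series_cached()[[1]]
  zn <- coordination_stats(m100, list(resseq = 90, name = "ZN"),
                           list(name = "SG"))
  expect_equal(zn$n_ligands, 4)
  expect_equal(unname(zn$distances), rep(2.34, 4), tolerance = 1e-9)
  expect_equal(zn$mean, 2.34, tolerance = 1e-9)

  toy <- bare_model(rbind(c(0, 0, 0), c(0, 0, 1)), c("ZN", "O"),
                    resseq = c(1, 2), element = c("ZN", "O"))
  expect_equal(coordination_stats(toy, list(resseq = 1),
                                  list(resseq = 2))$mean, 1.0)
  toy2 <- bare_model(rbind(c(0, 0, 0), c(2, 0, 0), c(0, 4, 0)),
                     c("ZN", "O", "O"), resseq = c(1, 2, 3))
  expect_equal(coordination_stats(toy2, list(resseq = 1),
                                  list(name = "O"))$mean, 3.0)
  expect_error(coordination_stats(toy2, list(name = "O"), list(resseq = 1)),
               "exactly 1")
})

test_that("triclinic cell volume matches the triple-product oracle", {
  expect_equal(unit_cell_volume(unit_cell(10, 10, 10)), 1000)
  expect_equal(unit_cell_volume(unit_cell(3, 5, 7)), 105)
  triple_product <- function(cl) {
    # explicit lattice vectors in the standard crystallographic frame
    al <- cl$alpha * pi / 180; be <- cl$beta * pi / 180
    ga <- cl$gamma * pi / 180
    va <- c(cl$a, 0, 0)
    vb <- cl$b * c(cos(ga), sin(ga), 0)
    cx <- cos(be)
    cy <- (cos(al) - cos(be) * cos(ga)) / sin(ga)
    vc <- cl$c * c(cx, cy, sqrt(1 - cx^2 - cy^2))
    abs(sum(va * pracma::cross(vb, vc)))
  }
  set.seed(15)
  for (i in 1:20) {
    cl <- unit_cell(runif(1, 5, 80), runif(1, 5, 80), runif(1, 5, 80),
                    runif(1, 60, 120), runif(1, 60, 120), runif(1, 60, 120))
    v <- tryCatch(unit_cell_volume(cl), error = function(e) NA)
    if (is.na(v)) next
    expect_equal(v, triple_product(cl), tolerance = 1e-9)
  }
  expect_equal(unit_cell_volume(unit_cell(10, 10, 10, 90, 90, 120)),
               triple_product(unit_cell(10, 10, 10, 90, 90, 120)),
               tolerance = 1e-9)
  expect_error(unit_cell_volume(unit_cell(10, 10, 10, 10, 10, 170)),
               "radicand")
})

test_that("grid volume matches sphere closed forms and their unions", {
  single <- bare_model(matrix(0, 1, 3), "C")
  v1 <- protein_volume(single)
  expect_equal(v1, 4 / 3 * pi * 1.7^3, tolerance = 0.05)
  two_far <- bare_model(rbind(c(0, 0, 0), c(10, 0, 0)), c("C", "C"))
  expect_equal(protein_volume(two_far), 2 * v1, tolerance = 0.05)
  two_same <- bare_model(rbind(c(0, 0, 0), c(0, 0, 0)), c("C", "C"))
  expect_equal(protein_volume(two_same), v1, tolerance = 0.05)
  expect_error(protein_volume(bare_model(matrix(0, 1, 3), "O", "HOH",
                                         record = "HETATM")), "heavy atoms")
})

test_that("grid volume is rigid-motion invariant and monotone", {
  set.seed(16)
  xyz <- matrix(rnorm(90, sd = 3), 30, 3)
  blob <- bare_model(xyz, rep("C", 30))
  v <- protein_volume(blob)
  moved <- apply_rigid(blob, random_rotation(), c(5.3, -2.1, 9.9))
  expect_equal(protein_volume(moved), v, tolerance = 0.01)
  bigger <- bare_model(rbind(xyz, c(20, 0, 0)), rep("C", 31))
  expect_gte(protein_volume(bigger), v)
})

test_that("B-factor profiles follow residue order and loop structure", {
  m <- fixture_series_cached()[[1]]
  p <- bfactor_profile(m)
  expect_equal(p$resseq, 1:54)
  loops <- c(16:27, 30:38)
  expect_true(all(p$bfactor[p$resseq %in% loops] >
                    max(p$bfactor[!p$resseq %in% loops])))
  # values rise with temperature residue by residue
  p_hi <- bfactor_profile(fixture_series_cached()[[12]])
  expect_true(all(p_hi$bfactor > p$bfactor))

  uni <- bare_model(matrix(rnorm(9), 3, 3), rep("CA", 3), resseq = 1:3,
                    b = 20)
  expect_equal(bfactor_profile(uni)$bfactor, rep(20, 3))
  # a residue without CA is skipped with a warning
  noca <- bare_model(matrix(rnorm(12), 4, 3), c("CA", "CA", "N", "CA"),
                     resseq = c(1, 2, 3, 4))
  expect_warning(p2 <- bfactor_profile(noca), "lack a C-alpha")
  expect_equal(p2$resseq, c(1, 2, 4))
})

test_that("z-score normalization has an exact contract", {
  m <- bare_model(matrix(rnorm(9), 3, 3), rep("CA", 3), resseq = 1:3)
  m$atoms$bfactor <- c(10, 20, 30)
  z <- normalize_bfactors(bfactor_profile(m))
  expect_equal(z$bfactor, c(-1, 0, 1))
  # mean 0, sd 1 within 1e-12 on arbitrary profiles
  set.seed(17)
  m$atoms <- m$atoms[rep(1:3, 6), ]
  m$atoms$resseq <- 1:18
  m$atoms$bfactor <- rexp(18, 0.05)
  p <- bfactor_profile(m)
  z <- normalize_bfactors(p)
  expect_equal(mean(z$bfactor), 0, tolerance = 1e-12)
  expect_equal(sd(z$bfactor), 1, tolerance = 1e-12)
  # affine invariance
  p2 <- p; p2$bfactor <- 3.7 * p2$bfactor + 11
  expect_equal(normalize_bfactors(p2)$bfactor, z$bfactor, tolerance = 1e-12)
  # degenerate spread is an error
  p3 <- p; p3$bfactor <- rep(5, nrow(p3))
  expect_error(normalize_bfactors(p3), "zero spread")
})

test_that("B-factor / mean-square-displacement conversion inverts", {
  expect_equal(b_to_msd(msd_to_b(0.37)), 0.37)
  expect_equal(msd_to_b(3 / (8 * pi^2)), 1)
})
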