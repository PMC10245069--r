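test_that("PDB write/read round trips a toy model", {
  tc <- generate_toy_complex(8, 6, cbind(c(2, 5), c(1, 4)), seed = 3)
  f <- tempfile(fileext = ".pdb")
  write_structure(tc, f)
  m <- load_structure(f)
  expect_equal(nrow(m$atoms), nrow(tc$atoms))
  expect_equal(m$chains, tc$chains)  # chain ids preserved in order
  expect_equal(as.matrix(m$atoms[, c("x", "y", "z")]),
               as.matrix(tc$atoms[, c("x", "y", "z")]),
               tolerance = 1e-3, ignore_attr = TRUE)
  unlink(f)
})

test_that("hydrogens are dropped and altlocs resolve to highest occupancy", {
  f <- tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA  GLY A   1       0.000   0.000   0.000  1.00  0.00           C",
    "ATOM      2  H   GLY A   1       1.000   0.000   0.000  1.00  0.00           H",
    "ATOM      3  CB AGLY A   2       2.000   0.000   0.000  0.30  0.00           C",
    "ATOM      4  CB BGLY A   2       3.000   0.000   0.000  0.70  0.00           C",
    "END"), f)
  m <- load_structure(f)
  expect_equal(nrow(m$atoms), 2)
  expect_false(any(grepl("^H", m$atoms$elety)))
  expect_equal(m$atoms$x[m$atoms$resno == 2], 3.0)  # occupancy 0.70 wins
  unlink(f)
})

test_that("numbering offsets shift residue numbers per chain", {
  tc <- generate_toy_complex(4, 4, seed = 5)
  f <- tempfile(fileext = ".pdb")
  write_structure(tc, f)
  m <- load_structure(f, offsets = c(A = 21))
  expect_equal(sort(unique(m$atoms$resno[m$atoms$chain == "A"])), 22:25)
  expect_equal(sort(unique(m$atoms$resno[m$atoms$chain == "B"])), 1:4)
  unlink(f)
})

test_that("contacts respect a strict distance boundary", {
  atoms <- data.frame(chain = c("A", "B", "B"), resno = c(1, 1, 2),
                      resid = "GLY", elety = "CA",
                      x = c(0, 3.9, 50), y = 0, z = 0)
  m <- mlascan:::new_structure(atoms)
  cm <- interchain_contacts(m, "A", "B", 4.0)
  expect_equal(nrow(cm), 1)
  expect_equal(cm$res_b, 1)
  expect_equal(cm$min_dist, 3.9, tolerance = 1e-9)
  atoms$x[2] <- 4.1
  expect_equal(nrow(interchain_contacts(mlascan:::new_structure(atoms),
                                        "A", "B", 4.0)), 0)
  # exactly at the cutoff is NOT a contact (strict inequality)
  atoms$x[2] <- 4.0
  expect_equal(nrow(interchain_contacts(mlascan:::new_structure(atoms),
                                        "A", "B", 4.0)), 0)
})

test_that("grid contact search equals brute force on random fixtures", {
  for (s in 1:50) {
    set.seed(s)
    n <- sample(10:40, 1)
    atoms <- data.frame(chain = sample(c("A", "B"), n, replace = TRUE),
                        resno = sample(1:12, n, replace = TRUE),
                        resid = "GLY", elety = "CA",
                        x = runif(n, 0, 15), y = runif(n, 0, 15),
                        z = runif(n, 0, 15))
    if (!all(c("A", "B") %in% atoms$chain)) next
    m <- mlascan:::new_structure(atoms)
    for (cutoff in c(3.5, 4.0, 4.5)) {
      cm <- interchain_contacts(m, "A", "B", cutoff)
      expect_setequal(contact_keys(cm), brute_contacts(m, "A", "B", cutoff))
    }
  }
})

test_that("contact maps are symmetric under group swap and monotone in cutoff", {
  tc <- generate_toy_complex(10, 10, cbind(c(1, 4, 7), c(2, 5, 9)), seed = 9)
  ab <- interchain_contacts(tc, "A", "B", 4.0)
  ba <- interchain_contacts(tc, "B", "A", 4.0)
  expect_setequal(contact_keys(ab),
                  paste(ba$chain_b, ba$res_b, ba$chain_a, ba$res_a))
  k35 <- contact_keys(interchain_contacts(tc, "A", "B", 3.5))
  k40 <- contact_keys(ab)
  k45 <- contact_keys(interchain_contacts(tc, "A", "B", 4.5))
  expect_true(all(k35 %in% k40))
  expect_true(all(k40 %in% k45))
})

test_that("footprints project contact maps onto one side", {
  tc <- generate_toy_complex(10, 10, cbind(c(5, 5, 7), c(10, 8, 10)), seed = 2)
  cm <- interchain_contacts(tc, "A", "B", 4.0)
  expect_equal(footprint(cm, "A")$resno, c(5, 7))
  expect_equal(footprint(cm, "B")$resno, c(8, 10))
  expect_error(footprint(cm, "C"), "side")
  # empty map -> empty footprints
  tc0 <- generate_toy_complex(5, 5, NULL, seed = 1)
  cm0 <- interchain_contacts(tc0, "A", "B", 4.0)
  expect_equal(nrow(cm0), 0)
  expect_equal(nrow(footprint(cm0, "A")), 0)
})

test_that("footprint equals a brute-force set projection on random maps", {
  for (s in 1:20) {
    set.seed(s)
    k <- sample(0:6, 1)
    pl <- if (k > 0) unique(cbind(sample(1:8, k, TRUE), sample(1:8, k, TRUE)))
          else NULL
    tc <- generate_toy_complex(8, 8, pl, seed = s + 100)
    cm <- interchain_contacts(tc, "A", "B", 4.0)
    expect_setequal(footprint(cm, "A")$resno, unique(cm$res_a))
    expect_setequal(footprint(cm, "B")$resno, unique(cm$res_b))
  }
})

test_that("DMS-overlap reports intersection and set differences", {
  ov <- overlap_with_dms(1:10, c(5, 6, 20))
  expect_equal(ov$n_overlap, 2)
  expect_equal(ov$overlap, c(5, 6))
  expect_equal(ov$n_fp, 10)
  expect_equal(ov$hits_only, 20)
  expect_warning(overlap_with_dms(1:5, 100:105), "offsets")
})

test_that("planted contacts are recovered exactly on 100 random fixtures", {
  for (s in 1:100) {
    set.seed(s)
    nA <- sample(5:15, 1); nB <- sample(5:15, 1)
    k <- sample(0:5, 1)
    pl <- if (k > 0) {
      p <- cbind(sample(nA, k, replace = TRUE), sample(nB, k, replace = TRUE))
      p[!duplicated(paste(p[, 1], p[, 2])), , drop = FALSE]
    } else NULL
    tc <- generate_toy_complex(nA, nB, pl, cutoff = 4.0, seed = s)
    cm <- interchain_contacts(tc, "A", "B", 4.0)
    want <- if (is.null(pl) || nrow(pl) == 0) character(0)
            else paste("A", pl[, 1], "B", pl[, 2])
    expect_setequal(contact_keys(cm), want)
  }
})

test_that("toy complexes are deterministic under a fixed seed", {
  t1 <- generate_toy_complex(6, 6, cbind(1, 1), seed = 4)
  t2 <- generate_toy_complex(6, 6, cbind(1, 1), seed = 4)
  expect_identical(t1$atoms, t2$atoms)
})

test_that("superposition recovers identity, constructed rotations, and is proper", {
  set.seed(11)
  pts <- matrix(rnorm(30), 10, 3)
  tr0 <- superpose(pts, pts)
  expect_equal(tr0$rmsd, 0, tolerance = 1e-9)
  # acos is ill-conditioned at the identity, so the zero angle is only
  # recovered to ~sqrt(machine eps)
  expect_lt(tr0$rotation_angle, 1e-4)
  R <- rotation_about(c(1, 2, 3), 30)
  tr <- superpose(pts %*% t(R) + rep(c(4, -2, 9), each = 10), pts)
  expect_lt(abs(tr$rotation_angle - 30), 1e-6)
  expect_equal(tr$rmsd, 0, tolerance = 1e-8)
  expect_equal(det(tr$rotation), 1, tolerance = 1e-9)
  # reflected target cannot be reached by a proper rotation
  refl <- pts %*% diag(c(-1, 1, 1))
  trr <- superpose(refl, pts)
  expect_equal(det(trr$rotation), 1, tolerance = 1e-9)
  expect_gt(trr$rmsd, 0.1)
  # degenerate (colinear) sets are rejected
  line <- cbind(1:5, 2 * (1:5), 3 * (1:5))
  expect_error(superpose(line, line), "degenerate")
})

test_that("superposition agrees with an independent least-squares fit", {
  set.seed(21)
  a <- matrix(rnorm(45), 15, 3)
  b <- a %*% t(rotation_about(c(0, 0, 1), 50)) + matrix(rnorm(45, 0, 0.3), 15, 3)
  tr <- superpose(a, b)
  fitted <- apply_transform(a, tr)
  ref_rmsd <- bio3d::rmsd(as.vector(t(b)), as.vector(t(a)), fit = TRUE)
  expect_equal(tr$rmsd, ref_rmsd, tolerance = 1e-3)
})

test_that("superposition rmsd is invariant to rigid pre-transformation", {
  set.seed(31)
  a <- matrix(rnorm(36), 12, 3)
  b <- a + matrix(rnorm(36, 0, 0.5), 12, 3)
  base <- superpose(a, b)$rmsd
  for (s in 1:5) {
    set.seed(s)
    R <- rotation_about(rnorm(3), runif(1, 0, 180))
    moved <- a %*% t(R) + rep(rnorm(3, 0, 20), each = 12)
    expect_equal(superpose(moved, b)$rmsd, base, tolerance = 1e-9)
  }
})

test_that("conformation metrics: duplicates give zero angles, radial shifts give score gaps", {
  ring_chains <- paste0("D", 1:6)
  m1 <- make_ring_model(carrier_radius = 25, seed = 1)
  dup <- conformation_metrics(list(m1, m1), ring_chains, "C")
  expect_equal(max(dup$pairwise_angles), 0, tolerance = 1e-6)
  expect_equal(dup$axis_distance[1], dup$axis_distance[2], tolerance = 1e-12)

  m2 <- make_ring_model(carrier_radius = 30, seed = 1)
  cm <- conformation_metrics(list(m1, m2), ring_chains, "C")
  expect_equal(cm$axis_distance[2] - cm$axis_distance[1], 5, tolerance = 0.05)
  expect_equal(cm$labels, c("inward", "outward"))

  # a carrier rotated about the ring by a known hinge angle is measured back
  m3 <- make_ring_model(carrier_radius = 25, rotate_carrier_deg = 21, seed = 1)
  cm3 <- conformation_metrics(list(m1, m3), ring_chains, "C")
  expect_equal(cm3$pairwise_angles[1, 2], 21, tolerance = 1e-4)

  expect_error(conformation_metrics(list(m1), ring_chains, "Z"),
               "carrier")
})

test_that("residue lists read back as sorted unique integers", {
  f <- tempfile()
  writeLines(c("# hits", "12", "5", "12", "40"), f)
  expect_equal(read_residue_list(f), c(5L, 12L, 40L))
  unlink(f)
})
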