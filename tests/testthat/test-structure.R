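test_that("contact detection on a constructed two-residue toy", {
  atoms <- data.frame(
    serial = 1:3, name = c("CA", "CA", "C1"), element = "C",
    resname = c("ALA", "ALA", "LIG"), resno = c(1L, 2L, 900L),
    chain = c("A", "A", "L"), is_ligand = c(FALSE, FALSE, TRUE),
    stringsAsFactors = FALSE)
  coords <- rbind(c(3, 0, 0), c(0, 4, 0), c(0, 0, 0))
  cs <- make_complex(atoms, coords)
  rep <- contact_residues(cs, cutoff = 3.4)
  expect_equal(nrow(rep), 1L)
  expect_equal(rep$resno, 1L)
  expect_equal(rep$min_distance, 3.0)
  expect_equal(nrow(contact_residues(cs, cutoff = 0.5)), 0L)
})

test_that("contact residues equal the exhaustive all-pairs oracle on random complexes", {
  for (seed in 1:10) {
    set.seed(seed)
    cs <- random_complex(n_res = 20, n_lig = 6)
    cutoff <- runif(1, 2, 6)
    rep <- contact_residues(cs, cutoff = cutoff)
    oracle <- contact_oracle(cs, cutoff)
    expect_equal(paste(rep$chain, rep$resno), oracle$key)
    expect_equal(rep$min_distance, oracle$min_distance)
  }
})

test_that("contact counts are nondecreasing in the cutoff", {
  set.seed(3)
  cs <- random_complex(n_res = 25, n_lig = 5)
  counts <- vapply(seq(1, 10, by = 0.5),
                   function(co) nrow(contact_residues(cs, co)), numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("hydrogen-bond heuristic selects polar protein atoms near ligand oxygens", {
  atoms <- data.frame(
    serial = 1:7,
    name = c("OG", "CB", "CB", "CB", "ND1", "C1", "O1"),
    element = c("O", "C", "C", "C", "N", "C", "O"),
    resname = c("SER", "ALA", "ALA", "ALA", "HIS", "LIG", "LIG"),
    resno = c(1L, 2L, 3L, 4L, 5L, 900L, 900L),
    chain = c(rep("A", 5), "L", "L"),
    is_ligand = c(rep(FALSE, 5), TRUE, TRUE),
    stringsAsFactors = FALSE)
  # ligand O at origin; 2 polar protein atoms within 3.5 A, 3 apolar ones
  coords <- rbind(c(2.8, 0, 0), c(3.0, 0, 0), c(0, 3.1, 0), c(0, 0, 3.2),
                  c(0, -3.3, 0), c(0, 0, 10), c(0, 0, 0))
  cs <- make_complex(atoms, coords)
  hb <- hydrogen_bonds(cs, d_max = 3.5)
  expect_equal(nrow(hb), 2L)
  expect_setequal(hb$protein_atom, c("OG", "ND1"))
  expect_equal(min(hb$distance), 2.8)
  # only carbons in range: empty result
  cs2 <- make_complex(atoms[c(2:4, 6:7), ], coords[c(2:4, 6:7), ])
  cs2$atoms$serial <- seq_len(5)
  expect_equal(nrow(hydrogen_bonds(cs2, 3.5)), 0L)
})

test_that("superposition RMSD is zero under rigid transforms and symmetric", {
  set.seed(5)
  for (i in 1:8) {
    a <- matrix(rnorm(3 * 12), ncol = 3)
    rot <- random_rotation()
    b <- a %*% t(rot) + matrix(rep(rnorm(3), each = 12), ncol = 3)
    expect_equal(superpose_rmsd(a, b), 0, tolerance = 1e-9)
    expect_equal(superpose_rmsd(b, a), 0, tolerance = 1e-9)
  }
  a <- matrix(rnorm(3 * 12), ncol = 3)
  b <- a + matrix(rnorm(3 * 12, 0, 0.5), ncol = 3)
  expect_equal(superpose_rmsd(a, b), superpose_rmsd(b, a), tolerance = 1e-9)
  expect_error(superpose_rmsd(a, b[1:5, ]), "equal")
  expect_error(superpose_rmsd(a[1:2, ], b[1:2, ]), ">= 3")
})

test_that("superposition RMSD matches a rotation-grid oracle on a displaced-atom toy", {
  a <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  b <- a
  b[4, ] <- b[4, ] + c(0, 0, 1)   # one atom displaced by 1 A
  got <- superpose_rmsd(a, b)
  # oracle: center both sets, scan Euler angles coarsely, refine by optim
  ac <- scale(a, scale = FALSE); bc <- scale(b, scale = FALSE)
  rot_euler <- function(p) {
    cz <- cos(p[1]); sz <- sin(p[1]); cy <- cos(p[2]); sy <- sin(p[2])
    cx <- cos(p[3]); sx <- sin(p[3])
    matrix(c(cz, -sz, 0, sz, cz, 0, 0, 0, 1), 3, byrow = TRUE) %*%
      matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3, byrow = TRUE) %*%
      matrix(c(1, 0, 0, 0, cx, -sx, 0, sx, cx), 3, byrow = TRUE)
  }
  obj <- function(p) sqrt(mean(rowSums((ac - bc %*% rot_euler(p))^2)))
  grid <- seq(0, 2 * pi, length.out = 13)
  best <- Inf; best_p <- c(0, 0, 0)
  for (az in grid) for (ay in grid[grid <= pi]) for (ax in grid) {
    v <- obj(c(az, ay, ax))
    if (v < best) { best <- v; best_p <- c(az, ay, ax) }
  }
  ref <- optim(best_p, obj, method = "Nelder-Mead",
               control = list(reltol = 1e-14, maxit = 5000))$value
  expect_equal(got, ref, tolerance = 1e-3)
  expect_lte(got, ref + 1e-9)   # Kabsch is the global optimum
})

test_that("radius of gyration matches closed forms and is rigid-invariant", {
  expect_equal(radius_of_gyration(matrix(c(1, 2, 3), ncol = 3)), 0)
  two <- rbind(c(0, 0, 0), c(4, 0, 0))
  expect_equal(radius_of_gyration(two), 2)   # d/2 for two equal masses
  cube <- as.matrix(expand.grid(c(-1, 1), c(-1, 1), c(-1, 1)))
  expect_equal(radius_of_gyration(cube), sqrt(3))
  # mass weighting: all mass on one atom collapses Rg to zero
  expect_equal(radius_of_gyration(two, masses = c(1e12, 1e-12)), 0,
               tolerance = 1e-6)
  set.seed(9)
  x <- matrix(rnorm(30), ncol = 3)
  rot <- random_rotation()
  expect_equal(radius_of_gyration(x %*% t(rot) + 5), radius_of_gyration(x),
               tolerance = 1e-9)
})

test_that("PDB round trip preserves the generated complex", {
  f <- tempfile(fileext = ".pdb")
  gen <- gen_toy_complex(12, contact_resno = c(5, 9), contact_distance = 3.0,
                         polar_resno = 9, file = f, seed = 2)
  cs <- read_complex(f)
  expect_equal(cs$n_models, 1L)
  rep <- contact_residues(cs, cutoff = 3.4)
  expect_setequal(rep$resno, gen$truth$contact_resno)
  # coordinates survive the fixed-width format to 3 decimals
  expect_equal(rep$min_distance, rep(3.0, 2), tolerance = 2e-3)
  hb <- hydrogen_bonds(cs, d_max = 3.5)
  expect_equal(unique(hb$protein_resno), 9L)
  expect_error(read_complex(f, ligand_resname = "XYZ"), "no ligand")
})

test_that("multi-model drift loses contacts monotonically", {
  f <- tempfile(fileext = ".pdb")
  gen_toy_complex(10, contact_resno = c(2, 4, 6), contact_distance = 3.0,
                  n_models = 3, drift = 4, file = f, seed = 2)
  cs <- read_complex(f)
  expect_equal(cs$n_models, 3L)
  counts <- vapply(1:3, function(m)
    nrow(contact_residues(cs, 3.4, model = m)), numeric(1))
  expect_true(all(diff(counts) <= 0))
  expect_gt(counts[1], counts[3])
  freq <- contact_frequency(cs, 3.4)
  expect_true(all(freq$frequency <= 1 & freq$frequency > 0))
})
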