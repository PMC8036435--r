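cube_mol <- function(id = "cube", lo = 0, hi = 10) {
  # two atoms spanning the diagonal of a cube
  pmol(id, rbind(patom("C", lo, lo, lo), patom("C", hi, hi, hi)))
}

test_that("grid dimensions follow extent + margins over spacing", {
  g <- buildGrid(list(cube_mol()), spacing = 1, margin = 3)
  expect_equal(gridDims(g), rep(17L, 3))
  expect_equal(gridOrigin(g), rep(-3, 3))
  g2 <- buildGrid(list(cube_mol()), spacing = 2, margin = 3)
  expect_equal(gridDims(g2), rep(9L, 3))
  # union bounding box of two molecules
  g3 <- buildGrid(list(cube_mol("a", 0, 4), cube_mol("b", 2, 8)),
                  spacing = 1, margin = 3)
  expect_equal(gridDims(g3), rep(15L, 3))
  expect_error(buildGrid(list()), "empty")
})

test_that("exclusion masks exactly the sub-min_dist points", {
  m <- pmol("one", patom("C", 0, 0, 0))
  g <- buildGrid(list(m), spacing = 1, margin = 3)
  fg <- exclusionMask(g, list(m), min_dist = 2)
  pts <- gridPoints(g)
  d <- sqrt(rowSums(pts^2))
  expect_equal(activeMask(fg), d >= 2)
  expect_false(activeMask(fg)[which(d == 0)])
  # degenerate bounds
  expect_true(all(activeMask(exclusionMask(g, list(m), 0))))
  fg_all <- exclusionMask(g, list(m), min_dist = 1000)
  expect_equal(sum(activeMask(fg_all)), 0)
  expect_error(assembleBlocks(list(m, m), fg_all, "G_steric"),
               "no active grid points")
})

test_that("raising min_dist never re-activates a masked point", {
  m <- list(pmol("a", rbind(patom("C", 0, 0, 0), patom("O", 2, 1, 0))))
  g <- buildGrid(m)
  prev <- rep(TRUE, prod(gridDims(g)))
  for (d in c(0, 1, 2, 3, 5)) {
    cur <- activeMask(exclusionMask(g, m, d))
    expect_true(all(cur <= prev))  # active set shrinks monotonically
    prev <- cur
  }
})

test_that("LJ steric field hits -epsilon_pair at the pair minimum", {
  m <- pmol("c", patom("C", 0, 0, 0))
  probe <- defaultProbe()
  rmin <- 1.70 + probe$radius
  pts <- matrix(c(rmin, 0, 0), 1)
  f <- ffFields(m, pts, probe)
  expect_equal(f$steric, -sqrt(0.10 * probe$epsilon), tolerance = 1e-12)
  expect_equal(f$electrostatic, 0)  # q = 0
})

test_that("steric clamps at +30 close in and flags saturation", {
  m <- pmol("c", patom("C", 0, 0, 0))
  f <- ffFields(m, matrix(c(0.1, 0, 0), 1))
  expect_equal(f$steric, 30.0)
  expect_true(f$saturated)
  f0 <- ffFields(m, matrix(c(0, 0, 0), 1))  # atom exactly on the point
  expect_equal(f0$steric, 30.0)
})

test_that("Coulomb term follows 332.06 q / r^2 (eps(r) = r)", {
  m <- pmol("q", patom("N", 0, 0, 0, charge = 1))
  f <- ffFields(m, matrix(c(10, 0, 0), 1))
  expect_equal(f$electrostatic, 332.06 / 100, tolerance = 1e-12)
})

test_that("Gaussian fields evaluate the stated kernel", {
  acc <- pmol("a", patom("O", 0, 0, 0, hba = TRUE))
  expect_equal(gaussianField(acc, matrix(0, 1, 3), "G_hba"), 1.0)
  carb <- pmol("c", patom("C", 0, 0, 0))
  expect_equal(gaussianField(carb, matrix(c(1, 0, 0), 1), "G_steric"),
               1.7^3 * exp(-0.3), tolerance = 1e-12)
  expect_equal(1.7^3 * exp(-0.3), 3.6396, tolerance = 1e-4)
  # all-zero charges give an identically zero electrostatic field
  m0 <- pmol("z", rbind(patom("C", 0, 0, 0), patom("C", 1, 1, 1)))
  pts <- matrix(runif(30, -2, 2), 10)
  expect_equal(gaussianField(m0, pts, "G_electrostatic"), rep(0, 10))
  expect_error(gaussianField(m0, pts, "G_bogus"), "unknown")
})

test_that("Gaussian fields are additive over atoms", {
  a1 <- patom("C", 0, 0, 0, charge = 0.2)
  a2 <- patom("O", 1.5, 0.5, -0.5, charge = -0.4, hba = TRUE)
  both <- pmol("ab", rbind(a1, a2))
  pts <- matrix(runif(45, -3, 3), 15)
  for (ft in c("G_steric", "G_electrostatic", "G_hydrophobic", "G_hba")) {
    expect_equal(gaussianField(both, pts, ft),
                 gaussianField(pmol("a", a1), pts, ft) +
                 gaussianField(pmol("b", a2), pts, ft),
                 tolerance = 1e-12)
  }
})

test_that("translating molecules and grid together is exact", {
  # dyadic coordinates and shift: the translation itself is exact in
  # floating point, so equivariance must be bit-for-bit
  m <- pmol("m", rbind(patom("C", 0, 0, 0, 0.1),
                       patom("O", 1.25, 0.375, -0.5, -0.3, hba = TRUE)))
  shift <- c(5.5, -2.25, 11)
  mt <- m
  mt@atoms$x <- mt@atoms$x + shift[1]
  mt@atoms$y <- mt@atoms$y + shift[2]
  mt@atoms$z <- mt@atoms$z + shift[3]
  set.seed(99)
  pts <- matrix(sample(seq(-3, 3, by = 0.25), 30, replace = TRUE), 10)
  ptst <- sweep(pts, 2, shift, `+`)
  f1 <- ffFields(m, pts); f2 <- ffFields(mt, ptst)
  expect_identical(f1$steric, f2$steric)
  expect_identical(f1$electrostatic, f2$electrostatic)
  expect_identical(gaussianField(m, pts, "G_steric"),
                   gaussianField(mt, ptst, "G_steric"))
})

test_that("vectorized fields match the naive triple-loop reference", {
  gen <- generateSeries(syntheticSpec(n_molecules = 8, seed = 7))
  mol <- gen$molecules[[1]]
  g <- new("GridSpec", origin = c(-2, -2, -2), spacing = 1,
           dims = c(10L, 10L, 10L), margin = 0)
  pts <- gridPoints(g)
  ref <- naive_ff(mol, pts)
  f <- ffFields(mol, pts)
  expect_equal(f$steric, ref$steric, tolerance = 1e-9)
  expect_equal(f$electrostatic, ref$electrostatic, tolerance = 1e-9)
  for (ft in c("G_steric", "G_electrostatic", "G_hydrophobic",
               "G_hba", "G_hbd"))
    expect_equal(gaussianField(mol, pts, ft), naive_gaussian(mol, pts, ft),
                 tolerance = 1e-9)
})

test_that("block assembly filters variables by across-molecule SD", {
  gen <- generateSeries(syntheticSpec(n_molecules = 10, seed = 3))
  mols <- gen$molecules
  g <- buildGrid(mols)
  fg <- exclusionMask(g, mols)
  blocks <- assembleBlocks(mols, fg, c("G_steric", "FF_steric"))
  # brute-force SD oracle over all active points
  pts <- gridPoints(g)[activeMask(fg), , drop = FALSE]
  raw <- t(sapply(mols, function(m) gaussianField(m, pts, "G_steric")))
  sds <- apply(raw, 2, function(col) sqrt(mean(col^2) - mean(col)^2))
  expect_equal(pointIndex(blocks$G_steric),
               which(activeMask(fg))[sds >= 0.05])
  expect_equal(unname(fieldValues(blocks$G_steric)),
               unname(raw[, sds >= 0.05]))
  # retained points cluster near what varies: the substituent sites
  co <- pointCoords(blocks$G_steric)
  sites <- rbind(c(-3.8, 0, 0), c(7.2, -1.4, 1.8))
  dmin <- pmin(sqrt(colSums((t(co) - sites[1, ])^2)),
               sqrt(colSums((t(co) - sites[2, ])^2)))
  expect_lt(max(dmin), 5)
  # clamp respected on the force-field block
  expect_gte(min(fieldValues(blocks$FF_steric)), -30)
  expect_lte(max(fieldValues(blocks$FF_steric)), 30)
})

test_that("degenerate assemblies fail loudly, sd_min = 0 keeps all", {
  m <- pmol("a", rbind(patom("C", 0, 0, 0), patom("O", 1.5, 0, 0)))
  m2 <- m; m2@id <- "b"
  g <- buildGrid(list(m, m2))
  fg <- exclusionMask(g, list(m, m2))
  expect_error(assembleBlocks(list(m, m2), fg, "G_steric"),
               "below the SD filter")
  b0 <- assembleBlocks(list(m, m2), fg, "G_steric", sd_min = 0)
  expect_equal(ncol(fieldValues(b0$G_steric)), sum(activeMask(fg)))
  expect_error(assembleBlocks(list(m), fg, "G_steric"), ">= 2 molecules")
})

test_that("saturated electrostatic values take the column mean fill", {
  # molecule b has an atom close to one retained grid point -> saturation
  near <- patom("C", 2.2, 0, 0, charge = 0.3)
  base <- rbind(patom("C", 0, 0, 0, charge = 0.5),
                patom("O", 1.4, 0, 0, charge = -0.5, hba = TRUE))
  mols <- list(pmol("a", base),
               pmol("b", rbind(base, near)),
               pmol("c", rbind(base, patom("N", -1.4, 0, 0, -0.2))))
  g <- buildGrid(mols, spacing = 1, margin = 3)
  fg <- exclusionMask(g, mols, min_dist = 2)
  blocks <- assembleBlocks(mols, fg, c("FF_steric", "FF_electrostatic"),
                           sd_min = 0)
  pts <- gridPoints(g)[activeMask(fg), , drop = FALSE]
  sat <- t(sapply(mols, function(m) ffFields(m, pts)$saturated))
  expect_true(any(sat))  # the fixture does exercise the fill path
  es <- fieldValues(blocks$FF_electrostatic)
  raw <- t(sapply(mols, function(m) ffFields(m, pts)$electrostatic))
  j <- which(colSums(sat) > 0)[1]
  i <- which(sat[, j])
  expect_equal(unname(es[i, j]),
               rep(mean(raw[!sat[, j], j]), length(i)))
  # and with es_at_clash = "clamp" the raw (clamped) values remain
  b2 <- assembleBlocks(mols, fg, c("FF_steric", "FF_electrostatic"),
                       sd_min = 0, es_at_clash = "clamp")
  expect_equal(unname(fieldValues(b2$FF_electrostatic)), unname(raw))
})
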