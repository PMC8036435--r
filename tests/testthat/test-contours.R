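# a controllable model: hand-set coefficients/SDs on a small lattice
toy_model <- function(scores_seed = 1, p = 40) {
  set.seed(scores_seed)
  co <- as.matrix(expand.grid(x = 1:4, y = 1:5, z = 1:2))
  co <- co[seq_len(p), , drop = FALSE]
  new("QsarModel", field_types = "G_steric", n_factors = 2L,
      x_mean = rep(0, p), x_scale = rep(1, p),
      coefficients = rnorm(p), intercept = 7,
      col_field = factor(rep("G_steric", p), levels = "G_steric"),
      col_sd = runif(p, 0.5, 2),
      point_index = list(seq_len(p)), coords = list(co),
      es_fill = numeric(0), field_params = list(),
      stats = list(), training_ids = character(0),
      training_centroid = colMeans(co))
}

test_that("contour sets honor their percentile thresholds", {
  m <- toy_model()
  cs <- extractContours(m, "G_steric", 90, 10)
  s <- m@coefficients * m@col_sd
  expect_equal(nrow(cs@favored), sum(s >= quantile(s, 0.9)))
  expect_equal(nrow(cs@disfavored), sum(s <= quantile(s, 0.1)))
  expect_true(all(cs@favored$score >= cs@pos_threshold))
  expect_true(all(cs@disfavored$score <= cs@neg_threshold))
  expect_length(intersect(cs@favored$point_index,
                          cs@disfavored$point_index), 0)
  expect_error(extractContours(m, "G_hba"), "not part")
})

test_that("raising the positive percentile never grows the favored set", {
  m <- toy_model(2)
  prev <- Inf
  for (pct in c(50, 70, 80, 90, 95)) {
    cs <- extractContours(m, "G_steric", pct, 10)
    expect_lte(nrow(cs@favored), prev)
    prev <- nrow(cs@favored)
  }
})

test_that("a median split partitions all points", {
  m <- toy_model(3)
  cs <- extractContours(m, "G_steric", 50, 50)
  expect_equal(nrow(cs@favored) + nrow(cs@disfavored),
               length(m@coefficients))
  expect_length(intersect(cs@favored$point_index,
                          cs@disfavored$point_index), 0)
})

test_that("constant scores yield empty sets with a warning", {
  m <- toy_model()
  m@coefficients <- rep(2, length(m@coefficients))
  m@col_sd <- rep(1, length(m@col_sd))
  expect_warning(cs <- extractContours(m, "G_steric"), "identical")
  expect_equal(nrow(cs@favored), 0)
  expect_equal(nrow(cs@disfavored), 0)
})

test_that("contour membership is invariant to rescaling the activities", {
  gen <- generateSeries(syntheticSpec(n_molecules = 14, seed = 51))
  mols <- gen$molecules
  y <- vapply(mols, activity, numeric(1))
  fg <- exclusionMask(buildGrid(mols), mols)
  blocks <- assembleBlocks(mols, fg, c("G_steric", "G_hba"))
  m1 <- fitPls(blocks, y, 3)
  m2 <- fitPls(blocks, 10 * y, 3)
  c1 <- extractContours(m1, "G_steric")
  c2 <- extractContours(m2, "G_steric")
  expect_equal(sort(c1@favored$point_index), sort(c2@favored$point_index))
  expect_equal(sort(c1@disfavored$point_index),
               sort(c2@disfavored$point_index))
  expect_equal(c2@pos_threshold, 10 * c1@pos_threshold, tolerance = 1e-9)
})

test_that("a planted steric effect surfaces near its site", {
  rc <- recoveryCheck()
  cs <- extractContours(rc$model, "G_steric", 90, 10)
  centroid <- c(mean(cs@favored$x), mean(cs@favored$y),
                mean(cs@favored$z))
  site <- c(-3.8, 0, 0)
  expect_lt(sqrt(sum((centroid - site)^2)), 2)
})

test_that("connected components label spatially separate regions", {
  m <- toy_model()
  # two well-separated favored clusters on a fresh coordinate set
  co <- rbind(as.matrix(expand.grid(0:1, 0:1, 0)),
              as.matrix(expand.grid(10:11, 0:1, 0)))
  p <- nrow(co)
  m@coords <- list(co)
  m@point_index <- list(seq_len(p))
  # two points per cluster score above the median
  m@coefficients <- c(1, 1, 5, 5, 1, 1, 5, 5) / 2
  m@col_sd <- rep(2, p)
  m@col_field <- factor(rep("G_steric", p), levels = "G_steric")
  m@x_mean <- rep(0, p); m@x_scale <- rep(1, p)
  cs <- extractContours(m, "G_steric", 50, 10)
  expect_equal(length(unique(cs@favored$component)), 2)
  smry <- contourSummary(cs)
  expect_true(all(c("set", "component", "n_points", "volume") %in%
                  names(smry)))
})

test_that("OpenDX files round-trip values and the grid header", {
  spec <- new("GridSpec", origin = c(-1.5, 0, 2), spacing = 0.5,
              dims = c(4L, 3L, 5L), margin = 0)
  vals <- round(rnorm(prod(spec@dims)), 4)
  f <- tempfile(fileext = ".dx")
  writeDx(vals, spec, f, point_index = seq_along(vals))
  got <- readDx(f)
  expect_equal(got$spec@dims, spec@dims)
  expect_equal(got$spec@origin, spec@origin, tolerance = 1e-6)
  expect_equal(got$spec@spacing, spec@spacing, tolerance = 1e-6)
  expect_equal(got$values, vals, tolerance = 1e-5)
})

test_that("an empty contour set writes an all-zero volume", {
  m <- toy_model()
  m@coefficients <- rep(2, length(m@coefficients))
  m@col_sd <- rep(1, length(m@col_sd))
  suppressWarnings(cs <- extractContours(m, "G_steric"))
  spec <- new("GridSpec", origin = c(0, 0, 0), spacing = 1,
              dims = c(5L, 6L, 3L), margin = 0)
  f <- tempfile(fileext = ".dx")
  writeDx(cs, spec, f)
  expect_true(all(readDx(f)$values == 0))
})

test_that("masked field vectors are embedded at their lattice indices", {
  m <- pmol("m", patom("C", 0, 0, 0))
  g <- buildGrid(list(m), spacing = 1, margin = 2)
  fg <- exclusionMask(g, list(m), 2)
  v <- gaussianField(m, fg, "G_steric")
  f <- tempfile(fileext = ".dx")
  writeDx(v, fg, f)
  got <- readDx(f)
  full <- numeric(prod(gridDims(g)))
  full[which(activeMask(fg))] <- v
  expect_equal(got$values, full, tolerance = 1e-5)
})
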