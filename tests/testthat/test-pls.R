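test_that("one factor recovers a signal confined to one column", {
  n <- 14; p <- 6
  # orthogonal centered columns: a single-column signal is exactly
  # recoverable by one PLS factor
  X <- unclass(stats::poly(seq_len(n), degree = p))
  y <- 3 + 2.5 * X[, 4]
  b <- mat_block("G_steric", X)
  m <- fitPls(list(G_steric = b), y, n_factors = 1)
  expect_equal(modelStats(m)$r2_training, 1.0, tolerance = 1e-10)
  cf <- coef(m)
  expect_gt(abs(cf[4]), 1e-3)
  expect_lt(max(abs(cf[-4])), 1e-8 * abs(cf[4]))
})

test_that("full-factor PLS on full-rank X equals ordinary least squares", {
  set.seed(11)
  n <- 15; p <- 6
  X <- matrix(rnorm(n * p), n)
  y <- drop(X %*% runif(p, -1, 1)) + rnorm(n, 0, 0.3)
  m <- fitPls(list(G_steric = mat_block("G_steric", X)), y, n_factors = p)
  ols <- lm(y ~ X)
  expect_equal(drop(X %*% coef(m)) + m@intercept,
               unname(fitted(ols)), tolerance = 1e-8)
  Xnew <- matrix(rnorm(3 * p), 3)
  expect_equal(drop(Xnew %*% coef(m)) + m@intercept,
               unname(drop(cbind(1, Xnew) %*% coef(ols))),
               tolerance = 1e-8)
})

test_that("jointly permuting rows of X and y leaves the fit unchanged", {
  set.seed(2)
  X <- matrix(rnorm(10 * 8), 10)
  y <- rnorm(10)
  perm <- sample(10)
  m1 <- fitPls(list(G_hba = mat_block("G_hba", X)), y, 3)
  m2 <- fitPls(list(G_hba = mat_block("G_hba", X[perm, ])), y[perm], 3)
  expect_equal(coef(m1), coef(m2), tolerance = 1e-12)
  expect_equal(m1@intercept, m2@intercept, tolerance = 1e-12)
})

test_that("training R2 is non-decreasing in the number of factors", {
  set.seed(3)
  X <- matrix(rnorm(12 * 20), 12)
  y <- rnorm(12)
  r2 <- vapply(1:6, function(a)
    modelStats(fitPls(list(G_steric = mat_block("G_steric", X)),
                      y, a))$r2_training, numeric(1))
  expect_true(all(diff(r2) >= -1e-12))
})

test_that("degenerate fits are rejected with clear errors", {
  X <- matrix(rnorm(10 * 4), 10)
  b <- list(G_steric = mat_block("G_steric", X))
  expect_error(fitPls(b, rep(1, 10), 2), "zero variance")
  expect_error(fitPls(b, rnorm(10), 0), ">= 1")
  b3 <- list(G_steric = mat_block("G_steric", X[1:3, ]))
  expect_error(fitPls(b3, rnorm(3), 5), "at least")
})

test_that("leave-one-out Q2 equals an independently coded naive loop", {
  ts <- tiny_series(n = 12)
  g <- buildGrid(ts$mols)
  fg <- exclusionMask(g, ts$mols)
  blocks <- assembleBlocks(ts$mols, fg,
                           c("G_steric", "G_electrostatic"), sd_min = 0.02)
  q2 <- looQ2(blocks, ts$y, n_factors = 3)
  X <- do.call(cbind, lapply(blocks, fieldValues))
  cf <- factor(rep(names(blocks), sapply(blocks, function(b)
    ncol(fieldValues(b)))), levels = names(blocks))
  press <- 0
  for (i in seq_len(12)) {
    pred <- naive_pls_predict(X[-i, , drop = FALSE], cf,
                              ts$y[-i], 3, X[i, , drop = FALSE])
    press <- press + (ts$y[i] - unname(pred))^2
  }
  expect_equal(q2, 1 - press / sum((ts$y - mean(ts$y))^2),
               tolerance = 1e-10)
})

test_that("Q2 reflects model quality: perfect signal vs shuffled signal", {
  set.seed(5)
  n <- 20
  X <- matrix(rnorm(n * 10), n)
  y <- 5 + drop(X %*% c(2, rep(0, 9)))       # noise-free linear
  b <- list(G_steric = mat_block("G_steric", X))
  expect_equal(looQ2(b, y, 10), 1.0, tolerance = 1e-8)
  y_shuf <- sample(y)
  m <- fitPls(b, y_shuf, 3)
  expect_lt(looQ2(b, y_shuf, 3), modelStats(m)$r2_training)
})

test_that("y-scrambling: identity permutation reproduces training R2", {
  set.seed(6)
  X <- matrix(rnorm(15 * 12), 15)
  y <- rnorm(15)
  b <- list(G_hbd = mat_block("G_hbd", X))
  m <- fitPls(b, y, 3)
  expect_equal(scrambleR2(b, y, 3, perms = list(1:15)),
               modelStats(m)$r2_training, tolerance = 1e-12)
})

test_that("y-scrambling separates signal from capacity", {
  # pure-noise X: the scrambled mean matches the unscrambled fit within
  # 0.1 (both are chance correlation) at n=40, 200 columns, 5 factors
  set.seed(7)
  X <- matrix(rnorm(40 * 200), 40)
  y <- rnorm(40)
  b <- list(G_steric = mat_block("G_steric", X))
  r2 <- modelStats(fitPls(b, y, 5))$r2_training
  expect_lt(abs(scrambleR2(b, y, 5, n_perm = 20, seed = 1) - r2), 0.1)
  # strong planted signal: scrambling destroys >= 0.2 of R2
  gen <- generateSeries(syntheticSpec())
  mols <- gen$molecules
  yy <- vapply(mols, activity, numeric(1))
  fg <- exclusionMask(buildGrid(mols), mols)
  blocks <- assembleBlocks(mols, fg, c("G_steric", "G_hba", "G_hbd"))
  r2s <- modelStats(fitPls(blocks, yy, 5))$r2_training
  expect_gte(r2s - scrambleR2(blocks, yy, 5, n_perm = 20, seed = 2), 0.2)
})

test_that("stability is 1 for full subsamples and high for clean signal", {
  set.seed(8)
  X <- matrix(rnorm(20 * 15), 20)
  y <- 2 + drop(X %*% c(1.5, -1, rep(0, 13)))
  b <- list(G_steric = mat_block("G_steric", X))
  expect_equal(stability(b, y, 3, frac = 1.0, n_rep = 5), 1.0,
               tolerance = 1e-9)
  expect_gte(stability(b, y, 3, frac = 0.9, n_rep = 10, seed = 1), 0.99)
  # fitting pure noise: predictions depend materially on which
  # molecules were seen
  set.seed(8)
  Xn <- matrix(rnorm(20 * 8), 20)
  bn <- list(G_steric = mat_block("G_steric", Xn))
  y_noise <- rnorm(20)
  expect_lt(stability(bn, y_noise, 5, frac = 0.9, n_rep = 20, seed = 1),
            0.9)
})

test_that("contribution fractions are normalized and symmetric", {
  set.seed(9)
  X <- matrix(rnorm(12 * 6), 12)
  y <- rnorm(12)
  m1 <- fitPls(list(G_steric = mat_block("G_steric", X)), y, 2)
  expect_equal(unname(fieldContributions(m1)), 1.0)
  # two byte-identical blocks under different labels split 50/50
  m2 <- fitPls(list(G_steric = mat_block("G_steric", X),
                    G_hba = mat_block("G_hba", X)), y, 2)
  expect_equal(unname(fieldContributions(m2)), c(0.5, 0.5),
               tolerance = 1e-6)
  # sums to 1 regardless of composition
  gen <- generateSeries(syntheticSpec(n_molecules = 12, seed = 21))
  mols <- gen$molecules
  yy <- vapply(mols, activity, numeric(1))
  fg <- exclusionMask(buildGrid(mols), mols)
  blocks <- assembleBlocks(mols, fg, c("G_steric", "G_hba", "G_hbd"))
  m3 <- fitPls(blocks, yy, 4)
  expect_equal(sum(fieldContributions(m3)), 1.0, tolerance = 1e-9)
  expect_true(all(fieldContributions(m3) >= 0))
  # relabelling fields permutes the fractions with them
  m4 <- fitPls(blocks[c(3, 1, 2)], yy, 4)
  expect_equal(unname(fieldContributions(m4)),
               unname(fieldContributions(m3)[c(3, 1, 2)]),
               tolerance = 1e-9)
})

test_that("signal planted in one field dominates its contribution", {
  spec <- syntheticSpec(effects = list(
    list(center = c(-3.8, 0, 0), radius = 3.5, field_type = "G_steric",
         weight = 5)))
  gen <- generateSeries(spec)
  mols <- gen$molecules
  y <- vapply(mols, activity, numeric(1))
  fg <- exclusionMask(buildGrid(mols), mols)
  blocks <- assembleBlocks(mols, fg, c("G_steric", "G_hydrophobic",
                                       "G_hba"))
  m <- fitPls(blocks, y, 5)
  expect_gt(fieldContributions(m)["G_steric"], 0.8)
})

test_that("the combination scan enumerates every non-empty subset once", {
  set.seed(10)
  n <- 16
  Xs <- replicate(5, matrix(rnorm(n * 6), n), simplify = FALSE)
  fts <- c("G_steric", "G_electrostatic", "G_hydrophobic", "G_hba",
           "G_hbd")
  blocks <- Map(mat_block, fts, Xs)
  y <- 6 + Xs[[1]][, 1] + rnorm(n, 0, 0.2)
  tab <- scanCombinations(blocks, y, 3, n_perm = 3, n_rep = 3, seed = 1)
  expect_equal(nrow(tab), 31)               # 2^5 - 1
  expect_equal(anyDuplicated(tab$fields), 0)
  expect_true(all(tab$ok))
  tab2 <- scanCombinations(blocks[1:2], y, 3, n_perm = 3, n_rep = 3)
  expect_equal(nrow(tab2), 3)               # S, E, S+E
  expect_equal(nrow(scanCombinations(blocks[1], y, 3, n_perm = 3,
                                     n_rep = 3)), 1)
})

test_that("scan ranks by external R2, then training R2, then size", {
  set.seed(12)
  n <- 20
  Xs <- list(matrix(rnorm(n * 5), n), matrix(rnorm(n * 5), n))
  blocks <- Map(mat_block, c("G_steric", "G_hba"), Xs)
  y <- 5 + 2 * Xs[[1]][, 2] + rnorm(n, 0, 0.1)
  Xt <- list(matrix(rnorm(8 * 5), 8), matrix(rnorm(8 * 5), 8))
  tblocks <- Map(mat_block, c("G_steric", "G_hba"), Xt)
  yt <- 5 + 2 * Xt[[1]][, 2] + rnorm(8, 0, 0.1)
  tab <- scanCombinations(blocks, y, 3, test_blocks = tblocks,
                          y_test = yt, n_perm = 3, n_rep = 3)
  expect_equal(nrow(tab), 3)
  expect_true(all(diff(tab$r2_test) <= 1e-12))
  expect_true(grepl("G_steric", tab$fields[1]))
})

test_that("prediction reproduces fitted values and flags far molecules", {
  gen <- generateSeries(syntheticSpec(n_molecules = 15, seed = 31))
  mols <- gen$molecules
  y <- vapply(mols, activity, numeric(1))
  fg <- exclusionMask(buildGrid(mols), mols)
  blocks <- assembleBlocks(mols, fg, c("G_steric", "G_hba"))
  m <- fitPls(blocks, y, 4)
  X <- do.call(cbind, lapply(blocks, fieldValues))
  fitted_vals <- unname(drop(X %*% coef(m)) + m@intercept)
  expect_equal(unname(predict(m, mols)), fitted_vals, tolerance = 1e-10)
  far <- mols[[1]]
  far@atoms$x <- far@atoms$x + 1000
  expect_warning(predict(m, list(far)), "translation|centroid|grid")
})

test_that("a model survives a JSON round trip", {
  gen <- generateSeries(syntheticSpec(n_molecules = 12, seed = 41))
  mols <- gen$molecules
  y <- vapply(mols, activity, numeric(1))
  fg <- exclusionMask(buildGrid(mols), mols)
  blocks <- assembleBlocks(mols, fg, c("G_steric", "G_hba"))
  m <- fitPls(blocks, y, 3)
  f <- tempfile(fileext = ".json")
  writeQsarModel(m, f)
  m2 <- readQsarModel(f)
  expect_equal(coef(m2), coef(m), tolerance = 1e-12)
  expect_equal(predict(m2, mols), predict(m, mols), tolerance = 1e-10)
})
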