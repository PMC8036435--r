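#' @include AllClasses.R AllGenerics.R fields.R
NULL

## run expr with a private RNG seed, restoring the caller's RNG state
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  expr
}

.concat_blocks <- function(blocks) {
  X <- do.call(cbind, lapply(blocks, fieldValues))
  col_field <- factor(rep(vapply(blocks, fieldType, character(1)),
                          vapply(blocks, function(b) ncol(b@values),
                                 integer(1))),
                      levels = vapply(blocks, fieldType, character(1)))
  list(X = X, col_field = col_field)
}

## per-column centering + per-block variance equalization: each block is
## scaled so its total column variance is 1, making blocks with very
## different natural units (kcal/mol vs similarity sums) commensurable
.block_scaling <- function(X, col_field) {
  mu <- colMeans(X)
  v <- .pop_sd(X)^2
  tot <- tapply(v, col_field, sum)
  if (any(tot <= 0)) stop("a block has zero total variance")
  s <- 1 / sqrt(as.numeric(tot[as.character(col_field)]))
  list(mean = mu, scale = s)
}

## NIPALS PLS1: X (n x p) centered+scaled, y centered; returns regression
## vector in the scaled space
.nipals <- function(Xs, yc, n_factors) {
  n <- nrow(Xs); p <- ncol(Xs)
  W <- matrix(0, p, 0); P <- matrix(0, p, 0); qv <- numeric(0)
  X <- Xs; y <- yc
  for (a in seq_len(n_factors)) {
    w <- crossprod(X, y)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) break
    w <- w / nw
    t_ <- X %*% w
    tt <- sum(t_^2)
    if (tt < 1e-12) break
    p_ <- crossprod(X, t_) / tt
    q_ <- sum(y * t_) / tt
    X <- X - tcrossprod(t_, p_)
    y <- y - t_ * q_
    W <- cbind(W, w); P <- cbind(P, p_); qv <- c(qv, q_)
  }
  if (!ncol(W)) return(rep(0, p))
  drop(W %*% solve(crossprod(P, W), qv))
}

## full fit on a raw descriptor matrix; shared by fitPls, LOO, scrambling,
## stability and the combination scan
.fit_matrix <- function(X, col_field, y, n_factors) {
  n <- nrow(X)
  if (n_factors < 1L) stop("'n_factors' must be >= 1")
  if (n < n_factors + 1L)
    stop("need at least n_factors + 1 molecules (", n_factors + 1L,
         "), got ", n)
  if (stats::var(y) == 0) stop("activity vector has zero variance")
  sc <- .block_scaling(X, col_field)
  Xs <- sweep(X, 2, sc$mean) * rep(1, n) %o% sc$scale
  yc <- y - mean(y)
  b <- .nipals(Xs, yc, n_factors)
  coefs <- sc$scale * b
  intercept <- mean(y) - sum(coefs * sc$mean)
  fitted <- drop(X %*% coefs) + intercept
  rss <- sum((y - fitted)^2)
  tss <- sum((y - mean(y))^2)
  r2 <- 1 - rss / tss
  dfres <- n - n_factors - 1L
  sdres <- if (dfres > 0) sqrt(rss / dfres) else NA_real_
  f <- if (dfres > 0 && r2 < 1)
    (r2 / n_factors) / ((1 - r2) / dfres) else Inf
  list(coefficients = coefs, intercept = intercept, fitted = fitted,
       x_mean = sc$mean, x_scale = sc$scale,
       r2_training = r2, sd = sdres, f_ratio = f)
}

#' Fit a grid-field PLS model
#'
#' Concatenates the field blocks into one descriptor matrix (rows =
#' molecules in the order of \code{y}), centers every column, equalizes
#' the total variance across blocks, extracts up to \code{n_factors}
#' NIPALS PLS factors (capped at 5 by convention) and back-transforms the
#' regression vector to original field units.  The fit is deterministic
#' for a fixed input order and invariant to joint row permutations.
#'
#' @param blocks named list of \linkS4class{FieldBlock} sharing molecule
#'   order.
#' @param y numeric pEC50 vector aligned with the block rows.
#' @param n_factors number of latent factors, 1--5 typical; must satisfy
#'   \code{n >= n_factors + 1}.
#' @return a \linkS4class{QsarModel}; training statistics (R2, standard
#'   error of estimate, F ratio, per-field contribution fractions) are in
#'   \code{modelStats(model)}.
#' @examples
#' ## see the package vignette for an end-to-end example on a synthetic
#' ## aligned series
#' @export
fitPls <- function(blocks, y, n_factors = 5L) {
  n_factors <- as.integer(n_factors)
  ns <- vapply(blocks, function(b) nrow(b@values), integer(1))
  if (length(unique(ns)) != 1L || ns[1] != length(y))
    stop("all blocks must have one row per element of y")
  cb <- .concat_blocks(blocks)
  fit <- .fit_matrix(cb$X, cb$col_field, y, n_factors)
  col_sd <- .pop_sd(cb$X)
  ids <- rownames(blocks[[1]]@values)
  if (is.null(ids)) ids <- paste0("mol", seq_along(y))
  contrib <- .contributions(fit$coefficients, col_sd, cb$col_field)
  es_fill <- numeric(0)
  fp <- blocks[[1]]@params
  if ("FF_electrostatic" %in% names(blocks))
    es_fill <- blocks[["FF_electrostatic"]]@params$fill_means %||% numeric(0)
  all_coords <- do.call(rbind, lapply(blocks, pointCoords))
  centroid <- colMeans(all_coords)
  new("QsarModel",
      field_types = vapply(blocks, fieldType, character(1)),
      n_factors = n_factors,
      x_mean = fit$x_mean, x_scale = fit$x_scale,
      coefficients = fit$coefficients, intercept = fit$intercept,
      col_field = cb$col_field, col_sd = col_sd,
      point_index = lapply(blocks, pointIndex),
      coords = lapply(blocks, pointCoords),
      es_fill = es_fill,
      field_params = fp[c("probe", "clamp", "alpha", "es_at_clash")],
      stats = list(r2_training = fit$r2_training, sd = fit$sd,
                   f_ratio = fit$f_ratio, n = length(y),
                   n_factors = n_factors, contributions = contrib),
      training_ids = ids,
      training_centroid = unname(centroid))
}

.contributions <- function(coefs, col_sd, col_field) {
  w <- tapply(abs(coefs) * col_sd, col_field, sum)
  w <- as.numeric(w)
  names(w) <- levels(col_field)
  if (sum(w) == 0) w[] <- 1 / length(w) else w <- w / sum(w)
  w
}

#' Per-field contribution fractions of a fitted model
#'
#' Contribution of field f = sum over its columns of |coefficient| x
#' training-column SD, normalized over all fields; the standard
#' SD-weighted measure of how much each field type drives the model.
#' Fractions are non-negative and sum to 1.
#'
#' @param model a \linkS4class{QsarModel}.
#' @param blocks optional blocks to recompute the column SDs from;
#'   defaults to the SDs stored at fit time.
#' @return named numeric vector of fractions, one per field.
#' @export
fieldContributions <- function(model, blocks = NULL) {
  col_sd <- if (is.null(blocks)) model@col_sd
            else .pop_sd(.concat_blocks(blocks)$X)
  .contributions(model@coefficients, col_sd, model@col_field)
}

#' Predict pEC50 for aligned molecules
#'
#' Evaluates the model's field types at its retained grid points for each
#' molecule (applying the stored electrostatic fill means at sterically
#' saturated points) and applies the stored linear model.  Predicting the
#' training molecules reproduces the fitted values.  Because the fields
#' are anchored to the training grid, a molecule whose centroid lies far
#' outside the training region triggers a warning: translated copies of a
#' training molecule are different objects to a grid-based model.
#'
#' @param object a \linkS4class{QsarModel}.
#' @param mols list of parameterized \linkS4class{AlignedMolecule}.
#' @param ... unused.
#' @return named numeric vector of predicted pEC50 values.
#' @export
setMethod("predict", "QsarModel", function(object, mols, ...) {
  if (is(mols, "AlignedMolecule")) mols <- list(mols)
  lapply(mols, .check_parameterized)
  extent <- max(sqrt(rowSums(sweep(do.call(rbind, object@coords), 2,
                                   object@training_centroid)^2)))
  for (m in mols) {
    d <- sqrt(sum((colMeans(.mol_coords(m)) - object@training_centroid)^2))
    if (d > 2 * extent)
      warning("molecule '", m@id, "' lies ", format(d, digits = 3),
              " A from the training-grid centroid; grid-anchored fields ",
              "are not translation-portable", call. = FALSE)
  }
  X <- do.call(cbind, lapply(seq_along(object@field_types), function(k) {
    ft <- object@field_types[k]
    fill <- if (ft == "FF_electrostatic") object@es_fill else numeric(0)
    .block_rows(mols, ft, object@coords[[k]], object@field_params, fill)
  }))
  out <- drop(X %*% object@coefficients) + object@intercept
  names(out) <- vapply(mols, molId, character(1))
  out
})

#' Leave-one-out cross-validated Q2
#'
#' Refits the model n times, each time holding out one molecule, with
#' centering and block scaling recomputed inside each fold, and returns
#' \eqn{Q^2 = 1 - PRESS / \sum (y - \bar y)^2}.  A degenerate fold (fit
#' failure, e.g. zero-variance descriptors) predicts the fold-training
#' mean.
#'
#' @inheritParams fitPls
#' @return Q2, a scalar <= 1 (negative when the model predicts worse than
#'   the mean).
#' @export
looQ2 <- function(blocks, y, n_factors = 5L) {
  cb <- .concat_blocks(blocks)
  n <- length(y)
  if (n < 3L) stop("need at least 3 molecules for leave-one-out")
  press <- 0
  for (i in seq_len(n)) {
    pred <- tryCatch({
      f <- .fit_matrix(cb$X[-i, , drop = FALSE], cb$col_field, y[-i],
                       n_factors)
      sum(f$coefficients * cb$X[i, ]) + f$intercept
    }, error = function(e) mean(y[-i]))
    press <- press + (y[i] - pred)^2
  }
  1 - press / sum((y - mean(y))^2)
}

#' Y-scrambling control
#'
#' Mean training R2 over models refitted on permuted activities: measures
#' how well the grid variables can fit meaningless data (chance
#' correlation / capacity control).
#'
#' @inheritParams fitPls
#' @param n_perm number of permutations (default 50).
#' @param seed RNG seed; the caller's RNG state is left untouched.
#' @param perms optional list of explicit permutation index vectors
#'   (overrides \code{n_perm}/\code{seed}); mainly for testing.
#' @return mean scrambled R2_training.
#' @export
scrambleR2 <- function(blocks, y, n_factors = 5L, n_perm = 50L, seed = 1L,
                       perms = NULL) {
  cb <- .concat_blocks(blocks)
  if (is.null(perms)) {
    if (n_perm < 1L) stop("'n_perm' must be >= 1")
    perms <- .with_seed(seed, replicate(n_perm, sample(length(y)),
                                        simplify = FALSE))
  }
  r2 <- vapply(perms, function(p)
    .fit_matrix(cb$X, cb$col_field, y[p], n_factors)$r2_training,
    numeric(1))
  mean(r2)
}

#' Stability of model predictions to training-set composition
#'
#' Refits the model on random subsamples (fraction \code{frac} of the
#' molecules, default 0.9) and returns the mean Pearson correlation
#' between the full-model and subsample-model predictions over the full
#' training set.  A replicate with constant predictions contributes 0.
#' 1 means the predictions do not depend on which molecules were seen.
#'
#' @inheritParams scrambleR2
#' @param frac subsample fraction; \code{round(frac * n)} must be at
#'   least \code{n_factors + 1}.
#' @param n_rep number of subsample replicates (default 20).
#' @return mean correlation in [-1, 1].
#' @export
stability <- function(blocks, y, n_factors = 5L, frac = 0.9, n_rep = 20L,
                      seed = 1L) {
  cb <- .concat_blocks(blocks)
  n <- length(y)
  m <- round(frac * n)
  if (m < n_factors + 1L)
    stop("subsample size ", m, " too small for ", n_factors, " factors")
  full <- .fit_matrix(cb$X, cb$col_field, y, n_factors)
  pred_full <- drop(cb$X %*% full$coefficients) + full$intercept
  subs <- .with_seed(seed, replicate(n_rep, sample(n, m), simplify = FALSE))
  r <- vapply(subs, function(idx) {
    p <- tryCatch({
      f <- .fit_matrix(cb$X[idx, , drop = FALSE], cb$col_field, y[idx],
                       n_factors)
      drop(cb$X %*% f$coefficients) + f$intercept
    }, error = function(e) rep(NA_real_, n))
    if (anyNA(p) || stats::sd(p) == 0 || stats::sd(pred_full) == 0) 0
    else stats::cor(pred_full, p)
  }, numeric(1))
  mean(r)
}

#' Exhaustive field-combination model scan
#'
#' Fits every non-empty subset of the supplied field types (2^k - 1
#' models) and tabulates, per model: standard error of estimate (SD),
#' R2_training, scrambled R2, external R2 on the test set (both squared
#' Pearson and predictive flavors), stability, and per-field contribution
#' fractions.  A model that fails to fit becomes a flagged row rather
#' than aborting the scan.  Rows are ranked by external R2 (descending),
#' then R2_training (descending), then fewer fields.
#'
#' @inheritParams fitPls
#' @param test_blocks optional blocks for the external test molecules, as
#'   returned by \code{\link{evaluateBlocks}} on all fields of
#'   \code{blocks}.
#' @param y_test pEC50 of the test molecules.
#' @param n_perm,n_rep,frac,seed controls for the scrambling and
#'   stability columns.
#' @return data.frame with one row per field subset, ranked; column
#'   \code{fields} holds the subset label (e.g. \code{"S+E"}-style joined
#'   field names), \code{ok} flags rows whose fit succeeded.
#' @export
scanCombinations <- function(blocks, y, n_factors = 5L,
                             test_blocks = NULL, y_test = NULL,
                             n_perm = 50L, n_rep = 20L, frac = 0.9,
                             seed = 1L) {
  fts <- vapply(blocks, fieldType, character(1))
  if (!length(fts)) stop("supply at least one field block")
  k <- length(fts)
  subsets <- unlist(lapply(seq_len(k), function(m)
    utils::combn(seq_len(k), m, simplify = FALSE)), recursive = FALSE)
  ymean_train <- mean(y)
  rows <- lapply(subsets, function(sel) {
    sub <- blocks[sel]
    label <- paste(fts[sel], collapse = "+")
    base <- data.frame(fields = label, n_fields = length(sel),
                       sd = NA_real_, r2_training = NA_real_,
                       r2_scramble = NA_real_, r2_test = NA_real_,
                       r2_test_pred = NA_real_, stability = NA_real_,
                       q2_loo = NA_real_, ok = FALSE,
                       stringsAsFactors = FALSE)
    contrib <- stats::setNames(rep(NA_real_, k), paste0("contrib_", fts))
    res <- tryCatch({
      model <- fitPls(sub, y, n_factors)
      s <- model@stats
      base$sd <- s$sd; base$r2_training <- s$r2_training
      base$r2_scramble <- scrambleR2(sub, y, n_factors, n_perm, seed)
      base$stability <- stability(sub, y, n_factors, frac, n_rep, seed)
      base$q2_loo <- looQ2(sub, y, n_factors)
      contrib[paste0("contrib_", fts[sel])] <- s$contributions
      if (!is.null(test_blocks) && !is.null(y_test)) {
        Xt <- do.call(cbind, lapply(test_blocks[sel], fieldValues))
        pred <- drop(Xt %*% model@coefficients) + model@intercept
        base$r2_test <- stats::cor(y_test, pred)^2
        base$r2_test_pred <-
          1 - sum((y_test - pred)^2) / sum((y_test - ymean_train)^2)
      }
      base$ok <- TRUE
      base
    }, error = function(e) {
      base$fields <- label
      base
    })
    cbind(res, as.data.frame(as.list(contrib)))
  })
  tab <- do.call(rbind, rows)
  key_test <- ifelse(is.na(tab$r2_test), -Inf, tab$r2_test)
  key_train <- ifelse(is.na(tab$r2_training), -Inf, tab$r2_training)
  tab <- tab[order(-key_test, -key_train, tab$n_fields), ]
  rownames(tab) <- NULL
  tab
}

#' Persist a fitted model as JSON
#'
#' Writes metadata, statistics, per-field retained lattice indices and the
#' coefficient vector to a single JSON file readable with
#' \code{\link{readQsarModel}}.
#'
#' @param model a \linkS4class{QsarModel}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeQsarModel <- function(model, path) {
  obj <- list(field_types = model@field_types,
              n_factors = model@n_factors,
              x_mean = model@x_mean, x_scale = model@x_scale,
              coefficients = model@coefficients,
              intercept = model@intercept,
              col_field = as.character(model@col_field),
              col_sd = model@col_sd,
              point_index = model@point_index,
              coords = lapply(model@coords, function(m)
                as.data.frame(m, col.names = c("x", "y", "z"))),
              es_fill = model@es_fill,
              field_params = model@field_params,
              stats = model@stats,
              training_ids = model@training_ids,
              training_centroid = model@training_centroid)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Restore a model written by \code{\link{writeQsarModel}}
#'
#' @param path JSON file.
#' @return a \linkS4class{QsarModel}.
#' @export
readQsarModel <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  new("QsarModel",
      field_types = o$field_types, n_factors = as.integer(o$n_factors),
      x_mean = o$x_mean, x_scale = o$x_scale,
      coefficients = o$coefficients, intercept = o$intercept,
      col_field = factor(o$col_field, levels = o$field_types),
      col_sd = o$col_sd,
      point_index = lapply(o$point_index, as.integer),
      coords = lapply(o$coords, function(d) unname(as.matrix(d))),
      es_fill = as.numeric(unlist(o$es_fill)),
      field_params = o$field_params,
      stats = o$stats, training_ids = o$training_ids,
      training_centroid = o$training_centroid)
}
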