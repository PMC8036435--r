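#' @include AllClasses.R AllGenerics.R grid.R
NULL

#' Default force-field probe: an sp3 carbon bearing unit positive charge
#'
#' The conventional probe for force-field QSAR grids: van der Waals radius
#' 1.70 Angstrom, Lennard-Jones well depth 0.10 kcal/mol, charge +1 e.
#'
#' @return list with elements \code{radius}, \code{epsilon}, \code{charge}.
#' @export
defaultProbe <- function() list(radius = 1.70, epsilon = 0.10, charge = 1.0)

.COULOMB <- 332.06  # kcal*Angstrom/(mol*e^2)

.check_parameterized <- function(mol) {
  need <- c("vdw_radius", "epsilon", "hydrophobicity", "is_hbd", "is_hba")
  if (!all(need %in% names(mol@atoms)) ||
      anyNA(mol@atoms[, intersect(need, names(mol@atoms))]))
    stop("molecule '", mol@id, "' is not parameterized; ",
         "call assignParameters() first")
  invisible(TRUE)
}

## squared distances from every atom of 'mol' to every point: A x P
## matrix.  Computed from coordinate differences (not the expanded inner
## product form) so that jointly translating molecule and points leaves
## every distance, hence every field value, bit-identical.
.dist2 <- function(mol, pts) {
  xyz <- .mol_coords(mol)
  d2 <- matrix(0, nrow(xyz), nrow(pts))
  for (i in seq_len(nrow(xyz)))
    d2[i, ] <- (pts[, 1] - xyz[i, 1])^2 + (pts[, 2] - xyz[i, 2])^2 +
               (pts[, 3] - xyz[i, 3])^2
  pmax(d2, 1e-12)  # an atom sitting exactly on a point saturates the clamp
}

#' Lennard-Jones and Coulomb probe fields of one molecule
#'
#' Steric field: \eqn{\sum_i \epsilon_i [(R_i/r_{iq})^{12} -
#' 2 (R_i/r_{iq})^6]} with Lorentz-Berthelot combination
#' (\eqn{R_i} = atom radius + probe radius, \eqn{\epsilon_i} = geometric
#' mean of the well depths), so the value at the pair minimum distance is
#' exactly minus the pair well depth.  Electrostatic field:
#' \eqn{\sum_i 332.06\, z_{probe} q_i / (\epsilon(r) r_{iq})} with the
#' distance-dependent dielectric \eqn{\epsilon(r) = r}.  Both are clamped
#' symmetrically to \code{[-clamp, +clamp]} kcal/mol (default 30).  Points
#' where the unclamped steric energy reaches the clamp are flagged: there
#' the electrostatic value is meaningless (probe inside the molecule) and
#' is later replaced by the training-set column mean during block assembly
#' (see \code{\link{assembleBlocks}}).
#'
#' @param mol a parameterized \linkS4class{AlignedMolecule}.
#' @param grid a \linkS4class{FieldGrid}, or a numeric points-x-3
#'   coordinate matrix.
#' @param probe probe parameters, see \code{\link{defaultProbe}}.
#' @param clamp truncation threshold, kcal/mol.
#' @return list with numeric vectors \code{steric}, \code{electrostatic}
#'   (one value per active grid point) and logical \code{saturated}.
#' @export
ffFields <- function(mol, grid, probe = defaultProbe(), clamp = 30.0) {
  .check_parameterized(mol)
  pts <- if (is(grid, "FieldGrid"))
    gridPoints(grid@spec)[grid@active_mask, , drop = FALSE]
  else as.matrix(grid)
  a <- mol@atoms
  d2 <- .dist2(mol, pts)                       # atoms x points
  rmin <- a$vdw_radius + probe$radius
  epair <- sqrt(a$epsilon * probe$epsilon)
  s <- (rmin^2) / d2                           # (R/r)^2, atoms x points
  s3 <- s * s * s
  steric_raw <- colSums(epair * (s3 * s3 - 2 * s3))
  saturated <- steric_raw >= clamp
  steric <- pmin(pmax(steric_raw, -clamp), clamp)
  es_raw <- .COULOMB * probe$charge * colSums(a$charge / d2)  # eps(r)=r
  electrostatic <- pmin(pmax(es_raw, -clamp), clamp)
  list(steric = unname(steric), electrostatic = unname(electrostatic),
       saturated = unname(saturated))
}

#' Gaussian similarity field of one molecule
#'
#' Distance-attenuated property sum \eqn{\sum_i w_i e^{-\alpha r_{iq}^2}}
#' with no cutoff and no clamping.  The atom weight \eqn{w_i} depends on
#' the field type: cube of the van der Waals radius (\code{G_steric}),
#' signed partial charge (\code{G_electrostatic}), hydrophobicity atom
#' constant (\code{G_hydrophobic}), or a 0/1 indicator of the
#' acceptor/donor flag (\code{G_hba}, \code{G_hbd}).
#'
#' @inheritParams ffFields
#' @param field_type one of \code{"G_steric"}, \code{"G_electrostatic"},
#'   \code{"G_hydrophobic"}, \code{"G_hba"}, \code{"G_hbd"}.
#' @param alpha attenuation factor, 1/Angstrom^2 (default 0.3).
#' @return numeric vector, one value per active grid point.
#' @export
gaussianField <- function(mol, grid, field_type, alpha = 0.3) {
  .check_parameterized(mol)
  pts <- if (is(grid, "FieldGrid"))
    gridPoints(grid@spec)[grid@active_mask, , drop = FALSE]
  else as.matrix(grid)
  a <- mol@atoms
  w <- switch(field_type,
    G_steric = a$vdw_radius^3,
    G_electrostatic = a$charge,
    G_hydrophobic = a$hydrophobicity,
    G_hba = as.numeric(a$is_hba),
    G_hbd = as.numeric(a$is_hbd),
    stop("unknown Gaussian field type: ", field_type))
  d2 <- .dist2(mol, pts)
  unname(colSums(w * exp(-alpha * d2)))
}

.field_matrix <- function(mols, pts, field_type, probe, clamp, alpha) {
  ## FF pair handled by caller; this fills one plain field type
  t(vapply(mols, function(m) {
    if (field_type == "FF_steric")
      ffFields(m, pts, probe, clamp)$steric
    else if (field_type == "FF_electrostatic")
      ffFields(m, pts, probe, clamp)$electrostatic
    else gaussianField(m, pts, field_type, alpha)
  }, numeric(nrow(pts))))
}

# population SD (divide by n), used by the variance filter and the
# contribution/contour weights
.pop_sd <- function(x) {
  mu <- colMeans(x)
  sqrt(pmax(colMeans(x^2) - mu^2, 0))
}

#' Assemble per-field descriptor blocks with variance filtering
#'
#' Computes the requested field types for every molecule at the active
#' grid points, applies the deferred electrostatic fill (at points where a
#' molecule's steric field is clamp-saturated, its electrostatic value is
#' replaced by the column mean over the non-saturated molecules --
#' \code{es_at_clash = "mean"}, the default -- or left clamped with
#' \code{"clamp"}), and then removes, per block, every column whose
#' across-molecule population standard deviation is below \code{sd_min}
#' (default 0.05).
#'
#' @param mols list of >= 2 parameterized molecules.
#' @param grid a \linkS4class{FieldGrid}.
#' @param field_types character vector of field labels (see
#'   \linkS4class{FieldBlock}).
#' @param sd_min variance-filter threshold on the population SD.
#' @param probe,clamp,alpha field parameters, see \code{\link{ffFields}}
#'   and \code{\link{gaussianField}}.
#' @param es_at_clash treatment of electrostatic values at sterically
#'   saturated points.
#' @return named list of \linkS4class{FieldBlock}, one per field type.
#' @export
assembleBlocks <- function(mols, grid, field_types,
                           sd_min = 0.05, probe = defaultProbe(),
                           clamp = 30.0, alpha = 0.3,
                           es_at_clash = c("mean", "clamp")) {
  es_at_clash <- match.arg(es_at_clash)
  if (length(mols) < 2L)
    stop("need >= 2 molecules for across-molecule SDs")
  stopifnot(all(field_types %in% .FIELD_TYPES))
  lapply(mols, .check_parameterized)
  active <- which(grid@active_mask)
  if (!length(active))
    stop("no active grid points (exclusion removed the whole lattice)")
  pts <- gridPoints(grid@spec)[active, , drop = FALSE]
  ids <- vapply(mols, molId, character(1))

  need_ff <- any(c("FF_steric", "FF_electrostatic") %in% field_types)
  ff <- if (need_ff) lapply(mols, ffFields, grid = pts, probe = probe,
                            clamp = clamp)
  params <- list(probe = probe, clamp = clamp, alpha = alpha,
                 es_at_clash = es_at_clash)

  out <- list()
  for (ft in field_types) {
    vals <- if (ft == "FF_steric")
      do.call(rbind, lapply(ff, `[[`, "steric"))
    else if (ft == "FF_electrostatic")
      do.call(rbind, lapply(ff, `[[`, "electrostatic"))
    else
      t(vapply(mols, gaussianField, numeric(nrow(pts)),
               grid = pts, field_type = ft, alpha = alpha))
    fill_means <- numeric(0)
    if (ft == "FF_electrostatic" && es_at_clash == "mean") {
      sat <- do.call(rbind, lapply(ff, `[[`, "saturated"))
      fill_means <- vapply(seq_len(ncol(vals)), function(j) {
        ok <- !sat[, j]
        if (any(ok)) mean(vals[ok, j]) else 0
      }, numeric(1))
      for (j in which(colSums(sat) > 0))
        vals[sat[, j], j] <- fill_means[j]
    }
    sds <- .pop_sd(vals)
    keep <- sds >= sd_min
    if (!any(keep))
      stop("field ", ft, ": all ", ncol(vals),
           " columns fall below the SD filter (sd_min = ", sd_min, ")")
    p <- params
    if (length(fill_means)) p$fill_means <- fill_means[keep]
    rownames(vals) <- ids
    out[[ft]] <- new("FieldBlock", field_type = ft,
                     values = vals[, keep, drop = FALSE],
                     point_index = active[keep],
                     coords = pts[keep, , drop = FALSE],
                     params = p)
  }
  out
}

## Field rows for new molecules at a block's retained points, replicating
## the training-time electrostatic fill.
.block_rows <- function(mols, field_type, coords, params,
                        fill_means = numeric(0)) {
  probe <- params$probe %||% defaultProbe()
  clamp <- params$clamp %||% 30.0
  alpha <- params$alpha %||% 0.3
  t(vapply(mols, function(m) {
    if (field_type %in% c("FF_steric", "FF_electrostatic")) {
      f <- ffFields(m, coords, probe, clamp)
      if (field_type == "FF_steric") f$steric
      else {
        v <- f$electrostatic
        if (length(fill_means) && (params$es_at_clash %||% "mean") == "mean")
          v[f$saturated] <- fill_means[f$saturated]
        v
      }
    } else gaussianField(m, coords, field_type, alpha)
  }, numeric(nrow(coords))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate new molecules on the retained points of existing blocks
#'
#' Builds descriptor rows for \code{mols} that are column-compatible with
#' \code{blocks} (same retained points, same parameters, same
#' electrostatic fill means), e.g. for external test sets.
#'
#' @param mols list of parameterized molecules.
#' @param blocks named list of \linkS4class{FieldBlock} from
#'   \code{\link{assembleBlocks}}.
#' @return named list of \linkS4class{FieldBlock} with one row per
#'   molecule.
#' @export
evaluateBlocks <- function(mols, blocks) {
  lapply(mols, .check_parameterized)
  ids <- vapply(mols, molId, character(1))
  lapply(blocks, function(b) {
    vals <- .block_rows(mols, b@field_type, b@coords, b@params,
                        b@params$fill_means %||% numeric(0))
    rownames(vals) <- ids
    new("FieldBlock", field_type = b@field_type, values = vals,
        point_index = b@point_index, coords = b@coords, params = b@params)
  })
}
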