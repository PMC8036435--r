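#' @include AllClasses.R AllGenerics.R
NULL

.mol_coords <- function(mol) as.matrix(mol@atoms[, c("x", "y", "z")])

.all_coords <- function(mols) do.call(rbind, lapply(mols, .mol_coords))

#' Build the orthohedral sampling lattice for an aligned series
#'
#' Axis-aligned lattice covering the union bounding box of the defining
#' molecules, expanded by \code{margin} Angstrom on every side and sampled
#' every \code{spacing} Angstrom.  Per axis the point count is
#' \code{floor((extent + 2*margin)/spacing) + 1} and the origin is the
#' minimum corner minus the margin.  The lattice is conventionally defined
#' on the training set only; test and prediction molecules are evaluated
#' on the same lattice (the fields are analytic, so out-of-grid atoms are
#' allowed).
#'
#' @param mols non-empty list of \linkS4class{AlignedMolecule}.
#' @param spacing lattice step, Angstrom (default 1.0).
#' @param margin box expansion, Angstrom (default 3.0).
#' @return a \linkS4class{GridSpec}.
#' @examples
#' ## a 10 A cube with 3 A margin at 1 A spacing gives 17 points per axis
#' @export
buildGrid <- function(mols, spacing = 1.0, margin = 3.0) {
  if (!length(mols)) stop("cannot build a grid from an empty molecule list")
  if (spacing <= 0) stop("'spacing' must be > 0")
  xyz <- .all_coords(mols)
  lo <- apply(xyz, 2, min)
  hi <- apply(xyz, 2, max)
  dims <- as.integer(floor((hi - lo + 2 * margin) / spacing) + 1)
  dims <- pmax(dims, 2L)
  new("GridSpec", origin = unname(lo - margin), spacing = spacing,
      dims = dims, margin = margin)
}

#' Cartesian coordinates of every lattice point
#'
#' @param spec a \linkS4class{GridSpec} or \linkS4class{FieldGrid}.
#' @return numeric matrix (points x 3) in x-fastest order.
#' @export
gridPoints <- function(spec) {
  if (is(spec, "FieldGrid")) spec <- spec@spec
  ax <- lapply(1:3, function(k)
    spec@origin[k] + spec@spacing * (seq_len(spec@dims[k]) - 1))
  as.matrix(expand.grid(x = ax[[1]], y = ax[[2]], z = ax[[3]],
                        KEEP.OUT.ATTRS = FALSE))
}

#' Mask lattice points too close to the defining molecules
#'
#' A point stays active exactly when its distance to every atom of every
#' defining molecule is at least \code{min_dist} (default 2 Angstrom);
#' points inside that shell sample the repulsive wall rather than the
#' interaction-relevant surface region and are eliminated.
#'
#' @param spec a \linkS4class{GridSpec}.
#' @param mols defining molecule set.
#' @param min_dist exclusion distance, Angstrom; >= 0.
#' @return a \linkS4class{FieldGrid}.
#' @export
exclusionMask <- function(spec, mols, min_dist = 2.0) {
  if (min_dist < 0) stop("'min_dist' must be >= 0")
  pts <- gridPoints(spec)
  mask <- rep(TRUE, nrow(pts))
  if (min_dist > 0) {
    d2min <- min_dist^2
    xyz <- .all_coords(mols)
    for (i in seq_len(nrow(xyz))) {
      d2 <- (pts[, 1] - xyz[i, 1])^2 + (pts[, 2] - xyz[i, 2])^2 +
            (pts[, 3] - xyz[i, 3])^2
      mask <- mask & (d2 >= d2min)
    }
  }
  new("FieldGrid", spec = spec, active_mask = mask, min_dist = min_dist)
}
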