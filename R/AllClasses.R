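#' @import methods
NULL

#' AlignedMolecule: a rigid, pre-aligned small molecule
#'
#' Container for one member of an aligned molecular series: a per-atom table
#' (element, Cartesian coordinates in Angstrom, partial charge in elementary
#' charge units, and -- once parameterized -- van der Waals radius, well
#' depth, a hydrophobicity atom constant and hydrogen-bond donor/acceptor
#' flags), the bond list, and an optional activity expressed as pEC50
#' (-log10 of the molar EC50).  Coordinates are taken as already mutually
#' aligned across the series; the package never re-orients them.
#'
#' @slot id character scalar, unique within a dataset.
#' @slot atoms data.frame with columns \code{element}, \code{x}, \code{y},
#'   \code{z}, \code{charge} and (after \code{\link{assignParameters}})
#'   \code{vdw_radius}, \code{epsilon}, \code{hydrophobicity},
#'   \code{is_hbd}, \code{is_hba}.
#' @slot bonds data.frame with columns \code{a1}, \code{a2}, \code{order}
#'   (1-based atom indices); may have zero rows.
#' @slot activity numeric scalar, pEC50; \code{NA_real_} for
#'   prediction-only molecules.
#' @slot flat logical; \code{TRUE} when the record looked 2D on input
#'   (all z coordinates zero).
#'
#' @seealso \code{\link{readSdf}}, \code{\link{assignParameters}}
#' @export
setClass("AlignedMolecule",
  representation(id = "character", atoms = "data.frame",
                 bonds = "data.frame", activity = "numeric",
                 flat = "logical"),
  prototype(activity = NA_real_, flat = FALSE,
            bonds = data.frame(a1 = integer(), a2 = integer(),
                               order = integer())))

setValidity("AlignedMolecule", function(object) {
  msg <- character()
  if (length(object@id) != 1L || is.na(object@id) || !nzchar(object@id))
    msg <- c(msg, "'id' must be a non-empty string")
  a <- object@atoms
  need <- c("element", "x", "y", "z", "charge")
  if (!all(need %in% names(a)))
    msg <- c(msg, paste("atoms must have columns:", paste(need, collapse = ", ")))
  else {
    if (nrow(a) < 1L) msg <- c(msg, "molecule must have at least one atom")
    if (!all(is.finite(as.matrix(a[, c("x", "y", "z")]))))
      msg <- c(msg, "atom coordinates must be finite")
    if ("vdw_radius" %in% names(a) && any(!is.na(a$vdw_radius) & a$vdw_radius <= 0))
      msg <- c(msg, "vdw_radius must be > 0")
  }
  if (length(object@activity) != 1L)
    msg <- c(msg, "'activity' must be a single pEC50 (or NA)")
  if (length(msg)) msg else TRUE
})

#' GridSpec: the rectilinear sampling lattice
#'
#' Axis-aligned orthohedral lattice enclosing an aligned training series:
#' the union bounding box of the defining molecules expanded by
#' \code{margin} on every side, sampled every \code{spacing} Angstrom.
#'
#' @slot origin numeric(3), minimum corner, Angstrom.
#' @slot spacing numeric scalar, lattice step, Angstrom (default 1.0).
#' @slot dims integer(3), points per axis.
#' @slot margin numeric scalar, box expansion, Angstrom (default 3.0).
#' @export
setClass("GridSpec",
  representation(origin = "numeric", spacing = "numeric",
                 dims = "integer", margin = "numeric"))

setValidity("GridSpec", function(object) {
  msg <- character()
  if (length(object@origin) != 3L || !all(is.finite(object@origin)))
    msg <- c(msg, "'origin' must be a finite 3-vector")
  if (length(object@spacing) != 1L || object@spacing <= 0)
    msg <- c(msg, "'spacing' must be a positive scalar")
  if (length(object@dims) != 3L || any(object@dims < 2L))
    msg <- c(msg, "'dims' must be three integers >= 2")
  if (length(msg)) msg else TRUE
})

#' FieldGrid: lattice plus the active-point mask
#'
#' A \linkS4class{GridSpec} together with a logical mask marking the lattice
#' points retained for field sampling: points closer than the exclusion
#' distance (default 2 Angstrom) to any atom of the defining molecule set
#' are switched off.
#'
#' @slot spec a \linkS4class{GridSpec}.
#' @slot active_mask logical vector, one flag per lattice point in
#'   x-fastest order.
#' @slot min_dist numeric scalar, exclusion distance used, Angstrom.
#' @export
setClass("FieldGrid",
  representation(spec = "GridSpec", active_mask = "logical",
                 min_dist = "numeric"))

setValidity("FieldGrid", function(object) {
  if (length(object@active_mask) != prod(object@spec@dims))
    "active_mask length must equal prod(dims)" else TRUE
})

#' FieldBlock: molecules x retained-grid-points value matrix for one field
#'
#' One block of the QSAR descriptor matrix: the field values of every
#' molecule at every retained lattice point, for a single field type.
#' Force-field blocks (\code{FF_steric}, \code{FF_electrostatic}) are in
#' kcal/mol and clamped; Gaussian blocks (\code{G_steric},
#' \code{G_electrostatic}, \code{G_hydrophobic}, \code{G_hba},
#' \code{G_hbd}) are dimensionless similarity sums.
#'
#' @slot field_type one of the seven field labels.
#' @slot values numeric matrix, rows = molecules (named by id),
#'   columns = retained grid points.
#' @slot point_index integer vector, linear lattice index (x-fastest) of
#'   each retained column.
#' @slot coords numeric matrix (points x 3), Cartesian coordinates of the
#'   retained columns.
#' @slot params list of the computation parameters (probe, clamp, alpha,
#'   es_at_clash) plus, for a mean-filled electrostatic block, the
#'   per-column training fill means (\code{fill_means}).
#' @export
setClass("FieldBlock",
  representation(field_type = "character", values = "matrix",
                 point_index = "integer", coords = "matrix",
                 params = "list"),
  prototype(params = list()))

.FIELD_TYPES <- c("FF_steric", "FF_electrostatic", "G_steric",
                  "G_electrostatic", "G_hydrophobic", "G_hba", "G_hbd")

setValidity("FieldBlock", function(object) {
  msg <- character()
  if (!object@field_type %in% .FIELD_TYPES)
    msg <- c(msg, paste("unknown field_type:", object@field_type))
  if (!all(is.finite(object@values)))
    msg <- c(msg, "field values must all be finite")
  if (ncol(object@values) != length(object@point_index))
    msg <- c(msg, "point_index length must equal number of columns")
  if (length(msg)) msg else TRUE
})

#' QsarModel: a fitted grid-field PLS model
#'
#' Partial-least-squares regression linking concatenated field blocks to
#' pEC50.  Stores everything needed to reproduce fitted values and to
#' predict new aligned molecules on the training grid: per-column centering
#' constants, per-block variance-equalization scale factors, coefficients
#' in original field units, the per-column training SDs (used for contour
#' scores and field contributions), and the column-to-field map.
#'
#' @slot field_types character, ordered field labels entering the model.
#' @slot n_factors integer, number of latent factors (1--5).
#' @slot x_mean numeric, per-column centering constants.
#' @slot x_scale numeric, per-column scale factors (shared within a block).
#' @slot coefficients numeric, per-column regression weights, activity
#'   units per original field unit.
#' @slot intercept numeric scalar, pEC50.
#' @slot col_field factor, field label of every column.
#' @slot col_sd numeric, training-set population SD of every column.
#' @slot point_index list of integer vectors, lattice indices per field.
#' @slot coords list of point-coordinate matrices per field.
#' @slot es_fill numeric, training column means used to fill the
#'   electrostatic field at sterically saturated points (empty unless the
#'   model contains \code{FF_electrostatic} with mean-fill).
#' @slot field_params list of the field-computation parameters (probe,
#'   clamp, alpha, es_at_clash) needed to evaluate new molecules.
#' @slot stats list of training statistics (see \code{\link{modelStats}}).
#' @slot training_ids character, molecule ids in training order.
#' @slot training_centroid numeric(3), mean atom position of the training
#'   set (used to warn on far-out-of-grid prediction queries).
#' @export
setClass("QsarModel",
  representation(field_types = "character", n_factors = "integer",
                 x_mean = "numeric", x_scale = "numeric",
                 coefficients = "numeric", intercept = "numeric",
                 col_field = "factor", col_sd = "numeric",
                 point_index = "list", coords = "list",
                 es_fill = "numeric", field_params = "list", stats = "list",
                 training_ids = "character", training_centroid = "numeric"))

setValidity("QsarModel", function(object) {
  msg <- character()
  p <- length(object@coefficients)
  if (length(object@x_mean) != p || length(object@x_scale) != p ||
      length(object@col_field) != p || length(object@col_sd) != p)
    msg <- c(msg, "coefficient-aligned slots must share one length")
  if (object@n_factors < 1L)
    msg <- c(msg, "n_factors must be >= 1")
  if (length(msg)) msg else TRUE
})

#' ContourSet: favored/disfavored spatial regions for one field
#'
#' Grid points whose SD-weighted coefficient score falls in the upper or
#' lower percentile tail of the model's scores for one field, carrying the
#' field's conventional display colors (steric green/yellow, electrostatic
#' blue/red, HBA red/magenta, HBD purple/cyan).
#'
#' @slot field_type field label.
#' @slot favored data.frame: \code{x,y,z,score,point_index} of points with
#'   score >= \code{pos_threshold}.
#' @slot disfavored data.frame: likewise with score <= \code{neg_threshold}.
#' @slot pos_threshold,neg_threshold numeric score cutoffs.
#' @slot colors character(2), favored/disfavored display colors.
#' @export
setClass("ContourSet",
  representation(field_type = "character", favored = "data.frame",
                 disfavored = "data.frame", pos_threshold = "numeric",
                 neg_threshold = "numeric", colors = "character"))

setValidity("ContourSet", function(object) {
  msg <- character()
  if (nrow(object@favored) && any(object@favored$score < object@pos_threshold))
    msg <- c(msg, "favored scores must be >= pos_threshold")
  if (nrow(object@disfavored) && any(object@disfavored$score > object@neg_threshold))
    msg <- c(msg, "disfavored scores must be <= neg_threshold")
  if (length(intersect(object@favored$point_index,
                       object@disfavored$point_index)))
    msg <- c(msg, "favored and disfavored sets must be disjoint")
  if (length(msg)) msg else TRUE
})
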