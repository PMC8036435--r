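#' @include AllClasses.R
NULL

#' Accessors for package classes
#'
#' Small read-only accessors: \code{molId}, \code{atoms}, \code{bonds},
#' \code{activity} (with replacement method), \code{nAtoms} for
#' \linkS4class{AlignedMolecule}; \code{fieldType}, \code{fieldValues},
#' \code{pointCoords}, \code{pointIndex} for \linkS4class{FieldBlock} and
#' \linkS4class{ContourSet}; \code{modelStats}, \code{fieldTypes},
#' \code{nFactors} for \linkS4class{QsarModel}; \code{gridDims},
#' \code{gridOrigin}, \code{gridSpacing}, \code{activeMask} for grids.
#'
#' @param x an object of the documented class.
#' @param value replacement value.
#' @return the slot contents (see class documentation).
#' @name accessors
#' @aliases molId atoms bonds activity activity<- nAtoms fieldType
#'   fieldValues pointCoords pointIndex modelStats fieldTypes nFactors
#'   gridDims gridOrigin gridSpacing activeMask
NULL

#' @rdname accessors
#' @export
setGeneric("molId", function(x) standardGeneric("molId"))
#' @rdname accessors
#' @export
setGeneric("atoms", function(x) standardGeneric("atoms"))
#' @rdname accessors
#' @export
setGeneric("bonds", function(x) standardGeneric("bonds"))
#' @rdname accessors
#' @export
setGeneric("activity", function(x) standardGeneric("activity"))
#' @rdname accessors
#' @export
setGeneric("activity<-", function(x, value) standardGeneric("activity<-"))
#' @rdname accessors
#' @export
setGeneric("nAtoms", function(x) standardGeneric("nAtoms"))
#' @rdname accessors
#' @export
setGeneric("fieldType", function(x) standardGeneric("fieldType"))
#' @rdname accessors
#' @export
setGeneric("fieldValues", function(x) standardGeneric("fieldValues"))
#' @rdname accessors
#' @export
setGeneric("pointCoords", function(x) standardGeneric("pointCoords"))
#' @rdname accessors
#' @export
setGeneric("pointIndex", function(x) standardGeneric("pointIndex"))
#' @rdname accessors
#' @export
setGeneric("modelStats", function(x) standardGeneric("modelStats"))
#' @rdname accessors
#' @export
setGeneric("fieldTypes", function(x) standardGeneric("fieldTypes"))
#' @rdname accessors
#' @export
setGeneric("nFactors", function(x) standardGeneric("nFactors"))
#' @rdname accessors
#' @export
setGeneric("gridDims", function(x) standardGeneric("gridDims"))
#' @rdname accessors
#' @export
setGeneric("gridOrigin", function(x) standardGeneric("gridOrigin"))
#' @rdname accessors
#' @export
setGeneric("gridSpacing", function(x) standardGeneric("gridSpacing"))
#' @rdname accessors
#' @export
setGeneric("activeMask", function(x) standardGeneric("activeMask"))

#' @rdname accessors
setMethod("molId", "AlignedMolecule", function(x) x@id)
#' @rdname accessors
setMethod("atoms", "AlignedMolecule", function(x) x@atoms)
#' @rdname accessors
setMethod("bonds", "AlignedMolecule", function(x) x@bonds)
#' @rdname accessors
setMethod("activity", "AlignedMolecule", function(x) x@activity)
#' @rdname accessors
setMethod("activity<-", "AlignedMolecule", function(x, value) {
  x@activity <- as.numeric(value)
  validObject(x)
  x
})
#' @rdname accessors
setMethod("nAtoms", "AlignedMolecule", function(x) nrow(x@atoms))

#' @rdname accessors
setMethod("fieldType", "FieldBlock", function(x) x@field_type)
#' @rdname accessors
setMethod("fieldValues", "FieldBlock", function(x) x@values)
#' @rdname accessors
setMethod("pointCoords", "FieldBlock", function(x) x@coords)
#' @rdname accessors
setMethod("pointIndex", "FieldBlock", function(x) x@point_index)
#' @rdname accessors
setMethod("fieldType", "ContourSet", function(x) x@field_type)

#' @rdname accessors
setMethod("modelStats", "QsarModel", function(x) x@stats)
#' @rdname accessors
setMethod("fieldTypes", "QsarModel", function(x) x@field_types)
#' @rdname accessors
setMethod("nFactors", "QsarModel", function(x) x@n_factors)
#' @rdname accessors
#' @param object a \linkS4class{QsarModel}.
#' @param ... unused.
#' @export
setMethod("coef", "QsarModel", function(object, ...) object@coefficients)

#' @rdname accessors
setMethod("gridDims", "GridSpec", function(x) x@dims)
#' @rdname accessors
setMethod("gridOrigin", "GridSpec", function(x) x@origin)
#' @rdname accessors
setMethod("gridSpacing", "GridSpec", function(x) x@spacing)
#' @rdname accessors
setMethod("gridDims", "FieldGrid", function(x) x@spec@dims)
#' @rdname accessors
setMethod("gridOrigin", "FieldGrid", function(x) x@spec@origin)
#' @rdname accessors
setMethod("gridSpacing", "FieldGrid", function(x) x@spec@spacing)
#' @rdname accessors
setMethod("activeMask", "FieldGrid", function(x) x@active_mask)

setMethod("show", "AlignedMolecule", function(object) {
  cat("AlignedMolecule ", object@id, ": ", nrow(object@atoms), " atoms, ",
      nrow(object@bonds), " bonds", sep = "")
  if (!is.na(object@activity))
    cat(", pEC50 = ", format(object@activity, digits = 4), sep = "")
  if (object@flat) cat(" [flat: all-zero z]")
  cat("\n")
  invisible(NULL)
})

setMethod("show", "GridSpec", function(object) {
  cat("GridSpec: ", paste(object@dims, collapse = " x "),
      " points, spacing ", object@spacing, " A, origin (",
      paste(format(object@origin, digits = 4), collapse = ", "),
      "), margin ", object@margin, " A\n", sep = "")
  invisible(NULL)
})

setMethod("show", "FieldGrid", function(object) {
  show(object@spec)
  cat("  active points: ", sum(object@active_mask), " / ",
      length(object@active_mask), " (exclusion ", object@min_dist,
      " A)\n", sep = "")
  invisible(NULL)
})

setMethod("show", "FieldBlock", function(object) {
  cat("FieldBlock ", object@field_type, ": ", nrow(object@values),
      " molecules x ", ncol(object@values), " retained points\n", sep = "")
  invisible(NULL)
})

setMethod("show", "QsarModel", function(object) {
  s <- object@stats
  cat("QsarModel: fields [", paste(object@field_types, collapse = ", "),
      "], ", object@n_factors, " PLS factor(s), ",
      length(object@coefficients), " grid variables\n", sep = "")
  if (length(s))
    cat(sprintf("  R2_training = %.3f  SD = %.3f  F = %.2f\n",
                s$r2_training, s$sd, s$f_ratio))
  invisible(NULL)
})

setMethod("show", "ContourSet", function(object) {
  cat("ContourSet ", object@field_type, ": ", nrow(object@favored),
      " favored (", object@colors[1], "), ", nrow(object@disfavored),
      " disfavored (", object@colors[2], ")\n", sep = "")
  invisible(NULL)
})
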