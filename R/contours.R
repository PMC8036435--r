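#' @include AllClasses.R AllGenerics.R pls.R
NULL

.CONTOUR_COLORS <- list(
  FF_steric        = c("green", "yellow"),
  G_steric         = c("green", "yellow"),
  FF_electrostatic = c("blue", "red"),
  G_electrostatic  = c("blue", "red"),
  G_hydrophobic    = c("yellow", "white"),
  G_hba            = c("red", "magenta"),
  G_hbd            = c("purple", "cyan"))

#' Extract favored/disfavored contour regions from a fitted model
#'
#' Scores every retained grid point of one field by its SD-weighted
#' coefficient \eqn{s_j = c_j \sigma_j} (the conventional contour
#' statistic for grid-based QSAR: the coefficient alone overweights
#' low-variance points).  Points at or above the \code{pos_pct} percentile
#' of the scores form the favored set, points at or below the
#' \code{neg_pct} percentile the disfavored set; ties at a shared
#' threshold go to the favored set so the two sets are always disjoint.
#' Each set carries a connected-component label (26-neighborhood on the
#' lattice) so distinct spatial regions can be referred to individually.
#'
#' @param model a \linkS4class{QsarModel}.
#' @param field_type one of the model's field types.
#' @param pos_pct,neg_pct percentile thresholds, 0 < neg_pct < pos_pct
#'   < 100 (defaults 90/10).
#' @return a \linkS4class{ContourSet}; when every score is identical the
#'   sets are empty and a warning is issued.
#' @export
extractContours <- function(model, field_type, pos_pct = 90,
                            neg_pct = 10) {
  if (!field_type %in% model@field_types)
    stop("field '", field_type, "' is not part of this model")
  if (!(neg_pct > 0 && neg_pct <= pos_pct && pos_pct < 100))
    stop("need 0 < neg_pct <= pos_pct < 100")
  k <- which(model@field_types == field_type)
  sel <- model@col_field == field_type
  s <- model@coefficients[sel] * model@col_sd[sel]
  coords <- model@coords[[k]]
  pidx <- model@point_index[[k]]
  colors <- .CONTOUR_COLORS[[field_type]]
  empty <- data.frame(x = numeric(), y = numeric(), z = numeric(),
                      score = numeric(), point_index = integer(),
                      component = integer())
  if (max(s) - min(s) < .Machine$double.eps * max(1, abs(max(s)))) {
    warning("all contour scores for ", field_type,
            " are identical; returning empty contour sets")
    return(new("ContourSet", field_type = field_type, favored = empty,
               disfavored = empty, pos_threshold = Inf,
               neg_threshold = -Inf, colors = colors))
  }
  pos_thr <- unname(stats::quantile(s, pos_pct / 100))
  neg_thr <- unname(stats::quantile(s, neg_pct / 100))
  fav <- s >= pos_thr
  dis <- (s <= neg_thr) & !fav
  mk <- function(keep) {
    d <- data.frame(x = coords[keep, 1], y = coords[keep, 2],
                    z = coords[keep, 3], score = s[keep],
                    point_index = pidx[keep])
    d$component <- .connected_components(d[, c("x", "y", "z")],
                                         spacing = .guess_spacing(coords))
    d
  }
  new("ContourSet", field_type = field_type,
      favored = mk(fav), disfavored = mk(dis),
      pos_threshold = pos_thr, neg_threshold = neg_thr, colors = colors)
}

.guess_spacing <- function(coords) {
  ux <- sort(unique(round(coords[, 1], 9)))
  if (length(ux) > 1) min(diff(ux)) else 1
}

## union-find over lattice points; neighbors = 26-adjacent cells
.connected_components <- function(xyz, spacing = 1) {
  n <- nrow(xyz)
  if (!n) return(integer(0))
  key <- apply(round(as.matrix(xyz) / spacing), 1, paste, collapse = ",")
  idx <- stats::setNames(seq_len(n), key)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  cells <- round(as.matrix(xyz) / spacing)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  for (i in seq_len(n)) {
    nb <- sweep(offs, 2, as.numeric(cells[i, ]), "+")
    nbkey <- apply(nb, 1, paste, collapse = ",")
    js <- idx[nbkey]
    for (j in js[!is.na(js)]) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[ri] <- rj
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  as.integer(factor(roots))
}

#' Write a scalar field or contour set as an OpenDX volumetric file
#'
#' Produces a regular-grid OpenDX (.dx) file loadable by standard
#' molecular viewers (PyMOL, VMD, Chimera).  Values are laid out in the
#' conventional z-fastest order; lattice points that are masked, filtered
#' out, or outside the contour set are written as 0.
#'
#' @param x either a numeric vector with one value per retained/active
#'   point together with \code{point_index} giving their linear lattice
#'   indices, or a \linkS4class{ContourSet} (scores are written, favored
#'   positive / disfavored negative), or a \linkS4class{FieldBlock} row
#'   (pass \code{row}).
#' @param grid a \linkS4class{GridSpec} or \linkS4class{FieldGrid}
#'   consistent with the point indices.
#' @param path output file.
#' @param point_index linear lattice indices (x-fastest) for a bare
#'   numeric \code{x}.
#' @param row molecule row to export when \code{x} is a
#'   \linkS4class{FieldBlock}.
#' @return \code{path}, invisibly.
#' @export
writeDx <- function(x, grid, path, point_index = NULL, row = 1L) {
  spec <- if (is(grid, "FieldGrid")) grid@spec else grid
  full <- numeric(prod(spec@dims))
  if (is(x, "ContourSet")) {
    full[x@favored$point_index] <- x@favored$score
    full[x@disfavored$point_index] <- x@disfavored$score
  } else if (is(x, "FieldBlock")) {
    full[x@point_index] <- x@values[row, ]
  } else {
    if (is.null(point_index)) {
      if (is(grid, "FieldGrid") && sum(grid@active_mask) == length(x))
        point_index <- which(grid@active_mask)
      else if (length(x) == length(full))
        point_index <- seq_along(full)
      else stop("supply 'point_index' for a bare numeric vector")
    }
    full[point_index] <- x
  }
  nx <- spec@dims[1]; ny <- spec@dims[2]; nz <- spec@dims[3]
  ## reorder from x-fastest storage to z-fastest file order
  arr <- array(full, dim = c(nx, ny, nz))
  vals <- as.numeric(aperm(arr, c(3, 2, 1)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# OpenDX scalar field written by fieldqsar",
    sprintf("object 1 class gridpositions counts %d %d %d", nx, ny, nz),
    sprintf("origin %.6f %.6f %.6f", spec@origin[1], spec@origin[2],
            spec@origin[3]),
    sprintf("delta %.6f 0.000000 0.000000", spec@spacing),
    sprintf("delta 0.000000 %.6f 0.000000", spec@spacing),
    sprintf("delta 0.000000 0.000000 %.6f", spec@spacing),
    sprintf("object 2 class gridconnections counts %d %d %d", nx, ny, nz),
    sprintf("object 3 class array type double rank 0 items %d data follows",
            length(vals))), con)
  writeLines(vapply(split(vals, ceiling(seq_along(vals) / 3)),
                    function(v) paste(sprintf("%.6e", v), collapse = " "),
                    character(1)), con)
  writeLines(c('attribute "dep" string "positions"',
               'object "regular positions regular connections" class field',
               'component "positions" value 1',
               'component "connections" value 2',
               'component "data" value 3'), con)
  invisible(path)
}

#' Read a regular-grid OpenDX file written by \code{\link{writeDx}}
#'
#' @param path .dx file.
#' @return list with \code{spec} (a \linkS4class{GridSpec}) and
#'   \code{values} (numeric vector in the package's x-fastest order).
#' @export
readDx <- function(path) {
  lines <- readLines(path, warn = FALSE)
  cl <- grep("class gridpositions counts", lines, value = TRUE)[1]
  dims <- as.integer(strsplit(sub(".*counts +", "", cl), " +")[[1]])
  org <- as.numeric(strsplit(sub("^origin +", "",
    grep("^origin", lines, value = TRUE)[1]), " +")[[1]])
  deltas <- grep("^delta", lines, value = TRUE)
  sp <- as.numeric(strsplit(sub("^delta +", "", deltas[1]), " +")[[1]])[1]
  i0 <- grep("data follows", lines)[1]
  i1 <- grep("^attribute", lines)[1]
  vals <- as.numeric(unlist(strsplit(trimws(lines[(i0 + 1):(i1 - 1)]),
                                     " +")))
  arr <- array(vals, dim = rev(dims))      # file is z-fastest
  list(spec = new("GridSpec", origin = org, spacing = sp, dims = dims,
                  margin = NA_real_),
       values = as.numeric(aperm(arr, c(3, 2, 1))))
}

#' Summarize contour regions as JSON
#'
#' Centroid, point count and approximate volume (points x spacing^3) of
#' every connected component in a contour set.
#'
#' @param cs a \linkS4class{ContourSet}.
#' @param spacing lattice spacing, Angstrom.
#' @param path optional JSON output file.
#' @return data.frame of region summaries, invisibly when writing.
#' @export
contourSummary <- function(cs, spacing = 1, path = NULL) {
  one <- function(d, label) {
    if (!nrow(d)) return(NULL)
    do.call(rbind, lapply(split(d, d$component), function(g)
      data.frame(set = label, component = g$component[1],
                 n_points = nrow(g), volume = nrow(g) * spacing^3,
                 x = mean(g$x), y = mean(g$y), z = mean(g$z),
                 mean_score = mean(g$score))))
  }
  out <- rbind(one(cs@favored, "favored"), one(cs@disfavored, "disfavored"))
  if (is.null(out))
    out <- data.frame(set = character(), component = integer(),
                      n_points = integer(), volume = numeric(),
                      x = numeric(), y = numeric(), z = numeric(),
                      mean_score = numeric())
  rownames(out) <- NULL
  if (!is.null(path)) {
    jsonlite::write_json(out, path, digits = NA, dataframe = "rows")
    return(invisible(out))
  }
  out
}
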