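#' @include AllClasses.R AllGenerics.R
NULL

#' Convert an EC50 in nanomolar to pEC50
#'
#' pEC50 is the negative decadic logarithm of the molar EC50, so an EC50 of
#' 1 nM (1e-9 M) corresponds to pEC50 9.
#'
#' @param ec50_nM numeric vector of EC50 values, nanomolar; all > 0.
#' @return numeric vector of pEC50 values: \code{9 - log10(ec50_nM)}.
#' @examples
#' pEC50FromEC50(c(1, 10, 0.1))   # 9, 8, 10
#' @export
pEC50FromEC50 <- function(ec50_nM) {
  ec50_nM <- as.numeric(ec50_nM)
  if (any(!is.finite(ec50_nM)) || any(ec50_nM <= 0))
    stop("EC50 values must be finite and > 0 (got ",
         paste(format(ec50_nM[!is.finite(ec50_nM) | ec50_nM <= 0]),
               collapse = ", "), ")")
  9 - log10(ec50_nM)
}

#' Residual between experimental and calculated pEC50
#'
#' @param exp_p,calc_p numeric vectors, experimental and calculated pEC50.
#' @return \code{exp_p - calc_p} (full precision; round only for display).
#' @export
residualValue <- function(exp_p, calc_p) {
  stopifnot(is.finite(exp_p), is.finite(calc_p))
  exp_p - calc_p
}

## --- SDF input ---------------------------------------------------------

.split_sdf_records <- function(lines) {
  ends <- grep("^\\$\\$\\$\\$", lines)
  if (!length(ends)) ends <- length(lines)
  starts <- c(1L, head(ends, -1L) + 1L)
  keep <- starts <= length(lines)
  recs <- Map(function(s, e) lines[s:min(e, length(lines))],
              starts[keep], ends[keep])
  recs[vapply(recs, function(r) any(nzchar(trimws(r))), logical(1))]
}

.parse_sdf_record <- function(rec_lines, index) {
  txt <- paste(c(rec_lines, if (!any(grepl("^\\$\\$\\$\\$", rec_lines))) "$$$$"),
               collapse = "\n")
  parsed <- tryCatch({
    ## ChemmineR warns on zero-bond records; the count cross-check below
    ## is the validity test we actually rely on
    set <- suppressWarnings(
      ChemmineR::read.SDFset(ChemmineR::read.SDFstr(textConnection(txt))))
    sdf <- set[[1]]
    ab <- ChemmineR::atomblock(sdf)
    bb <- ChemmineR::bondblock(sdf)
    ## cross-check the declared counts; a zero-bond record is legal
    n_decl <- suppressWarnings(as.integer(substr(rec_lines[4], 1, 3)))
    b_decl <- suppressWarnings(as.integer(substr(rec_lines[4], 4, 6)))
    if (is.na(n_decl) || n_decl < 1L || !is.matrix(ab) ||
        nrow(ab) != n_decl)
      stop("invalid V2000 atom block")
    nb <- if (is.matrix(bb) && ncol(bb) >= 3L) nrow(bb) else 0L
    if (!is.na(b_decl) && b_decl > 0L && nb != b_decl)
      stop("invalid V2000 bond block")
    if (nb == 0L) bb <- matrix(integer(0), 0, 3)
    list(sdf = sdf, ab = ab, bb = bb)
  }, error = function(e)
    stop("SDF record ", index, " is malformed: ", conditionMessage(e),
         call. = FALSE))
  sdf <- parsed$sdf; ab <- parsed$ab; bb <- parsed$bb
  atoms <- data.frame(
    element = sub("_[0-9]+$", "", rownames(ab)),
    x = as.numeric(ab[, 1]), y = as.numeric(ab[, 2]),
    z = as.numeric(ab[, 3]), charge = 0,
    stringsAsFactors = FALSE)
  bonds <- if (is.matrix(bb) && nrow(bb))
    data.frame(a1 = as.integer(bb[, 1]), a2 = as.integer(bb[, 2]),
               order = as.integer(bb[, 3]))
  else data.frame(a1 = integer(), a2 = integer(), order = integer())
  db <- tryCatch(ChemmineR::datablock(sdf), error = function(e) character())
  id <- trimws(ChemmineR::header(sdf)[1])
  list(atoms = atoms, bonds = bonds, data = db, id = id)
}

.parse_charge_field <- function(txt, n, index) {
  vals <- suppressWarnings(as.numeric(
    strsplit(trimws(txt), "[,;[:space:]]+")[[1]]))
  if (length(vals) != n || any(is.na(vals)))
    stop("SDF record ", index, ": charge field must hold ", n,
         " numeric values", call. = FALSE)
  vals
}

## Gasteiger charges for a whole SDF file via the Open Babel CLI
## (mol2 output carries one partial charge per atom).
.gasteiger_charges <- function(path, n_atoms_per_mol) {
  if (!nzchar(Sys.which("obabel"))) {
    warning("obabel not found on PATH; partial charges set to 0")
    return(lapply(n_atoms_per_mol, function(n) rep(0, n)))
  }
  out <- suppressWarnings(system2("obabel",
    c(shQuote(path), "-omol2", "--partialcharge", "gasteiger"),
    stdout = TRUE, stderr = FALSE))
  starts <- grep("^@<TRIPOS>ATOM", out)
  charges <- lapply(seq_along(starts), function(k) {
    i <- starts[k] + 1L
    vals <- numeric()
    while (i <= length(out) && !grepl("^@<TRIPOS>", out[i])) {
      f <- strsplit(trimws(out[i]), "[[:space:]]+")[[1]]
      vals <- c(vals, as.numeric(f[length(f)]))
      i <- i + 1L
    }
    vals
  })
  if (length(charges) != length(n_atoms_per_mol) ||
      !all(lengths(charges) == n_atoms_per_mol)) {
    warning("obabel charge output did not match molecule list; charges set to 0")
    return(lapply(n_atoms_per_mol, function(n) rep(0, n)))
  }
  charges
}

#' Read an aligned molecular series from an SDF V2000 file
#'
#' Each record becomes an \linkS4class{AlignedMolecule}; coordinates are
#' preserved exactly and never re-oriented.  Activity is taken from the
#' \code{pEC50} data field when present, otherwise from \code{EC50_nM}
#' (converted with \code{\link{pEC50FromEC50}}); records carrying neither
#' are loaded with activity unset, which is normal for prediction-only
#' molecules.  Per-atom partial charges are read from a data field holding
#' one number per atom; when the field is absent, Gasteiger-type charges
#' are computed with Open Babel (\code{charges = "gasteiger"}), a
#' reproducibility caveat relative to quantum-derived charge schemes.
#'
#' @param path SDF V2000 file with 3D coordinates.
#' @param activity_field,ec50_field data field names for pEC50 and for
#'   nanomolar EC50 (checked in that order).
#' @param charge_field data field holding whitespace/comma-separated
#'   per-atom partial charges.
#' @param charges charge source when \code{charge_field} is absent:
#'   \code{"gasteiger"} (default, Open Babel) or \code{"zero"}.
#' @return list of \linkS4class{AlignedMolecule}; a record whose z
#'   coordinates are all zero is flagged \code{flat} with a warning.
#' @seealso \code{\link{writeSdf}}, \code{\link{assignParameters}}
#' @export
readSdf <- function(path, activity_field = "pEC50", ec50_field = "EC50_nM",
                    charge_field = "PARTIAL_CHARGES",
                    charges = c("gasteiger", "zero")) {
  charges <- match.arg(charges)
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  recs <- .split_sdf_records(lines)
  if (!length(recs)) stop("no SDF records found in ", path)
  parsed <- lapply(seq_along(recs),
                   function(i) .parse_sdf_record(recs[[i]], i))

  need_gast <- vapply(parsed, function(p) !charge_field %in% names(p$data),
                      logical(1))
  gast <- NULL
  if (charges == "gasteiger" && any(need_gast))
    gast <- .gasteiger_charges(path, vapply(parsed, function(p)
      nrow(p$atoms), integer(1)))

  ids_seen <- character()
  mols <- vector("list", length(parsed))
  for (i in seq_along(parsed)) {
    p <- parsed[[i]]
    id <- if (nzchar(p$id)) p$id else paste0("mol", i)
    if (id %in% ids_seen) id <- paste0(id, "_", i)
    ids_seen <- c(ids_seen, id)
    if (charge_field %in% names(p$data))
      p$atoms$charge <- .parse_charge_field(p$data[[charge_field]],
                                            nrow(p$atoms), i)
    else if (!is.null(gast))
      p$atoms$charge <- gast[[i]]
    act <- NA_real_
    if (activity_field %in% names(p$data))
      act <- as.numeric(p$data[[activity_field]])
    else if (ec50_field %in% names(p$data))
      act <- pEC50FromEC50(as.numeric(p$data[[ec50_field]]))
    flat <- all(p$atoms$z == 0)
    if (flat)
      warning("record ", i, " (", id, "): all z coordinates are zero; ",
              "molecule looks 2D", call. = FALSE)
    mols[[i]] <- new("AlignedMolecule", id = id, atoms = p$atoms,
                     bonds = p$bonds, activity = act, flat = flat)
  }
  mols
}

#' Write aligned molecules to an SDF V2000 file
#'
#' Emits one V2000 record per molecule: coordinates at 4 decimals, the bond
#' block, a \code{pEC50} data field when activity is set, and a
#' \code{PARTIAL_CHARGES} data field holding the per-atom charges, so a
#' read/write round trip preserves geometry, activity and charges.
#'
#' @param mols list of \linkS4class{AlignedMolecule}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeSdf <- function(mols, path) {
  if (is(mols, "AlignedMolecule")) mols <- list(mols)
  con <- file(path, "w")
  on.exit(close(con))
  for (m in mols) {
    a <- m@atoms; b <- m@bonds
    writeLines(c(m@id, "  fieldqsar", ""), con)
    writeLines(sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                       nrow(a), nrow(b)), con)
    writeLines(sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                       a$x, a$y, a$z, a$element), con)
    if (nrow(b))
      writeLines(sprintf("%3d%3d%3d  0", b$a1, b$a2, b$order), con)
    writeLines("M  END", con)
    if (!is.na(m@activity))
      writeLines(c(">  <pEC50>", format(m@activity, digits = 10), ""), con)
    writeLines(c(">  <PARTIAL_CHARGES>",
                 paste(format(a$charge, digits = 8), collapse = " "), "",
                 "$$$$"), con)
  }
  invisible(path)
}

## --- atom parameterization ---------------------------------------------

#' Bundled per-element interaction parameters
#'
#' Bondi van der Waals radii (Angstrom), Lennard-Jones well depths
#' (kcal/mol) and coarse Crippen-style hydrophobicity atom constants for
#' the elements H, C, N, O, F, P, S, Cl, Br, I.
#'
#' @return data.frame with columns \code{element}, \code{vdw_radius},
#'   \code{epsilon}, \code{hydrophobicity}.
#' @export
defaultAtomParams <- function() {
  utils::read.csv(system.file("extdata", "atom_params.csv",
                              package = "fieldqsar"),
                  stringsAsFactors = FALSE)
}

#' Assign probe-interaction parameters and H-bond flags to every atom
#'
#' Looks up van der Waals radius, well depth and hydrophobicity constant by
#' element, and sets hydrogen-bond flags by rule: a donor (\code{is_hbd})
#' is a hydrogen bonded to N or O; an acceptor (\code{is_hba}) is an N or O
#' that is neither positively charged (total bond order >= 4 for N) nor an
#' amide-like N (N single-bonded to a carbon that is double-bonded to O or
#' S).  All atoms must be parameterizable before any field computation.
#'
#' @param mol an \linkS4class{AlignedMolecule} (bond block required for the
#'   H-bond rules; a molecule without bonds gets all flags \code{FALSE}
#'   except element-level acceptors).
#' @param params parameter table as from \code{\link{defaultAtomParams}}.
#' @return the molecule with \code{vdw_radius}, \code{epsilon},
#'   \code{hydrophobicity}, \code{is_hbd}, \code{is_hba} columns filled.
#' @export
assignParameters <- function(mol, params = defaultAtomParams()) {
  a <- mol@atoms
  idx <- match(a$element, params$element)
  if (anyNA(idx))
    stop("unparameterized element(s): ",
         paste(unique(a$element[is.na(idx)]), collapse = ", "),
         " at atom(s) ", paste(which(is.na(idx)), collapse = ", "))
  a$vdw_radius <- params$vdw_radius[idx]
  a$epsilon <- params$epsilon[idx]
  a$hydrophobicity <- params$hydrophobicity[idx]

  n <- nrow(a)
  b <- mol@bonds
  nb <- function(i) c(b$a2[b$a1 == i], b$a1[b$a2 == i])
  bond_order_sum <- vapply(seq_len(n), function(i)
    sum(b$order[b$a1 == i | b$a2 == i]), numeric(1))
  a$is_hbd <- vapply(seq_len(n), function(i)
    a$element[i] == "H" && any(a$element[nb(i)] %in% c("N", "O")),
    logical(1))
  is_amide_n <- vapply(seq_len(n), function(i) {
    if (a$element[i] != "N") return(FALSE)
    carbons <- nb(i)
    carbons <- carbons[a$element[carbons] == "C"]
    any(vapply(carbons, function(cc) {
      dbl <- b$order == 2 & (b$a1 == cc | b$a2 == cc)
      partners <- c(b$a2[dbl & b$a1 == cc], b$a1[dbl & b$a2 == cc])
      any(a$element[partners] %in% c("O", "S"))
    }, logical(1)))
  }, logical(1))
  a$is_hba <- (a$element %in% c("N", "O")) &
    !(a$element == "N" & bond_order_sum >= 4) & !is_amide_n
  mol@atoms <- a
  validObject(mol)
  mol
}

## --- experimental/calculated activity tables ---------------------------

#' Load an experimental/calculated activity table
#'
#' Reads a six-column CSV (compound id; experimental pEC50; calculated
#' pEC50 and residual for the force-field model; calculated pEC50 and
#' residual for the Gaussian-field model), normalizes U+2212 minus signs,
#' and checks per row that residual = experimental - calculated to printed
#' precision (|discrepancy| <= 0.001 allows for 3-decimal rounding).
#'
#' @param path CSV file with a header row; the packaged transcription is at
#'   \code{system.file("extdata", "table3_fixture.csv", package = "fieldqsar")}.
#' @return data.frame with the six columns plus logical
#'   \code{consistent_ff} and \code{consistent_gf}; inconsistent rows
#'   trigger a warning naming the compound ids.
#' @export
loadActivityFixture <- function(path) {
  raw <- readLines(path, warn = FALSE)
  raw <- gsub("−", "-", raw)
  nf <- utils::count.fields(textConnection(raw), sep = ",")
  bad <- which(nf != 6L)
  if (length(bad))
    stop("expected 6 comma-separated columns; line ", bad[1],
         " has ", nf[bad[1]])
  d <- utils::read.csv(textConnection(raw), stringsAsFactors = FALSE,
                       col.names = c("compound_id", "pec50_exp",
                                     "pec50_calc_ff", "res_ff",
                                     "pec50_calc_gf", "res_gf"))
  tol <- 0.001 + 1e-9
  d$consistent_ff <- abs((d$pec50_exp - d$pec50_calc_ff) - d$res_ff) <= tol
  d$consistent_gf <- abs((d$pec50_exp - d$pec50_calc_gf) - d$res_gf) <= tol
  viol <- d$compound_id[!(d$consistent_ff & d$consistent_gf)]
  if (length(viol))
    warning("residual inconsistency for compound(s): ",
            paste(viol, collapse = ", "))
  d
}
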