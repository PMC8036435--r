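#' @include AllClasses.R chem-io.R
NULL

.parse_formula <- function(f) {
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", f)[[1]]
  parts <- regmatches(f, gregexpr("([A-Z][a-z]?)([0-9]*)", f))[[1]]
  el <- sub("[0-9]+$", "", parts)
  ct <- as.integer(sub("^[A-Za-z]+", "", parts))
  ct[is.na(ct)] <- 1L
  stats::setNames(ct, el)
}

.largest_smiles_fragment <- function(smi) {
  frags <- strsplit(smi, ".", fixed = TRUE)[[1]]
  heavy <- vapply(frags, function(f)
    length(gregexpr("[A-Za-z]", gsub("H", "", f))[[1]]), integer(1))
  frags[which.max(heavy)]
}

#' Physicochemical descriptors for drug-likeness screening
#'
#' Computes, per molecule: molecular weight (g/mol), Wildman-Crippen-type
#' logP, Ertl topological polar surface area (A^2), molar refractivity
#' and rotatable-bond count via Open Babel, plus hydrogen-bond donor
#' count (Open Babel) and Lipinski-style acceptor count (number of N + O
#' atoms, from the molecular formula) and the total atom count including
#' hydrogens.  One logP estimator is used for every rule filter; the
#' estimator is named in the \code{logp_estimator} attribute of the
#' result.
#'
#' @param x input molecules: a character vector of SMILES, the path of an
#'   SDF file, or a list of \linkS4class{AlignedMolecule} (written out
#'   with their bond blocks).  A SMILES containing disconnected
#'   components (salt dots) is reduced to its largest fragment with a
#'   warning.
#' @return data.frame with columns \code{id}, \code{mw}, \code{logp},
#'   \code{hbd_count}, \code{hba_count}, \code{rotatable_bonds},
#'   \code{tpsa}, \code{molar_refractivity},
#'   \code{heavy_plus_h_atom_count}.
#' @examples
#' \dontrun{computeDescriptors("CCO")  # ethanol: 1 donor, 1 acceptor}
#' @export
computeDescriptors <- function(x) {
  if (!nzchar(Sys.which("obabel")))
    stop("computeDescriptors requires the Open Babel CLI (obabel) on PATH")
  tmp <- NULL
  if (is.list(x) && all(vapply(x, is, logical(1), "AlignedMolecule"))) {
    tmp <- tempfile(fileext = ".sdf")
    writeSdf(x, tmp)
    infile <- tmp; informat <- character(0)
    ids <- vapply(x, molId, character(1))
  } else if (is.character(x) && length(x) == 1L && file.exists(x)) {
    infile <- x; informat <- character(0)
    ids <- NULL
  } else if (is.character(x)) {
    if (any(grepl(".", x, fixed = TRUE))) {
      warning("disconnected components in SMILES; using largest fragment")
      x <- vapply(x, .largest_smiles_fragment, character(1))
    }
    tmp <- tempfile(fileext = ".smi")
    ids <- if (!is.null(names(x))) names(x) else paste0("mol", seq_along(x))
    writeLines(paste(x, ids), tmp)
    infile <- tmp; informat <- "-ismi"
  } else stop("unsupported input type")
  on.exit(if (!is.null(tmp)) unlink(tmp))

  out <- suppressWarnings(system2("obabel",
    c(informat, shQuote(infile), "-otxt", "--append",
      shQuote("formula MW logP TPSA MR rotors HBD")),
    stdout = TRUE, stderr = FALSE))
  out <- out[nzchar(trimws(out))]
  if (!length(out)) stop("obabel produced no descriptor output")
  rows <- lapply(seq_along(out), function(i) {
    f <- strsplit(trimws(out[i]), "[[:space:]]+")[[1]]
    nf <- length(f)
    if (nf < 7) stop("unparseable obabel output line: ", out[i])
    num <- as.numeric(f[(nf - 5):nf])
    formula <- f[nf - 6]
    title <- if (nf > 7) paste(f[1:(nf - 7)], collapse = " ") else ""
    comp <- .parse_formula(formula)
    data.frame(
      id = if (nzchar(title)) title else paste0("mol", i),
      mw = num[1], logp = num[2], tpsa = num[3],
      molar_refractivity = num[4], rotatable_bonds = as.integer(num[5]),
      hbd_count = as.integer(num[6]),
      hba_count = sum(comp[names(comp) %in% c("N", "O")]),
      heavy_plus_h_atom_count = sum(comp),
      stringsAsFactors = FALSE)
  })
  d <- do.call(rbind, rows)
  if (!is.null(ids) && length(ids) == nrow(d)) d$id <- ids
  d <- d[, c("id", "mw", "logp", "hbd_count", "hba_count",
             "rotatable_bonds", "tpsa", "molar_refractivity",
             "heavy_plus_h_atom_count")]
  attr(d, "logp_estimator") <- "Open Babel (Wildman-Crippen atom types)"
  d
}

.viol <- function(cond, name, value, bound) {
  if (cond) sprintf("%s %g %s", name, value, bound) else character(0)
}

#' Apply the four rule-based drug-likeness filters
#'
#' Pure function of a descriptor row (no structure re-reads).  Filters:
#' Lipinski rule of five (MW <= 500, logP <= 5, HBD <= 5, HBA <= 10; the
#' original usage tolerates one violation, so both the tolerant verdict
#' (\code{pass}) and the strict one (\code{pass_strict}) are reported);
#' Ghose (160 <= MW <= 480, -0.4 <= logP <= 5.6, 40 <= MR <= 130,
#' 20 <= atoms <= 70, strict); Veber (rotatable bonds <= 10 and TPSA
#' <= 140); Egan (logP <= 5.88 and TPSA <= 131.6).  All bounds are
#' inclusive.  Every violation string names the descriptor, its value and
#' the violated bound.
#'
#' @param d a single-row data.frame as produced by
#'   \code{\link{computeDescriptors}} (or a named list with the same
#'   fields).
#' @return list with elements \code{lipinski}, \code{ghose},
#'   \code{veber}, \code{egan}; each holds \code{pass} and
#'   \code{violations} (and \code{pass_strict} for Lipinski).
#' @export
applyRules <- function(d) {
  d <- as.list(d)
  lip <- c(.viol(d$mw > 500, "MW", d$mw, "> 500"),
           .viol(d$logp > 5, "logP", d$logp, "> 5"),
           .viol(d$hbd_count > 5, "HBD", d$hbd_count, "> 5"),
           .viol(d$hba_count > 10, "HBA", d$hba_count, "> 10"))
  gho <- c(.viol(d$mw < 160, "MW", d$mw, "< 160"),
           .viol(d$mw > 480, "MW", d$mw, "> 480"),
           .viol(d$logp < -0.4, "logP", d$logp, "< -0.4"),
           .viol(d$logp > 5.6, "logP", d$logp, "> 5.6"),
           .viol(d$molar_refractivity < 40, "MR", d$molar_refractivity,
                 "< 40"),
           .viol(d$molar_refractivity > 130, "MR", d$molar_refractivity,
                 "> 130"),
           .viol(d$heavy_plus_h_atom_count < 20, "atoms",
                 d$heavy_plus_h_atom_count, "< 20"),
           .viol(d$heavy_plus_h_atom_count > 70, "atoms",
                 d$heavy_plus_h_atom_count, "> 70"))
  veb <- c(.viol(d$rotatable_bonds > 10, "rotatable bonds",
                 d$rotatable_bonds, "> 10"),
           .viol(d$tpsa > 140, "TPSA", d$tpsa, "> 140"))
  ega <- c(.viol(d$logp > 5.88, "logP", d$logp, "> 5.88"),
           .viol(d$tpsa > 131.6, "TPSA", d$tpsa, "> 131.6"))
  list(
    lipinski = list(pass = length(lip) <= 1L, pass_strict = !length(lip),
                    violations = lip),
    ghose = list(pass = !length(gho), violations = gho),
    veber = list(pass = !length(veb), violations = veb),
    egan = list(pass = !length(ega), violations = ega))
}

#' Rule-filter table for a set of molecules
#'
#' One row per molecule, one yes/no column per rule filter, shaped like
#' the drug-likeness tables of the QSAR literature.  No
#' synthetic-accessibility column is produced: that score depends on an
#' external fragment-frequency corpus and is out of this package's scope.
#'
#' @param desc data.frame from \code{\link{computeDescriptors}}.
#' @param path optional CSV output file.
#' @return data.frame with columns \code{id}, \code{lipinski},
#'   \code{ghose}, \code{veber}, \code{egan} ("yes"/"no") and
#'   \code{lipinski_strict}.
#' @export
druglikenessTable <- function(desc, path = NULL) {
  yn <- function(x) ifelse(x, "yes", "no")
  rows <- lapply(seq_len(nrow(desc)), function(i) {
    r <- applyRules(desc[i, ])
    data.frame(id = desc$id[i],
               lipinski = yn(r$lipinski$pass),
               lipinski_strict = yn(r$lipinski$pass_strict),
               ghose = yn(r$ghose$pass),
               veber = yn(r$veber$pass),
               egan = yn(r$egan$pass),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!is.null(path)) utils::write.csv(out, path, row.names = FALSE)
  out
}
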