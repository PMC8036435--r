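#' @include AllClasses.R AllGenerics.R fields.R pls.R
NULL

.default_scaffold <- function() {
  ## rigid amide + aliphatic linker + basic amine motif, already
  ## parameterized; identical (exact coordinates) in every generated
  ## molecule, which is what mutual alignment of a rigid series means
  data.frame(
    element = c("C", "O", "N", "H", "C", "C", "C", "N", "C", "C"),
    x = c(0.0, 0.0, 1.2, 1.2, 2.5, 3.7, 4.9, 6.1, -1.3, -2.5),
    y = c(0.0, 1.25, -0.7, -1.7, -0.1, -0.9, -0.1, -0.8, -0.8, 0.0),
    z = c(0.0, 0.0, 0.0, 0.0, 0.0, 0.4, 0.8, 1.2, 0.0, 0.0),
    charge = c(0.30, -0.45, -0.35, 0.20, 0.05, 0.05, 0.05, -0.40,
               0.00, 0.00),
    vdw_radius = c(1.70, 1.52, 1.55, 1.20, 1.70, 1.70, 1.70, 1.55,
                   1.70, 1.70),
    epsilon = c(0.10, 0.21, 0.17, 0.03, 0.10, 0.10, 0.10, 0.17,
                0.10, 0.10),
    hydrophobicity = c(0.36, -0.40, -0.60, 0.12, 0.36, 0.36, 0.36,
                       -0.60, 0.36, 0.36),
    is_hbd = c(FALSE, FALSE, FALSE, TRUE, FALSE, FALSE, FALSE, FALSE,
               FALSE, FALSE),
    is_hba = c(FALSE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE, TRUE,
               FALSE, FALSE),
    stringsAsFactors = FALSE)
}

## candidate substituents: small parameterized atom groups positioned
## relative to an attachment site
.default_substituents <- function() {
  at <- function(element, dx, dy, dz, charge, r, eps, hyd, hbd, hba)
    data.frame(element = element, x = dx, y = dy, z = dz,
               charge = charge, vdw_radius = r, epsilon = eps,
               hydrophobicity = hyd, is_hbd = hbd, is_hba = hba,
               stringsAsFactors = FALSE)
  list(
    hydrogen = at("H", 0, 0, 0, 0.05, 1.20, 0.03, 0.12, FALSE, FALSE),
    methyl   = at("C", 0, 0, 0, 0.00, 1.70, 0.10, 0.36, FALSE, FALSE),
    hydroxyl = rbind(
      at("O", 0, 0, 0, -0.45, 1.52, 0.21, -0.40, FALSE, TRUE),
      at("H", 0.65, 0.75, 0, 0.30, 1.20, 0.03, 0.12, TRUE, FALSE)),
    chloro   = at("Cl", 0, 0, 0, -0.20, 1.75, 0.30, 0.65, FALSE, FALSE),
    ## acceptor-only oxygen so the donor and acceptor indicator fields are
    ## not collinear across the palette (hydroxyl/amino carry both)
    etherO   = at("O", 0, 0, 0, -0.35, 1.52, 0.21, -0.40, FALSE, TRUE),
    amino    = rbind(
      at("N", 0, 0, 0, -0.70, 1.55, 0.17, -0.60, FALSE, TRUE),
      at("H", 0.65, 0.75, 0, 0.35, 1.20, 0.03, 0.12, TRUE, FALSE)))
}

#' Specification of a synthetic aligned-molecule series
#'
#' Defines the study conditions the generator emulates: a rigid shared
#' scaffold, substituent attachment sites with candidate atom groups, a
#' planted field-space activity model (each effect term reads the mean of
#' one field type over a spherical grid region and multiplies it by a
#' weight), Gaussian activity noise, and a seed.  Effects are planted in
#' field space rather than atom space so that an error anywhere in the
#' grid / field / PLS plumbing breaks parameter recovery.
#'
#' @param n_molecules series size, >= 8 (default 40).
#' @param noise_sd activity noise SD, pEC50 units (default 0.2).
#' @param seed RNG seed (default 1234).
#' @param scaffold parameterized atom data.frame shared by all molecules.
#' @param substituent_sites list of sites, each with \code{position}
#'   (3-vector) and \code{options} (named list of substituent atom
#'   data.frames, coordinates relative to the site).
#' @param effects list of effect terms, each with \code{center}
#'   (3-vector), \code{radius} (Angstrom), \code{field_type} and
#'   \code{weight} (pEC50 per field unit).
#' @param intercept baseline activity, pEC50.
#' @return a validated list of class \code{"SyntheticSpec"}.
#' @export
syntheticSpec <- function(n_molecules = 40L, noise_sd = 0.2,
                          seed = 1234L,
                          scaffold = .default_scaffold(),
                          substituent_sites = list(
                            list(position = c(-3.8, 0.0, 0.0),
                                 options = .default_substituents()),
                            list(position = c(7.2, -1.4, 1.8),
                                 options = .default_substituents())),
                          effects = list(
                            list(center = c(-3.8, 0.0, 0.0),
                                 radius = 3.5, field_type = "G_steric",
                                 weight = 4),
                            list(center = c(7.2, -1.4, 1.8),
                                 radius = 3.5, field_type = "G_hba",
                                 weight = 3),
                            list(center = c(7.2, -1.4, 1.8),
                                 radius = 3.5, field_type = "G_hbd",
                                 weight = -2)),
                          intercept = 5.5) {
  if (n_molecules < 8L) stop("'n_molecules' must be >= 8")
  if (noise_sd < 0) stop("'noise_sd' must be >= 0")
  if (!length(effects)) stop("at least one effect term is required")
  for (s in substituent_sites)
    if (!length(s$options)) stop("a substituent site has no options")
  for (e in effects)
    if (!e$field_type %in% .FIELD_TYPES)
      stop("unknown effect field type: ", e$field_type)
  structure(list(n_molecules = as.integer(n_molecules),
                 noise_sd = noise_sd, seed = as.integer(seed),
                 scaffold = scaffold,
                 substituent_sites = substituent_sites,
                 effects = effects, intercept = intercept),
            class = "SyntheticSpec")
}

## lattice on which the generative function reads its planted regions:
## fixed by the scaffold + site positions, independent of the draws
.truth_lattice <- function(spec) {
  anchor <- rbind(as.matrix(spec$scaffold[, c("x", "y", "z")]),
                  do.call(rbind, lapply(spec$substituent_sites,
                                        function(s) s$position)))
  lo <- apply(anchor, 2, min) - 3
  hi <- apply(anchor, 2, max) + 3
  dims <- as.integer(floor(hi - lo) + 1)
  g <- new("GridSpec", origin = unname(lo), spacing = 1.0, dims = dims,
           margin = 3.0)
  gridPoints(g)
}

#' Generate a synthetic aligned series with a known activity model
#'
#' Each molecule is the fixed scaffold plus one randomly drawn substituent
#' per site (seeded); its activity is the spec's intercept plus the
#' weighted planted-region field means plus Gaussian noise.  Both the
#' molecules and the closed-form generative function are returned, so
#' tests can compare any pipeline output against ground truth.
#'
#' @param spec a \code{\link{syntheticSpec}}.
#' @return list with \code{molecules} (list of
#'   \linkS4class{AlignedMolecule}, activities set),
#'   \code{truth} (function: molecule -> noise-free activity),
#'   \code{choices} (character matrix of drawn substituent names) and
#'   \code{spec}.
#' @export
generateSeries <- function(spec) {
  stopifnot(inherits(spec, "SyntheticSpec"))
  lattice <- .truth_lattice(spec)
  region_pts <- lapply(spec$effects, function(e) {
    d2 <- (lattice[, 1] - e$center[1])^2 + (lattice[, 2] - e$center[2])^2 +
          (lattice[, 3] - e$center[3])^2
    lattice[d2 <= e$radius^2, , drop = FALSE]
  })
  region_mean <- function(mol, k) {
    e <- spec$effects[[k]]
    f <- if (e$field_type %in% c("FF_steric", "FF_electrostatic")) {
      ff <- ffFields(mol, region_pts[[k]])
      if (e$field_type == "FF_steric") ff$steric else ff$electrostatic
    } else gaussianField(mol, region_pts[[k]], e$field_type)
    mean(f)
  }
  ## effects are measured relative to the bare scaffold, so the intercept
  ## is the scaffold's own activity and values stay in a pEC50-like range
  bare <- new("AlignedMolecule", id = ".scaffold", atoms = spec$scaffold,
              activity = NA_real_)
  baseline <- vapply(seq_along(spec$effects), function(k)
    region_mean(bare, k), numeric(1))
  truth <- function(mol) {
    vals <- vapply(seq_along(spec$effects), function(k)
      spec$effects[[k]]$weight * (region_mean(mol, k) - baseline[k]),
      numeric(1))
    spec$intercept + sum(vals)
  }
  nsite <- length(spec$substituent_sites)
  res <- .with_seed(spec$seed, {
    choices <- matrix("", spec$n_molecules, nsite)
    mols <- vector("list", spec$n_molecules)
    for (i in seq_len(spec$n_molecules)) {
      atoms <- spec$scaffold
      for (s in seq_len(nsite)) {
        site <- spec$substituent_sites[[s]]
        pick <- sample(names(site$options), 1L)
        choices[i, s] <- pick
        sub <- site$options[[pick]]
        sub$x <- sub$x + site$position[1]
        sub$y <- sub$y + site$position[2]
        sub$z <- sub$z + site$position[3]
        atoms <- rbind(atoms, sub)
      }
      m <- new("AlignedMolecule", id = sprintf("syn%03d", i),
               atoms = atoms, activity = NA_real_)
      activity(m) <- truth(m) + stats::rnorm(1, 0, spec$noise_sd)
      mols[[i]] <- m
    }
    list(molecules = mols, choices = choices)
  })
  list(molecules = res$molecules, truth = truth, choices = res$choices,
       spec = spec)
}

#' End-to-end parameter-recovery harness
#'
#' Runs the full pipeline on a generated series -- grid construction,
#' exclusion mask, field blocks with variance filtering, PLS fit,
#' leave-one-out Q2 -- then predicts a fresh seeded hold-out series and
#' summarizes how well the planted effects were recovered.
#' \code{sign_agreement} is the fraction of retained grid variables lying
#' inside a planted region (matching field type) whose fitted coefficient
#' sign matches the planted weight sign; zero-weight effects are skipped.
#'
#' @param spec a \code{\link{syntheticSpec}}.
#' @param field_types fields entering the model (default: the five
#'   Gaussian fields).
#' @param n_factors PLS factors (default 5).
#' @param n_holdout hold-out series size (default 10), generated with
#'   seed \code{spec$seed + 1}.
#' @return list with \code{q2_achieved}, \code{sign_agreement},
#'   \code{rmse_holdout}, \code{r2_training}, and the fitted
#'   \code{model}.
#' @export
recoveryCheck <- function(spec = syntheticSpec(),
                          field_types = c("G_steric", "G_electrostatic",
                                          "G_hydrophobic", "G_hba",
                                          "G_hbd"),
                          n_factors = 5L, n_holdout = 10L) {
  gen <- generateSeries(spec)
  hspec <- spec
  hspec$n_molecules <- max(8L, as.integer(n_holdout))
  hspec$seed <- spec$seed + 1L
  hold <- generateSeries(hspec)
  hold_mols <- hold$molecules[seq_len(n_holdout)]

  train <- gen$molecules
  y <- vapply(train, activity, numeric(1))
  gspec <- buildGrid(train, spacing = 1.0, margin = 3.0)
  fgrid <- exclusionMask(gspec, train, min_dist = 2.0)
  blocks <- assembleBlocks(train, fgrid, field_types)
  model <- fitPls(blocks, y, n_factors)
  q2 <- looQ2(blocks, y, n_factors)
  preds <- predict(model, hold_mols)
  y_hold <- vapply(hold_mols, activity, numeric(1))
  rmse <- sqrt(mean((y_hold - preds)^2))

  agree <- total <- 0L
  for (e in spec$effects) {
    if (e$weight == 0 || !e$field_type %in% model@field_types) next
    k <- which(model@field_types == e$field_type)
    co <- model@coords[[k]]
    d2 <- (co[, 1] - e$center[1])^2 + (co[, 2] - e$center[2])^2 +
          (co[, 3] - e$center[3])^2
    inside <- d2 <= e$radius^2
    if (!any(inside)) next
    cf <- model@coefficients[model@col_field == e$field_type][inside]
    agree <- agree + sum(sign(cf) == sign(e$weight))
    total <- total + length(cf)
  }
  list(q2_achieved = q2,
       sign_agreement = if (total) agree / total else NA_real_,
       rmse_holdout = rmse,
       r2_training = model@stats$r2_training,
       model = model)
}

#' Write a generated series as an SDF + activity CSV pair
#'
#' @param gen result of \code{\link{generateSeries}}.
#' @param sdf_path,csv_path output files.
#' @return invisibly, a list of the two paths.
#' @export
writeSeries <- function(gen, sdf_path, csv_path) {
  writeSdf(gen$molecules, sdf_path)
  utils::write.csv(
    data.frame(compound_id = vapply(gen$molecules, molId, character(1)),
               pec50 = vapply(gen$molecules, activity, numeric(1))),
    csv_path, row.names = FALSE)
  invisible(list(sdf = sdf_path, csv = csv_path))
}
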