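# Shared fixtures: tiny molecules built in code, SDF text builders, and
# independent (naive) oracles for fields and PLS predictions.

# a fully parameterized atom row
patom <- function(element, x, y, z, charge = 0,
                  hbd = FALSE, hba = FALSE) {
  p <- fieldqsar::defaultAtomParams()
  i <- match(element, p$element)
  data.frame(element = element, x = x, y = y, z = z, charge = charge,
             vdw_radius = p$vdw_radius[i], epsilon = p$epsilon[i],
             hydrophobicity = p$hydrophobicity[i],
             is_hbd = hbd, is_hba = hba, stringsAsFactors = FALSE)
}

pmol <- function(id, atoms, activity = NA_real_) {
  m <- new("AlignedMolecule", id = id, atoms = atoms,
           activity = as.numeric(activity))
  m
}

# methane with explicit 3D coordinates (tetrahedral-ish)
methane_sdf <- function(pec50 = "7.0", field = "pEC50") {
  paste(c(
    "methane", "  test", "",
    "  5  4  0  0  0  0  0  0  0  0999 V2000",
    "    0.0000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
    "    0.6290    0.6290    0.6290 H   0  0  0  0  0  0  0  0  0  0  0  0",
    "   -0.6290   -0.6290    0.6290 H   0  0  0  0  0  0  0  0  0  0  0  0",
    "   -0.6290    0.6290   -0.6290 H   0  0  0  0  0  0  0  0  0  0  0  0",
    "    0.6290   -0.6290   -0.6290 H   0  0  0  0  0  0  0  0  0  0  0  0",
    "  1  2  1  0", "  1  3  1  0", "  1  4  1  0", "  1  5  1  0",
    "M  END",
    paste0(">  <", field, ">"), pec50, "", "$$$$"), collapse = "\n")
}

# N-methylacetamide-like fragment: carbonyl O, amide N-H, methyls
amide_sdf <- function() {
  paste(c(
    "nma", "  test", "",
    "  6  5  0  0  0  0  0  0  0  0999 V2000",
    "    0.0000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
    "    0.0000    1.2300    0.1000 O   0  0  0  0  0  0  0  0  0  0  0  0",
    "    1.2000   -0.7000    0.0000 N   0  0  0  0  0  0  0  0  0  0  0  0",
    "    1.2000   -1.7000    0.0500 H   0  0  0  0  0  0  0  0  0  0  0  0",
    "    2.5000   -0.1000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
    "   -1.3000   -0.8000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
    "  1  2  2  0", "  1  3  1  0", "  3  4  1  0", "  3  5  1  0",
    "  1  6  1  0",
    "M  END",
    ">  <pEC50>", "8.0", "", "$$$$"), collapse = "\n")
}

# small seeded series of parameterized 1-3 atom molecules with activity
# linear in a planted quantity; convenient for PLS-level tests
tiny_series <- function(n = 12, seed = 42, noise = 0) {
  withr_seed <- function(expr) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed); expr
  }
  withr_seed({
    mols <- lapply(seq_len(n), function(i) {
      r <- runif(1, 1.2, 1.8)
      a <- rbind(
        patom("C", 0, 0, 0, charge = runif(1, -0.3, 0.3)),
        patom("O", r, 0, 0, charge = runif(1, -0.5, -0.1), hba = TRUE),
        patom("H", -1.1, runif(1, -0.5, 0.5), 0, charge = 0.1))
      pmol(sprintf("t%02d", i), a)
    })
    y <- vapply(mols, function(m) {
      7 + 2 * m@atoms$x[2] + 1.5 * m@atoms$charge[1]
    }, numeric(1)) + rnorm(n, 0, noise)
    for (i in seq_len(n)) mols[[i]]@activity <- y[i]
    list(mols = mols, y = y)
  })
}

# --- independent naive oracles -----------------------------------------

# triple-loop force-field reference (per point, per atom; no vectorization)
naive_ff <- function(mol, pts, probe = fieldqsar::defaultProbe(),
                     clamp = 30) {
  a <- fieldqsar::atoms(mol)
  ns <- ne <- numeric(nrow(pts))
  for (q in seq_len(nrow(pts))) {
    s <- e <- 0
    for (i in seq_len(nrow(a))) {
      r2 <- (a$x[i] - pts[q, 1])^2 + (a$y[i] - pts[q, 2])^2 +
        (a$z[i] - pts[q, 3])^2
      r2 <- max(r2, 1e-12)
      rmin <- a$vdw_radius[i] + probe$radius
      eps <- sqrt(a$epsilon[i] * probe$epsilon)
      rat <- rmin^2 / r2
      s <- s + eps * (rat^6 - 2 * rat^3)
      e <- e + 332.06 * probe$charge * a$charge[i] / r2
    }
    ns[q] <- min(max(s, -clamp), clamp)
    ne[q] <- min(max(e, -clamp), clamp)
  }
  list(steric = ns, electrostatic = ne)
}

naive_gaussian <- function(mol, pts, field_type, alpha = 0.3) {
  a <- fieldqsar::atoms(mol)
  w <- switch(field_type,
    G_steric = a$vdw_radius^3, G_electrostatic = a$charge,
    G_hydrophobic = a$hydrophobicity, G_hba = as.numeric(a$is_hba),
    G_hbd = as.numeric(a$is_hbd))
  out <- numeric(nrow(pts))
  for (q in seq_len(nrow(pts))) {
    v <- 0
    for (i in seq_len(nrow(a))) {
      r2 <- (a$x[i] - pts[q, 1])^2 + (a$y[i] - pts[q, 2])^2 +
        (a$z[i] - pts[q, 3])^2
      v <- v + w[i] * exp(-alpha * r2)
    }
    out[q] <- v
  }
  out
}

# Independent PLS1 prediction: centering + block variance equalization
# re-derived here, factors by explicit deflation, prediction by the
# iterative score-projection algorithm (no closed-form W(P'W)^-1 q).
naive_pls_predict <- function(X, col_field, y, n_factors, Xnew) {
  mu <- colMeans(X)
  v <- apply(X, 2, function(c) mean(c^2) - mean(c)^2)
  tot <- tapply(v, col_field, sum)
  s <- 1 / sqrt(as.numeric(tot[as.character(col_field)]))
  Xs <- sweep(sweep(X, 2, mu), 2, s, `*`)
  yc <- y - mean(y)
  Ws <- list(); Ps <- list(); qs <- numeric(0)
  Xd <- Xs; yd <- yc
  for (a in seq_len(n_factors)) {
    w <- drop(crossprod(Xd, yd)); nw <- sqrt(sum(w^2))
    if (nw < 1e-12) break
    w <- w / nw
    t_ <- drop(Xd %*% w); tt <- sum(t_^2)
    if (tt < 1e-12) break
    p_ <- drop(crossprod(Xd, t_)) / tt
    q_ <- sum(yd * t_) / tt
    Xd <- Xd - outer(t_, p_); yd <- yd - t_ * q_
    Ws[[a]] <- w; Ps[[a]] <- p_; qs <- c(qs, q_)
  }
  apply(Xnew, 1, function(x) {
    xs <- (x - mu) * s
    pred <- mean(y)
    for (a in seq_along(qs)) {
      t_ <- sum(xs * Ws[[a]])
      xs <- xs - t_ * Ps[[a]]
      pred <- pred + t_ * qs[a]
    }
    pred
  })
}

# blocks from plain matrices (bypasses the field pipeline)
mat_block <- function(field_type, X, ids = NULL) {
  if (is.null(ids)) ids <- paste0("m", seq_len(nrow(X)))
  rownames(X) <- ids
  new("FieldBlock", field_type = field_type, values = X,
      point_index = seq_len(ncol(X)),
      coords = cbind(seq_len(ncol(X)), 0, 0), params = list())
}
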