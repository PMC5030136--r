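# Seeded generator of toy targets and rigid-body decoy populations with
# analytically known ground truth. These are the package's test and demo
# data engine: backbone-only subunits with ideal local geometry, assembled
# into exactly symmetric dimers and tetramers, then perturbed by known
# transforms.

# Evaluate expr with a temporary RNG state seeded from `seed`, restoring
# the caller's stream afterwards.
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

.normalize <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) c(1, 0, 0) else v / n
}

# CA trace -> full backbone (N, CA, C, O) with near-ideal bond lengths.
.backbone_from_ca <- function(ca) {
  n <- nrow(ca)
  fwd <- rbind(ca[-1, , drop = FALSE] - ca[-n, , drop = FALSE],
               ca[n, ] - ca[n - 1, ])
  bwd <- rbind(ca[2, ] - ca[1, ], ca[-n, , drop = FALSE] -
                 ca[-1, , drop = FALSE])
  bwd <- -bwd  # direction towards previous CA
  out <- vector("list", n)
  for (i in seq_len(n)) {
    f <- .normalize(fwd[i, ]); b <- .normalize(bwd[i, ])
    up <- .normalize(c(f[2] * b[3] - f[3] * b[2],
                       f[3] * b[1] - f[1] * b[3],
                       f[1] * b[2] - f[2] * b[1]))
    if (sum(abs(up)) < 1e-9)  # straight segment: pick any perpendicular
      up <- .normalize(c(-f[2], f[1], 0) + c(0, -f[3], f[2]))
    nn <- ca[i, ] + 1.46 * .normalize(0.8 * b + 0.6 * up)
    cc <- ca[i, ] + 1.52 * .normalize(0.8 * f + 0.6 * up)
    oo <- cc + 1.23 * up
    out[[i]] <- rbind(N = nn, CA = ca[i, ], C = cc, O = oo)
  }
  out
}

#' Generate a synthetic single-chain subunit
#'
#' Deterministically builds a backbone-only (N, CA, C, O) chain with
#' CA-CA spacing of about 3.8 A: an ideal alpha-helix, an extended strand,
#' or a compact self-avoiding random walk. Backbone-only geometry is
#' sufficient because every assessment metric is backbone- or
#' heavy-atom-based. The same seed always yields identical coordinates.
#'
#' @param n_residues number of residues (>= 5).
#' @param fold one of \code{"helix"}, \code{"strand"},
#'   \code{"random-compact"}.
#' @param seed integer seed controlling the sequence (and the walk for the
#'   random fold).
#' @param chain chain identifier.
#' @return a \code{capri_structure} with one chain and 4 atoms per residue.
#' @export
make_subunit <- function(n_residues, fold = c("helix", "strand",
                                              "random-compact"),
                         seed = 1, chain = "A") {
  fold <- match.arg(fold)
  stopifnot(n_residues >= 5)
  ca <- .with_seed(seed, {
    if (fold == "helix") {
      i <- seq_len(n_residues)
      th <- (i - 1) * 100 * pi / 180
      cbind(2.3 * cos(th), 2.3 * sin(th), 1.5 * (i - 1))
    } else if (fold == "strand") {
      i <- seq_len(n_residues)
      cbind(3.5 * (i - 1), 0.9 * (-1)^i, 0)
    } else {
      pts <- matrix(0, n_residues, 3)
      for (i in 2:n_residues) {
        placed <- FALSE
        for (try in 1:200) {
          v <- stats::rnorm(3)
          # bias towards the centroid to stay compact
          v <- .normalize(.normalize(v) * 2 +
                            .normalize(colMeans(pts[1:(i - 1), , drop = FALSE]) -
                                         pts[i - 1, ]) * 0.7)
          cand <- pts[i - 1, ] + 3.8 * v
          if (i <= 2L || min(sqrt(rowSums(sweep(
            pts[1:(i - 2), , drop = FALSE], 2, cand)^2))) > 3.6) {
            pts[i, ] <- cand; placed <- TRUE; break
          }
        }
        if (!placed) stop("could not place residue ", i,
                          " without self-collision")
      }
      pts
    }
  })
  aa1 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K", "M",
           "F", "P", "S", "T", "W", "Y", "V")
  aa3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
           "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
           "TYR", "VAL")
  seq_i <- .with_seed(seed + 1L, sample.int(20, n_residues, replace = TRUE))
  bb <- .backbone_from_ca(ca)
  atoms <- do.call(rbind, lapply(seq_len(n_residues), function(i) {
    m <- bb[[i]]
    data.frame(chain = chain, resno = i, insert = "",
               resid = aa3[seq_i[i]], aa = aa1[seq_i[i]],
               elety = rownames(m),
               elesy = c("N", "C", "C", "O"),
               x = m[, 1], y = m[, 2], z = m[, 3], o = 1,
               stringsAsFactors = FALSE)
  }))
  rownames(atoms) <- NULL
  structure(list(id = paste0("synth-", fold, "-", n_residues),
                 atoms = atoms, source = "synthetic"),
            class = "capri_structure")
}

.transform_atoms <- function(atoms, rot, trans) {
  xyz <- as.matrix(atoms[, c("x", "y", "z")]) %*% t(rot) +
    rep(trans, each = nrow(atoms))
  atoms$x <- xyz[, 1]; atoms$y <- xyz[, 2]; atoms$z <- xyz[, 3]
  atoms
}

#' Assemble an exactly C2-symmetric homodimer
#'
#' Chain A is the subunit re-centred at (+separation/2, 0, 0); chain B is
#' its image under a 180-degree rotation about the z axis, so the dimer has
#' exact C2 symmetry and the two subunit centroids are \code{separation}
#' angstroms apart.
#'
#' @param subunit a single-chain \code{capri_structure} (see
#'   [make_subunit()]).
#' @param separation centroid-centroid distance in angstroms.
#' @return a two-chain \code{capri_structure}.
#' @export
make_c2_dimer <- function(subunit, separation) {
  at <- subunit$atoms
  ctr <- colMeans(as.matrix(at[, c("x", "y", "z")]))
  a <- .transform_atoms(at, diag(3), c(separation / 2, 0, 0) - ctr)
  a$chain <- "A"
  b <- .transform_atoms(a, rotation_about_axis(c(0, 0, 1), 180), c(0, 0, 0))
  b$chain <- "B"
  if (count_clashes(a, b, cutoff = 2.5) > 0L)
    stop("separation ", separation, " A produces steric clashes")
  structure(list(id = paste0(subunit$id, "-c2"),
                 atoms = rbind(a, b), source = "synthetic"),
            class = "capri_structure")
}

#' Assemble an exactly D2-symmetric tetramer (dimer of dimers)
#'
#' Takes the subunit of the dimer (its chain A), offsets it by
#' \code{second_axis_separation / 2} along y, and generates the exact D2
#' orbit under the three perpendicular two-fold axes through the origin:
#' chain B is the y-axis image (the intra-dimer partner across x), chain C
#' the x-axis image (the inter-dimer partner across y) and chain D the
#' z-axis image (the diagonal). By construction there are at most two
#' distinct contacting interface classes: the intra-dimer interface
#' (A:B congruent to C:D) and the inter-dimer interface (A:C congruent to
#' B:D); the diagonal pairs are farther apart.
#'
#' @param dimer a two-chain C2 dimer (see [make_c2_dimer()]); its subunit
#'   geometry and x offset are reused.
#' @param second_axis_separation centroid-centroid distance between the two
#'   dimers in angstroms.
#' @return a four-chain \code{capri_structure}.
#' @export
make_d2_tetramer <- function(dimer, second_axis_separation) {
  a <- dimer$atoms[dimer$atoms$chain == structure_chains(dimer)[1], ,
                   drop = FALSE]
  a <- .transform_atoms(a, diag(3), c(0, second_axis_separation / 2, 0))
  a$chain <- "A"
  img <- function(axis, id) {
    x <- .transform_atoms(a, rotation_about_axis(axis, 180), c(0, 0, 0))
    x$chain <- id
    x
  }
  b <- img(c(0, 1, 0), "B")
  cc <- img(c(1, 0, 0), "C")
  d <- img(c(0, 0, 1), "D")
  chains <- list(A = a, B = b, C = cc, D = d)
  for (pair in combn(names(chains), 2L, simplify = FALSE)) {
    if (count_clashes(chains[[pair[1]]], chains[[pair[2]]],
                      cutoff = 2.5) > 0L)
      stop("second_axis_separation ", second_axis_separation,
           " A produces steric clashes between chains ",
           pair[1], " and ", pair[2])
  }
  structure(list(id = paste0(dimer$id, "-d2"),
                 atoms = do.call(rbind, unname(chains)),
                 source = "synthetic"),
            class = "capri_structure")
}

#' Specification of one rigid-body decoy
#'
#' @param translation length-3 translation of the ligand chain (A).
#' @param angle rotation angle in degrees about \code{axis} through the
#'   ligand backbone centre of mass, applied before the translation.
#' @param axis rotation axis.
#' @param noise_sd standard deviation of iid isotropic Gaussian noise added
#'   to every atom position (A); 0 for exact rigid decoys.
#' @param relabel swap the chain labels of the decoy (tests permutation
#'   invariance).
#' @param seed integer seed for the noise.
#' @param name decoy identifier.
#' @return list of class \code{decoy_spec}.
#' @export
decoy_spec <- function(translation = c(0, 0, 0), angle = 0,
                       axis = c(0, 0, 1), noise_sd = 0, relabel = FALSE,
                       seed = 1, name = NULL) {
  if (is.null(name))
    name <- sprintf("t%.3g_r%.3g_n%.3g", sqrt(sum(translation^2)), angle,
                    noise_sd)
  structure(list(translation = translation, angle = angle, axis = axis,
                 noise_sd = noise_sd, relabel = relabel, seed = seed,
                 name = name),
            class = "decoy_spec")
}

#' Generate rigid-body decoys of a dimer target with known ground truth
#'
#' Each decoy perturbs the last chain (the "ligand") of the target by a
#' rotation about its backbone centre of mass followed by a translation,
#' optionally adding Gaussian coordinate noise and/or swapping chain
#' labels. For noise-free decoys the manifest carries closed-form expected
#' metrics: a pure translation t gives L-rms = d_L = |t| and theta_L = 0; a
#' pure rotation by phi about the ligand centre of mass gives theta_L = phi
#' and d_L = 0.
#'
#' @param target a multi-chain \code{capri_structure}.
#' @param specs list of [decoy_spec()] objects.
#' @param outdir optional directory; when given, each decoy is written as a
#'   PDB file and the manifest as a TSV.
#' @return list with \code{models} (list of \code{capri_structure}) and
#'   \code{manifest} (data frame with the true transform and expected
#'   metrics; \code{NA} where no closed form applies).
#' @export
make_decoys <- function(target, specs, outdir = NULL) {
  chains <- structure_chains(target)
  stopifnot(length(chains) >= 2L)
  lig <- chains[length(chains)]
  models <- vector("list", length(specs))
  rows <- vector("list", length(specs))
  for (k in seq_along(specs)) {
    sp <- specs[[k]]
    at <- target$atoms
    sel <- at$chain == lig
    xyz <- as.matrix(at[sel, c("x", "y", "z")])
    com <- colMeans(xyz)
    rot <- rotation_about_axis(sp$axis, sp$angle)
    xyz <- sweep(xyz, 2, com) %*% t(rot) + rep(com, each = nrow(xyz)) +
      rep(sp$translation, each = nrow(xyz))
    if (sp$noise_sd > 0) {
      noise <- .with_seed(sp$seed, matrix(
        stats::rnorm(length(at$x) * 3, sd = sp$noise_sd), ncol = 3))
      axyz <- as.matrix(at[, c("x", "y", "z")])
      axyz[sel, ] <- xyz
      axyz <- axyz + noise
      at$x <- axyz[, 1]; at$y <- axyz[, 2]; at$z <- axyz[, 3]
    } else {
      at$x[sel] <- xyz[, 1]; at$y[sel] <- xyz[, 2]; at$z[sel] <- xyz[, 3]
    }
    if (isTRUE(sp$relabel) && length(chains) == 2L) {
      at$chain <- ifelse(at$chain == chains[1], chains[2], chains[1])
      at <- at[order(match(at$chain, chains)), , drop = FALSE]
    }
    models[[k]] <- structure(list(id = sp$name, atoms = at,
                                  source = "synthetic"),
                             class = "capri_structure")
    exact <- sp$noise_sd == 0
    tl <- sqrt(sum(sp$translation^2))
    pure_t <- exact && sp$angle == 0
    pure_r <- exact && tl == 0
    rows[[k]] <- data.frame(
      name = sp$name, tx = sp$translation[1], ty = sp$translation[2],
      tz = sp$translation[3], angle = sp$angle, noise_sd = sp$noise_sd,
      relabel = isTRUE(sp$relabel),
      expected_l_rms = if (pure_t) tl else NA_real_,
      expected_theta_l = if (exact) sp$angle else NA_real_,
      expected_d_l = if (pure_t) tl else if (pure_r) 0 else NA_real_,
      stringsAsFactors = FALSE
    )
  }
  manifest <- do.call(rbind, rows)
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    for (m in models)
      write_pdb(m, file.path(outdir, paste0(m$id, ".pdb")))
    write.table(manifest, file.path(outdir, "manifest.tsv"), sep = "\t",
                row.names = FALSE, quote = FALSE)
  }
  list(models = models, manifest = manifest)
}
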