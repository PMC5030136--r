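# Residue-residue contacts, interface residues, steric clashes and
# solvent-accessible surface areas.
#
# All operators take atom data frames (as returned by chain_atoms()) for the
# two subunits; hydrogens are excluded upstream at parse time, so every
# distance here is a heavy-atom distance.

# Cross-set neighbour search on a uniform spatial grid with cell size equal
# to the cutoff: only the 27 neighbouring cells of an atom can hold partners
# within the cutoff, so the result is exactly the all-pairs answer.
# Returns data.frame(i, j, d) for all pairs with d <= cutoff.
.grid_pairs <- function(xyz_a, xyz_b, cutoff) {
  na <- nrow(xyz_a); nb <- nrow(xyz_b)
  if (na == 0L || nb == 0L)
    return(data.frame(i = integer(), j = integer(), d = numeric()))
  cell_a <- floor(xyz_a / cutoff)
  cell_b <- floor(xyz_b / cutoff)
  key_b <- paste(cell_b[, 1], cell_b[, 2], cell_b[, 3])
  idx_b <- split(seq_len(nb), key_b)
  key_a <- paste(cell_a[, 1], cell_a[, 2], cell_a[, 3])
  groups_a <- split(seq_len(na), key_a)
  cells_a <- do.call(rbind, strsplit(names(groups_a), " ", fixed = TRUE))
  storage.mode(cells_a) <- "numeric"
  off <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  out_i <- list(); out_j <- list(); out_d <- list(); k <- 0L
  for (g in seq_along(groups_a)) {
    neigh <- sweep(off, 2, cells_a[g, ], "+")
    keys <- paste(neigh[, 1], neigh[, 2], neigh[, 3])
    cand <- unlist(idx_b[keys], use.names = FALSE)
    if (!length(cand)) next
    ia <- groups_a[[g]]
    pa <- xyz_a[ia, , drop = FALSE]
    pb <- xyz_b[cand, , drop = FALSE]
    d2 <- outer(rowSums(pa^2), rowSums(pb^2), "+") - 2 * tcrossprod(pa, pb)
    hit <- which(d2 <= cutoff^2 + 1e-12, arr.ind = TRUE)
    if (!nrow(hit)) next
    k <- k + 1L
    out_i[[k]] <- ia[hit[, 1]]
    out_j[[k]] <- cand[hit[, 2]]
    out_d[[k]] <- sqrt(pmax(d2[hit], 0))
  }
  if (!k) return(data.frame(i = integer(), j = integer(), d = numeric()))
  data.frame(i = unlist(out_i), j = unlist(out_j), d = unlist(out_d))
}

.atom_xyz <- function(atoms) as.matrix(atoms[, c("x", "y", "z")])

#' Residue-residue contacts between two subunits
#'
#' A contact is any residue pair, one residue from each subunit, with at
#' least one heavy-atom pair within the cutoff (inclusive: "within 5 A").
#' Implemented with a spatial grid that reproduces the all-pairs result
#' exactly.
#'
#' @param sub_a,sub_b atom data frames of the two subunits (see
#'   [chain_atoms()]).
#' @param cutoff heavy-atom distance cutoff in angstroms.
#' @return object of class \code{contact_set}: data frame with columns
#'   \code{res_a}, \code{res_b} (residue keys), deduplicated; the cutoff is
#'   stored as an attribute. Empty subunits give an empty set.
#' @export
residue_contacts <- function(sub_a, sub_b, cutoff = 5.0) {
  pr <- .grid_pairs(.atom_xyz(sub_a), .atom_xyz(sub_b), cutoff)
  ra <- .res_key(sub_a$chain, sub_a$resno, sub_a$insert)[pr$i]
  rb <- .res_key(sub_b$chain, sub_b$resno, sub_b$insert)[pr$j]
  out <- unique(data.frame(res_a = ra, res_b = rb, stringsAsFactors = FALSE))
  rownames(out) <- NULL
  structure(out, cutoff = cutoff, class = c("contact_set", "data.frame"))
}

#' Interface residues of two subunits
#'
#' A residue belongs to the interface when any of its heavy atoms lies
#' within the cutoff of any heavy atom of the partner subunit.
#'
#' @inheritParams residue_contacts
#' @param cutoff heavy-atom distance cutoff in angstroms (10 A is the
#'   protocol's residue-level cutoff).
#' @return list with \code{residues_a}, \code{residues_b} (character vectors
#'   of residue keys) and \code{cutoff}.
#' @export
interface_residues <- function(sub_a, sub_b, cutoff = 10.0) {
  pr <- .grid_pairs(.atom_xyz(sub_a), .atom_xyz(sub_b), cutoff)
  list(
    residues_a = unique(.res_key(sub_a$chain, sub_a$resno,
                                 sub_a$insert)[pr$i]),
    residues_b = unique(.res_key(sub_b$chain, sub_b$resno,
                                 sub_b$insert)[pr$j]),
    cutoff = cutoff
  )
}

#' Count cross-subunit atomic clashes
#'
#' A clash is a cross-subunit heavy-atom pair strictly below the cutoff
#' ("below 3 A").
#'
#' @inheritParams residue_contacts
#' @param cutoff clash distance in angstroms (strict less-than).
#' @return integer clash count.
#' @export
count_clashes <- function(sub_a, sub_b, cutoff = 3.0) {
  pr <- .grid_pairs(.atom_xyz(sub_a), .atom_xyz(sub_b), cutoff)
  sum(pr$d < cutoff)
}

#' Population clash-disqualification threshold
#'
#' The threshold above which a model is disqualified is calibrated on the
#' submitted population: the mean clash count plus two standard deviations
#' (sample SD, n - 1 denominator). With fewer than two counts there is no
#' population to calibrate and the threshold is +Inf with a warning.
#'
#' @param clash_counts integer vector of per-model clash counts.
#' @return numeric threshold; models with counts strictly above it should be
#'   flagged disqualified.
#' @export
clash_threshold <- function(clash_counts) {
  if (length(clash_counts) < 2L) {
    warning("fewer than 2 clash counts; threshold set to +Inf")
    return(Inf)
  }
  mean(clash_counts) + 2 * sd(clash_counts)
}

# ---- solvent accessible surface area ----------------------------------------

# Deterministic near-uniform points on the unit sphere (golden-spiral
# lattice).
.sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

.default_radii <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      f <- system.file("extdata", "vdw_radii.tsv", package = "capriqa")
      if (f == "") f <- file.path("inst", "extdata", "vdw_radii.tsv")
      tb <- read.table(f, header = TRUE, sep = "\t",
                       stringsAsFactors = FALSE)
      cache <<- setNames(tb$radius, tb$element)
    }
    cache
  }
})

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Per-residue accessible area from a deterministic spherical quadrature:
#' each atom is inflated by the probe radius, sampled with a fixed
#' golden-spiral point set, and a sample point counts as accessible when it
#' lies outside every neighbouring inflated atom. van der Waals radii are an
#' element-keyed table shipped with the package (fallback 1.8 A for unknown
#' elements).
#'
#' @param atoms atom data frame (heavy atoms).
#' @param probe probe radius in angstroms.
#' @param sphere_points number of quadrature points per atom.
#' @param radii optional named vector overriding the element radii table.
#' @return named numeric vector of per-residue areas in square angstroms
#'   (names are residue keys); per-atom areas in attribute
#'   \code{per_atom}.
#' @export
sasa <- function(atoms, probe = 1.4, sphere_points = 960, radii = NULL) {
  if (is.null(radii)) radii <- .default_radii()
  n <- nrow(atoms)
  if (n == 0L) return(numeric(0))
  r <- unname(radii[atoms$elesy])
  r[is.na(r)] <- 1.8
  rr <- r + probe
  xyz <- .atom_xyz(atoms)
  pts <- .sphere_points(sphere_points)
  # neighbour lists: atoms i, j can occlude each other only when
  # d(i, j) < rr_i + rr_j <= 2 * max(rr)
  pr <- .grid_pairs(xyz, xyz, 2 * max(rr))
  pr <- pr[pr$i != pr$j & pr$d < rr[pr$i] + rr[pr$j], , drop = FALSE]
  neigh <- split(pr$j, factor(pr$i, levels = seq_len(n)))
  area <- numeric(n)
  for (i in seq_len(n)) {
    p <- pts * rr[i] + rep(xyz[i, ], each = sphere_points)
    acc <- rep(TRUE, sphere_points)
    for (j in neigh[[i]]) {
      if (!any(acc)) break
      dx <- p[, 1] - xyz[j, 1]; dy <- p[, 2] - xyz[j, 2]
      dz <- p[, 3] - xyz[j, 3]
      acc <- acc & (dx * dx + dy * dy + dz * dz > rr[j]^2)
    }
    area[i] <- 4 * pi * rr[i]^2 * sum(acc) / sphere_points
  }
  key <- .res_key(atoms$chain, atoms$resno, atoms$insert)
  per_res <- tapply(area, factor(key, levels = unique(key)), sum)
  out <- setNames(as.numeric(per_res), names(per_res))
  attr(out, "per_atom") <- area
  out
}

#' Buried surface area of a subunit pair
#'
#' Area buried on complex formation: \code{sasa(A) + sasa(B) - sasa(AB)}.
#' The interface area follows the PISA convention of halving the total
#' buried area; both numbers are reported to avoid convention confusion.
#'
#' @inheritParams residue_contacts
#' @param probe,sphere_points,radii passed to [sasa()].
#' @return list of class \code{area_report}: \code{sasa_a}, \code{sasa_b},
#'   \code{sasa_ab}, \code{buried_total}, \code{interface_area} (all in
#'   square angstroms).
#' @export
interface_area <- function(sub_a, sub_b, probe = 1.4, sphere_points = 960,
                           radii = NULL) {
  sa <- sum(sasa(sub_a, probe, sphere_points, radii))
  sb <- sum(sasa(sub_b, probe, sphere_points, radii))
  sab <- sum(sasa(rbind(sub_a, sub_b), probe, sphere_points, radii))
  buried <- max(0, sa + sb - sab)
  structure(list(sasa_a = sa, sasa_b = sb, sasa_ab = sab,
                 buried_total = buried, interface_area = buried / 2),
            class = "area_report")
}

#' @export
print.area_report <- function(x, ...) {
  cat(sprintf(
    "Buried area: %.1f A^2 total (interface area %.1f A^2, PISA convention)\n",
    x$buried_total, x$interface_area))
  invisible(x)
}
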