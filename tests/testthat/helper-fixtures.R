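# Shared fixtures and independent oracles for the test suite.
# All fixtures are generated in code from fixed seeds; nothing is read from
# disk.

# standard toy complexes used across test files
fix_subunit <- function(n = 30, seed = 2, fold = "helix")
  make_subunit(n, fold, seed = seed)

fix_dimer <- function(n = 30, seed = 2, separation = 10)
  make_c2_dimer(fix_subunit(n, seed), separation)

fix_tetramer <- function(n = 30, seed = 2, separation = 10, second = 11)
  make_d2_tetramer(fix_dimer(n, seed, separation), second)

# fast config for surface-area heavy paths
fix_config <- function(...) capri_config(sphere_points = 240, ...)

# introduce point mutations into a structure's sequence (labels only)
mutate_residues <- function(s, chain, positions, to = "G") {
  at <- s$atoms
  keys <- unique(paste(at$chain, at$resno)[at$chain == chain])
  for (p in positions) {
    sel <- at$chain == chain & at$resno == p
    at$aa[sel] <- to
    at$resid[sel] <- "GLY"
  }
  s$atoms <- at
  s
}

# renumber all residues of a structure by a fixed offset
renumber <- function(s, offset) {
  s$atoms$resno <- s$atoms$resno + offset
  s
}

# ---- independent oracles -----------------------------------------------------

# Horn's quaternion method for optimal superposition: independent of the
# SVD/Kabsch route used by the package.
quaternion_superpose <- function(mobile, fixed) {
  cm <- colMeans(mobile); cf <- colMeans(fixed)
  a <- sweep(mobile, 2, cm); b <- sweep(fixed, 2, cf)
  m <- crossprod(a, b)  # sum over points of a_i b_i^T
  sxx <- m[1, 1]; sxy <- m[1, 2]; sxz <- m[1, 3]
  syx <- m[2, 1]; syy <- m[2, 2]; syz <- m[2, 3]
  szx <- m[3, 1]; szy <- m[3, 2]; szz <- m[3, 3]
  n4 <- matrix(c(
    sxx + syy + szz, syz - szy,       szx - sxz,       sxy - syx,
    syz - szy,       sxx - syy - szz, sxy + syx,       szx + sxz,
    szx - sxz,       sxy + syx,       -sxx + syy - szz, syz + szy,
    sxy - syx,       szx + sxz,       syz + szy,       -sxx - syy + szz
  ), 4, 4, byrow = TRUE)
  q <- eigen(n4, symmetric = TRUE)$vectors[, 1]
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  rot <- matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3, byrow = TRUE)
  tr <- as.numeric(cf - rot %*% cm)
  moved <- mobile %*% t(rot) + rep(tr, each = nrow(mobile))
  list(rotation = rot, translation = tr,
       rmsd = sqrt(sum((moved - fixed)^2) / nrow(mobile)))
}

# O(N^2) brute-force cross-set distance computations
brute_pairs <- function(xyz_a, xyz_b) {
  d2 <- outer(rowSums(xyz_a^2), rowSums(xyz_b^2), "+") -
    2 * tcrossprod(xyz_a, xyz_b)
  sqrt(pmax(d2, 0))
}

brute_residue_contacts <- function(sub_a, sub_b, cutoff = 5) {
  d <- brute_pairs(as.matrix(sub_a[, c("x", "y", "z")]),
                   as.matrix(sub_b[, c("x", "y", "z")]))
  hit <- which(d <= cutoff, arr.ind = TRUE)
  ka <- paste(sub_a$chain, sub_a$resno, sub_a$insert, sep = "|")
  kb <- paste(sub_b$chain, sub_b$resno, sub_b$insert, sep = "|")
  unique(data.frame(res_a = ka[hit[, 1]], res_b = kb[hit[, 2]],
                    stringsAsFactors = FALSE))
}

brute_clashes <- function(sub_a, sub_b, cutoff = 3) {
  d <- brute_pairs(as.matrix(sub_a[, c("x", "y", "z")]),
                   as.matrix(sub_b[, c("x", "y", "z")]))
  sum(d < cutoff)
}

# Independently written tier truth table (deliberately different shape from
# the package's vectorised implementation).
oracle_classify_one <- function(f, l, i) {
  if (f >= 0.5) {
    if (l <= 1.0 || i <= 1.0) return("high")
  }
  if (f >= 0.3) {
    if (l <= 5.0 || i <= 2.0) return("medium")
  }
  if (f >= 0.1) {
    if (l <= 10.0 || i <= 4.0) return("acceptable")
  }
  "incorrect"
}

# Exhaustive GDT per-cutoff search for tiny instances: try every subset of
# size >= 3, superpose on it, count inliers.
exhaustive_gdt_counts <- function(xm, xt, cutoffs = c(1, 2, 4, 8)) {
  n <- nrow(xm)
  stopifnot(n <= 14)
  best <- setNames(integer(length(cutoffs)), cutoffs)
  idx <- seq_len(n)
  for (k in 3:n) {
    subs <- combn(idx, k, simplify = FALSE)
    for (s in subs) {
      fit <- try(superpose(xm[s, , drop = FALSE], xt[s, , drop = FALSE]),
                 silent = TRUE)
      if (inherits(fit, "try-error")) next
      d <- sqrt(rowSums((apply_transform(fit, xm) - xt)^2))
      for (ci in seq_along(cutoffs))
        best[ci] <- max(best[ci], sum(d <= cutoffs[ci]))
    }
  }
  best
}

# random cloud of "residues" (one atom each) for contact oracles
random_blob <- function(n_atoms, seed, spread = 12, chain = "A") {
  set.seed(seed)
  data.frame(
    chain = chain, resno = seq_len(n_atoms), insert = "",
    resid = "ALA", aa = "A", elety = "CA", elesy = "C",
    x = runif(n_atoms, 0, spread), y = runif(n_atoms, 0, spread),
    z = runif(n_atoms, 0, spread), o = 1, stringsAsFactors = FALSE
  )
}

# one-atom "residue" at a point
atom_at <- function(x, y, z, chain = "A", resno = 1, elety = "CA",
                    elesy = "C") {
  data.frame(chain = chain, resno = resno, insert = "", resid = "ALA",
             aa = "A", elety = elety, elesy = elesy, x = x, y = y, z = z,
             o = 1, stringsAsFactors = FALSE)
}

random_rotation <- function() {
  repeat {
    q <- rnorm(4)
    if (sum(q^2) > 1e-6) break
  }
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3, byrow = TRUE)
}
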