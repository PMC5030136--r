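# Rigid-body superposition and RMSD primitives.
#
# Conventions: coordinate sets are n x 3 matrices (rows are atoms, columns
# x/y/z); a rigid transform maps x to R x + t, i.e. rows to x %*% t(R) + t.

#' Optimal rigid superposition (Kabsch)
#'
#' Finds the proper rotation and translation that minimise the RMSD between
#' corresponding points, by SVD of the cross-covariance matrix with a sign
#' correction on the smallest singular vector so that reflections are never
#' returned. Correspondence is given by row order; weights are uniform.
#'
#' @param mobile,fixed n x 3 coordinate matrices with n >= 3.
#' @return object of class \code{rigid_transform}: list with \code{rotation}
#'   (3 x 3, det +1), \code{translation} (length 3) and \code{rmsd}, the
#'   residual RMSD in angstroms after applying the transform to
#'   \code{mobile}.
#' @export
superpose <- function(mobile, fixed) {
  mobile <- as.matrix(mobile); fixed <- as.matrix(fixed)
  if (nrow(mobile) != nrow(fixed))
    stop("point counts differ: ", nrow(mobile), " vs ", nrow(fixed))
  n <- nrow(mobile)
  if (n < 3L) stop("superposition requires at least 3 points, got ", n)
  cm <- colMeans(mobile); cf <- colMeans(fixed)
  xm <- sweep(mobile, 2, cm); xf <- sweep(fixed, 2, cf)
  # degenerate (collinear) sets have no unique rotation about the line
  svm <- svd(xm)$d
  if (svm[2] <= 1e-8 * max(svm[1], 1e-300))
    stop("degenerate (collinear) point set; superposition is not unique")
  h <- crossprod(xm, xf)                    # 3 x 3 covariance
  sv <- svd(h)
  d <- sign(det(sv$v %*% t(sv$u)))
  rot <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  tr <- as.numeric(cf - rot %*% cm)
  moved <- mobile %*% t(rot) + rep(tr, each = n)
  res <- sqrt(sum((moved - fixed)^2) / n)
  structure(list(rotation = rot, translation = tr, rmsd = res),
            class = "rigid_transform")
}

#' Construct a rigid transform from rotation and translation
#' @param rotation 3 x 3 proper orthonormal matrix.
#' @param translation length-3 numeric.
#' @return a \code{rigid_transform}.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  stopifnot(all(dim(rotation) == c(3L, 3L)), length(translation) == 3L)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-6 ||
      abs(det(rotation) - 1) > 1e-6)
    stop("rotation must be proper orthonormal (det +1)")
  structure(list(rotation = rotation, translation = as.numeric(translation),
                 rmsd = NA_real_),
            class = "rigid_transform")
}

#' Apply a rigid transform to coordinates
#' @param transform a \code{rigid_transform}.
#' @param coords n x 3 matrix.
#' @return transformed n x 3 matrix.
#' @export
apply_transform <- function(transform, coords) {
  coords <- as.matrix(coords)
  coords %*% t(transform$rotation) +
    rep(transform$translation, each = nrow(coords))
}

#' RMSD after applying a fixed transform (no re-fit)
#' @param transform a \code{rigid_transform}.
#' @param mobile,fixed n x 3 matrices, corresponding by row.
#' @return RMSD in angstroms.
#' @export
rmsd_after <- function(transform, mobile, fixed) {
  mobile <- as.matrix(mobile); fixed <- as.matrix(fixed)
  if (nrow(mobile) != nrow(fixed))
    stop("point counts differ: ", nrow(mobile), " vs ", nrow(fixed))
  moved <- apply_transform(transform, mobile)
  sqrt(sum((moved - fixed)^2) / nrow(moved))
}

#' Rotation angle of a rigid transform
#'
#' The mis-orientation angle, from the trace formula
#' \code{acos((tr(R) - 1) / 2)}, in degrees in [0, 180].
#'
#' @param transform a \code{rigid_transform}.
#' @return angle in degrees.
#' @export
rotation_angle <- function(transform) {
  ct <- (sum(diag(transform$rotation)) - 1) / 2
  acos(max(-1, min(1, ct))) * 180 / pi
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("Rigid transform: rotation ", sprintf("%.2f", rotation_angle(x)),
      " deg, translation |t| = ",
      sprintf("%.3f", sqrt(sum(x$translation^2))), " A", sep = "")
  if (!is.na(x$rmsd)) cat(", fit rmsd ", sprintf("%.3f", x$rmsd), " A",
                          sep = "")
  cat("\n")
  invisible(x)
}

# Rotation matrix about a (unit) axis by an angle in degrees (Rodrigues).
rotation_about_axis <- function(axis, angle_deg) {
  a <- axis / sqrt(sum(axis^2))
  th <- angle_deg * pi / 180
  k <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) + sin(th) * k + (1 - cos(th)) * (k %*% k)
}
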