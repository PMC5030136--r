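# Sequence-dependent GDT_TS-style accuracy score for individual subunits.
#
# This is an analogue of the GDT_TS component of the LGA program, built on
# the standard search heuristic (window seeds + iterative inlier
# refinement). It runs in sequence-dependent mode only: the residue
# correspondence is fixed before scoring. The sequence-independent LGA_S
# score of the external LGA program is deliberately not reimplemented.

#' GDT_TS-style subunit accuracy score
#'
#' For each distance cutoff (1, 2, 4, 8 A) the search looks for the rigid
#' superposition that places the largest fraction of corresponded CA pairs
#' within the cutoff. Superpositions are seeded from every contiguous
#' window of lengths 3, 5, 7 and the full chain, then refined iteratively:
#' fit on the current inlier set, re-collect inliers, until the set is
#' stable (at most 20 iterations). Fits found at a smaller cutoff also seed
#' the larger cutoffs, which makes the per-cutoff fractions non-decreasing
#' by construction. Chains of at most 12 residues are scored by exhaustive
#' subset search instead, so tiny instances are exact. GDT_TS is 100 times
#' the mean of the four fractions.
#'
#' @param model_subunit,target_subunit single-chain
#'   \code{capri_structure} objects.
#' @param corr optional \code{residue_correspondence}; computed by sequence
#'   alignment when absent.
#' @param cutoffs distance cutoffs in angstroms.
#' @param max_iter refinement iteration cap per seed.
#' @return object of class \code{gdt_result}: list with \code{gdt_ts} (0 to
#'   100), \code{per_cutoff} (named fractions), \code{ca_rmsd} (RMSD of the
#'   single global CA superposition) and \code{n_residues}.
#' @export
gdt_ts <- function(model_subunit, target_subunit, corr = NULL,
                   cutoffs = c(1, 2, 4, 8), max_iter = 20L) {
  if (is.null(corr))
    corr <- map_common_residues(model_subunit, target_subunit)
  cb <- .common_backbone(model_subunit, target_subunit, corr,
                         unique(corr$pairs$target_chain), backbone = "CA")
  xm <- cb$model; xt <- cb$target
  n <- nrow(xm)
  if (n < 3L) stop("fewer than 3 corresponded CA pairs")
  fit_dist <- function(idx) {
    fit <- try(superpose(xm[idx, , drop = FALSE], xt[idx, , drop = FALSE]),
               silent = TRUE)
    if (inherits(fit, "try-error")) return(NULL)
    moved <- apply_transform(fit, xm)
    sqrt(rowSums((moved - xt)^2))
  }
  cutoffs <- sort(cutoffs)
  best_count <- setNames(integer(length(cutoffs)), cutoffs)
  if (n <= 12L) {
    # tiny chains: exhaustive search over every residue subset; one fit
    # serves all cutoffs
    for (k in 3:n) for (s in combn(n, k, simplify = FALSE)) {
      d <- fit_dist(s)
      if (is.null(d)) next
      for (ci in seq_along(cutoffs))
        best_count[ci] <- max(best_count[ci], sum(d <= cutoffs[ci]))
    }
  } else {
    seeds <- list()
    for (w in unique(pmin(c(3L, 5L, 7L, n), n)))
      for (s in seq_len(n - w + 1L))
        seeds[[length(seeds) + 1L]] <- s:(s + w - 1L)
    best_sets <- list()  # best inlier set per cutoff, carried upward
    for (ci in seq_along(cutoffs)) {
      cu <- cutoffs[ci]
      pool <- c(seeds, best_sets)
      for (sd in pool) {
        cur <- sd
        for (it in seq_len(max_iter)) {
          d <- fit_dist(cur)
          if (is.null(d)) break
          inl <- which(d <= cu)
          if (length(inl) > best_count[ci]) {
            best_count[ci] <- length(inl)
            if (length(inl) >= 3L) best_sets[[ci]] <- inl
          }
          if (length(inl) < 3L || identical(inl, cur)) break
          cur <- inl
        }
      }
      # monotonicity: an inlier at a smaller cutoff is one at a larger
      if (ci > 1L && best_count[ci] < best_count[ci - 1L]) {
        best_count[ci] <- best_count[ci - 1L]
        best_sets[[ci]] <- best_sets[[ci - 1L]]
      }
    }
  }
  dglob <- fit_dist(seq_len(n))
  per_cutoff <- setNames(as.numeric(best_count) / n, cutoffs)
  structure(list(
    gdt_ts = 100 * mean(per_cutoff),
    per_cutoff = per_cutoff,
    ca_rmsd = if (is.null(dglob)) NA_real_ else sqrt(mean(dglob^2)),
    n_residues = n
  ), class = "gdt_result")
}

#' @export
print.gdt_result <- function(x, ...) {
  cat(sprintf("GDT_TS %.1f (CA rmsd %.2f A over %d residues)\n  fractions:",
              x$gdt_ts, x$ca_rmsd, x$n_residues))
  for (nm in names(x$per_cutoff))
    cat(sprintf(" %s A: %.2f", nm, x$per_cutoff[[nm]]))
  cat("\n")
  invisible(x)
}
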