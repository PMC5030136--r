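# Mapping metric bundles to the four CAPRI quality tiers.

.quality_levels <- c("incorrect", "acceptable", "medium", "high")

#' Classify a model into a CAPRI quality tier
#'
#' The tier criteria are cumulative, with OR between the two RMSD
#' conditions and thresholds inclusive for the tier they admit:
#' \describe{
#'   \item{high (***)}{f(nat) >= 0.5 and (L-rms <= 1.0 or I-rms <= 1.0)}
#'   \item{medium (**)}{f(nat) >= 0.3 and (L-rms <= 5.0 or I-rms <= 2.0)}
#'   \item{acceptable (*)}{f(nat) >= 0.1 and (L-rms <= 10.0 or I-rms <= 4.0)}
#'   \item{incorrect}{anything else}
#' }
#' A model meeting a higher tier is never demoted by the band bounds of a
#' lower tier. Disqualified models are incorrect regardless of metrics.
#'
#' @param f_nat fraction of native contacts (or a \code{capri_metrics}
#'   object, in which case the remaining metric arguments are taken from
#'   it).
#' @param l_rms,i_rms ligand and interface RMSD in angstroms.
#' @param disqualified logical; clash-disqualified models.
#' @return ordered factor with levels
#'   \code{incorrect < acceptable < medium < high}; vectorised over the
#'   inputs.
#' @export
classify <- function(f_nat, l_rms = NULL, i_rms = NULL,
                     disqualified = FALSE) {
  if (inherits(f_nat, "capri_metrics")) {
    m <- f_nat
    disqualified <- isTRUE(m$disqualified)
    f_nat <- m$f_nat; l_rms <- m$l_rms; i_rms <- m$i_rms
  }
  n <- max(length(f_nat), length(l_rms), length(i_rms))
  f <- rep_len(f_nat, n); l <- rep_len(l_rms, n); i <- rep_len(i_rms, n)
  dq <- rep_len(disqualified, n)
  if (any(!is.finite(f) | !is.finite(l) | !is.finite(i)))
    stop("non-finite metric values cannot be classified")
  if (any(f < 0 | f > 1 | l < 0 | i < 0))
    stop("metrics out of range: f(nat) must be in [0,1], RMSDs >= 0")
  tier <- rep("incorrect", n)
  tier[f >= 0.1 & (l <= 10.0 | i <= 4.0)] <- "acceptable"
  tier[f >= 0.3 & (l <= 5.0 | i <= 2.0)] <- "medium"
  tier[f >= 0.5 & (l <= 1.0 | i <= 1.0)] <- "high"
  tier[dq] <- "incorrect"
  factor(tier, levels = .quality_levels, ordered = TRUE)
}

#' Star count of a quality tier
#' @param level quality tier(s), as returned by [classify()].
#' @return integer vector: high = 3, medium = 2, acceptable = 1,
#'   incorrect = 0.
#' @export
quality_stars <- function(level) {
  match(as.character(level), .quality_levels) - 1L
}

#' Classify a population of models with clash disqualification
#'
#' Applies the population clash threshold (mean + 2 SD of the clash counts,
#' [clash_threshold()]), flags models with counts strictly above it as
#' disqualified, and classifies every model. Disqualified models are
#' labelled incorrect but keep their metric values.
#'
#' @param records data frame with columns \code{f_nat}, \code{l_rms},
#'   \code{i_rms} and \code{n_clashes} (one row per model).
#' @return the input with added columns \code{disqualified} and
#'   \code{quality}; tier counts in attribute \code{tier_counts} and the
#'   threshold used in attribute \code{clash_threshold}.
#' @export
classify_batch <- function(records) {
  stopifnot(is.data.frame(records),
            all(c("f_nat", "l_rms", "i_rms", "n_clashes") %in%
                  names(records)))
  thr <- clash_threshold(records$n_clashes)
  records$disqualified <- records$n_clashes > thr
  records$quality <- classify(records$f_nat, records$l_rms, records$i_rms,
                              records$disqualified)
  attr(records, "clash_threshold") <- thr
  attr(records, "tier_counts") <-
    table(factor(records$quality, levels = rev(.quality_levels)))
  records
}
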