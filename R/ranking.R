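# Aggregation of assessment records into per-target summaries and
# cross-target group rankings, and report output.

#' Flatten assessment records into a table
#'
#' @param records list of \code{capri_assessment} objects, or an existing
#'   data frame (returned unchanged).
#' @return data frame with one row per record: \code{model_id},
#'   \code{group_id}, \code{target_id}, \code{best_interface},
#'   \code{quality}, \code{n_clashes}, \code{disqualified}.
#' @export
assessment_table <- function(records) {
  if (is.data.frame(records)) return(records)
  do.call(rbind, lapply(records, function(r) {
    stopifnot(inherits(r, "capri_assessment"))
    data.frame(model_id = r$model_id, group_id = r$group_id,
               target_id = r$target_id, best_interface = r$best_interface,
               quality = as.character(r$best_quality),
               n_clashes = r$n_clashes,
               disqualified = isTRUE(r$best_metrics$disqualified),
               stringsAsFactors = FALSE)
  }))
}

.quality_ord <- function(q) {
  factor(as.character(q), levels = .quality_levels, ordered = TRUE)
}

#' Rank predictor groups across targets
#'
#' Two ranking conventions are provided. \code{"best-per-target"} counts,
#' for each group, the targets whose best submitted model reaches a tier:
#' groups are ordered by targets with an acceptable-or-better best model,
#' ties broken by targets with medium-or-better, then high, then group id.
#' \code{"model-counts"} ranks by total acceptable-or-better models with
#' ties broken by the number of medium-or-better models (the "same number
#' of acceptable models, more high-quality models ranks higher" rule), then
#' group id. Both orderings are deterministic and independent of the input
#' row order.
#'
#' @param records list of \code{capri_assessment} objects or a data frame
#'   from [assessment_table()] (columns \code{group_id}, \code{target_id},
#'   \code{quality}; \code{disqualified} optional).
#' @param mode ranking convention.
#' @return data frame of class \code{group_tally}, one row per group in
#'   rank order, with a \code{rank} column.
#' @export
tally_groups <- function(records, mode = c("best-per-target",
                                           "model-counts")) {
  mode <- match.arg(mode)
  tb <- assessment_table(records)
  stopifnot(all(c("group_id", "target_id", "quality") %in% names(tb)))
  tb$group_id[is.na(tb$group_id)] <- "(unassigned)"
  q <- .quality_ord(tb$quality)
  groups <- sort(unique(tb$group_id))
  rows <- lapply(groups, function(g) {
    sel <- tb$group_id == g
    qg <- q[sel]
    tg <- tb$target_id[sel]
    best <- tapply(qg, tg, max)
    best <- .quality_ord(.quality_levels[best])
    data.frame(
      group_id = g,
      targets_submitted = length(unique(tg)),
      targets_acceptable_plus = sum(best >= "acceptable"),
      targets_medium_plus = sum(best >= "medium"),
      targets_high = sum(best >= "high"),
      models_submitted = sum(sel),
      models_acceptable_plus = sum(qg >= "acceptable"),
      models_medium_plus = sum(qg >= "medium"),
      models_high = sum(qg >= "high"),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  ord <- if (mode == "best-per-target") {
    order(-out$targets_acceptable_plus, -out$targets_medium_plus,
          -out$targets_high, out$group_id)
  } else {
    order(-out$models_acceptable_plus, -out$models_medium_plus,
          -out$models_high, out$group_id)
  }
  out <- out[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  structure(out, mode = mode, class = c("group_tally", "data.frame"))
}

#' @export
print.group_tally <- function(x, ...) {
  cat("Group ranking (", attr(x, "mode"), "):\n", sep = "")
  for (i in seq_len(nrow(x)))
    cat(sprintf("  %2d. %-16s targets %d/%d acceptable+ (%d medium+)\n",
                x$rank[i], x$group_id[i], x$targets_acceptable_plus[i],
                x$targets_submitted[i], x$targets_medium_plus[i]))
  invisible(x)
}

#' Per-target summary fractions
#'
#' For one target, the fraction of submitted models of acceptable-or-better
#' and of medium-or-better quality, per assessed interface when records
#' carry per-interface results. Disqualified models count in the
#' denominator (they were submitted) but, being classified incorrect, never
#' in the numerators.
#'
#' @param records list of \code{capri_assessment} objects for one target,
#'   or a data frame with columns \code{target_id}, \code{quality} and
#'   optionally \code{interface_id}.
#' @return data frame of class \code{target_summary} with columns
#'   \code{target_id}, \code{interface_id}, \code{n_models},
#'   \code{n_groups}, \code{frac_acceptable_plus}, \code{frac_medium_plus}.
#' @export
summarize_target <- function(records) {
  if (is.data.frame(records)) {
    tb <- records
  } else {
    tb <- do.call(rbind, lapply(records, function(r) {
      pi <- r$per_interface
      data.frame(target_id = r$target_id, group_id = r$group_id,
                 model_id = r$model_id, interface_id = pi$interface_id,
                 quality = pi$quality, stringsAsFactors = FALSE)
    }))
  }
  if (is.null(tb) || nrow(tb) == 0L) stop("no models to summarise")
  if (length(unique(tb$target_id)) != 1L)
    stop("summarize_target() expects records for a single target")
  if (is.null(tb$interface_id)) tb$interface_id <- 1L
  q <- .quality_ord(tb$quality)
  out <- do.call(rbind, lapply(sort(unique(tb$interface_id)), function(ii) {
    sel <- tb$interface_id == ii
    data.frame(
      target_id = tb$target_id[1], interface_id = ii,
      n_models = sum(sel),
      n_groups = if (!is.null(tb$group_id))
        length(unique(tb$group_id[sel])) else NA_integer_,
      frac_acceptable_plus = mean(q[sel] >= "acceptable"),
      frac_medium_plus = mean(q[sel] >= "medium"),
      stringsAsFactors = FALSE
    )
  }))
  structure(out, class = c("target_summary", "data.frame"))
}

#' Write ranking reports to disk
#'
#' @param tallies a \code{group_tally} data frame.
#' @param summaries a \code{target_summary} data frame (or several row-bound
#'   together); may be \code{NULL}.
#' @param path_prefix output path prefix; files are
#'   \code{<prefix>_groups.<ext>} and \code{<prefix>_targets.<ext>}.
#' @param format \code{"tsv"} (stable column order, floats to 3 decimals)
#'   or \code{"json"} (round-trips through \code{jsonlite}).
#' @return character vector of the files written, invisibly.
#' @export
write_report <- function(tallies, summaries = NULL, path_prefix = "report",
                         format = c("tsv", "json")) {
  if (is.null(tallies) || nrow(tallies) == 0L)
    stop("empty tally; nothing to report")
  if (!is.character(format) ||
      !all(format %in% c("tsv", "json")) || length(format) < 1L)
    stop("unknown report format")
  format <- match.arg(format)
  round_floats <- function(df) {
    num <- vapply(df, is.numeric, logical(1)) &
      !vapply(df, is.integer, logical(1))
    df[num] <- lapply(df[num], function(v) round(v, 3))
    df
  }
  files <- character(0)
  emit <- function(df, suffix) {
    f <- paste0(path_prefix, "_", suffix, ".", format)
    df <- as.data.frame(df)
    if (format == "tsv") {
      write.table(round_floats(df), f, sep = "\t", quote = FALSE,
                  row.names = FALSE)
    } else {
      jsonlite::write_json(df, f, dataframe = "rows", digits = NA,
                           pretty = TRUE)
    }
    files <<- c(files, f)
  }
  emit(tallies, "groups")
  if (!is.null(summaries) && nrow(summaries)) emit(summaries, "targets")
  invisible(files)
}
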