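# Homo-oligomer assessment: candidate target interfaces (including
# crystallographic symmetry images) ranked by buried area, chain-permutation
# matching of model subunit pairs to target interfaces, and the
# simultaneous multi-interface check for tetramers.

#' Crystallographic symmetry operator
#'
#' @param rotation 3 x 3 matrix; must be a proper rotation (det +1). The
#'   assessed molecules are chiral, so improper operators are rejected: they
#'   can enter only through the full space group, never as a single
#'   interface-generating operator.
#' @param translation length-3 translation in angstroms.
#' @param label operator label (e.g. its index in REMARK 290).
#' @return list of class \code{symmetry_operator}.
#' @export
symmetry_operator <- function(rotation, translation = c(0, 0, 0),
                              label = "op") {
  rotation <- as.matrix(rotation)
  stopifnot(all(dim(rotation) == c(3L, 3L)), length(translation) == 3L)
  d <- det(rotation)
  if (abs(abs(d) - 1) > 1e-6)
    stop("operator determinant is ", signif(d, 6), "; not a rigid rotation")
  if (d < 0)
    stop("improper operator (reflection); not allowed for chiral molecules")
  structure(list(rotation = rotation, translation = as.numeric(translation),
                 label = as.character(label)),
            class = "symmetry_operator")
}

#' Read symmetry operators from a plain-text config file
#'
#' Each operator is four whitespace-separated numeric lines (rows of a 4 x 4
#' homogeneous transform, rotation in the upper-left 3 x 3, translation in
#' the last column); blank lines and lines starting with '#' separate
#' operators, mirroring the layout of BIOMT/REMARK 290 style tables.
#'
#' @param file path to the operator file.
#' @return list of [symmetry_operator()] objects.
#' @export
read_operators <- function(file) {
  lines <- readLines(file, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[lines != "" & !startsWith(lines, "#")]
  if (length(lines) %% 4L != 0L)
    stop("operator file must contain 4 numeric rows per operator")
  n <- length(lines) %/% 4L
  lapply(seq_len(n), function(k) {
    rows <- lines[(4 * k - 3):(4 * k)]
    m <- do.call(rbind, lapply(rows, function(l)
      as.numeric(strsplit(l, "\\s+")[[1L]])))
    if (ncol(m) != 4L) stop("operator rows must have 4 numbers")
    symmetry_operator(m[1:3, 1:3], m[1:3, 4], label = as.character(k))
  })
}

#' Generate contacting crystal-symmetry neighbours
#'
#' Applies each supplied operator to each chain of the asymmetric unit and
#' retains images that touch it (any heavy atom within \code{cutoff} of the
#' asymmetric unit). Identity-like images (the chain mapped onto itself) are
#' discarded. Operators are supplied explicitly; no space-group expansion
#' from symbols is attempted.
#'
#' @param asu a \code{capri_structure} (the asymmetric unit).
#' @param operators list of [symmetry_operator()] objects.
#' @param cutoff contact distance in angstroms deciding retention.
#' @return the input structure with contacting image chains appended; image
#'   chains are named \code{<chain>~<label>} and described in attribute
#'   \code{images}.
#' @export
generate_crystal_neighbors <- function(asu, operators, cutoff = 5.0) {
  asu_xyz <- .atom_xyz(asu$atoms)
  new_atoms <- list(); info <- list(); k <- 0L
  for (op in operators) {
    stopifnot(inherits(op, "symmetry_operator"))
    for (ch in structure_chains(asu)) {
      at <- chain_atoms(asu, ch)
      img <- .transform_atoms(at, op$rotation, op$translation)
      disp <- max(sqrt(rowSums((.atom_xyz(img) - .atom_xyz(at))^2)))
      if (disp < 0.1) next  # identity image of this chain
      touching <- nrow(.grid_pairs(.atom_xyz(img), asu_xyz, cutoff)) > 0L
      if (!touching) next
      k <- k + 1L
      img$chain <- paste0(ch, "~", op$label)
      new_atoms[[k]] <- img
      info[[k]] <- data.frame(chain = img$chain[1], base_chain = ch,
                              operator = op$label,
                              stringsAsFactors = FALSE)
    }
  }
  out <- asu
  if (k > 0L) out$atoms <- rbind(asu$atoms, do.call(rbind, new_atoms))
  attr(out, "images") <- if (k > 0L) do.call(rbind, info) else
    data.frame(chain = character(), base_chain = character(),
               operator = character())
  out
}

# Rotate/translate a subunit pair into a canonical principal-axes frame.
# The buried area is rotation invariant, but the spherical quadrature is
# not exactly so; evaluating every pair in the same canonical frame makes
# symmetry-equivalent (congruent) pairs give numerically identical areas,
# which the duplicate merge relies on.
.canonicalize_pair <- function(sub_a, sub_b) {
  xyz <- rbind(.atom_xyz(sub_a), .atom_xyz(sub_b))
  ctr <- colMeans(xyz)
  xc <- sweep(xyz, 2, ctr)
  # frame from extremal atoms: symmetry images preserve atom order, so
  # congruent pairs pick corresponding atoms and land on identical
  # coordinates (mirror-related pairs do not, which is intended: the
  # molecules are chiral)
  e1 <- xc[which.max(rowSums(xc^2)), ]
  e1 <- e1 / sqrt(sum(e1^2))
  resid <- xc - outer(as.numeric(xc %*% e1), e1)
  e2 <- resid[which.max(rowSums(resid^2)), ]
  e2 <- e2 / sqrt(sum(e2^2))
  e3 <- c(e1[2] * e2[3] - e1[3] * e2[2],
          e1[3] * e2[1] - e1[1] * e2[3],
          e1[1] * e2[2] - e1[2] * e2[1])
  proj <- xc %*% cbind(e1, e2, e3)
  na <- nrow(sub_a)
  sub_a[, c("x", "y", "z")] <- proj[seq_len(na), , drop = FALSE]
  sub_b[, c("x", "y", "z")] <- proj[-seq_len(na), , drop = FALSE]
  list(a = sub_a, b = sub_b)
}

# Contact fingerprint of a chain pair, invariant under chain naming:
# the sorted set of unordered residue-number contact pairs.
.contact_fingerprint <- function(con, sub_a, sub_b) {
  if (nrow(con) == 0L) return(character(0))
  ra <- as.integer(sub("^[^|]*\\|([^|]*)\\|.*$", "\\1", con$res_a))
  rb <- as.integer(sub("^[^|]*\\|([^|]*)\\|.*$", "\\1", con$res_b))
  sort(paste(pmin(ra, rb), pmax(ra, rb), sep = ":"))
}

#' Enumerate candidate interfaces of an assembly
#'
#' Computes the buried area of every distinct subunit (chain) pair,
#' discards pairs at or below the area floor, merges symmetry-equivalent
#' duplicates (areas within 1 A^2 and congruent residue-contact maps), and
#' ranks the survivors by decreasing interface area.
#'
#' @param assembly a \code{capri_structure}, possibly augmented with
#'   symmetry images ([generate_crystal_neighbors()]).
#' @param min_area interface-area floor in square angstroms (exclusive).
#' @param config a [capri_config()] (surface parameters and contact
#'   cutoff).
#' @return data frame of class \code{capri_interfaces} with columns
#'   \code{id} (rank), \code{chain_a}, \code{chain_b}, \code{area},
#'   \code{n_equivalent} (pairs merged into the class).
#' @export
enumerate_interfaces <- function(assembly, min_area = 0,
                                 config = capri_config()) {
  chains <- structure_chains(assembly)
  if (length(chains) < 2L)
    return(structure(data.frame(id = integer(), chain_a = character(),
                                chain_b = character(), area = numeric(),
                                n_equivalent = integer()),
                     class = c("capri_interfaces", "data.frame")))
  pairs <- combn(chains, 2L)
  rows <- list(); k <- 0L
  for (p in seq_len(ncol(pairs))) {
    sub_a <- chain_atoms(assembly, pairs[1, p])
    sub_b <- chain_atoms(assembly, pairs[2, p])
    # cheap pre-screen: no atoms within 8 A means no buried area
    if (nrow(.grid_pairs(.atom_xyz(sub_a), .atom_xyz(sub_b), 8)) == 0L)
      next
    canon <- .canonicalize_pair(sub_a, sub_b)
    ar <- interface_area(canon$a, canon$b, probe = config$probe,
                         sphere_points = config$sphere_points)
    if (ar$interface_area <= min_area || ar$interface_area <= 0) next
    con <- residue_contacts(sub_a, sub_b, cutoff = config$contact_cutoff)
    k <- k + 1L
    rows[[k]] <- list(chain_a = pairs[1, p], chain_b = pairs[2, p],
                      area = ar$interface_area,
                      fp = .contact_fingerprint(con, sub_a, sub_b))
  }
  if (k == 0L)
    return(structure(data.frame(id = integer(), chain_a = character(),
                                chain_b = character(), area = numeric(),
                                n_equivalent = integer()),
                     class = c("capri_interfaces", "data.frame")))
  ord <- order(-vapply(rows, `[[`, numeric(1), "area"))
  rows <- rows[ord]
  kept <- list(); n_eq <- integer()
  for (r in rows) {
    dup <- FALSE
    for (j in seq_along(kept)) {
      if (abs(kept[[j]]$area - r$area) <= 1 &&
          identical(kept[[j]]$fp, r$fp)) {
        n_eq[j] <- n_eq[j] + 1L; dup <- TRUE; break
      }
    }
    if (!dup) { kept[[length(kept) + 1L]] <- r; n_eq <- c(n_eq, 1L) }
  }
  out <- data.frame(
    id = seq_along(kept),
    chain_a = vapply(kept, `[[`, character(1), "chain_a"),
    chain_b = vapply(kept, `[[`, character(1), "chain_b"),
    area = vapply(kept, `[[`, numeric(1), "area"),
    n_equivalent = n_eq,
    stringsAsFactors = FALSE
  )
  structure(out, class = c("capri_interfaces", "data.frame"))
}

#' @export
print.capri_interfaces <- function(x, ...) {
  cat("Assessed interfaces (ranked by buried area):\n")
  if (nrow(x) == 0L) { cat("  none\n"); return(invisible(x)) }
  for (i in seq_len(nrow(x)))
    cat(sprintf("  %d: %s:%s  %.0f A^2%s\n", x$id[i], x$chain_a[i],
                x$chain_b[i], x$area[i],
                if (x$n_equivalent[i] > 1L)
                  sprintf("  (x%d symmetry-equivalent)", x$n_equivalent[i])
                else ""))
  invisible(x)
}

# tier/i_rms/l_rms/f_nat tie-break: TRUE if metrics a beats b
.better_metrics <- function(a, b) {
  qa <- classify(a); qb <- classify(b)
  if (qa != qb) return(qa > qb)
  if (!isTRUE(all.equal(a$i_rms, b$i_rms))) return(a$i_rms < b$i_rms)
  if (!isTRUE(all.equal(a$l_rms, b$l_rms))) return(a$l_rms < b$l_rms)
  a$f_nat > b$f_nat
}

# All ways to injectively assign the values of `from` onto `to`, subject to
# compatibility matrix comp[from, to].
.bijections <- function(from, to, comp) {
  if (length(from) != length(to)) return(list())
  perms <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v))
      out <- c(out, lapply(perms(v[-i]), function(p) c(v[i], p)))
    out
  }
  res <- list()
  for (p in perms(to)) {
    ok <- all(vapply(seq_along(from),
                     function(i) comp[from[i], p[i]], logical(1)))
    if (ok) res[[length(res) + 1L]] <- setNames(p, from)
  }
  res
}

#' Assess a model against the ranked interfaces of a target
#'
#' Compares every pair of model subunits to every assessed target interface
#' under every chain-role assignment consistent with the sequence-identity
#' gate, keeps the best metrics per interface (highest tier, then lowest
#' I-rms, then lowest L-rms, then highest f(nat)), and records the best
#' interface overall. When the model has as many chains as the target
#' subunit set, whole-model chain bijections are also enumerated so that
#' [simultaneous_capture()] can ask whether one single mapping explains
#' several interfaces at once. The assignment search is exhaustive, which is
#' adequate for the tetramer-and-below targets this protocol addresses.
#'
#' @param model,target \code{capri_structure} objects (the target possibly
#'   augmented with symmetry images).
#' @param interfaces a \code{capri_interfaces} table; by default enumerated
#'   from the target with the configured area floor.
#' @param config a [capri_config()].
#' @param model_id,group_id,target_id metadata carried into the record.
#' @return object of class \code{capri_assessment}: list with
#'   \code{per_interface} (best metrics per interface id),
#'   \code{best_interface}, \code{best_quality}, \code{best_metrics},
#'   \code{chain_mapping} (model-to-target chain assignment of the best
#'   pair), \code{mapping_tiers} (per whole-model bijection and interface,
#'   when applicable) and \code{n_clashes} of the best pair.
#' @export
assess_model <- function(model, target, interfaces = NULL,
                         config = capri_config(), model_id = model$id,
                         group_id = NA_character_,
                         target_id = target$id) {
  if (is.null(interfaces))
    interfaces <- enumerate_interfaces(target, min_area = config$min_area,
                                       config = config)
  if (nrow(interfaces) == 0L) stop("no assessed interfaces for target")
  mch <- structure_chains(model)
  # all target chains, not only interface representatives: whole-model
  # bijections must cover the full subunit set
  tch <- structure_chains(target)
  if (length(mch) < 2L)
    stop("model has fewer than 2 chains; cannot assess an interface")
  # pairwise correspondences with the identity gate
  corr_cache <- new.env(parent = emptyenv())
  pair_corr <- function(mc, tc) {
    key <- paste(mc, tc, sep = "\r")
    if (!is.null(corr_cache[[key]])) return(corr_cache[[key]])
    cr <- map_common_residues(model, target,
                              data.frame(model = mc, target = tc,
                                         stringsAsFactors = FALSE))
    corr_cache[[key]] <- cr
    cr
  }
  comp <- matrix(FALSE, length(mch), length(tch),
                 dimnames = list(mch, tch))
  for (mc in mch) for (tc in tch)
    comp[mc, tc] <- passes_identity_gate(pair_corr(mc, tc),
                                         config$identity_threshold)
  if (!any(comp))
    stop("no model chain passes the ", 100 * config$identity_threshold,
         "% identity gate against any target subunit")
  metric_cache <- new.env(parent = emptyenv())
  pair_metrics <- function(ma, mb, ta, tb) {
    key <- paste(ma, mb, ta, tb, sep = "\r")
    if (!is.null(metric_cache[[key]])) return(metric_cache[[key]])
    ca <- pair_corr(ma, ta); cb <- pair_corr(mb, tb)
    corr <- structure(list(
      pairs = rbind(ca$pairs, cb$pairs),
      identity_fraction = (ca$identity_fraction * ca$aligned_length +
                             cb$identity_fraction * cb$aligned_length) /
        max(1L, ca$aligned_length + cb$aligned_length),
      aligned_length = ca$aligned_length + cb$aligned_length
    ), class = "residue_correspondence")
    m <- try(capri_metrics(model, target, receptor_chains = ta,
                           ligand_chains = tb, corr = corr,
                           config = config), silent = TRUE)
    metric_cache[[key]] <- m
    m
  }
  # best metrics per interface over all model pairs and role assignments
  best_per_iface <- vector("list", nrow(interfaces))
  best_pair <- vector("list", nrow(interfaces))
  model_pairs <- combn(mch, 2L, simplify = FALSE)
  for (ii in seq_len(nrow(interfaces))) {
    ta <- interfaces$chain_a[ii]; tb <- interfaces$chain_b[ii]
    for (mp in model_pairs) {
      for (assign in list(c(mp[1], mp[2]), c(mp[2], mp[1]))) {
        if (!comp[assign[1], ta] || !comp[assign[2], tb]) next
        m <- pair_metrics(assign[1], assign[2], ta, tb)
        if (inherits(m, "try-error")) next
        if (is.null(best_per_iface[[ii]]) ||
            .better_metrics(m, best_per_iface[[ii]])) {
          best_per_iface[[ii]] <- m
          best_pair[[ii]] <- setNames(c(ta, tb), assign)
        }
      }
    }
  }
  assessed <- !vapply(best_per_iface, is.null, logical(1))
  if (!any(assessed))
    stop("no model subunit pair could be evaluated against any interface")
  per_interface <- do.call(rbind, lapply(which(assessed), function(ii) {
    m <- best_per_iface[[ii]]
    data.frame(interface_id = interfaces$id[ii],
               f_nat = m$f_nat, f_nonnat = m$f_nonnat, l_rms = m$l_rms,
               theta_l = m$theta_l, d_l = m$d_l, i_rms = m$i_rms,
               n_clashes = m$n_clashes,
               quality = as.character(classify(m)),
               model_chain_a = names(best_pair[[ii]])[1],
               model_chain_b = names(best_pair[[ii]])[2],
               stringsAsFactors = FALSE)
  }))
  # whole-model bijections for the simultaneous multi-interface check
  mapping_tiers <- NULL; mappings <- NULL
  if (length(mch) == length(tch)) {
    mappings <- .bijections(mch, tch, comp)
    if (length(mappings)) {
      rows <- list()
      for (mi in seq_along(mappings)) {
        pm <- mappings[[mi]]
        inv <- setNames(names(pm), pm)  # target chain -> model chain
        for (ii in seq_len(nrow(interfaces))) {
          ta <- interfaces$chain_a[ii]; tb <- interfaces$chain_b[ii]
          m <- pair_metrics(inv[[ta]], inv[[tb]], ta, tb)
          q <- if (inherits(m, "try-error")) "incorrect"
               else as.character(classify(m))
          rows[[length(rows) + 1L]] <- data.frame(
            mapping = mi, interface_id = interfaces$id[ii], quality = q,
            stringsAsFactors = FALSE)
        }
      }
      mapping_tiers <- do.call(rbind, rows)
    }
  }
  ibest <- which(assessed)[1L]
  for (ii in which(assessed))
    if (.better_metrics(best_per_iface[[ii]], best_per_iface[[ibest]]))
      ibest <- ii
  bm <- best_per_iface[[ibest]]
  structure(list(
    model_id = model_id, group_id = group_id, target_id = target_id,
    interfaces = interfaces, per_interface = per_interface,
    best_interface = interfaces$id[ibest],
    best_quality = classify(bm), best_metrics = bm,
    chain_mapping = best_pair[[ibest]],
    mappings = mappings, mapping_tiers = mapping_tiers,
    n_clashes = bm$n_clashes
  ), class = "capri_assessment")
}

#' @export
print.capri_assessment <- function(x, ...) {
  cat("Assessment of model '", x$model_id, "' vs target '", x$target_id,
      "'\n", sep = "")
  pi <- x$per_interface
  for (i in seq_len(nrow(pi)))
    cat(sprintf(
      "  interface %d: %-10s f(nat) %.2f, L-rms %.2f, I-rms %.2f\n",
      pi$interface_id[i], pi$quality[i], pi$f_nat[i], pi$l_rms[i],
      pi$i_rms[i]))
  cat("  best: interface ", x$best_interface, " (",
      as.character(x$best_quality), ")\n", sep = "")
  invisible(x)
}

#' Does one chain mapping capture several interfaces simultaneously?
#'
#' Building a correct tetramer requires more than predicting each interface
#' in isolation: a single chain assignment of the whole model must achieve
#' the requested quality on all required interfaces at once.
#'
#' @param record a \code{capri_assessment} with whole-model mappings (model
#'   and target subunit counts equal).
#' @param required interface ids that must all be captured.
#' @param min_level minimum tier (default \code{"acceptable"}).
#' @return \code{TRUE} iff some single bijection achieves at least
#'   \code{min_level} on every required interface.
#' @export
simultaneous_capture <- function(record, required,
                                 min_level = "acceptable") {
  stopifnot(inherits(record, "capri_assessment"))
  missing_ids <- setdiff(required, record$interfaces$id)
  if (length(missing_ids))
    stop("required interface id(s) not assessed: ",
         paste(missing_ids, collapse = ", "))
  mt <- record$mapping_tiers
  if (is.null(mt) || nrow(mt) == 0L) return(FALSE)
  lvl <- factor(mt$quality, levels = .quality_levels, ordered = TRUE)
  need <- factor(min_level, levels = .quality_levels, ordered = TRUE)
  ok <- mt$interface_id %in% required & lvl >= need
  hits <- tapply(ok[mt$interface_id %in% required],
                 mt$mapping[mt$interface_id %in% required], all)
  any(hits, na.rm = TRUE)
}
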