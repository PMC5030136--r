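# The per-model CAPRI metric bundle: f(nat), f(non-nat), L-rms, I-rms,
# theta_L, d_L and the clash count, computed for one model against one
# target interface.

#' Assessment configuration
#'
#' Bundles the protocol's tunable cutoffs. Defaults are the protocol values:
#' 5 A heavy-atom contacts, 10 A interface residues, 3 A clashes, 70\%
#' sequence-identity gate, 400 A^2 interface-area floor.
#'
#' @param contact_cutoff residue-residue contact cutoff (A, inclusive).
#' @param interface_cutoff interface-residue cutoff (A, inclusive).
#' @param clash_cutoff clash cutoff (A, strict).
#' @param identity_threshold sequence-identity gate fraction.
#' @param backbone backbone atom set used for all RMSDs; \code{"CA"} for
#'   CA-only RMSDs.
#' @param min_area interface-area floor (A^2) for assessed interfaces.
#' @param probe,sphere_points surface-area quadrature parameters.
#' @return list of class \code{capri_config}.
#' @export
capri_config <- function(contact_cutoff = 5.0, interface_cutoff = 10.0,
                         clash_cutoff = 3.0, identity_threshold = 0.70,
                         backbone = c("N", "CA", "C", "O"),
                         min_area = 400, probe = 1.4, sphere_points = 960) {
  structure(list(contact_cutoff = contact_cutoff,
                 interface_cutoff = interface_cutoff,
                 clash_cutoff = clash_cutoff,
                 identity_threshold = identity_threshold,
                 backbone = backbone, min_area = min_area,
                 probe = probe, sphere_points = sphere_points),
            class = "capri_config")
}

.unordered_pair <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "&")
}

#' Fractions of native and non-native contacts
#'
#' \code{f_nat} is the fraction of the target's residue-residue contacts
#' reproduced in the model (computed over all target residues, not just the
#' common set); \code{f_nonnat} is the fraction of the model's predicted
#' contacts that are absent from the target. Model contacts are carried into
#' target numbering through the residue correspondence; model contacts
#' involving unmapped residues cannot be native.
#'
#' @param model_contacts,target_contacts \code{contact_set} objects computed
#'   at the same cutoff ([residue_contacts()]).
#' @param corr \code{residue_correspondence} mapping model residues onto
#'   target residues.
#' @return list with \code{f_nat}, \code{f_nonnat}, \code{n_native} (target
#'   contacts), \code{n_model} (model contacts), \code{n_reproduced}.
#' @export
native_contact_fractions <- function(model_contacts, target_contacts, corr) {
  if (nrow(target_contacts) == 0L)
    stop("target interface has no contacts; degenerate target")
  map <- setNames(corr$pairs$target_key, corr$pairs$model_key)
  tset <- .unordered_pair(target_contacts$res_a, target_contacts$res_b)
  ma <- unname(map[model_contacts$res_a])
  mb <- unname(map[model_contacts$res_b])
  mapped <- !is.na(ma) & !is.na(mb)
  mset <- .unordered_pair(ma[mapped], mb[mapped])
  n_rep <- length(intersect(unique(mset), unique(tset)))
  n_mod <- nrow(model_contacts)
  list(
    f_nat = n_rep / length(unique(tset)),
    f_nonnat = if (n_mod > 0L)
      (n_mod - sum(mset %in% tset)) / n_mod else 0,
    n_native = length(unique(tset)), n_model = n_mod, n_reproduced = n_rep
  )
}

# Matched backbone coordinate pairs over the common residue set.
# Returns list(model = n x 3, target = n x 3) for residues whose target
# chain is in `target_chains`.
.common_backbone <- function(model, target, corr, target_chains,
                             backbone = c("N", "CA", "C", "O")) {
  pr <- corr$pairs[corr$pairs$target_chain %in% target_chains, , drop = FALSE]
  if (nrow(pr) == 0L)
    return(list(model = matrix(0, 0, 3), target = matrix(0, 0, 3)))
  bm <- model$atoms[model$atoms$elety %in% backbone, , drop = FALSE]
  bt <- target$atoms[target$atoms$elety %in% backbone, , drop = FALSE]
  km <- paste(.res_key(bm$chain, bm$resno, bm$insert), bm$elety)
  kt <- paste(.res_key(bt$chain, bt$resno, bt$insert), bt$elety)
  want_m <- paste(rep(pr$model_key, each = length(backbone)), backbone)
  want_t <- paste(rep(pr$target_key, each = length(backbone)), backbone)
  im <- match(want_m, km)
  it <- match(want_t, kt)
  ok <- !is.na(im) & !is.na(it)  # atom present in both structures
  list(model = .atom_xyz(bm)[im[ok], , drop = FALSE],
       target = .atom_xyz(bt)[it[ok], , drop = FALSE],
       target_keys = pr$target_key[rep(seq_len(nrow(pr)),
                                       each = length(backbone))[ok]])
}

#' Ligand RMSD after receptor superposition
#'
#' Superposes the model receptor onto the target receptor over the common
#' backbone atoms and reports, for the ligand: the backbone RMSD
#' (\code{l_rms}), the residual mis-orientation angle \code{theta_l} (the
#' rotation of the best ligand-on-ligand fit after receptor superposition)
#' and the residual displacement \code{d_l} of the ligand centre of mass.
#'
#' @param model,target \code{capri_structure} objects.
#' @param corr \code{residue_correspondence} between them.
#' @param receptor_chains,ligand_chains target-side chain identifiers of the
#'   two subunits (model counterparts come from \code{corr}).
#' @param backbone backbone atom set.
#' @return list with \code{l_rms}, \code{theta_l} (degrees), \code{d_l} (A),
#'   \code{n_receptor_atoms}, \code{n_ligand_atoms}.
#' @export
ligand_rms <- function(model, target, corr, receptor_chains, ligand_chains,
                       backbone = c("N", "CA", "C", "O")) {
  rec <- .common_backbone(model, target, corr, receptor_chains, backbone)
  if (nrow(rec$model) < 3L)
    stop("receptor common set has fewer than 3 backbone atoms")
  lig <- .common_backbone(model, target, corr, ligand_chains, backbone)
  if (nrow(lig$model) == 0L) stop("ligand common set is empty")
  tf <- superpose(rec$model, rec$target)
  lig_moved <- apply_transform(tf, lig$model)
  l_rms <- sqrt(sum((lig_moved - lig$target)^2) / nrow(lig_moved))
  theta <- if (nrow(lig$model) >= 3L) {
    fit <- try(superpose(lig_moved, lig$target), silent = TRUE)
    if (inherits(fit, "try-error")) NA_real_ else rotation_angle(fit)
  } else NA_real_
  d_l <- sqrt(sum((colMeans(lig_moved) - colMeans(lig$target))^2))
  list(l_rms = l_rms, theta_l = theta, d_l = d_l,
       n_receptor_atoms = nrow(rec$model), n_ligand_atoms = nrow(lig$model))
}

#' Interface RMSD
#'
#' Backbone RMSD over the common set of interface residues after those
#' residues themselves are optimally superposed (re-fit, unlike L-rms).
#' Interface residues are defined on the target: any residue with a heavy
#' atom within the interface cutoff of the partner subunit.
#'
#' @inheritParams ligand_rms
#' @param interface_cutoff heavy-atom cutoff (A) defining target interface
#'   residues.
#' @return list with \code{i_rms} and \code{n_atoms}.
#' @export
interface_rms <- function(model, target, corr, receptor_chains,
                          ligand_chains, interface_cutoff = 10.0,
                          backbone = c("N", "CA", "C", "O")) {
  ta <- chain_atoms(target, receptor_chains)
  tb <- chain_atoms(target, ligand_chains)
  ir <- interface_residues(ta, tb, cutoff = interface_cutoff)
  keep <- c(ir$residues_a, ir$residues_b)
  both <- .common_backbone(model, target, corr,
                           c(receptor_chains, ligand_chains), backbone)
  sel <- both$target_keys %in% keep
  if (sum(sel) < 3L)
    stop("interface maps to fewer than 3 backbone atoms in the model")
  fit <- superpose(both$model[sel, , drop = FALSE],
                   both$target[sel, , drop = FALSE])
  list(i_rms = fit$rmsd, n_atoms = sum(sel))
}

#' Evaluate one model against one target interface
#'
#' Computes the full metric bundle: f(nat), f(non-nat), L-rms, theta_L, d_L,
#' I-rms and the cross-subunit clash count. The receptor is the subunit with
#' the larger common set; when the two subunits tie (homodimers), both role
#' assignments are evaluated and the one with the lower L-rms is kept, so
#' that symmetric models are never penalised by an arbitrary role choice.
#' Disqualification is a population property and is applied afterwards (see
#' [classify_batch()]).
#'
#' @param model,target \code{capri_structure} objects.
#' @param receptor_chains,ligand_chains target-side chain sets of the
#'   assessed interface; default: the first and second target chain.
#' @param corr optional precomputed \code{residue_correspondence}; by
#'   default chains are paired in file order.
#' @param config a [capri_config()].
#' @return object of class \code{capri_metrics}: list with fields
#'   \code{f_nat}, \code{f_nonnat}, \code{l_rms}, \code{theta_l},
#'   \code{d_l}, \code{i_rms}, \code{n_clashes}, \code{disqualified},
#'   plus bookkeeping counts.
#' @export
capri_metrics <- function(model, target, receptor_chains = NULL,
                          ligand_chains = NULL, corr = NULL,
                          config = capri_config()) {
  tch <- structure_chains(target)
  if (is.null(receptor_chains) || is.null(ligand_chains)) {
    if (length(tch) != 2L)
      stop("receptor_chains/ligand_chains required for targets with more ",
           "than two chains")
    receptor_chains <- tch[1L]; ligand_chains <- tch[2L]
  }
  if (is.null(corr)) corr <- map_common_residues(model, target)
  n_rec <- sum(corr$pairs$target_chain %in% receptor_chains)
  n_lig <- sum(corr$pairs$target_chain %in% ligand_chains)
  roles <- if (n_rec > n_lig) {
    list(list(rec = receptor_chains, lig = ligand_chains))
  } else if (n_lig > n_rec) {
    list(list(rec = ligand_chains, lig = receptor_chains))
  } else {
    list(list(rec = receptor_chains, lig = ligand_chains),
         list(rec = ligand_chains, lig = receptor_chains))
  }
  model_chains_for <- function(tchains)
    unique(corr$pairs$model_chain[corr$pairs$target_chain %in% tchains])
  # contacts: target over ALL residues of the interface's subunits
  t_con <- residue_contacts(chain_atoms(target, receptor_chains),
                            chain_atoms(target, ligand_chains),
                            cutoff = config$contact_cutoff)
  m_rec_ch <- model_chains_for(receptor_chains)
  m_lig_ch <- model_chains_for(ligand_chains)
  m_con <- residue_contacts(chain_atoms(model, m_rec_ch),
                            chain_atoms(model, m_lig_ch),
                            cutoff = config$contact_cutoff)
  fr <- native_contact_fractions(m_con, t_con, corr)
  clashes <- count_clashes(chain_atoms(model, m_rec_ch),
                           chain_atoms(model, m_lig_ch),
                           cutoff = config$clash_cutoff)
  best <- NULL
  for (ro in roles) {
    lr <- ligand_rms(model, target, corr, ro$rec, ro$lig,
                     backbone = config$backbone)
    if (is.null(best) || lr$l_rms < best$lr$l_rms)
      best <- list(lr = lr, role = ro)
  }
  ir <- interface_rms(model, target, corr, best$role$rec, best$role$lig,
                      interface_cutoff = config$interface_cutoff,
                      backbone = config$backbone)
  structure(list(
    f_nat = fr$f_nat, f_nonnat = fr$f_nonnat,
    l_rms = best$lr$l_rms, theta_l = best$lr$theta_l, d_l = best$lr$d_l,
    i_rms = ir$i_rms, n_clashes = clashes, disqualified = FALSE,
    n_native_contacts = fr$n_native, n_model_contacts = fr$n_model,
    n_interface_atoms = ir$n_atoms,
    receptor_chains = best$role$rec, ligand_chains = best$role$lig
  ), class = "capri_metrics")
}

#' @export
print.capri_metrics <- function(x, ...) {
  cat(sprintf(
    "CAPRI metrics: f(nat) %.3f, f(non-nat) %.3f\n  L-rms %.2f A, theta_L %.1f deg, d_L %.2f A, I-rms %.2f A\n  clashes %d%s\n",
    x$f_nat, x$f_nonnat, x$l_rms, x$theta_l, x$d_l, x$i_rms, x$n_clashes,
    if (isTRUE(x$disqualified)) " (DISQUALIFIED)" else ""))
  invisible(x)
}
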