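#' @importFrom stats sd setNames aggregate
#' @importFrom utils read.table write.table head combn
NULL

# Residue keys are "chain|resno|insert" strings; insert is "" when absent.
.res_key <- function(chain, resno, insert) {
  insert[is.na(insert)] <- ""
  paste(chain, resno, insert, sep = "|")
}

#' Parse a PDB-format coordinate file into a structure object
#'
#' Reads fixed-column \code{ATOM}/\code{HETATM} records into a flat atom table
#' grouped by chain and residue, in file order. Hydrogen (and deuterium) atoms
#' are dropped, since every distance-based quantity in the assessment protocol
#' is defined over heavy atoms only. Alternate locations are resolved to the
#' highest-occupancy variant (ties go to the first record). \code{HETATM}
#' records are skipped, with the single exception of selenomethionine
#' (\code{MSE}), which is converted to \code{MET} (the selenium atom becomes
#' \code{SD}).
#'
#' @param text character vector of PDB lines (or a single string with
#'   embedded newlines).
#' @param id identifier stored on the returned object.
#' @return an object of class \code{capri_structure}: a list with elements
#'   \code{id}, \code{atoms} (data frame with columns \code{chain},
#'   \code{resno}, \code{insert}, \code{resid}, \code{aa}, \code{elety},
#'   \code{elesy}, \code{x}, \code{y}, \code{z}, \code{o}) and \code{source}.
#' @seealso [read_pdb()] for reading from a file, [write_pdb()] for the
#'   inverse operation.
#' @export
parse_pdb <- function(text, id = "model") {
  if (length(text) == 1L && grepl("\n", text, fixed = TRUE))
    text <- strsplit(text, "\n", fixed = TRUE)[[1L]]
  is_atom <- startsWith(text, "ATOM") | startsWith(text, "HETATM")
  if (!any(is_atom)) {
    first <- if (length(text)) text[1L] else "<empty input>"
    stop("no ATOM records found; first line was: ", first)
  }
  tf <- tempfile(fileext = ".pdb")
  on.exit(unlink(tf))
  writeLines(text, tf)
  pdb <- bio3d::read.pdb(tf, rm.alt = FALSE, verbose = FALSE)
  at <- pdb$atom
  # HETATM rescue: MSE only; everything else is dropped with a warning.
  het <- at$type == "HETATM"
  if (any(het & at$resid != "MSE")) {
    dropped <- unique(at$resid[het & at$resid != "MSE"])
    warning("dropping HETATM residues: ", paste(dropped, collapse = ", "))
  }
  at <- at[at$type == "ATOM" | (het & at$resid == "MSE"), , drop = FALSE]
  if (nrow(at) == 0L) stop("no usable ATOM records after HETATM filtering")
  mse <- at$resid == "MSE"
  if (any(mse)) {
    at$resid[mse] <- "MET"
    se <- mse & at$elety == "SE"
    at$elety[se] <- "SD"
    at$elesy[se] <- "S"
  }
  # element symbol: take from columns 77-78 when present, else infer from name
  sy <- toupper(trimws(ifelse(is.na(at$elesy), "", at$elesy)))
  miss <- sy == ""
  sy[miss] <- substr(trimws(at$elety[miss]), 1L, 1L)
  at$elesy <- sy
  hyd <- sy %in% c("H", "D")
  at <- at[!hyd, , drop = FALSE]
  if (nrow(at) == 0L) stop("structure contains no heavy atoms")
  at$insert[is.na(at$insert)] <- ""
  at$alt[is.na(at$alt)] <- ""
  # altloc: keep highest occupancy per (chain, resno, insert, atom name)
  if (any(at$alt != "")) {
    occ <- ifelse(is.na(at$o), 1, at$o)
    key <- paste(at$chain, at$resno, at$insert, at$elety, sep = "|")
    ord <- order(factor(key, levels = unique(key)), -occ,
                 seq_len(nrow(at)))
    at <- at[ord, , drop = FALSE]
    at <- at[!duplicated(paste(at$chain, at$resno, at$insert, at$elety,
                               sep = "|")), , drop = FALSE]
    # restore file order
    at <- at[order(match(at$eleno, pdb$atom$eleno)), , drop = FALSE]
  }
  atoms <- data.frame(
    chain = as.character(at$chain),
    resno = as.integer(at$resno),
    insert = as.character(at$insert),
    resid = as.character(at$resid),
    aa = unname(bio3d::aa321(at$resid)),
    elety = as.character(at$elety),
    elesy = as.character(at$elesy),
    x = at$x, y = at$y, z = at$z,
    o = ifelse(is.na(at$o), 1, at$o),
    stringsAsFactors = FALSE
  )
  atoms$aa[is.na(atoms$aa)] <- "X"
  structure(list(id = id, atoms = atoms, source = "text"),
            class = "capri_structure")
}

#' Read a structure from a PDB file (gzip transparent)
#'
#' @param file path to a \code{.pdb} or \code{.pdb.gz} file.
#' @param id identifier; defaults to the file name without extension.
#' @return a \code{capri_structure}; see [parse_pdb()].
#' @export
read_pdb <- function(file, id = NULL) {
  if (is.null(id)) id <- sub("\\.(pdb|ent)(\\.gz)?$", "", basename(file))
  con <- if (grepl("\\.gz$", file)) gzfile(file) else file(file)
  on.exit(try(close(con), silent = TRUE))
  lines <- readLines(con, warn = FALSE)
  s <- parse_pdb(lines, id = id)
  s$source <- file
  s
}

#' Write a structure to PDB format
#'
#' Emits standard fixed-column \code{ATOM} records (coordinates to three
#' decimals) that round-trip through [parse_pdb()].
#'
#' @param s a \code{capri_structure}.
#' @param file optional path; when \code{NULL} the text is returned invisibly.
#' @return character vector of PDB lines, invisibly.
#' @export
write_pdb <- function(s, file = NULL) {
  stopifnot(inherits(s, "capri_structure"))
  at <- s$atoms
  if (any(nchar(at$chain) > 1L))
    stop("chain identifiers longer than one character cannot be written to PDB")
  tf <- if (is.null(file)) tempfile(fileext = ".pdb") else file
  bio3d::write.pdb(
    file = tf,
    xyz = as.numeric(t(as.matrix(at[, c("x", "y", "z")]))),
    resno = at$resno, resid = at$resid, chain = at$chain,
    insert = ifelse(at$insert == "", NA, at$insert),
    eleno = seq_len(nrow(at)), elety = at$elety,
    o = at$o, b = rep(0, nrow(at)), elesy = at$elesy
  )
  out <- readLines(tf, warn = FALSE)
  if (is.null(file)) unlink(tf)
  invisible(out)
}

#' @export
print.capri_structure <- function(x, ...) {
  ch <- table(factor(x$atoms$chain, levels = unique(x$atoms$chain)))
  nres <- vapply(split(.res_key(x$atoms$chain, x$atoms$resno, x$atoms$insert),
                       x$atoms$chain),
                 function(k) length(unique(k)), integer(1))
  cat("CAPRI structure '", x$id, "': ", length(ch), " chain(s), ",
      nrow(x$atoms), " heavy atoms\n", sep = "")
  for (c in names(ch))
    cat("  chain ", c, ": ", nres[[c]], " residues, ", ch[[c]], " atoms\n",
        sep = "")
  invisible(x)
}

#' Chains of a structure
#' @param s a \code{capri_structure}.
#' @return character vector of chain identifiers in file order.
#' @export
structure_chains <- function(s) unique(s$atoms$chain)

#' Atom table restricted to selected chains
#' @param s a \code{capri_structure}.
#' @param chains chain identifiers to keep.
#' @return atom data frame (same columns as \code{s$atoms}).
#' @export
chain_atoms <- function(s, chains) {
  miss <- setdiff(chains, s$atoms$chain)
  if (length(miss)) stop("chain(s) not in structure: ",
                         paste(miss, collapse = ", "))
  s$atoms[s$atoms$chain %in% chains, , drop = FALSE]
}

#' One-letter sequence of a chain
#'
#' @param s a \code{capri_structure}.
#' @param chain a chain identifier.
#' @return named character vector of one-letter codes, one per residue in
#'   file order; names are internal residue keys.
#' @export
chain_sequence <- function(s, chain) {
  at <- chain_atoms(s, chain)
  key <- .res_key(at$chain, at$resno, at$insert)
  first <- !duplicated(key)
  setNames(at$aa[first], key[first])
}

# ---- residue correspondence --------------------------------------------------

.identity_submat <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      ab <- c(LETTERS, "*")
      m <- matrix(0, length(ab), length(ab), dimnames = list(ab, ab))
      diag(m) <- 1
      m["X", "X"] <- 0  # unknown residues never count as identical
      cache <<- m
    }
    cache
  }
})

# Global Needleman-Wunsch alignment of two residue-key-named sequences.
# Scoring: identity +1, mismatch 0, linear gap -1.
.align_chain <- function(seq_m, seq_t) {
  al <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(paste(seq_m, collapse = "")),
    Biostrings::AAString(paste(seq_t, collapse = "")),
    substitutionMatrix = .identity_submat(),
    gapOpening = 0, gapExtension = 1, type = "global"
  )
  pa <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1L]]
  sa <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1L]]
  im <- cumsum(pa != "-")
  it <- cumsum(sa != "-")
  both <- pa != "-" & sa != "-"
  data.frame(
    model_key = names(seq_m)[im[both]],
    target_key = names(seq_t)[it[both]],
    aa_model = pa[both], aa_target = sa[both],
    stringsAsFactors = FALSE
  )
}

#' Map the residues a model and a target have in common
#'
#' Builds the residue correspondence on which all residue-dependent
#' quantities (RMSDs, native contacts) are computed. Residues are paired by
#' global pairwise sequence alignment of the extracted one-letter sequences
#' (identity +1, mismatch 0, gap -1), never by residue number, because
#' submission formats permit arbitrary renumbering. Aligned positions are
#' retained only when both residues carry at least one backbone atom.
#'
#' @param model,target \code{capri_structure} objects.
#' @param chain_pairing two-column data frame (\code{model}, \code{target})
#'   of chain identifiers to align; defaults to pairing chains in file order.
#' @return object of class \code{residue_correspondence}: list with
#'   \code{pairs} (data frame mapping model residue keys to target residue
#'   keys), \code{identity_fraction} (identical residues over aligned
#'   positions) and \code{aligned_length}.
#' @export
map_common_residues <- function(model, target, chain_pairing = NULL) {
  if (is.null(chain_pairing)) {
    cm <- structure_chains(model)
    ct <- structure_chains(target)
    if (length(cm) != length(ct))
      stop("model and target have different chain counts; ",
           "supply chain_pairing explicitly")
    chain_pairing <- data.frame(model = cm, target = ct,
                                stringsAsFactors = FALSE)
  }
  bb <- c("N", "CA", "C", "O")
  has_bb <- function(s, keys) {
    at <- s$atoms[s$atoms$elety %in% bb, , drop = FALSE]
    keys %in% .res_key(at$chain, at$resno, at$insert)
  }
  pairs <- list(); n_ident <- 0L; n_aligned <- 0L
  for (i in seq_len(nrow(chain_pairing))) {
    sm <- chain_sequence(model, chain_pairing$model[i])
    st <- chain_sequence(target, chain_pairing$target[i])
    if (!length(sm) || !length(st)) stop("empty chain in pairing row ", i)
    al <- .align_chain(sm, st)
    n_aligned <- n_aligned + nrow(al)
    n_ident <- n_ident + sum(al$aa_model == al$aa_target & al$aa_model != "X")
    keep <- has_bb(model, al$model_key) & has_bb(target, al$target_key)
    al <- al[keep, , drop = FALSE]
    al$model_chain <- chain_pairing$model[i]
    al$target_chain <- chain_pairing$target[i]
    pairs[[i]] <- al
  }
  pairs <- do.call(rbind, pairs)
  structure(list(
    pairs = pairs,
    identity_fraction = if (n_aligned) n_ident / n_aligned else 0,
    aligned_length = n_aligned
  ), class = "residue_correspondence")
}

#' @export
print.residue_correspondence <- function(x, ...) {
  cat("Residue correspondence: ", nrow(x$pairs), " paired residues, ",
      "identity ", sprintf("%.1f%%", 100 * x$identity_fraction),
      " over ", x$aligned_length, " aligned positions\n", sep = "")
  invisible(x)
}

#' Sequence-identity gate for model assessment
#'
#' Models whose sequence identity to the target falls below the gate are not
#' assessed. The threshold is set per target; 70\% is the customary default.
#'
#' @param corr a \code{residue_correspondence}.
#' @param threshold identity fraction required (inclusive).
#' @return \code{TRUE} when \code{identity_fraction >= threshold}.
#' @export
passes_identity_gate <- function(corr, threshold = 0.70) {
  stopifnot(inherits(corr, "residue_correspondence"))
  corr$identity_fraction >= threshold
}

#' Restrict correspondences to residues common to a whole submission set
#'
#' The protocol's batch mode: the common set is the intersection, across all
#' submitted models, of target residues present in each model-target
#' correspondence. Per-model mapping (the default elsewhere) is the library
#' primitive; this reproduces the whole-round convention.
#'
#' @param corrs list of \code{residue_correspondence} objects against the
#'   same target.
#' @return the input list with each \code{pairs} table restricted to target
#'   residues present in every correspondence.
#' @export
intersect_common_residues <- function(corrs) {
  stopifnot(length(corrs) >= 1L)
  common <- Reduce(intersect, lapply(corrs, function(cr) cr$pairs$target_key))
  lapply(corrs, function(cr) {
    cr$pairs <- cr$pairs[cr$pairs$target_key %in% common, , drop = FALSE]
    cr
  })
}
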