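# Structure-derived pocket metrics from PDB/mmCIF coordinates:
# atom-pair distances, residue-matched C-alpha RMSD after Kabsch
# superposition, normalized per-residue B-factors and their deltas,
# and signed torsion angles.

#' Read a coordinate file into a flat atom table
#'
#' Parses PDB or mmCIF (by extension; `.cif`/`.mmcif` vs anything else)
#' via bio3d. Only the first model is kept. Alternate locations are
#' resolved to the highest-occupancy altloc, ties going to altloc "A"
#' (then alphabetical). Hydrogens are retained in the table but carry an
#' `is_h` flag so B-factor statistics can exclude them.
#'
#' @param path coordinate file.
#' @return A `structure_model`: data frame with columns `chain`,
#'   `resno`, `insert`, `resid`, `atom` (atom name), `altloc`, `occ`,
#'   `x`, `y`, `z`, `b`, `element`, `is_h`; the source path is kept in
#'   `attr(x, "source")`.
#' @export
read_structure <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  is_cif <- grepl("\\.(cif|mmcif)$", path, ignore.case = TRUE)
  pdb <- if (is_cif) suppressWarnings(bio3d::read.cif(path, verbose = FALSE))
         else bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE,
                              verbose = FALSE)
  a <- pdb$atom
  if (is.null(a) || nrow(a) == 0L) {
    stop("no ATOM records in ", path, call. = FALSE)
  }
  insert <- a$insert
  insert[is.na(insert)] <- ""
  altloc <- a$alt
  altloc[is.na(altloc)] <- ""
  occ <- a$o
  occ[is.na(occ)] <- 1
  elem <- a$elesy
  if (is.null(elem) || all(is.na(elem))) {
    elem <- toupper(substr(gsub("[^A-Za-z].*$", "", a$elety), 1, 1))
  }
  m <- data.frame(chain = as.character(a$chain),
                  resno = as.integer(a$resno), insert = insert,
                  resid = as.character(a$resid),
                  atom = as.character(a$elety), altloc = altloc,
                  occ = occ, x = a$x, y = a$y, z = a$z, b = a$b,
                  element = as.character(elem),
                  stringsAsFactors = FALSE)
  if (!all(is.finite(c(m$x, m$y, m$z)))) {
    stop("non-finite coordinates in ", path, call. = FALSE)
  }
  # altloc resolution: keep one atom per (chain, resno, insert, atom name)
  key <- paste(m$chain, m$resno, m$insert, m$atom, sep = "\r")
  if (anyDuplicated(key)) {
    rank <- order(key, -m$occ,
                  ifelse(m$altloc == "A", 0L, 1L), m$altloc)
    m <- m[rank, , drop = FALSE]
    m <- m[!duplicated(paste(m$chain, m$resno, m$insert, m$atom,
                             sep = "\r")), , drop = FALSE]
    m <- m[order(as.integer(rownames(m))), , drop = FALSE]
  }
  rownames(m) <- NULL
  m$is_h <- m$element %in% c("H", "D")
  attr(m, "source") <- path
  class(m) <- c("structure_model", "data.frame")
  m
}

# Resolve "chain:resno:atom" (or a list with those fields) to one row.
resolve_atom <- function(model, sel) {
  if (is.character(sel) && length(sel) == 1L) {
    parts <- strsplit(sel, ":", fixed = TRUE)[[1]]
    if (length(parts) != 3L) {
      stop("selector must be \"chain:resno:atom\", got: ", sel, call. = FALSE)
    }
    sel <- list(chain = parts[1], resno = as.integer(parts[2]),
                atom = parts[3])
  }
  hit <- which(model$chain == sel$chain & model$resno == sel$resno &
                 model$atom == sel$atom)
  if (length(hit) != 1L) {
    stop("selector (", sel$chain, ":", sel$resno, ":", sel$atom,
         ") resolves to ", length(hit), " atoms", call. = FALSE)
  }
  hit
}

#' Euclidean distance between two atoms
#'
#' @param model a `structure_model`.
#' @param sel_a,sel_b atom selectors, `"chain:resno:atom_name"` (e.g.
#'   `"A:117:CA"`) or lists with `chain`, `resno`, `atom`.
#' @return distance in Angstrom.
#' @export
atom_distance <- function(model, sel_a, sel_b) {
  i <- resolve_atom(model, sel_a)
  j <- resolve_atom(model, sel_b)
  sqrt(sum((unlist(model[i, c("x", "y", "z")]) -
              unlist(model[j, c("x", "y", "z")]))^2))
}

# Kabsch: optimal rotation of b onto a (both n x 3, centered), with
# reflection guard.
kabsch_rotation <- function(a, b) {
  s <- svd(crossprod(b, a))
  d <- sign(det(s$u %*% t(s$v)))
  s$u %*% diag(c(1, 1, d)) %*% t(s$v)
}

#' Residue-matched C-alpha RMSD after optimal superposition
#'
#' Matches C-alpha atoms between the two models by (chain, residue
#' number) intersection within the selected chain/range, superposes them
#' by the least-squares Kabsch rotation (orthogonal Procrustes with
#' reflection guard) and returns the root-mean-square deviation.
#'
#' @param model_a,model_b `structure_model` objects.
#' @param chain_a chain id in `model_a` (default: its first chain).
#' @param chain_b chain id in `model_b` (default `chain_a`).
#' @param resno_range optional `c(lo, hi)` residue-number filter.
#' @return list with `rmsd` (Angstrom) and `n_matched`.
#' @export
calpha_rmsd <- function(model_a, model_b, chain_a = NULL, chain_b = NULL,
                        resno_range = NULL) {
  chain_a <- chain_a %||% model_a$chain[1]
  chain_b <- chain_b %||% chain_a
  pick <- function(m, ch) {
    ca <- m[m$chain == ch & m$atom == "CA" & !m$is_h, , drop = FALSE]
    if (!is.null(resno_range)) {
      ca <- ca[ca$resno >= resno_range[1] & ca$resno <= resno_range[2], ,
               drop = FALSE]
    }
    ca[!duplicated(ca$resno), , drop = FALSE]
  }
  ca_a <- pick(model_a, chain_a)
  ca_b <- pick(model_b, chain_b)
  common <- intersect(ca_a$resno, ca_b$resno)
  if (length(common) < 3L) {
    stop("fewer than 3 matched C-alpha pairs (", length(common), ")",
         call. = FALSE)
  }
  xa <- as.matrix(ca_a[match(common, ca_a$resno), c("x", "y", "z")])
  xb <- as.matrix(ca_b[match(common, ca_b$resno), c("x", "y", "z")])
  xa <- sweep(xa, 2, colMeans(xa))
  xb <- sweep(xb, 2, colMeans(xb))
  rot <- kabsch_rotation(xa, xb)
  diffs <- xa - xb %*% rot
  list(rmsd = sqrt(mean(rowSums(diffs^2))), n_matched = length(common))
}

#' Normalized per-residue B-factors
#'
#' The per-residue B-factor is the unweighted mean over the residue's
#' non-hydrogen atoms (or C-alpha only); the overall B-factor is the
#' mean over all selected non-hydrogen atoms; each residue's normalized
#' value is its mean divided by the overall mean, so the atom-count-
#' weighted average of normalized values is exactly 1.
#'
#' @param model a `structure_model`.
#' @param chain chain id of the receptor region (default: first chain).
#' @param resno_range optional `c(lo, hi)` residue filter.
#' @param atoms `"all"` (non-hydrogen, default) or `"calpha"`.
#' @return A `bfactor_profile`: data frame with `chain`, `resno`,
#'   `resid`, `n_atoms`, `mean_b`, `normalized_b`; the overall B-factor
#'   is in `attr(x, "overall_b")`.
#' @export
normalized_bfactors <- function(model, chain = NULL, resno_range = NULL,
                                atoms = c("all", "calpha")) {
  atoms <- match.arg(atoms)
  chain <- chain %||% model$chain[1]
  sel <- model[model$chain == chain & !model$is_h, , drop = FALSE]
  if (atoms == "calpha") sel <- sel[sel$atom == "CA", , drop = FALSE]
  if (!is.null(resno_range)) {
    sel <- sel[sel$resno >= resno_range[1] & sel$resno <= resno_range[2], ,
               drop = FALSE]
  }
  if (nrow(sel) == 0L) stop("empty selection", call. = FALSE)
  overall <- mean(sel$b)
  if (overall == 0) stop("overall B-factor is zero", call. = FALSE)
  agg <- do.call(rbind, lapply(split(sel, sel$resno), function(r) {
    data.frame(chain = chain, resno = r$resno[1], resid = r$resid[1],
               n_atoms = nrow(r), mean_b = mean(r$b),
               stringsAsFactors = FALSE)
  }))
  agg <- agg[order(agg$resno), , drop = FALSE]
  agg$normalized_b <- agg$mean_b / overall
  rownames(agg) <- NULL
  attr(agg, "overall_b") <- overall
  class(agg) <- c("bfactor_profile", "data.frame")
  agg
}

#' Per-residue difference of two normalized B-factor profiles
#'
#' Matches residues by number and reports
#' `delta = normalized_b_a - normalized_b_b` with a sign classification
#' (`"lower"` where structure A is less mobile than B, the
#' blue/red coloring convention for mapping stabilization onto a
#' structure).
#'
#' @param profile_a,profile_b `bfactor_profile` objects.
#' @return data frame with `resno`, `resid`, `normalized_b_a`,
#'   `normalized_b_b`, `delta` and `classification`
#'   (`"lower"`/`"higher"`/`"equal"` in A relative to B).
#' @export
bfactor_delta <- function(profile_a, profile_b) {
  common <- intersect(profile_a$resno, profile_b$resno)
  if (!length(common)) {
    stop("profiles share no residues", call. = FALSE)
  }
  ia <- match(common, profile_a$resno)
  ib <- match(common, profile_b$resno)
  delta <- profile_a$normalized_b[ia] - profile_b$normalized_b[ib]
  data.frame(resno = common, resid = profile_a$resid[ia],
             normalized_b_a = profile_a$normalized_b[ia],
             normalized_b_b = profile_b$normalized_b[ib],
             delta = delta,
             classification = ifelse(delta < 0, "lower",
                                     ifelse(delta > 0, "higher", "equal")),
             stringsAsFactors = FALSE)
}

#' Signed torsion angle over four atoms
#'
#' Standard IUPAC sign convention: looking down the central bond
#' (atom 2 to atom 3), a clockwise rotation from the 1-2 bond to the 3-4
#' bond is positive. The value lies in (-180, 180].
#'
#' @param model a `structure_model`.
#' @param sel1,sel2,sel3,sel4 atom selectors (see [atom_distance()]).
#' @return torsion angle in degrees.
#' @export
dihedral <- function(model, sel1, sel2, sel3, sel4) {
  idx <- vapply(list(sel1, sel2, sel3, sel4), resolve_atom, 0L,
                model = model)
  if (anyDuplicated(idx)) stop("the four atoms must be distinct", call. = FALSE)
  p <- as.matrix(model[idx, c("x", "y", "z")])
  b1 <- p[2, ] - p[1, ]
  b2 <- p[3, ] - p[2, ]
  b3 <- p[4, ] - p[3, ]
  n1 <- pracma_cross(b1, b2)
  n2 <- pracma_cross(b2, b3)
  if (sqrt(sum(n1^2)) < 1e-10 || sqrt(sum(n2^2)) < 1e-10) {
    stop("collinear atoms: torsion undefined", call. = FALSE)
  }
  x <- sum(n1 * n2)
  y <- sum(pracma_cross(n1, n2) * b2 / sqrt(sum(b2^2)))
  ang <- atan2(y, x) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Write a structure model as a minimal mmCIF atom_site loop
#'
#' Companion to [write_structure_pdb()] for exercising both coordinate
#' formats with identical content.
#'
#' @param model a `structure_model` (or compatible data frame).
#' @param path output path (`.cif`).
#' @return `path`, invisibly.
#' @export
write_structure_cif <- function(model, path) {
  fields <- c("group_PDB", "id", "type_symbol", "label_atom_id",
              "label_alt_id", "label_comp_id", "label_asym_id",
              "label_entity_id", "label_seq_id", "pdbx_PDB_ins_code",
              "Cartn_x", "Cartn_y", "Cartn_z", "occupancy",
              "B_iso_or_equiv", "pdbx_formal_charge", "auth_seq_id",
              "auth_comp_id", "auth_asym_id", "auth_atom_id",
              "pdbx_PDB_model_num")
  rows <- sprintf(
    "ATOM %d %s %s %s %s %s 1 %d %s %.3f %.3f %.3f %.2f %.2f ? %d %s %s %s 1",
    seq_len(nrow(model)), model$element, model$atom,
    ifelse(nzchar(model$altloc), model$altloc, "."),
    model$resid, model$chain, model$resno,
    ifelse(nzchar(model$insert), model$insert, "?"),
    model$x, model$y, model$z, model$occ, model$b,
    model$resno, model$resid, model$chain, model$atom)
  writeLines(c("data_synthetic", "loop_",
               paste0("_atom_site.", fields), rows), path)
  invisible(path)
}

#' Write a structure model back out as minimal PDB text
#'
#' Used mainly to materialize synthetic coordinate fixtures; writes
#' standard fixed-width ATOM records (occupancy and B-factor included).
#'
#' @param model a `structure_model` (or compatible data frame).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_structure_pdb <- function(model, path) {
  lines <- sprintf(
    "ATOM  %5d %-4s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    seq_len(nrow(model)),
    ifelse(nchar(model$atom) >= 4, model$atom, paste0(" ", model$atom)),
    " ", model$resid, model$chain, model$resno,
    ifelse(nzchar(model$insert), model$insert, " "),
    model$x, model$y, model$z, model$occ, model$b, model$element)
  writeLines(c(lines, "END"), path)
  invisible(path)
}
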