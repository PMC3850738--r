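# CAPRI docking quality measures: fnat, interface RMSD, ligand RMSD, and
# the four-class quality labels derived from them.

QUALITY_LEVELS <- c("incorrect", "acceptable", "medium", "high")

#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the proper rotation and translation minimising the RMSD between
#' two paired point sets, via SVD of the 3x3 cross-covariance with the
#' usual determinant correction so no reflection is returned.
#'
#' @param ref n x 3 reference coordinates.
#' @param mov n x 3 moving coordinates (paired row-wise with `ref`).
#' @return list with `rotation` (3x3, det +1), `translation` (length 3),
#'   and `rmsd`; the fitted coordinates are
#'   `mov %*% t(rotation) + translation` (rows).
#' @export
kabsch_superpose <- function(ref, mov) {
  ref <- as.matrix(ref); mov <- as.matrix(mov)
  if (!all(dim(ref) == dim(mov))) stop("coordinate sets differ in size")
  if (nrow(ref) < 3L) stop("need at least 3 points to superpose")
  cr <- colMeans(ref); cm <- colMeans(mov)
  P <- sweep(mov, 2, cm)   # moving, centred
  Q <- sweep(ref, 2, cr)   # reference, centred
  H <- crossprod(P, Q)     # 3x3
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  fitted <- P %*% t(R)
  rmsd <- sqrt(mean(rowSums((fitted - Q)^2)))
  list(rotation = R, translation = as.numeric(cr - R %*% cm), rmsd = rmsd)
}

apply_superposition <- function(coords, sup) {
  sweep(as.matrix(coords) %*% t(sup$rotation), 2, sup$translation, `+`)
}

rmsd_between <- function(a, b) sqrt(mean(rowSums((a - b)^2)))

# Heavy-atom coordinates and per-atom residue keys for one side of a
# partition.
side_heavy <- function(structure, chains) {
  a <- structure$atom
  keep <- a$chain %in% chains & is_heavy(structure)
  a <- a[keep, , drop = FALSE]
  ins <- ifelse(is.na(a$insert), "", a$insert)
  list(xyz = cbind(a$x, a$y, a$z), res = paste(a$chain, a$resno, ins, sep = "|"))
}

#' Intermolecular residue contacts
#'
#' A receptor residue and a ligand residue are in contact when any pair of
#' their heavy atoms lies within `cutoff` angstroms (5 by default, the
#' CAPRI fnat convention).
#'
#' @param structure A [pdb_structure].
#' @param partition A `complex_partition`.
#' @param cutoff Heavy-atom distance cutoff in angstroms.
#' @return Character vector of contact pairs
#'   `"rchain|resno|ins::lchain|resno|ins"` (set semantics, sorted).
#' @export
intermolecular_contacts <- function(structure, partition, cutoff = 5) {
  stopifnot(cutoff > 0)
  r <- side_heavy(structure, partition$receptor)
  l <- side_heavy(structure, partition$ligand)
  if (nrow(r$xyz) == 0L || nrow(l$xyz) == 0L)
    stop("empty receptor or ligand side")
  # cross squared-distance matrix (receptor atoms x ligand atoms)
  d2 <- outer(rowSums(r$xyz^2), rowSums(l$xyz^2), `+`) -
    2 * tcrossprod(r$xyz, l$xyz)
  hit <- which(d2 <= cutoff^2, arr.ind = TRUE)
  if (nrow(hit) == 0L) return(character(0))
  sort(unique(paste(r$res[hit[, 1]], l$res[hit[, 2]], sep = "::")))
}

#' Fraction of native contacts
#'
#' @param native_contacts,decoy_contacts Contact sets from
#'   [intermolecular_contacts].
#' @return `|native intersect decoy| / |native|`.
#' @export
fnat <- function(native_contacts, decoy_contacts) {
  if (length(native_contacts) == 0L)
    stop("fnat undefined: native complex has no intermolecular contacts")
  length(intersect(native_contacts, decoy_contacts)) / length(native_contacts)
}

#' Ligand RMSD
#'
#' Superposes the decoy receptor backbone onto the native receptor
#' backbone and reports the backbone RMSD over the ligand residues under
#' that transform (no second fit).
#'
#' @param native,decoy [pdb_structure] objects with matching numbering.
#' @param partition A `complex_partition`.
#' @return RMSD in angstroms.
#' @export
lrmsd <- function(native, decoy, partition) {
  lrmsd_bb(bb_select(native, partition$receptor),
           bb_select(native, partition$ligand),
           bb_select(decoy, partition$receptor),
           bb_select(decoy, partition$ligand))
}

# matrix-level LRMSD on precomputed backbone selections
lrmsd_bb <- function(nat_rec, nat_lig, dec_rec, dec_lig) {
  rec <- pair_bb(nat_rec, dec_rec)
  sup <- kabsch_superpose(rec$ref, rec$mov)
  lig <- pair_bb(nat_lig, dec_lig)
  rmsd_between(apply_superposition(lig$mov, sup), lig$ref)
}

# Residue keys of the native interface: residues of either molecule with a
# heavy atom within `cutoff` of the other molecule.
interface_residues <- function(native, partition, cutoff = 10) {
  r <- side_heavy(native, partition$receptor)
  l <- side_heavy(native, partition$ligand)
  d2 <- outer(rowSums(r$xyz^2), rowSums(l$xyz^2), `+`) -
    2 * tcrossprod(r$xyz, l$xyz)
  hit <- d2 <= cutoff^2
  keys <- c(unique(r$res[rowSums(hit) > 0]), unique(l$res[colSums(hit) > 0]))
  if (length(keys) == 0L) stop("empty native interface at cutoff ", cutoff)
  keys
}

#' Interface RMSD
#'
#' Interface residues are defined on the NATIVE complex (any heavy atom of
#' one molecule within `interface_cutoff` of the other; 10 angstroms by
#' default).  Returns the minimal backbone RMSD over those residues after
#' superposing the decoy interface onto the native interface.
#'
#' @inheritParams lrmsd
#' @param interface_cutoff Native heavy-atom distance defining the
#'   interface, in angstroms.
#' @return RMSD in angstroms.
#' @export
irmsd <- function(native, decoy, partition, interface_cutoff = 10) {
  keys <- interface_residues(native, partition, interface_cutoff)
  irmsd_bb(bb_pick(bb_select(native), keys), bb_pick(bb_select(decoy), keys))
}

# subset a backbone selection to atoms of the given residue keys
bb_pick <- function(bb, res_keys) {
  keep <- sub("\\|[A-Z0-9']+$", "", bb$key) %in% res_keys
  list(key = bb$key[keep], xyz = bb$xyz[keep, , drop = FALSE])
}

irmsd_bb <- function(nat_iface, dec_iface) {
  pb <- pair_bb(nat_iface, dec_iface)
  kabsch_superpose(pb$ref, pb$mov)$rmsd
}

#' Classify pose quality by the CAPRI criteria
#'
#' Assigns incorrect / acceptable / medium / high from (fnat, LRMSD,
#' IRMSD), evaluating the class predicates from high downwards so every
#' triple receives exactly one label:
#' \itemize{
#'  \item high: fnat >= 0.5 and (LRMSD <= 1 or IRMSD <= 1)
#'  \item medium: (fnat >= 0.5 and LRMSD > 1 and IRMSD > 1) or
#'    (0.3 <= fnat < 0.5 and (LRMSD <= 5 or IRMSD <= 2))
#'  \item acceptable: (fnat >= 0.3 and LRMSD > 5 and IRMSD > 2) or
#'    (0.1 <= fnat < 0.3 and (LRMSD <= 10 or IRMSD <= 4))
#'  \item incorrect: fnat < 0.1 or (LRMSD > 10 and IRMSD > 4)
#' }
#'
#' @param fnat,lrmsd,irmsd Numeric vectors (recycled to common length).
#' @return Ordered factor with levels incorrect < acceptable < medium <
#'   high.
#' @export
classify_quality <- function(fnat, lrmsd, irmsd) {
  n <- max(length(fnat), length(lrmsd), length(irmsd))
  f <- rep_len(fnat, n); L <- rep_len(lrmsd, n); I <- rep_len(irmsd, n)
  if (any(!is.finite(f) | !is.finite(L) | !is.finite(I)))
    stop("non-finite quality metrics")
  if (any(f < 0 | f > 1 | L < 0 | I < 0))
    stop("quality metrics out of domain (fnat in [0,1], RMSDs >= 0)")
  out <- rep("incorrect", n)
  acc <- (f >= 0.3 & L > 5 & I > 2) | (f >= 0.1 & f < 0.3 & (L <= 10 | I <= 4))
  med <- (f >= 0.5 & L > 1 & I > 1) | (f >= 0.3 & f < 0.5 & (L <= 5 | I <= 2))
  hig <- f >= 0.5 & (L <= 1 | I <= 1)
  out[acc] <- "acceptable"
  out[med] <- "medium"
  out[hig] <- "high"
  factor(out, levels = QUALITY_LEVELS, ordered = TRUE)
}

quality_ordinal <- function(class) as.integer(class) - 1L

#' Per-decoy quality table for a decoy set
#'
#' Computes fnat, IRMSD, LRMSD and the CAPRI class of every decoy against
#' the native.
#'
#' @param ds A [decoy_set].
#' @param contact_cutoff fnat heavy-atom contact cutoff (angstroms).
#' @param interface_cutoff Native interface cutoff for IRMSD (angstroms).
#' @return data.frame: `decoy_id`, `fnat`, `irmsd`, `lrmsd`, `class`.
#' @export
quality_table <- function(ds, contact_cutoff = 5, interface_cutoff = 10) {
  part <- ds$partition
  natc <- intermolecular_contacts(ds$native, part, contact_cutoff)
  nat_rec <- bb_select(ds$native, part$receptor)
  nat_lig <- bb_select(ds$native, part$ligand)
  ikeys <- interface_residues(ds$native, part, interface_cutoff)
  nat_iface <- bb_pick(bb_select(ds$native), ikeys)
  ids <- names(ds$decoys)
  f <- L <- I <- numeric(length(ids))
  for (k in seq_along(ids)) {
    d <- ds$decoys[[k]]
    f[k] <- fnat(natc, intermolecular_contacts(d, part, contact_cutoff))
    dec_rec <- bb_select(d, part$receptor)
    dec_lig <- bb_select(d, part$ligand)
    L[k] <- lrmsd_bb(nat_rec, nat_lig, dec_rec, dec_lig)
    I[k] <- irmsd_bb(nat_iface,
                     bb_pick(list(key = c(dec_rec$key, dec_lig$key),
                                  xyz = rbind(dec_rec$xyz, dec_lig$xyz)),
                             ikeys))
  }
  data.frame(decoy_id = ids, fnat = f, irmsd = I, lrmsd = L,
             class = classify_quality(f, L, I), stringsAsFactors = FALSE)
}

#' Write a per-case quality table as TSV
#' @param qt Result of [quality_table].
#' @param path Output path.
#' @export
write_quality_table <- function(qt, path) {
  utils::write.table(qt, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
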