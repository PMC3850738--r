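# Structure representation and PDB input.
#
# A `pdb_structure` is a thin S3 wrapper around an atom table using bio3d's
# column conventions (eleno, elety, alt, resid, chain, resno, insert, elesy,
# x, y, z).  Residue identity is (chain, resno, insert); PDB numbering is
# preserved verbatim.

BACKBONE_ATOMS <- c("N", "CA", "C", "O")

#' Construct a structure from an atom table
#'
#' @param atom data.frame with columns `elety`, `resid`, `chain`, `resno`,
#'   `x`, `y`, `z`; optional `eleno`, `alt`, `insert`, `elesy`.
#' @return An object of class `pdb_structure`.
#' @export
pdb_structure <- function(atom) {
  need <- c("elety", "resid", "chain", "resno", "x", "y", "z")
  miss <- setdiff(need, names(atom))
  if (length(miss) > 0L)
    stop("atom table missing columns: ", paste(miss, collapse = ", "))
  if (nrow(atom) == 0L) stop("empty structure: no atoms")
  if (!all(is.finite(atom$x) & is.finite(atom$y) & is.finite(atom$z)))
    stop("non-finite atom coordinates")
  if (any(!nzchar(atom$elety))) stop("atom with empty name")
  if (is.null(atom$eleno)) atom$eleno <- seq_len(nrow(atom))
  if (is.null(atom$alt)) atom$alt <- NA_character_
  if (is.null(atom$insert)) atom$insert <- NA_character_
  if (is.null(atom$elesy)) atom$elesy <- guess_element(atom$elety)
  atom$chain <- as.character(atom$chain)
  rownames(atom) <- NULL
  obj <- list(atom = atom)
  class(obj) <- "pdb_structure"
  obj
}

#' @export
print.pdb_structure <- function(x, ...) {
  cat(sprintf("pdb_structure: %d atoms, %d residues, chains: %s\n",
              nrow(x$atom), length(unique(residue_keys(x))),
              paste(chain_ids(x), collapse = " ")))
  invisible(x)
}

# Residue key "chain|resno|insert" per atom, in atom order.
residue_keys <- function(structure) {
  a <- structure$atom
  ins <- ifelse(is.na(a$insert), "", a$insert)
  paste(a$chain, a$resno, ins, sep = "|")
}

chain_ids <- function(structure) unique(structure$atom$chain)

n_atoms <- function(structure) nrow(structure$atom)

guess_element <- function(elety) {
  # first alphabetic character of the atom name; good enough for the
  # standard amino-acid heavy atoms and hydrogens written by this package
  sub("^[0-9]*([A-Za-z]).*$", "\\1", elety)
}

is_heavy <- function(structure) {
  el <- structure$atom$elesy
  bad <- is.na(el) | el == ""
  if (any(bad)) el[bad] <- guess_element(structure$atom$elety[bad])
  toupper(el) != "H"
}

#' Read a PDB coordinate file
#'
#' Parses ATOM (and optionally HETATM) records via bio3d.  For atoms with
#' multiple alternate-location indicators only the first-encountered
#' location is retained under the default policy, and waters/heteroatoms
#' are excluded by default.
#'
#' @param path Path to a PDB file.
#' @param altloc `"first"` (default) keeps the first-encountered location
#'   for each (chain, residue, atom name); `"all"` keeps every location.
#' @param keep_hetatm Keep non-water HETATM records (default `FALSE`).
#' @return A [pdb_structure].
#' @export
read_pdb <- function(path, altloc = c("first", "all"), keep_hetatm = FALSE) {
  altloc <- match.arg(altloc)
  if (!file.exists(path)) stop("cannot read PDB file: ", path)
  p <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, rm.alt = FALSE, verbose = FALSE)),
    error = function(e) stop("PDB parse error in '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  a <- p$atom
  a <- a[a$type == "ATOM" | (keep_hetatm & a$type == "HETATM" & a$resid != "HOH"), ,
         drop = FALSE]
  if (nrow(a) == 0L) stop("no ATOM records in '", path, "'")
  s <- pdb_structure(a[, c("eleno", "elety", "alt", "resid", "chain",
                           "resno", "insert", "elesy", "x", "y", "z")])
  if (altloc == "first") s <- filter_altloc_first(s)
  s
}

# Keep the first-encountered location per (chain, resno, insert, atom name).
filter_altloc_first <- function(structure) {
  a <- structure$atom
  key <- paste(residue_keys(structure), a$elety, sep = "|")
  structure$atom <- a[!duplicated(key), , drop = FALSE]
  rownames(structure$atom) <- NULL
  structure
}

#' Read a multi-MODEL PDB file as separate poses
#'
#' @param path Path to a PDB file with MODEL/ENDMDL records.
#' @return A list of [pdb_structure], one per model.
#' @export
read_pdb_models <- function(path) {
  p <- suppressWarnings(bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE,
                                        verbose = FALSE))
  a <- p$atom[p$atom$type == "ATOM", , drop = FALSE]
  if (nrow(a) == 0L) stop("no ATOM records in '", path, "'")
  nmod <- nrow(p$xyz)
  lapply(seq_len(nmod), function(i) {
    xyz <- matrix(p$xyz[i, ], ncol = 3L, byrow = TRUE)[p$atom$type == "ATOM", ,
                                                       drop = FALSE]
    b <- a
    b$x <- xyz[, 1]; b$y <- xyz[, 2]; b$z <- xyz[, 3]
    filter_altloc_first(pdb_structure(b))
  })
}

#' Write a structure as minimal PDB text
#'
#' Emits fixed-column ATOM records (columns 1-66) plus TER/END; the
#' counterpart of [read_pdb] used by the synthetic generator and tests.
#'
#' @param structure A [pdb_structure].
#' @param path Output file path.
#' @export
write_pdb <- function(structure, path) {
  a <- structure$atom
  name4 <- ifelse(nchar(a$elety) >= 4L, substr(a$elety, 1, 4),
                  sprintf(" %-3s", a$elety))
  lines <- sprintf("ATOM  %5d %4s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                   a$eleno %% 100000L, name4,
                   ifelse(is.na(a$alt), " ", a$alt), a$resid, a$chain,
                   a$resno, ifelse(is.na(a$insert), " ", a$insert),
                   a$x, a$y, a$z, 1, 0, toupper(a$elesy))
  writeLines(c(lines, "TER", "END"), path)
  invisible(path)
}

#' Partition a complex into receptor and ligand chains
#'
#' @param structure A [pdb_structure] with at least two chains.
#' @param receptor_chains Optional character vector naming the receptor
#'   chains; the complement becomes the ligand.  When omitted the largest
#'   chain (by atom count) is the receptor and the remaining chains the
#'   ligand, so the ligand is the smaller molecule.
#' @return A list with elements `receptor` and `ligand` (chain-id vectors),
#'   class `complex_partition`.
#' @export
partition_complex <- function(structure, receptor_chains = NULL) {
  ch <- chain_ids(structure)
  if (length(ch) < 2L) stop("cannot partition a single-chain structure")
  if (is.null(receptor_chains)) {
    sizes <- table(structure$atom$chain)[ch]
    receptor_chains <- ch[which.max(sizes)]
  } else {
    receptor_chains <- as.character(receptor_chains)
    absent <- setdiff(receptor_chains, ch)
    if (length(absent) > 0L)
      stop("receptor chain(s) not in structure: ", paste(absent, collapse = ","))
    if (length(receptor_chains) == length(ch))
      stop("receptor chains must leave at least one ligand chain")
  }
  part <- list(receptor = receptor_chains,
               ligand = setdiff(ch, receptor_chains))
  class(part) <- "complex_partition"
  part
}

#' Subset a structure to a set of chains
#'
#' @param structure A [pdb_structure].
#' @param chains Character vector of chain ids to keep.
#' @return A [pdb_structure] containing only those chains.
#' @export
subset_chains <- function(structure, chains) {
  keep <- structure$atom$chain %in% chains
  if (!any(keep)) stop("no atoms on chain(s): ", paste(chains, collapse = ","))
  pdb_structure(structure$atom[keep, , drop = FALSE])
}

#' Backbone atom selection
#'
#' Returns the N, CA, C, O coordinates per residue, in residue order, keyed
#' by (chain, resno, insert, atom name) so selections from a native and a
#' decoy can be index-aligned.  Residues missing some backbone atoms
#' contribute only the atoms present (a warning is raised).
#'
#' @param structure A [pdb_structure].
#' @param chains Optional chain filter.
#' @return data.frame with columns `key` (chain|resno|insert|atom), `x`,
#'   `y`, `z`.
#' @export
select_backbone <- function(structure, chains = NULL) {
  a <- structure$atom
  if (!is.null(chains)) a <- a[a$chain %in% chains, , drop = FALSE]
  rk <- {
    ins <- ifelse(is.na(a$insert), "", a$insert)
    paste(a$chain, a$resno, ins, sep = "|")
  }
  keep <- a$elety %in% BACKBONE_ATOMS
  res_order <- unique(rk)
  have <- tapply(a$elety[keep], factor(rk[keep], levels = res_order), length)
  if (any(is.na(have)) || any(have < 4L)) {
    n_bad <- sum(is.na(have) | have < 4L)
    warning(sprintf("%d residue(s) with incomplete backbone", n_bad))
  }
  a <- a[keep, , drop = FALSE]
  rk <- rk[keep]
  # residue order preserved, N/CA/C/O order within residue
  ord <- order(match(rk, res_order), match(a$elety, BACKBONE_ATOMS))
  a <- a[ord, , drop = FALSE]
  data.frame(key = paste(rk[ord], a$elety, sep = "|"),
             x = a$x, y = a$y, z = a$z, stringsAsFactors = FALSE)
}

# Internal backbone selection as plain matrices: list(key, xyz).
bb_select <- function(structure, chains = NULL) {
  bb <- select_backbone(structure, chains)
  list(key = bb$key, xyz = cbind(bb$x, bb$y, bb$z))
}

# Pair two backbone selections (list(key, xyz)) on their atom keys, so a
# missing atom on either side is excluded from both.  Fast path when the
# selections already share identical keys (decoys of one case normally
# have identical atom composition).  Returns list(ref = n x 3, mov = n x 3).
pair_bb <- function(ref, mov) {
  if (length(ref$key) == length(mov$key) && all(ref$key == mov$key))
    return(list(ref = ref$xyz, mov = mov$xyz))
  common <- intersect(ref$key, mov$key)
  if (length(common) < 3L) stop("fewer than 3 shared backbone atoms")
  list(ref = ref$xyz[match(common, ref$key), , drop = FALSE],
       mov = mov$xyz[match(common, mov$key), , drop = FALSE])
}

# data.frame-facing wrapper kept for select_backbone() outputs.
paired_backbone <- function(ref_bb, mov_bb) {
  pair_bb(list(key = ref_bb$key, xyz = cbind(ref_bb$x, ref_bb$y, ref_bb$z)),
          list(key = mov_bb$key, xyz = cbind(mov_bb$x, mov_bb$y, mov_bb$z)))
}

#' Assemble a decoy set
#'
#' @param case_id Case identifier.
#' @param native Native complex, a [pdb_structure].
#' @param decoys Named list of [pdb_structure] decoys.
#' @param partition A [partition_complex] result (defaults to auto).
#' @return A list with class `decoy_set`.
#' @export
decoy_set <- function(case_id, native, decoys, partition = NULL) {
  if (length(decoys) < 1L) stop("decoy set needs at least one decoy")
  if (is.null(names(decoys)) || any(!nzchar(names(decoys))))
    names(decoys) <- sprintf("decoy_%04d", seq_along(decoys))
  if (is.null(partition)) partition <- partition_complex(native)
  ds <- list(case_id = case_id, native = native, decoys = decoys,
             partition = partition)
  class(ds) <- "decoy_set"
  ds
}

#' @export
print.decoy_set <- function(x, ...) {
  cat(sprintf("decoy_set '%s': %d decoys; receptor %s | ligand %s\n",
              x$case_id, length(x$decoys),
              paste(x$partition$receptor, collapse = ""),
              paste(x$partition$ligand, collapse = "")))
  invisible(x)
}

#' Validate decoys against their native
#'
#' Report-only consistency check: per-decoy residue count, residue
#' sequence, and selected-atom count versus the native.
#'
#' @param ds A [decoy_set].
#' @return data.frame with one row per decoy: `decoy_id`,
#'   `residue_count_ok`, `sequence_ok`, `atom_count_ok`, `usable`.
#' @export
validate_decoy_set <- function(ds) {
  nat_keys <- unique(residue_keys(ds$native))
  nat_seq <- ds$native$atom$resid[!duplicated(residue_keys(ds$native))]
  nat_atoms <- n_atoms(ds$native)
  rows <- lapply(names(ds$decoys), function(id) {
    d <- ds$decoys[[id]]
    dk <- unique(residue_keys(d))
    dseq <- d$atom$resid[!duplicated(residue_keys(d))]
    res_ok <- length(dk) == length(nat_keys) && all(dk == nat_keys)
    seq_ok <- res_ok && all(dseq == nat_seq)
    atom_ok <- n_atoms(d) == nat_atoms
    data.frame(decoy_id = id, residue_count_ok = res_ok,
               sequence_ok = seq_ok, atom_count_ok = atom_ok,
               usable = seq_ok, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
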