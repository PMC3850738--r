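# Residue-level contact / distance-bin potential engine.
#
# A contact matrix is a 20 x 20 x nbins array of energies, symmetric in the
# residue types; a contact definition says which point (or atom set)
# represents a residue and which distance bins score.  The engine sums the
# matrix entry for every residue pair whose representative distance falls
# in a bin — over intermolecular pairs only, or over all pairs when used
# through the separable E_complex - (E_receptor + E_ligand) mode.

AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
         "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
         "TYR", "VAL")

# common PDB aliases mapped onto their standard parent residue
DEFAULT_PARENT_MAP <- c(MSE = "MET", SEC = "CYS", HSD = "HIS", HSE = "HIS",
                        HIE = "HIS", HID = "HIS", CYX = "CYS", PTR = "TYR",
                        SEP = "SER", TPO = "THR")

#' Define how residues are represented for contact scoring
#'
#' @param representative `"c_beta"` (CB, CA for glycine), `"centroid"`
#'   (heavy-atom centroid) or `"min_heavy_atom"` (minimum inter-residue
#'   heavy-atom distance).
#' @param bins Numeric matrix/2-column data of ascending, non-overlapping
#'   `[lo, hi]` distance intervals in angstroms, or `NULL` for the
#'   representative's conventional single contact bin (c_beta: 0-8,
#'   min_heavy_atom: 0-5, centroid: 0-8).
#' @return Object of class `contact_definition`.
#' @export
contact_definition <- function(representative = c("c_beta", "centroid",
                                                  "min_heavy_atom"),
                               bins = NULL) {
  representative <- match.arg(representative)
  if (is.null(bins)) {
    hi <- switch(representative, c_beta = 8, centroid = 8, min_heavy_atom = 5)
    bins <- matrix(c(0, hi), ncol = 2)
  }
  bins <- matrix(as.numeric(as.matrix(bins)), ncol = 2)
  if (any(!is.finite(bins)) || any(bins[, 2] <= bins[, 1]))
    stop("bins must be finite intervals with hi > lo")
  if (nrow(bins) > 1L) {
    o <- order(bins[, 1])
    bins <- bins[o, , drop = FALSE]
    if (any(bins[-1L, 1] < bins[-nrow(bins), 2]))
      stop("bins must be non-overlapping and ascending")
  }
  colnames(bins) <- c("lo", "hi")
  structure(list(representative = representative, bins = bins),
            class = "contact_definition")
}

# bin index per distance (0 = no bin); intervals are (lo, hi]
bin_of <- function(d, bins) {
  idx <- integer(length(d))
  for (b in seq_len(nrow(bins)))
    idx[d > bins[b, 1] & d <= bins[b, 2]] <- b
  idx
}

#' Build a contact matrix
#'
#' @param entries 20 x 20 matrix (dimnames = 3-letter codes) for a
#'   single-bin potential, or a 20 x 20 x nbins array.
#' @param name Matrix name.
#' @param definition The [contact_definition] the matrix was derived for.
#' @return Object of class `contact_matrix`.
#' @export
contact_matrix <- function(entries, name = "potential",
                           definition = contact_definition()) {
  if (length(dim(entries)) == 2L) {
    dn <- dimnames(entries)
    entries <- array(entries, dim = c(dim(entries), 1L),
                     dimnames = list(dn[[1]], dn[[2]], NULL))
  }
  dn <- dimnames(entries)
  if (is.null(dn) || is.null(dn[[1]]))
    dimnames(entries) <- list(AA3, AA3, NULL)
  ent <- entries[AA3, AA3, , drop = FALSE]
  if (any(!is.finite(ent))) stop("contact matrix has non-finite entries")
  if (dim(ent)[3] != nrow(definition$bins))
    stop("matrix bin count does not match contact definition")
  asym <- max(abs(ent - aperm(ent, c(2, 1, 3))))
  if (asym > 1e-9) {
    warning("asymmetric contact matrix; symmetrising by averaging")
  }
  ent <- (ent + aperm(ent, c(2, 1, 3))) / 2
  structure(list(name = name, entries = ent, definition = definition),
            class = "contact_matrix")
}

#' @export
print.contact_matrix <- function(x, ...) {
  cat(sprintf("contact_matrix '%s': %d bin(s), representative %s\n",
              x$name, dim(x$entries)[3], x$definition$representative))
  invisible(x)
}

#' Read a contact matrix file
#'
#' Plain-text format: header lines `#name NAME`, `#representative REP`,
#' `#bins lo:hi[,lo:hi...]`, then whitespace-delimited rows
#' `RES1 RES2 BIN_INDEX VALUE` with 3-letter residue codes.  Missing
#' symmetric counterparts are mirrored; all 20 standard residue types must
#' be covered.
#'
#' @param path File path.
#' @return A [contact_matrix].
#' @export
load_contact_matrix <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#")]
  getfield <- function(tag) {
    hit <- grep(paste0("^#", tag, "\\b"), hdr, value = TRUE)
    if (length(hit) == 0L) return(NULL)
    trimws(sub(paste0("^#", tag, "\\s*"), "", hit[1]))
  }
  name <- getfield("name")
  rep_ <- getfield("representative")
  bins_s <- getfield("bins")
  bins <- NULL
  if (!is.null(bins_s)) {
    parts <- strsplit(strsplit(bins_s, ",")[[1]], ":")
    bins <- t(vapply(parts, function(p) as.numeric(p), numeric(2)))
  }
  def <- contact_definition(if (is.null(rep_)) "min_heavy_atom" else rep_, bins)
  nb <- nrow(def$bins)
  ent <- array(NA_real_, dim = c(20, 20, nb), dimnames = list(AA3, AA3, NULL))
  for (k in seq_along(body)) {
    tok <- strsplit(trimws(body[k]), "\\s+")[[1]]
    if (length(tok) != 4L)
      stop("malformed matrix row at data line ", k, ": '", body[k], "'")
    val <- suppressWarnings(as.numeric(tok[4]))
    b <- suppressWarnings(as.integer(tok[3]))
    if (is.na(val) || is.na(b))
      stop("non-numeric entry at data line ", k, ": '", body[k], "'")
    i <- toupper(tok[1]); j <- toupper(tok[2])
    if (!(i %in% AA3) || !(j %in% AA3))
      stop("unknown residue code at data line ", k, ": '", body[k], "'")
    if (b < 1L || b > nb) stop("bin index out of range at data line ", k)
    ent[i, j, b] <- val
    if (is.na(ent[j, i, b])) ent[j, i, b] <- val
  }
  if (any(is.na(ent))) {
    miss <- which(is.na(ent), arr.ind = TRUE)
    stop("contact matrix incomplete: e.g. missing (",
         AA3[miss[1, 1]], ",", AA3[miss[1, 2]], ") bin ", miss[1, 3])
  }
  contact_matrix(ent, name = if (is.null(name)) basename(path) else name,
                 definition = def)
}

#' Write a contact matrix file
#' @param cm A [contact_matrix].
#' @param path Output path.
#' @export
write_contact_matrix <- function(cm, path) {
  bins <- cm$definition$bins
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste("#name", cm$name),
               paste("#representative", cm$definition$representative),
               paste("#bins", paste(sprintf("%g:%g", bins[, 1], bins[, 2]),
                                    collapse = ","))), con)
  for (b in seq_len(dim(cm$entries)[3]))
    for (i in seq_along(AA3))
      for (j in i:length(AA3))
        writeLines(sprintf("%s %s %d %.10g", AA3[i], AA3[j], b,
                           cm$entries[i, j, b]), con)
  invisible(path)
}

#' The packaged exemplar contact matrix
#'
#' Loads the synthetic quasi-chemical-style 20x20 single-bin matrix
#' shipped with the package (see `inst/extdata/synthetic_quasichemical.mat`).
#' It is a constructed exemplar with hydrophobic-attraction structure, not
#' a published potential; real analyses should load their own matrices
#' with [load_contact_matrix].
#'
#' @return A [contact_matrix].
#' @export
example_contact_matrix <- function() {
  load_contact_matrix(system.file("extdata", "synthetic_quasichemical.mat",
                                  package = "dockrank", mustWork = TRUE))
}

# Per-residue representatives for a structure under a contact definition.
# Returns list(res_keys, resid (parent-mapped 3-letter codes), and either
# `points` (n_res x 3) or, for min_heavy_atom, `xyz` + `res_index`.
residue_representatives <- function(structure, definition,
                                    parent_map = DEFAULT_PARENT_MAP) {
  a <- structure$atom[is_heavy(structure), , drop = FALSE]
  s <- pdb_structure(a)
  rk <- residue_keys(s)
  res_order <- unique(rk)
  first <- !duplicated(rk)
  resid <- toupper(a$resid[first])
  mapped <- resid %in% AA3
  alias <- !mapped & resid %in% names(parent_map)
  resid[alias] <- parent_map[resid[alias]]
  known <- resid %in% AA3
  if (any(!known))
    warning("skipping residue type(s) without matrix coverage: ",
            paste(unique(resid[!known]), collapse = ","))
  chain <- a$chain[first]
  if (definition$representative == "min_heavy_atom") {
    keep <- rk %in% res_order[known]
    return(list(res = res_order[known], resid = resid[known],
                chain = chain[known],
                xyz = cbind(a$x, a$y, a$z)[keep, , drop = FALSE],
                res_index = match(rk[keep], res_order[known])))
  }
  pts <- matrix(NA_real_, length(res_order), 3)
  if (definition$representative == "centroid") {
    f <- factor(rk, levels = res_order)
    pts <- cbind(tapply(a$x, f, mean), tapply(a$y, f, mean), tapply(a$z, f, mean))
  } else { # c_beta, CA fallback (glycine)
    for (i in seq_along(res_order)) {
      rows <- which(rk == res_order[i])
      cb <- rows[a$elety[rows] == "CB"]
      ca <- rows[a$elety[rows] == "CA"]
      pick <- if (length(cb) > 0L) cb[1] else if (length(ca) > 0L) ca[1] else rows[1]
      pts[i, ] <- c(a$x[pick], a$y[pick], a$z[pick])
    }
  }
  list(res = res_order[known], resid = resid[known], chain = chain[known],
       points = pts[known, , drop = FALSE])
}

# Minimum inter-residue heavy-atom distance matrix between two atom sets
# grouped by residue index.
min_dist_by_residue <- function(ra, rb) {
  d2 <- outer(rowSums(ra$xyz^2), rowSums(rb$xyz^2), `+`) -
    2 * tcrossprod(ra$xyz, rb$xyz)
  d2[d2 < 0] <- 0
  nr <- max(ra$res_index); nc <- max(rb$res_index)
  m <- matrix(Inf, nr, nc)
  # accumulate minima by residue-pair group
  grp <- (rep(ra$res_index, times = length(rb$res_index)) - 1L) * nc +
    rep(rb$res_index, each = length(ra$res_index))
  mins <- tapply(as.numeric(d2), grp, min)
  idx <- as.integer(names(mins))
  m[cbind((idx - 1L) %/% nc + 1L, (idx - 1L) %% nc + 1L)] <- sqrt(mins)
  m
}

# Residue-pair distance matrix between two sides under a definition.
cross_rep_distance <- function(sa, sb, definition) {
  if (definition$representative == "min_heavy_atom") {
    min_dist_by_residue(sa, sb)
  } else {
    d2 <- outer(rowSums(sa$points^2), rowSums(sb$points^2), `+`) -
      2 * tcrossprod(sa$points, sb$points)
    d2[d2 < 0] <- 0
    sqrt(d2)
  }
}

subset_reps <- function(reps, keep, definition) {
  if (definition$representative == "min_heavy_atom") {
    akeep <- reps$res_index %in% which(keep)
    list(res = reps$res[keep], resid = reps$resid[keep],
         xyz = reps$xyz[akeep, , drop = FALSE],
         res_index = match(reps$res_index[akeep], which(keep)))
  } else {
    list(res = reps$res[keep], resid = reps$resid[keep],
         points = reps$points[keep, , drop = FALSE])
  }
}

# Sum matrix entries over residue pairs given a cross-distance matrix.
sum_pair_energy <- function(dmat, resid_a, resid_b, cm) {
  bins <- cm$definition$bins
  b <- bin_of(as.numeric(dmat), bins)
  hit <- which(b > 0L)
  if (length(hit) == 0L) return(0)
  ia <- match(resid_a, AA3)[(hit - 1L) %% nrow(dmat) + 1L]
  ib <- match(resid_b, AA3)[(hit - 1L) %/% nrow(dmat) + 1L]
  sum(cm$entries[cbind(ia, ib, b[hit])])
}

#' Intermolecular contact-potential score
#'
#' Sums the matrix energy over receptor-ligand residue pairs whose
#' representative distance falls in a scoring bin.
#'
#' @param structure A [pdb_structure] of the complex.
#' @param partition A `complex_partition`.
#' @param cm A [contact_matrix].
#' @return Numeric energy (arbitrary units; lower is more favourable for
#'   conventional potentials).
#' @export
score_intermolecular <- function(structure, partition, cm) {
  def <- cm$definition
  reps <- residue_representatives(structure, def)
  on_r <- reps$chain %in% partition$receptor
  sa <- subset_reps(reps, on_r, def)
  sb <- subset_reps(reps, !on_r, def)
  if (length(sa$res) == 0L || length(sb$res) == 0L) return(0)
  dmat <- cross_rep_distance(sa, sb, def)
  sum_pair_energy(dmat, sa$resid, sb$resid, cm)
}

#' All-pairs contact-potential score
#'
#' Sums the matrix energy over every residue pair (intra- and
#' inter-molecular) of a structure; the structure-level scorer used by the
#' separable mode.
#'
#' @inheritParams score_intermolecular
#' @return Numeric energy.
#' @export
score_all_pairs <- function(structure, cm) {
  def <- cm$definition
  reps <- residue_representatives(structure, def)
  n <- length(reps$res)
  if (n < 2L) return(0)
  dmat <- cross_rep_distance(reps, reps, def)
  dmat[!upper.tri(dmat)] <- Inf   # each unordered pair once; skip i == j
  sum_pair_energy(dmat, reps$resid, reps$resid, cm)
}

#' Separable score E_complex - (E_receptor + E_ligand)
#'
#' Evaluates one structure-level scorer on the complex and on the isolated
#' receptor and ligand, and returns the difference, isolating the
#' interaction contribution.
#'
#' @param complex_s Complex [pdb_structure].
#' @param receptor_s,ligand_s The isolated molecules; defaults extract
#'   them from `complex_s` by `partition`.
#' @param scorer Function `structure -> energy` (e.g. a closure over
#'   [score_all_pairs]).
#' @param partition Used only for the default extraction.
#' @return Numeric energy difference.
#' @export
score_separable <- function(complex_s, scorer, partition = NULL,
                            receptor_s = NULL, ligand_s = NULL) {
  if (is.null(receptor_s) || is.null(ligand_s)) {
    if (is.null(partition)) partition <- partition_complex(complex_s)
    receptor_s <- subset_chains(complex_s, partition$receptor)
    ligand_s <- subset_chains(complex_s, partition$ligand)
  }
  if (n_atoms(receptor_s) + n_atoms(ligand_s) != n_atoms(complex_s))
    stop("receptor + ligand atom composition does not match the complex")
  scorer(complex_s) - (scorer(receptor_s) + scorer(ligand_s))
}

#' Declare a scoring metric
#'
#' @param name Metric name.
#' @param fun Function `(structure, partition) -> numeric score` evaluated
#'   per decoy.
#' @param direction `"ascending_better"` (low score = good, the energy
#'   convention) or `"descending_better"` (high score = good, as for
#'   hydrogen-bond counts or propensity scores).
#' @param mode `"intermolecular"` or `"separable"` (informational).
#' @return Object of class `metric_spec`.
#' @export
metric_spec <- function(name, fun, direction = c("ascending_better",
                                                 "descending_better"),
                        mode = c("intermolecular", "separable")) {
  structure(list(name = name, fun = fun, direction = match.arg(direction),
                 mode = match.arg(mode)),
            class = "metric_spec")
}

#' Metric from a contact matrix
#'
#' @param cm A [contact_matrix].
#' @param mode `"intermolecular"` scores cross pairs of the complex;
#'   `"separable"` scores all pairs of complex, receptor and ligand and
#'   takes E_complex - (E_receptor + E_ligand).
#' @return A [metric_spec] (ascending_better).
#' @export
contact_potential_metric <- function(cm, mode = c("intermolecular", "separable")) {
  mode <- match.arg(mode)
  fun <- if (mode == "intermolecular") {
    function(structure, partition) score_intermolecular(structure, partition, cm)
  } else {
    function(structure, partition)
      score_separable(structure, function(s) score_all_pairs(s, cm),
                      partition = partition)
  }
  metric_spec(cm$name, fun, "ascending_better", mode)
}

#' Score every decoy with every metric
#'
#' Per-decoy failures are recorded as `NA`, not fatal, so one unusable
#' pose does not drop a case.
#'
#' @param ds A [decoy_set].
#' @param metrics List of [metric_spec].
#' @return data.frame: `decoy_id` plus one numeric column per metric.
#' @export
score_decoy_set <- function(ds, metrics) {
  names(metrics) <- vapply(metrics, `[[`, "", "name")
  out <- data.frame(decoy_id = names(ds$decoys), stringsAsFactors = FALSE)
  for (m in metrics) {
    out[[m$name]] <- vapply(ds$decoys, function(d) {
      tryCatch(as.numeric(m$fun(d, ds$partition)),
               error = function(e) NA_real_)
    }, numeric(1), USE.NAMES = FALSE)
  }
  out
}

#' Write a score table as TSV (`NA` for missing)
#' @param st Result of [score_decoy_set].
#' @param path Output path.
#' @export
write_score_table <- function(st, path) {
  utils::write.table(st, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a score table TSV
#' @param path TSV with first column `decoy_id`, one column per metric.
#' @return data.frame.
#' @export
read_score_table <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE)
}
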