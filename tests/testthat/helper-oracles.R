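# Independent brute-force oracles.  These deliberately use different
# algorithms / data paths from the package implementation.

# Contacts by exhaustive enumeration of every heavy-atom pair.
oracle_contacts <- function(structure, partition, cutoff = 5) {
  a <- structure$atom
  heavy <- toupper(substr(a$elety, 1, 1)) != "H"
  a <- a[heavy, , drop = FALSE]
  res_key <- paste(a$chain, a$resno,
                   ifelse(is.na(a$insert), "", a$insert), sep = "|")
  out <- character(0)
  ri <- which(a$chain %in% partition$receptor)
  li <- which(a$chain %in% partition$ligand)
  for (i in ri) for (j in li) {
    d <- sqrt((a$x[i] - a$x[j])^2 + (a$y[i] - a$y[j])^2 + (a$z[i] - a$z[j])^2)
    if (d <= cutoff) out <- c(out, paste(res_key[i], res_key[j], sep = "::"))
  }
  sort(unique(out))
}

# Literal scalar re-encoding of the printed CAPRI class predicates,
# evaluated highest class first.
oracle_classify <- function(f, L, I) {
  if (f >= 0.5 && (L <= 1 || I <= 1)) return("high")
  if ((f >= 0.5 && L > 1 && I > 1) ||
      ((f >= 0.3 && f < 0.5) && (L <= 5 || I <= 2))) return("medium")
  if ((f >= 0.3 && L > 5 && I > 2) ||
      ((f >= 0.1 && f < 0.3) && (L <= 10 || I <= 4))) return("acceptable")
  "incorrect"
}

# RMSD after optimal superposition via bio3d's independent implementation.
oracle_fit_rmsd <- function(ref, mov) {
  fx <- suppressWarnings(
    bio3d::fit.xyz(fixed = as.numeric(t(ref)), mobile = as.numeric(t(mov))))
  sqrt(mean(rowSums((matrix(fx, ncol = 3, byrow = TRUE) - ref)^2)))
}

# Greedy leader clustering re-implemented as a vector sweep over a
# precomputed full distance matrix.
oracle_greedy <- function(ids, dmat, threshold) {
  assign <- setNames(rep(NA_character_, length(ids)), ids)
  leaders <- character(0)
  for (id in ids) {
    hit <- NA_character_
    for (ld in leaders) {
      if (dmat[ld, id] <= threshold) { hit <- ld; break }
    }
    if (is.na(hit)) { leaders <- c(leaders, id); hit <- id }
    assign[id] <- hit
  }
  assign
}

# Naive O(n^3) complete-linkage agglomeration returning the cophenetic
# matrix (merge height of the lowest common ancestor).
oracle_complete_linkage_cophenetic <- function(D) {
  n <- nrow(D)
  labs <- rownames(D)
  clusters <- as.list(seq_len(n))
  coph <- matrix(0, n, n, dimnames = list(labs, labs))
  repeat {
    k <- length(clusters)
    if (k == 1L) break
    best <- c(NA, NA); bestd <- Inf
    for (i in seq_len(k - 1)) for (j in (i + 1):k) {
      d <- max(D[clusters[[i]], clusters[[j]]])
      if (d < bestd) { bestd <- d; best <- c(i, j) }
    }
    for (a in clusters[[best[1]]]) for (b in clusters[[best[2]]]) {
      coph[a, b] <- coph[b, a] <- bestd
    }
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  coph
}

# Set cardinalities by direct membership enumeration over a universe.
oracle_pair_card <- function(A, B, universe) {
  inA <- universe %in% A; inB <- universe %in% B
  list(union = sum(inA | inB), symdiff = sum(xor(inA, inB)),
       a_minus_b = sum(inA & !inB), b_minus_a = sum(!inA & inB),
       intersection = sum(inA & inB))
}

# Contact-potential score by explicit double loop over residues.
oracle_potential <- function(structure, partition, cm, intermolecular = TRUE) {
  def <- cm$definition
  a <- structure$atom
  heavy <- toupper(substr(a$elety, 1, 1)) != "H"
  a <- a[heavy, , drop = FALSE]
  rk <- paste(a$chain, a$resno, ifelse(is.na(a$insert), "", a$insert), sep = "|")
  res <- unique(rk)
  rtype <- a$resid[match(res, rk)]
  rchain <- a$chain[match(res, rk)]
  rep_point <- function(r) {
    rows <- which(rk == r)
    if (def$representative == "centroid") {
      c(mean(a$x[rows]), mean(a$y[rows]), mean(a$z[rows]))
    } else if (def$representative == "c_beta") {
      pick <- rows[a$elety[rows] == "CB"]
      if (length(pick) == 0L) pick <- rows[a$elety[rows] == "CA"]
      c(a$x[pick[1]], a$y[pick[1]], a$z[pick[1]])
    } else NULL
  }
  pair_dist <- function(r1, r2) {
    if (def$representative == "min_heavy_atom") {
      i <- which(rk == r1); j <- which(rk == r2)
      min(sqrt(outer(a$x[i], a$x[j], `-`)^2 + outer(a$y[i], a$y[j], `-`)^2 +
                 outer(a$z[i], a$z[j], `-`)^2))
    } else {
      sqrt(sum((rep_point(r1) - rep_point(r2))^2))
    }
  }
  total <- 0
  for (i in seq_along(res)) for (j in seq_along(res)) {
    if (j <= i) next
    if (intermolecular &&
        !((rchain[i] %in% partition$receptor & rchain[j] %in% partition$ligand) ||
          (rchain[j] %in% partition$receptor & rchain[i] %in% partition$ligand)))
      next
    d <- pair_dist(res[i], res[j])
    for (b in seq_len(nrow(def$bins))) {
      if (d > def$bins[b, 1] && d <= def$bins[b, 2]) {
        total <- total + cm$entries[rtype[i], rtype[j], b]
      }
    }
  }
  total
}
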