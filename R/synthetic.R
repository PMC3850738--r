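# Synthetic benchmark generator with known ground truth.
#
# Toy complexes are two idealised helical chains (full backbone + CB)
# placed in contact; decoys are rigid-body perturbations of the ligand
# whose quality labels are always computed by the real CAPRI classifier,
# never assigned.  Synthetic scoring metrics are monotone transforms of a
# quality-derived latent mixed with seeded noise, with controllable rank
# correlation (informativeness) and optional shared noise between metrics
# (planted cluster structure).

# Ideal helical chain: parametric helix per atom type (rise 1.5 A/residue,
# 100 degrees/residue).  Geometry is idealised, not refined chemistry; it
# provides named backbone + CB atoms with realistic spacing.
helix_chain <- function(n_res, chain, sequence, start_resno = 1L,
                        eleno_start = 1L) {
  stopifnot(length(sequence) == n_res)
  specs <- list(  # atom name -> (radius, phase offset deg, z offset)
    N  = c(1.80, -25, -0.80),
    CA = c(2.30,   0,  0.00),
    C  = c(2.00,  25,  0.70),
    O  = c(2.05,  30,  1.90),
    CB = c(3.30,  -5, -0.30))
  rows <- list()
  k <- 0L
  for (i in seq_len(n_res)) {
    t0 <- (i - 1) * 100 * pi / 180
    z0 <- (i - 1) * 1.5
    atoms <- c("N", "CA", "C", "O", if (sequence[i] != "GLY") "CB")
    for (at in atoms) {
      sp <- specs[[at]]
      k <- k + 1L
      rows[[k]] <- data.frame(
        eleno = eleno_start + k - 1L, elety = at, alt = NA_character_,
        resid = sequence[i], chain = chain,
        resno = start_resno + i - 1L, insert = NA_character_,
        elesy = substr(at, 1, 1),
        x = sp[1] * cos(t0 + sp[2] * pi / 180),
        y = sp[1] * sin(t0 + sp[2] * pi / 180),
        z = z0 + sp[3], stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

rotation_about_axis <- function(axis, angle_deg) {
  u <- axis / sqrt(sum(axis^2))
  th <- angle_deg * pi / 180
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' Apply a rigid transform to a structure
#'
#' @param structure A [pdb_structure].
#' @param rotation 3x3 rotation matrix.
#' @param translation Length-3 vector, angstroms.
#' @param center Rotation center (default origin).
#' @return Transformed [pdb_structure].
#' @export
transform_structure <- function(structure, rotation = diag(3),
                                translation = c(0, 0, 0),
                                center = c(0, 0, 0)) {
  xyz <- as.matrix(structure$atom[, c("x", "y", "z")])
  xyz <- sweep(sweep(xyz, 2, center) %*% t(rotation), 2, center + translation, `+`)
  structure$atom$x <- xyz[, 1]; structure$atom$y <- xyz[, 2]
  structure$atom$z <- xyz[, 3]
  structure
}

#' Build a synthetic native complex
#'
#' Two idealised helical chains (receptor chain A, ligand chain B) placed
#' antiparallel and in contact, guaranteeing at least `min_contacts`
#' native residue contacts at the 5-angstrom heavy-atom cutoff.
#'
#' @param receptor_size,ligand_size Residue counts (>= 5 each).
#' @param seed Integer seed (sequences are seeded draws).
#' @param sequence `"diverse"` samples residue types so contact-matrix
#'   lookups are non-trivial; `"polyala"` gives poly-alanine.
#' @param min_contacts Required native contact count.
#' @return A [pdb_structure] of the complex (chains A and B).
#' @export
make_native <- function(receptor_size = 12, ligand_size = 10, seed = 1,
                        sequence = c("diverse", "polyala"),
                        min_contacts = 5) {
  sequence <- match.arg(sequence)
  if (receptor_size < 5 || ligand_size < 5)
    stop("need at least 5 residues per side to form an interface")
  set.seed(seed)
  seq_r <- if (sequence == "diverse") sample(AA3, receptor_size, replace = TRUE)
           else rep("ALA", receptor_size)
  seq_l <- if (sequence == "diverse") sample(AA3, ligand_size, replace = TRUE)
           else rep("ALA", ligand_size)
  rec <- helix_chain(receptor_size, "A", seq_r)
  lig <- helix_chain(ligand_size, "B", seq_l, eleno_start = nrow(rec) + 1L)
  lig_s <- pdb_structure(lig)
  # antiparallel, axes offset along x; close in until enough contacts
  flip <- rotation_about_axis(c(1, 0, 0), 180)
  z_mid <- (receptor_size - 1) * 1.5 / 2 + (ligand_size - 1) * 1.5 / 2
  for (dx in seq(10.5, 6, by = -0.5)) {
    cand <- transform_structure(lig_s, flip, c(dx, 0, z_mid))
    cx <- pdb_structure(rbind(rec, cand$atom))
    part <- partition_complex(cx, "A")
    nc <- length(intermolecular_contacts(cx, part, 5))
    if (nc >= min_contacts) return(cx)
  }
  stop("could not build an interface with ", min_contacts, " contacts")
}

#' Default rigid-body perturbation schedule
#'
#' Bands of (translation angstroms, rotation degrees, count) spanning
#' magnitudes from 0 to beyond 30 angstroms, so decoys cover all four
#' CAPRI classes.  Counts are scaled to `n_decoys`.
#'
#' @param n_decoys Total decoy count (default 500).
#' @return data.frame `translation`, `rotation`, `count`.
#' @export
default_schedule <- function(n_decoys = 500) {
  bands <- data.frame(
    translation = c(0.2, 0.6, 1.0, 2.0, 3.0, 4.5, 6.0, 8.0, 12, 18, 30, 45),
    rotation    = c(1,   3,   5,   8,  12,  15,  20,  25,  35, 50, 90, 140),
    weight      = c(2,   2,   2,   2,   2,   2,   2,   2,   4,  6, 12, 12))
  cnt <- round(bands$weight / sum(bands$weight) * n_decoys)
  cnt[length(cnt)] <- cnt[length(cnt)] + (n_decoys - sum(cnt))
  data.frame(translation = bands$translation, rotation = bands$rotation,
             count = cnt)
}

#' Generate rigid-body decoys for a native complex
#'
#' Each decoy moves the ligand rigidly: rotation by the scheduled angle
#' about a random axis through the ligand centroid, then translation of
#' the scheduled magnitude in a random direction.
#'
#' @param native Complex [pdb_structure] from [make_native].
#' @param schedule data.frame `translation`, `rotation`, `count` (see
#'   [default_schedule]).
#' @param seed Integer seed.
#' @param partition Receptor/ligand partition (default: chain A receptor).
#' @param case_id Case identifier.
#' @return A [decoy_set] (quality labels are NOT attached; compute them
#'   with [quality_table]).
#' @export
make_decoys <- function(native, schedule = default_schedule(500), seed = 1,
                        partition = NULL, case_id = "synthetic") {
  if (is.null(partition)) partition <- partition_complex(native, "A")
  set.seed(seed)
  lig_idx <- native$atom$chain %in% partition$ligand
  lig_xyz <- as.matrix(native$atom[lig_idx, c("x", "y", "z")])
  cen <- colMeans(lig_xyz)
  decoys <- list()
  k <- 0L
  for (b in seq_len(nrow(schedule))) {
    for (r in seq_len(schedule$count[b])) {
      k <- k + 1L
      axis <- stats::rnorm(3)
      dirn <- stats::rnorm(3)
      dirn <- dirn / sqrt(sum(dirn^2))
      R <- rotation_about_axis(axis, schedule$rotation[b])
      new_xyz <- sweep(sweep(lig_xyz, 2, cen) %*% t(R), 2,
                       cen + schedule$translation[b] * dirn, `+`)
      d <- native
      d$atom$x[lig_idx] <- new_xyz[, 1]
      d$atom$y[lig_idx] <- new_xyz[, 2]
      d$atom$z[lig_idx] <- new_xyz[, 3]
      decoys[[sprintf("d%04d", k)]] <- d
    }
  }
  decoy_set(case_id, native, decoys, partition)
}

#' Sparse (hard) perturbation schedule
#'
#' A difficulty preset in which near-native poses are rare (two of
#' `n_decoys`, the rest scattered far from the native), emulating hard
#' benchmark cases where most docking output is incorrect and even
#' informative metrics miss some complexes.  With the default schedule's
#' generous near-native fraction, top-10 success saturates; this preset
#' keeps it away from 1 so metric disagreement is observable.
#'
#' @param n_decoys Total decoy count (default 40).
#' @return data.frame `translation`, `rotation`, `count`.
#' @export
sparse_schedule <- function(n_decoys = 40) {
  bands <- data.frame(
    translation = c(0.4, 2.5, 15, 25, 40, 55),
    rotation    = c(2,   8,   40, 60, 100, 140),
    count       = c(1,   1,   8,  10, 10, 10))
  extra <- n_decoys - sum(bands$count)
  if (extra < 0) stop("sparse_schedule needs n_decoys >= ", sum(bands$count))
  bands$count[nrow(bands)] <- bands$count[nrow(bands)] + extra
  bands
}

#' Declare a synthetic scoring metric
#'
#' @param name Metric name.
#' @param rho Informativeness: target Spearman rank correlation between
#'   the score and the quality-derived latent, in `[0, 1]`.
#' @param direction Score direction (see [metric_spec]).
#' @param noise_id Metrics sharing a `noise_id` share their noise vector,
#'   planting correlated found sets (a metric "family").
#' @return Object of class `synthetic_metric`.
#' @export
synthetic_metric <- function(name, rho, direction = "ascending_better",
                             noise_id = NULL) {
  stopifnot(rho >= 0, rho <= 1)
  structure(list(name = name, rho = rho, direction = direction,
                 noise_id = noise_id), class = "synthetic_metric")
}

# Latent pose quality (higher = better): CAPRI ordinal dominates, LRMSD
# orders poses within a class.
quality_latent <- function(quality) {
  n <- nrow(quality)
  quality_ordinal(quality$class) + 1 - rank(quality$lrmsd, ties.method = "first") / (n + 1)
}

#' Synthetic score table from quality labels
#'
#' Scores are generated on the normal-scores scale:
#' `z = a * z_latent + sqrt(1 - a^2) * noise` with `a = 2 sin(pi rho / 6)`,
#' so the Spearman correlation between score and latent approaches `rho`
#' (the Pearson-to-Spearman relation for bivariate normal ranks).  Good
#' poses receive low scores for `ascending_better` metrics, high scores
#' for `descending_better`.
#'
#' @param quality [quality_table] output for one case.
#' @param metrics List of [synthetic_metric].
#' @param seed Integer seed.
#' @return Score table data.frame (`decoy_id` + one column per metric).
#' @export
make_scores <- function(quality, metrics, seed = 1) {
  n <- nrow(quality)
  z_lat <- stats::qnorm(rank(quality_latent(quality), ties.method = "first") / (n + 1))
  out <- data.frame(decoy_id = quality$decoy_id, stringsAsFactors = FALSE)
  noise_cache <- list()
  for (i in seq_along(metrics)) {
    m <- metrics[[i]]
    nid <- if (is.null(m$noise_id)) paste0(".own.", i) else m$noise_id
    if (is.null(noise_cache[[nid]])) {
      set.seed((seed * 131L + sum(utf8ToInt(nid))) %% .Machine$integer.max)
      noise_cache[[nid]] <- stats::rnorm(n)
    }
    a <- 2 * sin(pi * m$rho / 6)
    z <- a * z_lat + sqrt(1 - a^2) * noise_cache[[nid]]
    out[[m$name]] <- if (m$direction == "ascending_better") -z else z
  }
  out
}

#' Score table with a planted top-10 success probability
#'
#' Engineers one `ascending_better` metric so that, per case, a
#' near-native (class >= `q`) pose is placed first (hence a top-ranked
#' cluster representative) with probability `p`, and otherwise all
#' near-native poses are pushed to the bottom of the ranking (behind every
#' incorrect pose, hence outside the top 10 whenever the case has more
#' than 10 incorrect clusters).  Used to validate success-rate recovery.
#'
#' @param quality [quality_table] output for one case.
#' @param p Per-case success probability.
#' @param seed Integer seed.
#' @param q Quality threshold defining "near-native".
#' @param name Metric column name.
#' @return Score table data.frame.
#' @export
make_planted_scores <- function(quality, p = 0.6, seed = 1,
                                q = "acceptable", name = "planted") {
  set.seed(seed)
  n <- nrow(quality)
  good <- quality$class >= as_quality(q)
  score <- stats::runif(n)              # base: random order
  if (any(good)) {
    if (stats::runif(1) < p) {
      # best near-native pose (highest class, then lowest LRMSD) first
      best <- which(good)[order(-quality_ordinal(quality$class[good]),
                                quality$lrmsd[good])[1]]
      score[best] <- -1
    } else {
      score[good] <- 1 + stats::runif(sum(good))
    }
  }
  out <- data.frame(decoy_id = quality$decoy_id, stringsAsFactors = FALSE)
  out[[name]] <- score
  out
}

#' Measure top-10 success recovery of a planted metric
#'
#' Generates `n_cases` toy cases, plants a metric whose per-case top-10
#' success probability is `p` (see [make_planted_scores]), runs the full
#' rank-cluster-evaluate machinery, and returns the observed success rate
#' with its binomial standard error — a calibration check that the
#' evaluation statistics recover a known generator parameter.
#'
#' @param n_cases Number of cases.
#' @param p Planted per-case success probability.
#' @param n_decoys Decoys per case.
#' @param seed Integer master seed.
#' @param threshold Cluster radius in angstroms.
#' @return List: `rate` (observed top-10 acceptable-or-better success
#'   rate), `p`, `n_cases`, `se` (binomial SE at `p`), `found` (logical
#'   per case), and `counts` (top-1/10/100 success counts).
#' @export
planted_success_experiment <- function(n_cases = 500, p = 0.6, n_decoys = 30,
                                       seed = 1, threshold = 3) {
  results <- lapply(seq_len(n_cases), function(i) {
    cseed <- (seed * 104729L + i) %% 2147483647L
    native <- make_native(seed = cseed)
    ds <- make_decoys(native, default_schedule(n_decoys), seed = cseed + 1L,
                      case_id = sprintf("case_%03d", i))
    qt <- quality_table(ds)
    st <- make_planted_scores(qt, p = p, seed = cseed + 2L)
    rl <- rank_case(ds, st, "planted", qt, threshold)
    case_result(ds$case_id, list(planted = rl), max(qt$class))
  })
  found <- vapply(results, case_found, logical(1),
                  metric = "planted", N = 10, q = "acceptable")
  counts <- vapply(c(1, 10, 100), function(N)
    success_counts(results, "planted", N, "acceptable"), integer(1))
  names(counts) <- c("top1", "top10", "top100")
  list(rate = mean(found), p = p, n_cases = n_cases,
       se = sqrt(p * (1 - p) / n_cases), found = found, counts = counts)
}

#' Generate and evaluate a synthetic benchmark
#'
#' Builds `n_cases` toy complexes with rigid-body decoys, computes quality
#' with the real classifier, attaches synthetic metric scores, ranks and
#' clusters, and returns the [case_result] list consumed by
#' [success_table], [conditional_probability] and [synergy_matrices].
#'
#' @param n_cases Number of cases.
#' @param metrics List of [synthetic_metric].
#' @param n_decoys Decoys per case.
#' @param seed Integer master seed (per-case seeds are derived from it).
#' @param receptor_size,ligand_size Residue counts per chain.
#' @param difficulty Difficulty labels, recycled over cases (default:
#'   roughly the benchmark's rigid-to-flexible mix, 2:1).
#' @param threshold Cluster radius in angstroms.
#' @param schedule Perturbation schedule (default [default_schedule];
#'   see [sparse_schedule] for the hard preset).
#' @return List of [case_result].
#' @export
make_benchmark <- function(n_cases, metrics, n_decoys = 60, seed = 1,
                           receptor_size = 12, ligand_size = 10,
                           difficulty = c("rigid_body", "rigid_body", "medium"),
                           threshold = 3, schedule = NULL) {
  difficulty <- rep_len(difficulty, n_cases)
  if (is.null(schedule)) schedule <- default_schedule(n_decoys)
  lapply(seq_len(n_cases), function(i) {
    cseed <- (seed * 7919L + i) %% 2147483647L
    native <- make_native(receptor_size, ligand_size, seed = cseed)
    ds <- make_decoys(native, schedule, seed = cseed + 1L,
                      case_id = sprintf("case_%03d", i))
    qt <- quality_table(ds)
    st <- make_scores(qt, metrics, seed = cseed + 2L)
    pd <- make_pose_distance(ds)
    ranked <- lapply(metrics, function(m)
      rank_case(ds, st, m$name, qt, threshold, direction = m$direction,
                pose_distance = pd))
    names(ranked) <- vapply(metrics, `[[`, "", "name")
    case_result(ds$case_id, ranked, max(qt$class), difficulty[i])
  })
}
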