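# Fixtures built in code: random toy complexes and hand-built evaluation
# objects.  All randomness is seeded by the caller.

# Random two-chain toy complex: every residue gets a full backbone
# (N, CA, C, O) plus CB, scattered inside a small box so the chains are
# near each other and intermolecular contacts occur.
random_toy_complex <- function(n_r = 5, n_l = 5, seed = 1, spread = 8) {
  set.seed(seed)
  mk_chain <- function(chain, n, offset) {
    rows <- list()
    for (i in seq_len(n)) {
      base <- stats::runif(3, 0, spread) + offset
      atoms <- c("N", "CA", "C", "O", "CB")
      for (a in seq_along(atoms)) {
        rows[[length(rows) + 1L]] <- data.frame(
          elety = atoms[a], resid = sample(dockrank:::AA3, 1),
          chain = chain, resno = i,
          x = base[1] + stats::rnorm(1, sd = 0.8),
          y = base[2] + stats::rnorm(1, sd = 0.8),
          z = base[3] + stats::rnorm(1, sd = 0.8),
          stringsAsFactors = FALSE)
      }
    }
    df <- do.call(rbind, rows)
    df$resid <- rep(df$resid[seq(1, nrow(df), by = 5)], each = 5)
    df
  }
  pdb_structure(rbind(mk_chain("A", n_r, c(0, 0, 0)),
                      mk_chain("B", n_l, c(spread * 0.6, 0, 0))))
}

# A rigid transform sampled from a seed: proper rotation + translation.
random_rigid <- function(seed, max_shift = 20) {
  set.seed(seed)
  ax <- stats::rnorm(3)
  R <- dockrank:::rotation_about_axis(ax, stats::runif(1, 0, 360))
  list(R = R, t = stats::runif(3, -max_shift, max_shift))
}

apply_rigid <- function(structure, rig) {
  transform_structure(structure, rig$R, rig$t)
}

# Hand-built per-case ranked list: a representatives data.frame where the
# classes at each rank are specified directly.
planted_ranked <- function(classes) {
  n <- length(classes)
  data.frame(rank = seq_len(n), decoy_id = sprintf("d%03d", seq_len(n)),
             score = seq_len(n), fnat = 0, irmsd = 99, lrmsd = 99,
             class = factor(classes, levels = dockrank:::QUALITY_LEVELS,
                            ordered = TRUE),
             stringsAsFactors = FALSE)
}

# A case_result with planted ranked lists per metric.
planted_case <- function(case_id, per_metric_classes, best_available,
                         difficulty = "rigid_body") {
  case_result(case_id, lapply(per_metric_classes, planted_ranked),
              best_available, difficulty)
}

# Small random contact matrix (symmetric) for a given definition.
random_contact_matrix <- function(seed, definition = contact_definition()) {
  set.seed(seed)
  nb <- nrow(definition$bins)
  E <- array(0, dim = c(20, 20, nb))
  for (b in seq_len(nb)) {
    m <- matrix(stats::rnorm(400), 20, 20)
    E[, , b] <- (m + t(m)) / 2
  }
  dimnames(E) <- list(dockrank:::AA3, dockrank:::AA3, NULL)
  contact_matrix(E, name = paste0("rand", seed), definition = definition)
}
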