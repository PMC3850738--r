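# Contact-matrix I/O, residue representatives, and the scoring engine.

test_that("contact matrix files round-trip, mirror symmetry and check coverage", {
  cm <- random_contact_matrix(1)
  p <- withr::local_tempfile(fileext = ".mat")
  write_contact_matrix(cm, p)
  cm2 <- load_contact_matrix(p)
  expect_equal(cm2$entries, cm$entries, tolerance = 1e-9)
  expect_equal(cm2$definition$representative, "c_beta")
  # a file with only (ALA, GLY) mirrors to (GLY, ALA) but is incomplete
  p2 <- withr::local_tempfile(fileext = ".mat")
  writeLines(c("#name toy", "#representative min_heavy_atom", "#bins 0:5",
               "ALA GLY 1 -1.25"), p2)
  expect_error(load_contact_matrix(p2), "incomplete")
  # malformed value is a parse error naming the line
  p3 <- withr::local_tempfile(fileext = ".mat")
  writeLines(c("#bins 0:5", "ALA GLY 1 xyz"), p3)
  expect_error(load_contact_matrix(p3), "non-numeric entry at data line 1")
  # full 210-value file resolves all 400 ordered lookups
  expect_true(all(is.finite(cm2$entries)))
  expect_equal(cm2$entries, aperm(cm2$entries, c(2, 1, 3)))
})

test_that("the packaged exemplar matrix loads, is symmetric and complete", {
  cm <- example_contact_matrix()
  expect_s3_class(cm, "contact_matrix")
  expect_equal(dim(cm$entries), c(20, 20, 1))
  expect_equal(cm$entries, aperm(cm$entries, c(2, 1, 3)))
  expect_true(all(is.finite(cm$entries)))
})

test_that("asymmetric input is symmetrised by averaging with a warning", {
  E <- matrix(0, 20, 20, dimnames = list(dockrank:::AA3, dockrank:::AA3))
  E["ALA", "GLY"] <- 1   # asymmetric on purpose
  expect_warning(cm <- contact_matrix(E), "symmetris")
  expect_equal(cm$entries["ALA", "GLY", 1], 0.5)
  expect_equal(cm$entries["GLY", "ALA", 1], 0.5)
})

test_that("residue representatives follow the CB/CA-fallback, centroid and atom-set rules", {
  nat <- make_native(6, 5, seed = 8)
  nat$atom$resid[nat$atom$chain == "A" & nat$atom$resno == 1] <- "GLY"
  nat <- pdb_structure(nat$atom[!(nat$atom$chain == "A" & nat$atom$resno == 1 &
                                    nat$atom$elety == "CB"), ])
  rep_cb <- dockrank:::residue_representatives(nat, contact_definition("c_beta"))
  ca1 <- nat$atom[nat$atom$chain == "A" & nat$atom$resno == 1 &
                    nat$atom$elety == "CA", ]
  expect_equal(unname(rep_cb$points[1, ]), c(ca1$x, ca1$y, ca1$z))  # glycine -> CA
  cb2 <- nat$atom[nat$atom$chain == "A" & nat$atom$resno == 2 &
                    nat$atom$elety == "CB", ]
  expect_equal(unname(rep_cb$points[2, ]), c(cb2$x, cb2$y, cb2$z))
  # centroid of a single-atom residue is that atom
  one <- pdb_structure(data.frame(elety = "CA", resid = "ALA", chain = "A",
                                  resno = 1, x = 1, y = 2, z = 3))
  rep_c <- dockrank:::residue_representatives(one, contact_definition("centroid"))
  expect_equal(unname(rep_c$points[1, ]), c(1, 2, 3))
  # min_heavy_atom keeps the full heavy-atom set
  rep_m <- dockrank:::residue_representatives(nat, contact_definition("min_heavy_atom"))
  expect_equal(nrow(rep_m$xyz), sum(dockrank:::is_heavy(nat)))
})

test_that("zero matrix scores zero and a single contact scores its entry", {
  nat <- make_native(8, 6, seed = 9)
  part <- partition_complex(nat, "A")
  zero <- contact_matrix(matrix(0, 20, 20,
                                dimnames = list(dockrank:::AA3, dockrank:::AA3)),
                         definition = contact_definition("min_heavy_atom"))
  expect_equal(score_intermolecular(nat, part, zero), 0)
  # two single-residue chains in contact: energy = the (type, type) entry
  a <- data.frame(elety = c("CA", "CB"), resid = "ALA", chain = "A",
                  resno = 1, x = c(0, 1), y = 0, z = 0)
  b <- data.frame(elety = c("CA", "CB"), resid = "TRP", chain = "B",
                  resno = 1, x = c(4, 5.5), y = 0, z = 0)
  s <- pdb_structure(rbind(a, b))
  E <- matrix(0, 20, 20, dimnames = list(dockrank:::AA3, dockrank:::AA3))
  E["ALA", "TRP"] <- E["TRP", "ALA"] <- -1.2
  cm <- contact_matrix(E, definition = contact_definition("min_heavy_atom"))
  expect_equal(score_intermolecular(s, partition_complex(s, "A"), cm), -1.2)
})

test_that("every representative mode matches exhaustive pair enumeration", {
  defs <- list(contact_definition("c_beta"),
               contact_definition("centroid"),
               contact_definition("min_heavy_atom"),
               contact_definition("centroid",
                                  bins = rbind(c(0, 4), c(4, 6.5), c(6.5, 9))))
  for (seed in 1:17) {
    toy <- random_toy_complex(6, 6, seed = seed, spread = 10)
    part <- partition_complex(toy, "A")
    for (d in defs) {
      cm <- random_contact_matrix(seed + 31, definition = d)
      expect_equal(score_intermolecular(toy, part, cm),
                   oracle_potential(toy, part, cm, intermolecular = TRUE),
                   tolerance = 1e-10)
      expect_equal(score_all_pairs(toy, cm),
                   oracle_potential(toy, part, cm, intermolecular = FALSE),
                   tolerance = 1e-10)
    }
  }
})

test_that("scores are invariant under global rigid transforms and label swaps", {
  cm <- example_contact_matrix()
  for (seed in 1:5) {
    toy <- random_toy_complex(5, 5, seed = seed)
    part <- partition_complex(toy, "A")
    s0 <- score_intermolecular(toy, part, cm)
    moved <- apply_rigid(toy, random_rigid(seed + 50))
    expect_equal(score_intermolecular(moved, part, cm), s0, tolerance = 1e-8)
    swapped <- partition_complex(toy, "B")
    expect_equal(score_intermolecular(toy, swapped, cm), s0, tolerance = 1e-10)
  }
})

test_that("separable score equals the intermolecular score for additive potentials", {
  cm <- example_contact_matrix()
  for (seed in 1:20) {
    toy <- random_toy_complex(5, 5, seed = seed)
    part <- partition_complex(toy, "A")
    sep <- score_separable(toy, function(s) score_all_pairs(s, cm),
                           partition = part)
    expect_equal(sep, score_intermolecular(toy, part, cm), tolerance = 1e-8)
  }
  # an additive per-structure property cancels exactly
  toy <- random_toy_complex(5, 5, seed = 3)
  expect_equal(score_separable(toy, function(s) nrow(s$atom),
                               partition = partition_complex(toy, "A")), 0)
  # separating the ligand beyond all cutoffs zeroes the interaction term
  nat <- make_native(8, 6, seed = 2)
  part <- partition_complex(nat, "A")
  far <- nat
  move <- far$atom$chain == "B"
  far$atom$x[move] <- far$atom$x[move] + 500
  expect_equal(score_separable(far, function(s) score_all_pairs(s, cm),
                               partition = part), 0, tolerance = 1e-12)
  # composition mismatch errors
  expect_error(score_separable(nat, function(s) 0, partition = part,
                               receptor_s = subset_chains(nat, "A"),
                               ligand_s = subset_chains(nat, "A")),
               "composition")
})

test_that("contact energy is non-increasing as an all-negative-matrix complex separates", {
  E <- matrix(-abs(matrix(rnorm(400, -1), 20, 20)), 20, 20,
              dimnames = list(dockrank:::AA3, dockrank:::AA3))
  E <- (E + t(E)) / 2
  cm <- contact_matrix(E, definition = contact_definition("min_heavy_atom"))
  nat <- make_native(8, 6, seed = 6)
  part <- partition_complex(nat, "A")
  sep <- seq(0, 30, by = 2)
  energies <- vapply(sep, function(dx) {
    d <- nat
    move <- d$atom$chain == "B"
    d$atom$x[move] <- d$atom$x[move] + dx
    -score_intermolecular(d, part, cm)   # -E: contact count-ish, decreasing
  }, numeric(1))
  expect_true(all(diff(energies) <= 1e-12))
})

test_that("score_decoy_set has one score per decoy x metric, NA on failure, deterministic", {
  nat <- make_native(6, 5, seed = 10)
  ds <- make_decoys(nat, default_schedule(3), seed = 3, case_id = "s")
  cm <- example_contact_matrix()
  boom <- metric_spec("boom", function(s, p) {
    if (sum(s$atom$x) > sum(nat$atom$x) + 5) stop("fail") else 1
  })
  st <- score_decoy_set(ds, list(contact_potential_metric(cm), boom))
  expect_equal(nrow(st), 3)
  expect_equal(ncol(st), 3)   # decoy_id + 2 metrics
  expect_true(all(is.finite(st[[cm$name]])))
  st2 <- score_decoy_set(ds, list(contact_potential_metric(cm), boom))
  expect_identical(st, st2)
  # a metric raising on one decoy yields NA there, not an error
  always_boom <- metric_spec("ab", function(s, p) stop("no"))
  st3 <- score_decoy_set(ds, list(always_boom))
  expect_true(all(is.na(st3$ab)))
})
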