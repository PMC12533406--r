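toy <- synthetic_parameter_table("toy-stabilizing")

test_that("config validation enforces the design input ranges", {
  expect_error(ga_config(peptide_length = 20), "\\[21, 40\\]")
  expect_error(ga_config(peptide_length = 41), "\\[21, 40\\]")
  expect_error(ga_config(target_tm = 75), "\\[30, 70\\]")
  expect_error(ga_config(target_specificity = 5), "\\[10, 35\\]")
  expect_error(ga_config(crossover_rate = 1.2), "\\[0, 1\\]")
  expect_error(motif_spec(leading = "GF"), "\\[3, 15\\]")
  expect_error(motif_spec(), "at least one strand")
  expect_silent(ga_config(peptide_length = 20, target_tm = 75,
                          target_specificity = 5, strict = FALSE))
})

test_that("motif configs fix a frame the motif glycines agree with", {
  cfg <- ga_config(composition = "ABC", peptide_length = 30,
                   motif = motif_spec(trailing = "GFOGER"), seed = 1)
  w <- cfg$motif_window
  expect_equal(unname(w["end"] - w["start"] + 1L), 6L)
  expect_equal(cfg$peptide_length, 2L * (w["start"] - 1L) + 6L,
               ignore_attr = TRUE)
  # GFOGER has G at motif offsets 0 and 3, so the window start pins the frame
  gp <- seq.int(cfg$frame_offset + 1L, cfg$peptide_length, by = 3L)
  expect_true(w[["start"]] %in% gp)
  # a motif whose glycines cannot sit on any frame is rejected
  expect_error(ga_config(motif = motif_spec(leading = "GFGOER")),
               "no Gly frame|misalign")
})

test_that("initial populations respect composition, motif and exclusions", {
  cfg <- ga_config(composition = "A2B", peptide_length = 24,
                   population_size = 30, excluded = list(Xaa = "W"),
                   seed = 4, strict = FALSE, target_tm = 30,
                   target_specificity = 10)
  set.seed(4)
  pop <- initialize_population(cfg)
  expect_length(pop, 30L)
  frames <- vapply(pop, function(ind) ind$frame, integer(1L))
  expect_setequal(unique(frames), 0:2)
  for (ind in pop) {
    expect_length(ind$peps, 2L)
    for (p in ind$peps) {
      gp <- which(p == "G")
      expect_equal(gp, seq.int(ind$frame + 1L, 24L, by = 3L))
      expect_false("W" %in% p[colhelix:::xaa_positions(ind$frame, 24L)])
    }
  }
  set.seed(4)
  pop2 <- initialize_population(cfg)
  expect_identical(pop, pop2)

  mcfg <- ga_config(composition = "ABC", peptide_length = 30,
                    motif = motif_spec(leading = "GFOGER"), seed = 2)
  set.seed(2)
  mpop <- initialize_population(mcfg)
  w <- mcfg$motif_window
  for (ind in mpop) {
    expect_equal(paste(ind$peps[[1L]][w["start"]:w["end"]], collapse = ""),
                 "GFOGER")
    expect_equal(ind$frame, mcfg$frame_offset)
  }
})

test_that("fitness combines Tm, specificity and the register bonus as stated", {
  cfg <- toy_config()
  peps <- list(make_peptide("GKOGKO", "A", 0L), make_peptide("GPDGPD", "B", 0L))
  fit <- helix_fitness(peps, toy, cfg)
  rep_ <- specificity_report(peps, toy)
  expect_identical(fit$score, 0.5 * fit$tm + 0.5 * fit$specificity)
  # fitness Tm is the best register of the target composition (A2B);
  # its specificity is the gap to the best of all other assemblies
  a2b <- rep_$ranked[rep_$ranked$composition == "A2B", ]
  expect_equal(fit$tm, max(a2b$tm), tolerance = 1e-12)
  others <- rep_$ranked$tm[!(rep_$ranked$register %in%
                               a2b$register[which.max(a2b$tm)])]
  expect_equal(fit$specificity, fit$tm - max(others), tolerance = 1e-12)
  # when the target composition is globally dominant the fitness values
  # coincide with the ranked report
  if (rep_$ranked$composition[1L] == "A2B") {
    expect_equal(fit$tm, rep_$ranked$tm[1L], tolerance = 1e-12)
    expect_equal(fit$specificity, rep_$specificity, tolerance = 1e-12)
  }

  # motif mode: weights 0.4/0.4/0.2 and a +/-50 register term
  mcfg <- ga_config(composition = "ABC", peptide_length = 30,
                    motif = motif_spec(leading = "GFOGER"))
  set.seed(8)
  ind <- colhelix:::new_individual(mcfg)
  mp <- colhelix:::as_peptide_set(ind)
  mfit <- helix_fitness(mp, toy, mcfg)
  cc <- if (identical(unname(mfit$best_register), c(1L, 2L, 3L))) 50 else -50
  expect_identical(mfit$score,
                   0.4 * mfit$specificity + 0.4 * mfit$tm + 0.2 * cc)
})

test_that("parent selection is argmax-2 with earliest-index ties", {
  expect_equal(select_parents(c(3, 9, 1, 9)), c(2L, 4L))
  expect_equal(select_parents(c(9, 7, 1)), c(1L, 2L))
  expect_equal(select_parents(rep(5, 4)), c(1L, 2L))
  expect_error(select_parents(5), "at least 2")
})

test_that("crossover cuts at one Gly boundary across all strands", {
  cfg <- ga_config(composition = "A2B", peptide_length = 21,
                   frame_offset = 2L, target_tm = 30,
                   target_specificity = 10, strict = FALSE)
  p1 <- list(peps = list(strsplit(pog_sequence(21L, 2L), "")[[1L]],
                         strsplit(pog_sequence(21L, 2L), "")[[1L]]),
             frame = 2L)
  pkg <- gsub("O", "K", pog_sequence(21L, 2L))
  p2 <- list(peps = list(strsplit(pkg, "")[[1L]], strsplit(pkg, "")[[1L]]),
             frame = 2L)
  # rate 0: identity
  expect_identical(ga_crossover(p1, p2, 0, cfg), p1)
  # rate 1: offspring is p1 up to a Gly position then p2
  set.seed(6)
  for (i in 1:50) {
    child <- ga_crossover(p1, p2, 1, cfg)
    s <- paste(child$peps[[1L]], collapse = "")
    expect_match(s, "^(POG)+(PKG)+$")
    # both strands cut at the same index
    expect_identical(child$peps[[1L]], child$peps[[2L]])
    g <- regexpr("PKG", s)[1L] - 1L
    expect_true(g %in% seq.int(3L, 18L, by = 3L))
  }
})

test_that("crossover never cuts inside the motif window", {
  mcfg <- ga_config(composition = "ABC", peptide_length = 30,
                    motif = motif_spec(middle = "GFOGERGFO"))
  set.seed(10)
  a <- colhelix:::new_individual(mcfg)
  b <- colhelix:::new_individual(mcfg)
  w <- mcfg$motif_window
  n <- mcfg$peptide_length
  glys <- seq.int(mcfg$frame_offset + 1L, n, by = 3L)
  for (i in 1:200) {
    child <- ga_crossover(a, b, 1, mcfg)
    # the set of cuts that explain the child on every strand must contain
    # at least one cut outside the motif interior (the one actually drawn)
    explains <- vapply(glys[glys < n], function(g) {
      all(vapply(seq_along(child$peps), function(s) {
        identical(child$peps[[s]],
                  c(a$peps[[s]][1:g], b$peps[[s]][(g + 1L):n]))
      }, logical(1L)))
    }, logical(1L))
    legal <- glys[glys < n][explains]
    expect_true(any(legal < w["start"] | legal >= w["end"]))
    expect_equal(paste(child$peps[[2L]][w["start"]:w["end"]], collapse = ""),
                 "GFOGERGFO")
  }
})

test_that("mutation is per-position, role-aware and motif/exclusion safe", {
  cfg <- ga_config(composition = "A2B", peptide_length = 21,
                   frame_offset = 0L, excluded = list(Xaa = c("W", "C")),
                   target_tm = 30, target_specificity = 10, strict = FALSE)
  set.seed(14)
  ind <- colhelix:::new_individual(cfg)
  expect_identical(ga_mutate(ind, 0, cfg), ind)

  # rate 1 with single-residue alphabets forces the canonical repeat
  forced_cfg <- ga_config(composition = "A2B", peptide_length = 21,
                          frame_offset = 0L,
                          excluded = list(Xaa = setdiff(CMP_ALPHABET, "P"),
                                          Yaa = setdiff(CMP_ALPHABET, "O")),
                          target_tm = 30, target_specificity = 10,
                          strict = FALSE)
  rnd <- colhelix:::new_individual(cfg)
  out <- ga_mutate(rnd, 1, forced_cfg)
  for (p in out$peps) {
    expect_equal(paste(p, collapse = ""), pog_sequence(21L, 0L))
  }

  # excluded residues never introduced; Gly positions never mutate
  set.seed(15)
  for (i in 1:50) {
    m <- ga_mutate(ind, 0.5, cfg)
    for (p in m$peps) {
      expect_equal(which(p == "G"), seq.int(1L, 21L, by = 3L))
      xr <- p[colhelix:::xaa_positions(0L, 21L)]
      expect_false(any(xr %in% c("W", "C")))
    }
  }

  # motif bytes immune at any rate
  mcfg <- ga_config(composition = "ABC", peptide_length = 30,
                    motif = motif_spec(leading = "GFOGER"))
  set.seed(16)
  mi <- colhelix:::new_individual(mcfg)
  w <- mcfg$motif_window
  mm <- ga_mutate(mi, 1, mcfg)
  expect_equal(paste(mm$peps[[1L]][w["start"]:w["end"]], collapse = ""),
               "GFOGER")
})

test_that("evolution is elitist, seeded-deterministic and conserves motifs", {
  cfg <- toy_config(seed = 99, population_size = 14L, max_rounds = 25L,
                    target_tm = 1e6, target_specificity = 1e6)
  r1 <- run_design(cfg, toy)
  r2 <- run_design(cfg, toy)
  expect_identical(lapply(r1$peptides, peptide_string),
                   lapply(r2$peptides, peptide_string))
  cols <- setdiff(names(r1$trace), "TimeElapsed")  # wall clock varies
  expect_identical(r1$trace[cols], r2$trace[cols])
  expect_false(r1$converged)   # unreachable targets end at the round cap
  expect_equal(r1$generations, 25L)
  # elitism: best fitness never decreases, over several seeds
  for (s in 1:20) {
    r <- run_design(toy_config(seed = s, population_size = 10L,
                               max_rounds = 15L,
                               target_tm = 1e6, target_specificity = 1e6),
                    toy)
    expect_true(all(diff(r$trace$FitnessScore) >= -1e-9))
    expect_equal(names(r$trace),
                 c("Generation", "TimeElapsed", "FitnessScore", "Tm", "Spec"))
  }

  # motif run: motif byte-identical in the final output
  mcfg <- ga_config(composition = "ABC", peptide_length = 27,
                    motif = motif_spec(trailing = "GFOGER"),
                    population_size = 20, max_rounds = 10,
                    target_tm = 70, target_specificity = 35, seed = 5,
                    excluded = list(Xaa = setdiff(CMP_ALPHABET, c("P", "K")),
                                    Yaa = setdiff(CMP_ALPHABET, c("O", "D"))))
  mr <- run_design(mcfg, toy)
  w <- mcfg$motif_window
  expect_equal(substr(peptide_string(mr$peptides[[3L]]),
                      w["start"], w["end"]), "GFOGER", ignore_attr = TRUE)
})

test_that("stagnation restart keeps returning the best-so-far", {
  cfg <- toy_config(seed = 3, population_size = 10L, max_rounds = 30L,
                    target_tm = 1e6, target_specificity = 1e6)
  cfg$restart_after <- 5L
  r <- run_design(cfg, toy)
  norestart <- run_design(toy_config(seed = 3, population_size = 10L,
                                     max_rounds = 30L, target_tm = 1e6,
                                     target_specificity = 1e6), toy)
  expect_gte(r$fitness, max(r$trace$FitnessScore) - 1e-9)
  expect_equal(r$generations, 30L)
  expect_s3_class(norestart, "design_result")
})
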