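#' Motif specification for motif-conserving design
#'
#' A biologically relevant sequence (such as the integrin-binding GFOGER
#' motif) to be carried, byte-identical, on one or more strands of the
#' designed helix.  Motifs are inserted centred in every strand and are
#' exempt from mutation and crossover; any glycine inside a motif must fall
#' on the global Gly frame.
#'
#' @param leading,middle,trailing Optional motif text for the strand in that
#'   register slot; each of length 3 to 15.  All supplied motifs must share
#'   one length (they occupy the same centred window on equal-length
#'   strands).
#' @return A `motif_spec` object.
#' @export
motif_spec <- function(leading = NULL, middle = NULL, trailing = NULL) {
  m <- list(leading = leading, middle = middle, trailing = trailing)
  m <- lapply(m, function(s) if (is.null(s)) NULL else toupper(s))
  given <- !vapply(m, is.null, logical(1L))
  if (!any(given)) stop("at least one strand must carry a motif", call. = FALSE)
  lens <- vapply(m[given], nchar, integer(1L))
  if (any(lens < 3L | lens > 15L)) {
    stop("motif length must be in [3, 15]", call. = FALSE)
  }
  if (length(unique(lens)) != 1L) {
    stop("all motifs must share one length", call. = FALSE)
  }
  for (s in m[given]) {
    bad <- which(!strsplit(s, "")[[1L]] %in% CMP_ALPHABET)
    if (length(bad)) stop("invalid motif residue at position ", bad[1L],
                          call. = FALSE)
  }
  structure(c(m, list(length = unname(lens[1L]))), class = "motif_spec")
}

#' Configuration of a design run
#'
#' Collects every knob of the evolutionary search.  With a motif the total
#' strand length is `2 * random_seq_length + motif_length` with the motif
#' centred; the fitness weights switch from (0.5, 0.5) on specificity and
#' Tm to (0.4, 0.4, 0.2) with the third weight on a register bonus of
#' +/- 50 awarded when the most stable register is the designated
#' input-order one.
#'
#' @param composition `"ABC"` (three distinct strands) or `"A2B"` (two).
#' @param peptide_length Target strand length; designs use 21 to 40.
#' @param target_tm Target melting temperature, degC; designs use 30 to 70.
#' @param target_specificity Target Tm gap to the runner-up species, degC;
#'   designs use 10 to 35.
#' @param population_size Helix sets per generation (default 500).
#' @param crossover_rate,mutation_rate Per-offspring crossover probability
#'   and per-position mutation probability (defaults 0.6 and 0.2).
#' @param motif Optional [motif_spec()].
#' @param excluded Named list (`Xaa`, `Yaa`) of residues barred from the
#'   draw alphabets at that role; barred residues never appear outside a
#'   motif.
#' @param max_rounds Generation cap (default 500000).
#' @param register_bonus Magnitude of the motif-mode register term
#'   (default 50).
#' @param frame_offset Fix the shared Gly frame of every set, or `NULL` to
#'   draw it per set (no-motif mode) / derive it from the motif.
#' @param allow_gly Offer Gly in the Xaa/Yaa mutation alphabet (off by
#'   default: designed CMPs never carry Gly outside the frame).
#' @param closure Interstrand closure convention, see [pairwise_contacts()].
#' @param restart_after Re-initialise the population after this many
#'   generations without fitness improvement (`NULL` = never).
#' @param seed Seed for the run's random number stream.
#' @param strict Enforce the design input ranges above; disable for
#'   scoring-only toy configurations.
#' @return A `ga_config` object.
#' @export
ga_config <- function(composition = c("ABC", "A2B"),
                      peptide_length = 30L,
                      target_tm = 40,
                      target_specificity = 15,
                      population_size = 500L,
                      crossover_rate = 0.6,
                      mutation_rate = 0.2,
                      motif = NULL,
                      excluded = list(),
                      max_rounds = 500000L,
                      register_bonus = 50,
                      frame_offset = NULL,
                      allow_gly = FALSE,
                      closure = c("cyclic", "open"),
                      restart_after = NULL,
                      seed = NULL,
                      strict = TRUE) {
  composition <- match.arg(composition)
  closure <- match.arg(closure)
  if (crossover_rate < 0 || crossover_rate > 1 ||
      mutation_rate < 0 || mutation_rate > 1) {
    stop("rates must be probabilities in [0, 1]", call. = FALSE)
  }
  if (strict) {
    if (peptide_length < 21 || peptide_length > 40) {
      stop("peptide length must be in [21, 40]", call. = FALSE)
    }
    if (target_tm < 30 || target_tm > 70) {
      stop("target Tm must be in [30, 70]", call. = FALSE)
    }
    if (target_specificity < 10 || target_specificity > 35) {
      stop("target specificity must be in [10, 35]", call. = FALSE)
    }
  }
  n_pep <- if (composition == "ABC") 3L else 2L
  slot_map <- if (composition == "ABC") c(1L, 2L, 3L) else c(1L, 1L, 2L)

  motif_window <- NULL
  pep_motifs <- vector("list", n_pep)
  n <- as.integer(peptide_length)
  if (!is.null(motif)) {
    if (!inherits(motif, "motif_spec")) stop("motif must be a motif_spec",
                                             call. = FALSE)
    ml <- motif$length
    rsl <- max(0L, (n - ml) %/% 2L)
    if (strict) while (2L * rsl + ml < 21L) rsl <- rsl + 1L
    n <- 2L * rsl + ml
    if (strict && n > 40L) stop("motif-padded length ", n,
                                " exceeds [21, 40]", call. = FALSE)
    motif_window <- c(start = rsl + 1L, end = rsl + ml)
    # map register-slot motifs onto peptide indices; slots sharing a
    # peptide (A2B leading/middle) must agree
    slot_seqs <- list(motif$leading, motif$middle, motif$trailing)
    for (s in 1:3) {
      i <- slot_map[s]
      if (!is.null(slot_seqs[[s]])) {
        if (!is.null(pep_motifs[[i]]) && pep_motifs[[i]] != slot_seqs[[s]]) {
          stop("slots sharing peptide ", LETTERS[i],
               " carry different motifs", call. = FALSE)
        }
        pep_motifs[[i]] <- slot_seqs[[s]]
      }
    }
    frame_offset <- motif_frame(pep_motifs, motif_window, n, frame_offset)
  }

  structure(
    list(composition = composition, n_pep = n_pep, slot_map = slot_map,
         target_register = slot_map,
         peptide_length = n,
         target_tm = target_tm, target_specificity = target_specificity,
         population_size = as.integer(population_size),
         crossover_rate = crossover_rate, mutation_rate = mutation_rate,
         motif = motif, motif_window = motif_window, pep_motifs = pep_motifs,
         excluded = excluded,
         xaa_alphabet = role_alphabet("Xaa", excluded, allow_gly),
         yaa_alphabet = role_alphabet("Yaa", excluded, allow_gly),
         max_rounds = as.integer(max_rounds),
         register_bonus = register_bonus,
         frame_offset = frame_offset,
         allow_gly = allow_gly, closure = closure,
         restart_after = restart_after, seed = seed,
         weights = if (is.null(motif)) c(spec = 0.5, tm = 0.5, register = 0)
                   else c(spec = 0.4, tm = 0.4, register = 0.2)),
    class = "ga_config")
}

# The global Gly frame compatible with every motif placed in the shared
# window: each frame position inside the window must hold G in the motif,
# and each motif G must sit on a frame position.  Errors when no frame
# fits; with several fits the smallest is taken (or the user's, if legal).
motif_frame <- function(pep_motifs, window, n, requested = NULL) {
  fits <- vapply(0:2, function(f) {
    gp <- gly_positions(f, n)
    for (m in pep_motifs) {
      if (is.null(m)) next
      chars <- strsplit(m, "")[[1L]]
      pos <- seq.int(window["start"], window["end"])
      on_frame <- pos %in% gp
      if (!all(chars[on_frame] == "G")) return(FALSE)
      if (any(chars[!on_frame] == "G")) return(FALSE)
    }
    TRUE
  }, logical(1L))
  legal <- which(fits) - 1L
  if (!length(legal)) {
    stop("motif glycines align with no Gly frame", call. = FALSE)
  }
  if (!is.null(requested)) {
    if (!requested %in% legal) {
      stop("requested frame ", requested, " misaligns the motif glycines",
           call. = FALSE)
    }
    return(as.integer(requested))
  }
  legal[1L]
}

# ---- individuals --------------------------------------------------------
# An individual ("helix set") is a list of n_pep residue vectors sharing
# one frame; peptide i answers to id LETTERS[i].

new_individual <- function(config) {
  f <- config$frame_offset
  if (is.null(f)) f <- sample.int(3L, 1L) - 1L
  n <- config$peptide_length
  gp <- gly_positions(f, n)
  xp <- xaa_positions(f, n)
  yp <- yaa_positions(f, n)
  peps <- vector("list", config$n_pep)
  for (i in seq_len(config$n_pep)) {
    res <- character(n)
    res[gp] <- "G"
    res[xp] <- sample(config$xaa_alphabet, length(xp), replace = TRUE)
    res[yp] <- sample(config$yaa_alphabet, length(yp), replace = TRUE)
    if (!is.null(config$pep_motifs[[i]])) {
      w <- config$motif_window
      res[w["start"]:w["end"]] <- strsplit(config$pep_motifs[[i]], "")[[1L]]
    }
    peps[[i]] <- res
  }
  list(peps = peps, frame = f)
}

as_peptide_set <- function(ind, permissive = FALSE) {
  lapply(seq_along(ind$peps), function(i) {
    collagen_peptide(ind$peps[[i]], id = LETTERS[i],
                     frame_offset = ind$frame, permissive = permissive)
  })
}

#' Draw the initial population
#'
#' `population_size` helix sets of 2 (A2B) or 3 (ABC) random Gly-periodic
#' strands.  Without a motif each set draws its own frame so all three
#' frames are represented; with a motif the frame is fixed by the motif's
#' glycines and the motif text is inserted centred on its strands.
#'
#' @param config A [ga_config()].
#' @return List of individuals (internal representation; convert with
#'   `as_peptide_set` via [run_design()] outputs).
#' @export
initialize_population <- function(config) {
  lapply(seq_len(config$population_size), function(i) new_individual(config))
}

#' Fitness of one helix set
#'
#' Scores every competing assembly of the set and evaluates the set
#' against the design goal: `tm` is the melting temperature of the best
#' register of the target composition (the heterotrimer the user asked
#' for), and `specificity` is its Tm gap to the best of all other
#' assemblies -- negative while a competing species still dominates, which
#' is what steers the search toward sets where the target is the sole
#' stable helix.  Whenever the target is the most stable assembly these
#' values coincide with the ranked-report Tm and specificity.
#'
#' Without a motif `F = 0.5 Tm + 0.5 dTm`; with a motif
#' `F = 0.4 dTm + 0.4 Tm + 0.2 R` where `R` is `+register_bonus` if the
#' most stable register is the designated input-order register and
#' `-register_bonus` otherwise.
#'
#' @param peptides List of [collagen_peptide] strands (one shared frame).
#' @param params A [scoring_parameters] object.
#' @param config A [ga_config()].
#' @return List with `score`, `tm`, `specificity`, `best_register` (the
#'   globally most stable register, as a strand-index triple) and
#'   `best_label`.
#' @export
helix_fitness <- function(peptides, params, config) {
  tt <- set_tm_table(peptides, params, closure = config$closure)
  ord <- order(-tt$tm, tt$label)
  target_ms <- sort(unname(config$target_register))
  is_target <- vapply(seq_along(tt$tm), function(r) {
    identical(sort(unname(tt$index[r, ])), target_ms)
  }, logical(1L))
  cand <- which(is_target)
  ti <- cand[order(-tt$tm[cand], tt$label[cand])][1L]
  tm <- tt$tm[ti]
  spec <- tm - max(tt$tm[-ti])
  best <- tt$index[ord[1L], ]
  w <- config$weights
  score <- w[["spec"]] * spec + w[["tm"]] * tm
  if (w[["register"]] > 0) {
    cc <- if (identical(unname(best), unname(config$target_register))) {
      config$register_bonus
    } else {
      -config$register_bonus
    }
    score <- score + w[["register"]] * cc
  }
  list(score = score, tm = tm, specificity = spec,
       best_register = best, best_label = tt$label[ord[1L]],
       target_label = tt$label[ti])
}

#' Select the two fittest helix sets
#'
#' Argmax-2 by fitness; ties resolved to the earliest index so selection is
#' deterministic.
#'
#' @param scores Numeric fitness vector, one per individual.
#' @return Integer vector of two indices.
#' @export
select_parents <- function(scores) {
  if (length(scores) < 2L) stop("population must hold at least 2 sets",
                                call. = FALSE)
  order(-scores)[1:2]
}

#' Gly-anchored crossover of two helix sets
#'
#' With probability `rate`, draws one cut point at a glycine position and
#' applies it at the same index across every strand of the set (so
#' registers stay aligned): residues up to the cut come from `parent1`,
#' the rest from `parent2`.  Cut points inside the motif window are never
#' drawn.  Otherwise, or when no legal cut exists (parents in different
#' frames, or the motif spans every glycine), the offspring is a copy of
#' `parent1`.
#'
#' @param parent1,parent2 Individuals from [initialize_population()].
#' @param rate Crossover probability.
#' @param config A [ga_config()].
#' @return An offspring individual.
#' @export
ga_crossover <- function(parent1, parent2, rate, config) {
  if (parent1$frame != parent2$frame) return(parent1)
  if (rate <= 0 || stats::runif(1L) >= rate) return(parent1)
  n <- config$peptide_length
  cuts <- gly_positions(parent1$frame, n)
  cuts <- cuts[cuts < n]
  w <- config$motif_window
  if (!is.null(w)) cuts <- cuts[cuts < w["start"] | cuts >= w["end"]]
  if (!length(cuts)) return(parent1)
  g <- cuts[sample.int(length(cuts), 1L)]
  child <- parent1
  for (i in seq_along(child$peps)) {
    child$peps[[i]] <- c(parent1$peps[[i]][1:g],
                         parent2$peps[[i]][(g + 1L):n])
  }
  child
}

#' Per-position mutation of a helix set
#'
#' Every Xaa and Yaa position outside the motif window mutates
#' independently with probability `rate` to a uniform draw from its role's
#' allowed alphabet excluding the current residue (so a mutation event
#' always changes the sequence and the changed-position count is exactly
#' binomial in `rate`).  Glycine frame positions never mutate, excluded
#' residues are never introduced, and motif bytes are never touched.  When
#' the role's alphabet holds a single residue the position is already
#' forced and stays put.
#'
#' @param ind An individual.
#' @param rate Per-position mutation probability.
#' @param config A [ga_config()].
#' @return The mutated individual.
#' @export
ga_mutate <- function(ind, rate, config) {
  if (rate <= 0) return(ind)
  n <- config$peptide_length
  f <- ind$frame
  xp <- xaa_positions(f, n)
  yp <- yaa_positions(f, n)
  w <- config$motif_window
  for (i in seq_along(ind$peps)) {
    xi <- xp
    yi <- yp
    if (!is.null(w) && !is.null(config$pep_motifs[[i]])) {
      inside <- function(p) p >= w["start"] & p <= w["end"]
      xi <- xi[!inside(xi)]
      yi <- yi[!inside(yi)]
    }
    for (hit in xi[stats::runif(length(xi)) < rate]) {
      ind$peps[[i]][hit] <- draw_other(config$xaa_alphabet,
                                       ind$peps[[i]][hit])
    }
    for (hit in yi[stats::runif(length(yi)) < rate]) {
      ind$peps[[i]][hit] <- draw_other(config$yaa_alphabet,
                                       ind$peps[[i]][hit])
    }
  }
  ind
}

# Uniform draw excluding the current residue; a one-letter alphabet keeps it.
draw_other <- function(alphabet, current) {
  pool <- alphabet[alphabet != current]
  if (!length(pool)) return(current)
  pool[sample.int(length(pool), 1L)]
}

#' Run the evolutionary design loop
#'
#' Each generation every helix set is scored with [helix_fitness()], the
#' two fittest sets become parents, and the next population is rebuilt from
#' them by Gly-anchored crossover and per-position mutation with both
#' parents carried over unchanged (elitism).  The loop stops when the best
#' set meets both targets with pairwise-distinct strand sequences and the
#' most stable assembly has the target composition (all peptides of the
#' set), or at the generation cap; an optional stagnation policy
#' re-initialises the population when the best fitness has not improved for
#' `restart_after` generations.
#'
#' @param config A [ga_config()].
#' @param params A [scoring_parameters] object.
#' @param verbose Print progress every 100 generations.
#' @return A `design_result`: `peptides` (best set as [collagen_peptide]
#'   objects), `tm`, `specificity`, `best_register`, `best_label`,
#'   `fitness`, `converged`, `generations`, and `trace` (data frame with
#'   columns Generation, TimeElapsed, FitnessScore, Tm, Spec).
#' @export
run_design <- function(config, params, verbose = FALSE) {
  if (!is.null(config$seed)) set.seed(config$seed)
  pop <- initialize_population(config)
  t0 <- proc.time()[["elapsed"]]
  trace <- vector("list", 0L)
  best_ever <- NULL
  converged <- FALSE
  stagnant <- 0L
  prev_best <- -Inf
  gen <- 0L

  repeat {
    gen <- gen + 1L
    # lightweight strand records: population members were built Gly-periodic
    # and only mutated role-safely, so re-validation per evaluation is skipped
    evals <- lapply(pop, function(ind) {
      helix_fitness(lapply(seq_along(ind$peps), function(i) {
        list(id = LETTERS[i], residues = ind$peps[[i]],
             frame_offset = ind$frame,
             n_term_acetylated = TRUE, c_term_amidated = TRUE)
      }), params, config)
    })
    scores <- vapply(evals, function(e) e$score, numeric(1L))
    b <- which.max(scores)
    best <- evals[[b]]
    if (is.null(best_ever) || best$score > best_ever$fit$score) {
      best_ever <- list(ind = pop[[b]], fit = best)
    }
    trace[[gen]] <- data.frame(
      Generation = gen,
      TimeElapsed = round(proc.time()[["elapsed"]] - t0, 3),
      FitnessScore = best$score, Tm = best$tm, Spec = best$specificity)
    if (verbose && gen %% 100L == 0L) {
      message(sprintf("generation %d: best Tm %.1f, specificity %.1f, %s",
                      gen, best$tm, best$specificity, best$best_label))
    }
    # stop as soon as ANY set satisfies every user criterion: both targets
    # met, strand sequences pairwise distinct, and the most stable assembly
    # is the target heterotrimer rather than a competing species that
    # happens to clear the thresholds
    satisfying <- which(vapply(seq_along(pop), function(i) {
      e <- evals[[i]]
      e$tm >= config$target_tm &&
        e$specificity >= config$target_specificity &&
        identical(sort(unname(e$best_register)),
                  sort(unname(config$target_register))) &&
        !anyDuplicated(vapply(pop[[i]]$peps, paste, character(1L),
                              collapse = ""))
    }, logical(1L)))
    if (length(satisfying)) {
      hit <- satisfying[which.max(scores[satisfying])]
      best_ever <- list(ind = pop[[hit]], fit = evals[[hit]])
      converged <- TRUE
      break
    }
    if (gen >= config$max_rounds) break

    if (best$score > prev_best + 1e-9) {
      stagnant <- 0L
      prev_best <- best$score
    } else {
      stagnant <- stagnant + 1L
    }
    if (!is.null(config$restart_after) && stagnant >= config$restart_after) {
      pop <- initialize_population(config)
      stagnant <- 0L
      prev_best <- -Inf
      next
    }

    parents <- pop[select_parents(scores)]
    nxt <- vector("list", config$population_size)
    nxt[[1L]] <- parents[[1L]]
    nxt[[2L]] <- parents[[2L]]
    for (s in seq_len(config$population_size)[-(1:2)]) {
      flip <- stats::runif(1L) < 0.5
      p1 <- if (flip) parents[[2L]] else parents[[1L]]
      p2 <- if (flip) parents[[1L]] else parents[[2L]]
      child <- ga_crossover(p1, p2, config$crossover_rate, config)
      nxt[[s]] <- ga_mutate(child, config$mutation_rate, config)
    }
    pop <- nxt
  }

  structure(
    list(peptides = as_peptide_set(best_ever$ind,
                                   permissive = config$allow_gly),
         tm = best_ever$fit$tm,
         specificity = best_ever$fit$specificity,
         best_register = best_ever$fit$best_register,
         best_label = best_ever$fit$best_label,
         fitness = best_ever$fit$score,
         converged = converged, generations = gen,
         trace = do.call(rbind, trace),
         config = config),
    class = "design_result")
}

#' @export
print.design_result <- function(x, ...) {
  cat("<design_result> ", if (x$converged) "converged" else
    "round cap reached (best so far)", " after ", x$generations,
    " generations\n", sep = "")
  for (p in x$peptides) {
    cat("  ", p$id, ": ", peptide_string(p), "\n", sep = "")
  }
  cat(sprintf("  Tm %.1f degC, specificity %.1f degC, best register %s\n",
              x$tm, x$specificity, x$best_label))
  invisible(x)
}
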