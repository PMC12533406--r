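# Independent brute-force oracle for the additive Tm model.  Shares no code
# with the package scorer: roles are decided by a bare modular test, contacts
# by an explicit position walk, every term accumulated in plain loops.

oracle_tm <- function(seqs, frame, params, closure = "cyclic",
                      nterm_capped = TRUE, cterm_capped = TRUE) {
  chars <- lapply(seqs, function(s) strsplit(s, "")[[1L]])
  n <- length(chars[[1L]])
  tm <- unname(params$baseline[as.character(n)])

  for (s in chars) {
    for (p in seq_len(n)) {
      r <- (p - 1L - frame) %% 3L
      if (r == 1L) {                       # Xaa
        tm <- tm + if (s[p] == "P") 0 else unname(params$xaa[s[p]])
      } else if (r == 2L) {                # Yaa
        tm <- tm + if (s[p] == "O") 0 else unname(params$yaa[s[p]])
      }
    }
  }

  pairs <- list(c(1L, 2L, 0L), c(2L, 3L, 0L))
  if (closure == "cyclic") pairs <- c(pairs, list(c(3L, 1L, 1L)))
  for (pr in pairs) {
    donor <- chars[[pr[1L]]]
    accep <- chars[[pr[2L]]]
    for (p in seq_len(n)) {
      if ((p - 1L - frame) %% 3L == 2L) {  # Yaa on the donor strand
        for (geom in c("axial", "lateral")) {
          step <- (if (geom == "axial") 1L else 0L) + pr[3L]
          q <- p - 1L + 3L * step          # Xaa of triplet t + step
          if (q >= 1L && q <= n) {
            mat <- if (geom == "axial") params$axial else params$lateral
            tm <- tm + mat[donor[p], accep[q]]
          }
        }
      }
    }
  }

  key <- paste(rep(frame, 3L), collapse = "")
  if (!is.na(params$frameshift[key])) {
    tm <- tm + unname(params$frameshift[key])
  } else if (!is.na(params$frameshift[as.character(frame)])) {
    tm <- tm + unname(params$frameshift[as.character(frame)])
  }
  for (s in chars) {
    kN <- paste0("N:", s[1L], ":", if (nterm_capped) "capped" else "free")
    kC <- paste0("C:", s[n], ":", if (cterm_capped) "capped" else "free")
    for (k in c(kN, kC)) {
      if (!is.na(params$terminal[k])) tm <- tm + unname(params$terminal[k])
    }
  }
  tm
}

# (POG)-repeat strand of a given length and frame.
pog_sequence <- function(length, frame = 2L) {
  unit <- switch(as.character(frame),
                 "0" = c("G", "X", "Y"), "1" = c("Y", "G", "X"),
                 "2" = c("X", "Y", "G"))
  res <- rep(unit, length.out = length)
  res[res == "X"] <- "P"
  res[res == "Y"] <- "O"
  paste(res, collapse = "")
}

make_peptide <- function(seq, id = "A", frame = NULL) {
  validate_sequence(seq, frame_offset = frame, id = id)
}

# Random helix-set fixture sharing one frame, as collagen_peptide list.
random_set <- function(k, length = 24L, frame = NULL, excluded = list()) {
  if (is.null(frame)) frame <- sample(0:2, 1L)
  lapply(seq_len(k), function(i) {
    random_peptide(length, frame_offset = frame, excluded = excluded,
                   id = LETTERS[i])
  })
}

# Toy design problem small enough to enumerate exhaustively: A2B sets of
# 6-mers in frame 0, Xaa in {P,K}, Yaa in {O,D} -- 16 peptides, 256 sets.
toy_excluded <- list(Xaa = setdiff(CMP_ALPHABET, c("P", "K")),
                     Yaa = setdiff(CMP_ALPHABET, c("O", "D")))

toy_config <- function(seed = NULL, population_size = 16L, max_rounds = 60L,
                       target_tm = -Inf, target_specificity = -Inf) {
  ga_config(composition = "A2B", peptide_length = 6L,
            target_tm = target_tm, target_specificity = target_specificity,
            population_size = population_size,
            max_rounds = max_rounds, frame_offset = 0L,
            excluded = toy_excluded, seed = seed, strict = FALSE)
}

# All 16 toy peptide sequences (frame 0: G x y G x y).
toy_peptides <- function() {
  out <- character(0)
  for (x1 in c("P", "K")) for (y1 in c("O", "D"))
    for (x2 in c("P", "K")) for (y2 in c("O", "D"))
      out <- c(out, paste0("G", x1, y1, "G", x2, y2))
  out
}

# Exhaustive-search optimum of the toy space under a parameter table.
toy_bruteforce_best <- function(params, config = toy_config()) {
  seqs <- toy_peptides()
  best <- list(score = -Inf)
  for (a in seqs) for (b in seqs) {
    peps <- list(make_peptide(a, "A", 0L), make_peptide(b, "B", 0L))
    fit <- helix_fitness(peps, params, config)
    if (fit$score > best$score) best <- c(fit, list(A = a, B = b))
  }
  best
}
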