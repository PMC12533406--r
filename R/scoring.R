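#' Predict the melting temperature of a triple-helical assembly
#'
#' Additive model: a length-dependent baseline for the canonical
#' (POG)-repeat host, plus substitution propensities summed over every Xaa
#' and Yaa position of all three strands, plus axial and lateral pairwise
#' interaction terms summed over the interstrand contacts of
#' [pairwise_contacts()], plus frameshift and terminal corrections.
#'
#' @param assembly A [helix_assembly].
#' @param params A [scoring_parameters] object.
#' @param closure Interstrand closure convention, see [pairwise_contacts()].
#' @return A `tm_prediction`: `tm` (deg C), `terms` (the six-term
#'   breakdown, summing to `tm`) and `display` (the conventional rendering,
#'   flooring values below 10 as `"<10.0"`).
#' @export
predict_tm <- function(assembly, params, closure = c("cyclic", "open")) {
  closure <- match.arg(closure)
  n <- length(assembly$strands[[1L]]$residues)
  base <- params$baseline[as.character(n)]
  if (is.na(base)) {
    stop("no baseline Tm tabulated for length ", n, call. = FALSE)
  }
  prop <- sum(vapply(assembly$strands, strand_propensity_sum, numeric(1L),
                     params = params))
  contacts <- pairwise_contacts(assembly, closure = closure)
  ax <- la <- 0
  if (!is.null(contacts) && nrow(contacts)) {
    a <- contacts$geometry == "axial"
    ax <- sum(params$axial[cbind(contacts$yaa_res[a], contacts$xaa_res[a])])
    la <- sum(params$lateral[cbind(contacts$yaa_res[!a], contacts$xaa_res[!a])])
  }
  fs <- frameshift_term(vapply(assembly$strands, function(p) p$frame_offset,
                               integer(1L)), params)
  tc <- sum(vapply(assembly$strands, terminal_term, numeric(1L),
                   params = params))
  terms <- list(baseline = unname(base), propensity_sum = prop,
                axial_sum = ax, lateral_sum = la,
                frameshift = fs, terminal = tc)
  tm <- sum(unlist(terms))
  structure(list(tm = tm, terms = terms, display = display_tm(tm)),
            class = "tm_prediction")
}

#' @export
print.tm_prediction <- function(x, ...) {
  cat("<tm_prediction> Tm = ", x$display, " degC\n", sep = "")
  t <- unlist(x$terms)
  cat(paste0("  ", format(names(t), width = 15), sprintf("%+8.2f", t),
             collapse = "\n"), "\n")
  invisible(x)
}

#' Conventional rendering of a predicted Tm
#'
#' Values below 10 degC fall outside the reliable range of the model and
#' are rendered with the floor marker `"<10.0"`; internal arithmetic always
#' uses the unclamped value.
#'
#' @param tm Numeric Tm in degC.
#' @return Character.
#' @export
display_tm <- function(tm) {
  ifelse(tm < 10, "<10.0", formatC(tm, format = "f", digits = 1))
}

# Propensity sum of one strand over its Xaa and Yaa positions.  The host
# residues (P at Xaa, O at Yaa) are the zero reference even when the table
# omits them; any other residue absent from the table is an error.
strand_propensity_sum <- function(pep, params) {
  f <- pep$frame_offset
  n <- length(pep$residues)
  role_sum(pep$residues, xaa_positions(f, n), params$xaa, "P", "Xaa") +
    role_sum(pep$residues, yaa_positions(f, n), params$yaa, "O", "Yaa")
}

role_sum <- function(residues, positions, table, host, role) {
  if (!length(positions)) return(0)
  r <- residues[positions]
  v <- unname(table[r])
  v[r == host] <- 0
  if (anyNA(v)) {
    stop("no ", role, " propensity tabulated for residue '",
         r[which(is.na(v))[1L]], "'", call. = FALSE)
  }
  sum(v)
}

# Frameshift correction keyed by the concatenated offset pattern, with a
# single-digit fallback when all three strands share one frame.
frameshift_term <- function(frames, params) {
  key <- paste(frames, collapse = "")
  v <- params$frameshift[key]
  if (is.na(v) && length(unique(frames)) == 1L) {
    v <- params$frameshift[as.character(frames[1L])]
  }
  if (is.na(v)) 0 else unname(v)
}

# Terminal correction of one strand: one lookup per end, keyed by end,
# residue identity and capping state; unparameterised termini are 0.
terminal_term <- function(pep, params) {
  n <- length(pep$residues)
  keyN <- paste0("N:", pep$residues[1L], ":",
                 if (pep$n_term_acetylated) "capped" else "free")
  keyC <- paste0("C:", pep$residues[n], ":",
                 if (pep$c_term_amidated) "capped" else "free")
  v <- params$terminal[c(keyN, keyC)]
  sum(v, na.rm = TRUE)
}

#' Score every assembly a peptide set can form and rank them
#'
#' Enumerates all competing compositions and registers with
#' [enumerate_assemblies()], predicts each melting temperature, and ranks
#' the species.  Specificity is the Tm gap between the most stable and the
#' second most stable assembly; a design is only useful if this gap is wide
#' enough that one species dominates at working temperature.
#'
#' @param peptides List of 1 to 3 [collagen_peptide] objects.
#' @inheritParams predict_tm
#' @return A `specificity_report`: `ranked` (data frame of register label,
#'   composition, Tm and display string, in descending Tm with ties broken
#'   lexicographically by label), `predictions` (the [predict_tm()] objects
#'   in the same order), `best_register` (strand indices of the winner, in
#'   input order), and `specificity` (degC; `Inf` when only one assembly
#'   exists).
#' @export
specificity_report <- function(peptides, params, closure = c("cyclic", "open")) {
  closure <- match.arg(closure)
  assemblies <- enumerate_assemblies(peptides)
  preds <- lapply(assemblies, predict_tm, params = params, closure = closure)
  tms <- vapply(preds, function(p) p$tm, numeric(1L))
  labels <- vapply(assemblies, function(a) a$register_label, character(1L))
  ord <- order(-tms, labels)
  spec <- if (length(tms) > 1L) tms[ord[1L]] - tms[ord[2L]] else Inf
  structure(
    list(ranked = data.frame(register = labels[ord],
                             composition = vapply(assemblies[ord],
                                                  function(a) a$composition_label,
                                                  character(1L)),
                             tm = tms[ord],
                             display = display_tm(tms[ord]),
                             stringsAsFactors = FALSE),
         predictions = preds[ord],
         assemblies = assemblies[ord],
         best_register = assemblies[[ord[1L]]]$strand_index,
         specificity = spec),
    class = "specificity_report")
}

#' @export
print.specificity_report <- function(x, ...) {
  cat("<specificity_report> ", nrow(x$ranked), " competing species\n", sep = "")
  df <- x$ranked
  cat(sprintf("  %-8s %-6s %8s\n", "register", "comp", "Tm"))
  for (i in seq_len(nrow(df))) {
    cat(sprintf("  %-8s %-6s %8s\n", df$register[i], df$composition[i],
                df$display[i]))
  }
  cat("  specificity: ",
      if (is.finite(x$specificity)) {
        paste0(formatC(x$specificity, format = "f", digits = 1), " degC")
      } else "n/a (single species)", "\n", sep = "")
  invisible(x)
}

# ---- fast path used inside the genetic algorithm ------------------------
#
# Computes the Tm of all k^3 registers of a set from per-strand propensity
# and terminal sums plus per-ordered-pair interaction sums, avoiding the
# per-assembly contact walk.  Agrees with predict_tm() (tested).
set_tm_table <- function(peptides, params, closure = "cyclic") {
  k <- length(peptides)
  frames <- vapply(peptides, function(p) p$frame_offset, integer(1L))
  if (length(unique(frames)) != 1L) {
    stop("fast scorer requires one shared frame", call. = FALSE)
  }
  n <- length(peptides[[1L]]$residues)
  base <- params$baseline[as.character(n)]
  if (is.na(base)) stop("no baseline Tm tabulated for length ", n, call. = FALSE)
  props <- vapply(peptides, strand_propensity_sum, numeric(1L), params = params)
  terms <- vapply(peptides, terminal_term, numeric(1L), params = params)
  # contact index masks depend only on frame and length: precompute once
  f <- frames[1L]
  yp <- yaa_positions(f, n)
  yt <- (yp - f) %/% 3L
  masks <- list()
  for (shift in 0:1) for (geom in c("axial", "lateral")) {
    d <- (if (geom == "axial") 1L else 0L) + shift
    xpos <- f - 1L + 3L * (yt + d)
    keep <- xpos >= 1L & xpos <= n
    masks[[length(masks) + 1L]] <- list(shift = shift, geom = geom,
                                        yp = yp[keep], xpos = xpos[keep])
  }
  pair0 <- pair1 <- matrix(0, k, k)
  for (i in seq_len(k)) for (j in seq_len(k)) {
    di <- peptides[[i]]$residues
    aj <- peptides[[j]]$residues
    for (m in masks) {
      if (!length(m$yp)) next
      mat <- if (m$geom == "axial") params$axial else params$lateral
      s <- sum(mat[cbind(di[m$yp], aj[m$xpos])])
      if (m$shift == 0L) pair0[i, j] <- pair0[i, j] + s
      else pair1[i, j] <- pair1[i, j] + s
    }
  }
  grid <- expand.grid(L = seq_len(k), M = seq_len(k), Tr = seq_len(k))
  tm <- numeric(nrow(grid))
  fs <- frameshift_term(rep(frames[1L], 3L), params)
  for (r in seq_len(nrow(grid))) {
    L <- grid$L[r]; M <- grid$M[r]; Tr <- grid$Tr[r]
    tm[r] <- base + props[L] + props[M] + props[Tr] +
      pair0[L, M] + pair0[M, Tr] +
      (if (closure == "cyclic") pair1[Tr, L] else 0) +
      fs + terms[L] + terms[M] + terms[Tr]
  }
  ids <- vapply(peptides, function(p) p$id, character(1L))
  labels <- paste0("{", ids[grid$L], ids[grid$M], ids[grid$Tr], "}")
  list(tm = unname(tm), label = labels,
       index = cbind(grid$L, grid$M, grid$Tr))
}
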