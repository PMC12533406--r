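#' Construct a collagen-mimetic peptide strand
#'
#' A `collagen_peptide` is one strand of a prospective triple helix: an
#' ordered run of residues over the 21-letter alphabet ([CMP_ALPHABET]),
#' Gly-periodic in one of three frames, with capping flags for the termini.
#' The frame offset records which position of the first triplet carries
#' glycine (0 = Gly-Xaa-Yaa, 1 = Yaa-Gly-Xaa, 2 = Xaa-Yaa-Gly).
#'
#' @param residues Character vector of single residues, or a single string.
#' @param id Short strand label, e.g. `"A"`.
#' @param frame_offset Integer in `0:2`; 0-based index of the first Gly.
#' @param n_term_acetylated,c_term_amidated Capping flags; synthetic CMPs are
#'   normally acetylated and amidated to avoid destabilised charged termini.
#' @param permissive Allow non-Gly residues at Gly-frame positions (off by
#'   default; designed CMPs never break Gly periodicity).
#'
#' @return An object of class `collagen_peptide` with fields `id`,
#'   `residues`, `frame_offset`, `n_term_acetylated`, `c_term_amidated`.
#' @export
collagen_peptide <- function(residues, id = "pep", frame_offset,
                             n_term_acetylated = TRUE, c_term_amidated = TRUE,
                             permissive = FALSE) {
  if (length(residues) == 1L && nchar(residues[1L]) > 1L) {
    residues <- strsplit(residues, "")[[1L]]
  }
  residues <- toupper(residues)
  bad <- which(!residues %in% CMP_ALPHABET)
  if (length(bad)) {
    stop("invalid residue '", residues[bad[1L]], "' at position ", bad[1L],
         " (alphabet is the 20 canonical codes plus 'O')", call. = FALSE)
  }
  n <- length(residues)
  if (n < 3L) stop("peptide must have at least 3 residues", call. = FALSE)
  frame_offset <- as.integer(frame_offset)
  if (!frame_offset %in% 0:2) stop("frame_offset must be 0, 1 or 2", call. = FALSE)
  gp <- gly_positions(frame_offset, n)
  if (!all(residues[gp] == "G")) {
    stop("Gly missing at frame position ",
         gp[which(residues[gp] != "G")[1L]], " (frame offset ", frame_offset,
         ")", call. = FALSE)
  }
  if (!permissive) {
    stray <- setdiff(which(residues == "G"), gp)
    if (length(stray)) {
      stop("Gly at non-frame position ", stray[1L],
           " breaks the Xaa-Yaa-Gly periodicity (use permissive = TRUE to allow)",
           call. = FALSE)
    }
  }
  structure(
    list(id = as.character(id), residues = residues,
         frame_offset = frame_offset,
         n_term_acetylated = isTRUE(n_term_acetylated),
         c_term_amidated = isTRUE(c_term_amidated)),
    class = "collagen_peptide"
  )
}

#' @export
print.collagen_peptide <- function(x, ...) {
  caps <- paste0(if (x$n_term_acetylated) "Ac-" else "H-",
                 "...",
                 if (x$c_term_amidated) "-NH2" else "-OH")
  cat("<collagen_peptide> ", x$id, ": ", peptide_string(x),
      "  [", length(x$residues), " aa, frame ", x$frame_offset,
      ", ", caps, "]\n", sep = "")
  invisible(x)
}

#' @export
length.collagen_peptide <- function(x) length(x$residues)

#' Sequence of a peptide as a single string
#' @param peptide A [collagen_peptide].
#' @return Single character string.
#' @export
peptide_string <- function(peptide) paste(peptide$residues, collapse = "")

#' Validate raw text as a collagen-mimetic peptide
#'
#' Checks the alphabet and the Gly periodicity; when the frame offset is
#' unknown it is inferred from the glycine positions.  A sequence whose
#' glycines fit no single frame is rejected.
#'
#' @param raw Sequence text (case-insensitive).
#' @param frame_offset Integer in `0:2`, or `NULL` to infer from the Gly
#'   pattern.
#' @inheritParams collagen_peptide
#' @return A [collagen_peptide].
#' @examples
#' validate_sequence("POGPOGPOG")          # frame inferred as 2
#' validate_sequence("GPOGPO")$frame_offset  # 0
#' @export
validate_sequence <- function(raw, frame_offset = NULL, id = "pep",
                              n_term_acetylated = TRUE, c_term_amidated = TRUE,
                              permissive = FALSE) {
  if (!is.character(raw) || length(raw) != 1L || !nzchar(raw)) {
    stop("sequence must be a non-empty string", call. = FALSE)
  }
  residues <- toupper(strsplit(raw, "")[[1L]])
  bad <- which(!residues %in% CMP_ALPHABET)
  if (length(bad)) {
    stop("invalid residue '", residues[bad[1L]], "' at position ", bad[1L],
         call. = FALSE)
  }
  if (is.null(frame_offset)) {
    frame_offset <- infer_frame(residues, permissive = permissive)
  }
  collagen_peptide(residues, id = id, frame_offset = frame_offset,
                   n_term_acetylated = n_term_acetylated,
                   c_term_amidated = c_term_amidated,
                   permissive = permissive)
}

# Infer the unique frame offset compatible with the Gly positions.
infer_frame <- function(residues, permissive = FALSE) {
  n <- length(residues)
  if (n < 3L) stop("sequence too short to determine the Gly frame", call. = FALSE)
  is_g <- residues == "G"
  fits <- vapply(0:2, function(f) {
    gp <- gly_positions(f, n)
    all(is_g[gp]) && (permissive || sum(is_g) == length(gp))
  }, logical(1L))
  hits <- which(fits) - 1L
  if (length(hits) == 0L) {
    stop("glycine pattern fits no frame: Gly must occur at every third ",
         "position and nowhere else", call. = FALSE)
  }
  if (length(hits) > 1L) {
    stop("glycine pattern is ambiguous between frames ",
         paste(hits, collapse = " and "), call. = FALSE)
  }
  hits
}

#' Structural role of a sequence position
#'
#' Under the Xaa-Yaa-Gly repeat, the role of every position is fixed by the
#' frame offset: Gly sits at the frame positions, the position two before a
#' Gly is Xaa and the one immediately before is Yaa.
#'
#' @param peptide A [collagen_peptide].
#' @param position 1-based position index.
#' @return List with `role` (`"Xaa"`, `"Yaa"` or `"Gly"`) and
#'   `triplet_index` (0-based index of the Xaa-Yaa-Gly unit).
#' @export
role_of <- function(peptide, position) {
  n <- length(peptide$residues)
  if (position < 1L || position > n) {
    stop("position ", position, " out of range 1..", n, call. = FALSE)
  }
  list(role = position_role(position, peptide$frame_offset),
       triplet_index = triplet_index(position, peptide$frame_offset))
}

#' Generate a random collagen-like peptide
#'
#' Draws Xaa and Yaa residues uniformly from their allowed alphabets and
#' inserts Gly at every third position starting from the frame offset, which
#' is itself drawn uniformly from `0:2` when not supplied.  By default Gly is
#' not offered at Xaa/Yaa positions so periodicity is never broken by chance.
#'
#' @param length Residue count; designed CMPs use 21 to 40 (set
#'   `relax_length = TRUE` for scoring-only toy strands outside this range).
#' @param frame_offset Integer in `0:2`, or `NULL` for a random frame.
#' @param excluded Named list with optional elements `Xaa` and `Yaa`, each a
#'   character vector of residues never to place at that role.
#' @param allow_gly Offer `"G"` in the Xaa/Yaa draw alphabets.
#' @param relax_length Permit lengths outside `[21, 40]`.
#' @inheritParams collagen_peptide
#' @return A [collagen_peptide]; reproducible under [set.seed()].
#' @export
random_peptide <- function(length, frame_offset = NULL,
                           excluded = list(), id = "pep",
                           allow_gly = FALSE, relax_length = FALSE) {
  length <- as.integer(length)
  if (!relax_length && (length < 21L || length > 40L)) {
    stop("peptide length must be in [21, 40]", call. = FALSE)
  }
  if (length < 3L) stop("length must be at least 3", call. = FALSE)
  if (is.null(frame_offset)) frame_offset <- sample.int(3L, 1L) - 1L
  x_ab <- role_alphabet("Xaa", excluded, allow_gly)
  y_ab <- role_alphabet("Yaa", excluded, allow_gly)
  res <- character(length)
  gp <- gly_positions(frame_offset, length)
  xp <- xaa_positions(frame_offset, length)
  yp <- yaa_positions(frame_offset, length)
  res[gp] <- "G"
  res[xp] <- sample(x_ab, base::length(xp), replace = TRUE)
  res[yp] <- sample(y_ab, base::length(yp), replace = TRUE)
  collagen_peptide(res, id = id, frame_offset = frame_offset,
                   permissive = allow_gly)
}

# Draw alphabet for one role after exclusions.
role_alphabet <- function(role, excluded = list(), allow_gly = FALSE) {
  ab <- CMP_ALPHABET
  if (!allow_gly) ab <- setdiff(ab, "G")
  ex <- excluded[[role]]
  if (!is.null(ex)) ab <- setdiff(ab, toupper(ex))
  if (length(ab) == 0L) {
    stop("excluded set leaves no allowed residue at ", role, call. = FALSE)
  }
  ab
}
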