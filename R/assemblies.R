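#' Enumerate every triple-helical species formable from a peptide set
#'
#' A triple helix is an ordered (leading, middle, trailing) triple of
#' strands; register matters, so `{ABB}`, `{BAB}` and `{BBA}` are three
#' distinct assemblies.  From k distinct peptides there are exactly k^3
#' ordered triples: 1 homotrimer from one peptide, 8 species from two
#' (2 homotrimers plus 3 registers each of A2B and AB2), 27 from three.
#'
#' @param peptides List of 1 to 3 [collagen_peptide] objects of equal
#'   length, with distinct ids.
#' @return List of `helix_assembly` objects in lexicographic order of the
#'   register label.  Each carries `strands` (the ordered triple),
#'   `strand_index` (1-based indices into the input list),
#'   `composition_label` (multiset, e.g. `"A2B"`) and `register_label`
#'   (ordered, e.g. `"{ABB}"`).
#' @export
enumerate_assemblies <- function(peptides) {
  if (length(peptides) == 0L) stop("no peptides supplied", call. = FALSE)
  if (length(peptides) > 3L) stop("at most 3 distinct peptides", call. = FALSE)
  lens <- vapply(peptides, function(p) length(p$residues), integer(1L))
  if (length(unique(lens)) != 1L) {
    stop("all strands must have equal length (got ",
         paste(lens, collapse = ", "), ")", call. = FALSE)
  }
  ids <- vapply(peptides, function(p) p$id, character(1L))
  if (anyDuplicated(ids)) stop("peptide ids must be distinct", call. = FALSE)
  k <- length(peptides)
  grid <- expand.grid(L = seq_len(k), M = seq_len(k), Tr = seq_len(k))
  out <- lapply(seq_len(nrow(grid)), function(i) {
    idx <- c(grid$L[i], grid$M[i], grid$Tr[i])
    helix_assembly(peptides[idx], strand_index = idx)
  })
  out[order(vapply(out, function(a) a$register_label, character(1L)))]
}

#' Build a single helix assembly from an ordered strand triple
#'
#' @param strands List of exactly 3 [collagen_peptide] objects in
#'   (leading, middle, trailing) order; repeats allowed.
#' @param strand_index Optional 1-based indices of the strands in some
#'   reference peptide list (used to report best registers in input order).
#' @return A `helix_assembly`.
#' @export
helix_assembly <- function(strands, strand_index = NULL) {
  stopifnot(length(strands) == 3L)
  ids <- vapply(strands, function(p) p$id, character(1L))
  structure(
    list(strands = strands,
         strand_index = strand_index,
         composition_label = composition_label(ids),
         register_label = paste0("{", paste(ids, collapse = ""), "}")),
    class = "helix_assembly")
}

# Multiset label: A3 for a homotrimer, A2B / AB2, ABC, ...
composition_label <- function(ids) {
  tab <- table(ids)
  tab <- tab[order(names(tab))]
  paste0(vapply(seq_along(tab), function(i) {
    paste0(names(tab)[i], if (tab[i] > 1L) tab[i] else "")
  }, character(1L)), collapse = "")
}

#' @export
print.helix_assembly <- function(x, ...) {
  cat("<helix_assembly> ", x$register_label, " (", x$composition_label,
      ")\n", sep = "")
  for (role in 1:3) {
    cat(sprintf("  %-8s %s\n", c("leading", "middle", "trailing")[role],
                peptide_string(x$strands[[role]])))
  }
  invisible(x)
}

#' Interstrand pairwise contacts of an assembly
#'
#' Under the canonical one-residue stagger (leading ahead of middle ahead of
#' trailing) two contact geometries couple adjacent strands: an axial
#' contact between the Yaa of triplet n on one strand and the Xaa of triplet
#' n+1 on the next strand, and a lateral contact between Yaa of triplet n
#' and Xaa of the same triplet n on the next strand.  Adjacency runs
#' leading to middle and middle to trailing; with the default cyclic closure
#' the trailing strand also contacts the leading strand, with all triplet
#' indices shifted by one to account for the full turn of stagger.
#'
#' @param assembly A [helix_assembly]; all strands must share one frame.
#' @param closure `"cyclic"` (default; three strand pairs) or `"open"`
#'   (trailing-to-leading pair omitted).
#' @return Data frame with one row per contact: `geometry` (axial/lateral),
#'   `donor` / `acceptor` (strand slot 1..3), `yaa_triplet`, `xaa_triplet`,
#'   `yaa_pos`, `xaa_pos` (1-based), `yaa_res`, `xaa_res`.
#' @export
pairwise_contacts <- function(assembly, closure = c("cyclic", "open")) {
  closure <- match.arg(closure)
  frames <- vapply(assembly$strands, function(p) p$frame_offset, integer(1L))
  if (length(unique(frames)) != 1L) {
    stop("contact geometry requires all strands in one frame (offsets ",
         paste(frames, collapse = ", "), ")", call. = FALSE)
  }
  pairs <- list(c(1L, 2L, 0L), c(2L, 3L, 0L))
  if (closure == "cyclic") pairs <- c(pairs, list(c(3L, 1L, 1L)))
  rows <- lapply(pairs, function(pr) {
    strand_pair_contacts(assembly$strands[[pr[1L]]],
                         assembly$strands[[pr[2L]]],
                         donor = pr[1L], acceptor = pr[2L], shift = pr[3L])
  })
  do.call(rbind, rows)
}

# Contacts donated by one strand's Yaa positions onto an adjacent strand's
# Xaa positions.  `shift` adds to the acceptor triplet index (used to close
# the trailing-to-leading pair).
strand_pair_contacts <- function(donor_pep, acceptor_pep, donor, acceptor,
                                 shift = 0L) {
  f <- donor_pep$frame_offset
  n <- length(donor_pep$residues)
  yp <- yaa_positions(f, n)
  yt <- vapply(yp, triplet_index, integer(1L), frame_offset = f)
  geoms <- list(axial = 1L + shift, lateral = 0L + shift)
  out <- lapply(names(geoms), function(g) {
    xt <- yt + geoms[[g]]
    # Xaa of triplet t sits at 0-based position f - 2 + 3 t
    xpos <- f - 2L + 3L * xt + 1L
    keep <- xpos >= 1L & xpos <= length(acceptor_pep$residues)
    if (!any(keep)) return(NULL)
    data.frame(geometry = g, donor = donor, acceptor = acceptor,
               yaa_triplet = yt[keep], xaa_triplet = xt[keep],
               yaa_pos = yp[keep], xaa_pos = xpos[keep],
               yaa_res = donor_pep$residues[yp[keep]],
               xaa_res = acceptor_pep$residues[xpos[keep]],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
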