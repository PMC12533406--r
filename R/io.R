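#' Read peptide strands from FASTA
#'
#' Standard single-letter FASTA with `"O"` permitted for hydroxyproline.
#' The frame of each record is inferred from its Gly positions.
#'
#' @param path FASTA file.
#' @inheritParams collagen_peptide
#' @return List of [collagen_peptide] objects (empty list for an empty file).
#' @export
read_fasta <- function(path, permissive = FALSE) {
  if (file.size(path) %in% c(0L, NA)) return(list())
  recs <- tryCatch(
    seqinr::read.fasta(path, seqtype = "AA", as.string = TRUE,
                       forceDNAtolower = FALSE),
    error = function(e) stop("cannot parse FASTA '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  out <- vector("list", length(recs))
  for (i in seq_along(recs)) {
    out[[i]] <- tryCatch(
      validate_sequence(as.character(recs[[i]]), id = names(recs)[i],
                        permissive = permissive),
      error = function(e) stop("FASTA record ", i, " ('", names(recs)[i],
                               "'): ", conditionMessage(e), call. = FALSE))
  }
  out
}

#' Write peptide strands to FASTA
#'
#' @param peptides List of [collagen_peptide] objects.
#' @param path Output file.
#' @return `path`, invisibly.  Round-trips with [read_fasta()] on id and
#'   residues.
#' @export
write_fasta <- function(peptides, path) {
  seqinr::write.fasta(
    sequences = lapply(peptides, peptide_string),
    names = vapply(peptides, function(p) p$id, character(1L)),
    file.out = path, as.string = TRUE, nbchar = 60L)
  invisible(path)
}

#' Read peptides from a plain-text file
#'
#' One sequence per line, optionally preceded by `id<TAB>`; blank lines and
#' `#` comments are skipped.
#'
#' @inheritParams read_fasta
#' @return List of [collagen_peptide] objects.
#' @export
read_peptide_lines <- function(path, permissive = FALSE) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  out <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    parts <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(parts) == 1L) parts <- c(paste0("pep", i), parts)
    out[[i]] <- validate_sequence(parts[2L], id = parts[1L],
                                  permissive = permissive)
  }
  out
}
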