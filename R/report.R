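#' Run a design and write its artifacts
#'
#' The command-style front end: validates the input ranges (length 21-40,
#' target Tm 30-70, target specificity 10-35, motif length 3-15), runs
#' [run_design()], and writes three artifacts into `out_dir`: a FASTA of
#' the winning strands, a JSON report with the competing-species table,
#' and `FitnessLandscape.csv` with the per-generation trace.
#'
#' @param config A strict [ga_config()] (construct with `strict = TRUE`).
#' @param params A [scoring_parameters] object, or a path accepted by
#'   [load_parameters()].
#' @param out_dir Output directory (created if absent).
#' @param prefix File-name stem for the FASTA and JSON artifacts.
#' @param verbose Progress every 100 generations.
#' @return Invisibly, a list with `status` (0 on convergence, 3 when the
#'   round cap was hit), `result` (the `design_result`) and `files`.
#' @export
cmd_design <- function(config, params, out_dir = ".", prefix = "design",
                       verbose = FALSE) {
  if (is.character(params)) params <- load_parameters(params)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  result <- run_design(config, params, verbose = verbose)

  fasta <- file.path(out_dir, paste0(prefix, ".fasta"))
  write_fasta(result$peptides, fasta)

  csv <- file.path(out_dir, "FitnessLandscape.csv")
  write_trace_csv(result$trace, csv)

  report <- specificity_report(result$peptides, params,
                               closure = config$closure)
  json <- file.path(out_dir, paste0(prefix, "_report.json"))
  jsonlite::write_json(
    list(converged = result$converged,
         generations = result$generations,
         seed = config$seed,
         tm = result$tm,
         specificity = result$specificity,
         best_register = result$best_label,
         best_register_indices = as.integer(result$best_register),
         parameters_version = params$version_tag,
         peptides = lapply(result$peptides, function(p) {
           list(id = p$id, sequence = peptide_string(p),
                frame_offset = p$frame_offset)
         }),
         species = report$ranked),
    json, auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(status = if (result$converged) 0L else 3L,
                 result = result,
                 files = c(fasta = fasta, json = json, csv = csv)))
}

# Trace CSV with the exact header Generation,TimeElapsed,FitnessScore,Tm,Spec
write_trace_csv <- function(trace, path) {
  utils::write.table(trace, path, sep = ",", row.names = FALSE,
                     col.names = TRUE, quote = FALSE)
  invisible(path)
}

#' Audit the competing species of a peptide set
#'
#' Renders the full ranked assembly table for 1 to 3 peptides: every
#' register with its predicted Tm (floored rendering below 10 degC), the
#' best register and the specificity.
#'
#' @param peptides List of [collagen_peptide] objects, or a FASTA path.
#' @param params A [scoring_parameters] object or parameter-file path.
#' @inheritParams predict_tm
#' @return The [specificity_report()], invisibly; the table is printed.
#' @export
cmd_audit <- function(peptides, params, closure = c("cyclic", "open")) {
  closure <- match.arg(closure)
  if (is.character(peptides)) peptides <- read_fasta(peptides)
  if (is.character(params)) params <- load_parameters(params)
  report <- specificity_report(peptides, params, closure = closure)
  print(report)
  invisible(report)
}
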