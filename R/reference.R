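#' Reference melting-temperature tables for four designed heterotrimers
#'
#' Published reference values for four experimentally characterised
#' designed CMP heterotrimers (ABC-1, ABC-2, AAB-FOGER, ABC-FOGER), shipped
#' as regression fixtures: the model-predicted Tm of every peptide
#' combination, the CD-measured Tm of the same combinations, and the
#' predicted-versus-experimental comparison for the target assemblies.
#' Values below the reliable range carry a floor marker (`floored`) and are
#' stored at the floor value of 10.0.
#'
#' The comparison table's experimental Tm for ABC-FOGER (40.7) differs from
#' the melting table's (40.5); this inconsistency is in the source data and
#' both values are kept as published.
#'
#' @param which `"predicted"`, `"experimental"` or `"comparison"`.
#' @return Data frame.  For `"predicted"`/`"experimental"`: one row per
#'   heterotrimer and peptide combination, columns `heterotrimer`,
#'   `species` (A, B, C, AB, AC, BC, ABC), `tm`, `floored`, `register`
#'   (predicted register label, where reported).  For `"comparison"`:
#'   columns `heterotrimer`, `predicted`, `experimental`, `deviation`.
#' @export
reference_tm_table <- function(which = c("predicted", "experimental",
                                         "comparison")) {
  which <- match.arg(which)
  path <- system.file("extdata",
                      paste0("tm_", which, "_reference.tsv"),
                      package = "colhelix", mustWork = TRUE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          na.strings = "NA")
  if ("floored" %in% names(df)) df$floored <- as.logical(df$floored)
  df
}

#' Published specificities of the reference heterotrimers
#'
#' The printed specificity (Tm of the most stable assembly minus Tm of the
#' second most stable) of each reference heterotrimer, as reported
#' alongside the predicted and experimental melting tables.
#'
#' @param source `"predicted"` or `"experimental"`.
#' @return Named numeric vector, degC.
#' @export
reference_specificities <- function(source = c("predicted", "experimental")) {
  source <- match.arg(source)
  path <- system.file("extdata", "specificity_reference.tsv",
                      package = "colhelix", mustWork = TRUE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  df <- df[df$source == source, ]
  stats::setNames(df$specificity, df$heterotrimer)
}

#' Specificity recomputed from a table of melting temperatures
#'
#' Max minus second-max; the arithmetic behind every printed specificity
#' column.
#'
#' @param tms Numeric vector of melting temperatures (floors already at
#'   their floor values).
#' @return Tm gap in degC (`Inf` for a single value).
#' @export
specificity_from_tms <- function(tms) {
  tms <- sort(tms, decreasing = TRUE)
  if (length(tms) < 2L) return(Inf)
  tms[1L] - tms[2L]
}
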