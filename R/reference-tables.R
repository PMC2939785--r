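#' Clinicopathological contingency tables of the reference IBC cohort
#'
#' Counts transcribed from the published tumour-characteristics table of a
#' 20 IBC / 50 non-IBC breast cancer cohort, for use as worked examples with
#' [chi_square_association()]. Each matrix has IBC and non-IBC columns.
#'
#' @return named list of integer matrices: `her2` (positive/negative),
#'   `er` (positive/negative), `grade` (well/moderate/poor),
#'   `stage` (I/II/III/IV).
#' @examples
#' chi_square_association(ibc_contingency_tables()$her2, variable = "HER2")
#' @export
ibc_contingency_tables <- function() {
  list(
    her2 = matrix(c(8L, 12L, 9L, 41L), 2,
                  dimnames = list(c("pos", "neg"), c("IBC", "non-IBC"))),
    er = matrix(c(16L, 4L, 35L, 15L), 2,
                dimnames = list(c("pos", "neg"), c("IBC", "non-IBC"))),
    grade = matrix(c(0L, 9L, 11L, 8L, 23L, 19L), 3,
                   dimnames = list(c("well", "moderate", "poor"),
                                   c("IBC", "non-IBC"))),
    stage = matrix(c(0L, 0L, 10L, 10L, 21L, 15L, 11L, 3L), 4,
                   dimnames = list(c("I", "II", "III", "IV"),
                                   c("IBC", "non-IBC"))))
}

#' Direct miRNA target genes of the reference IBC cohort
#'
#' The bundled transcription of the reference cohort's direct (concordant)
#' target gene symbols for the four miRNAs whose predicted targets were
#' significantly enriched among their correlation-defined targets
#' (miR-29a, miR-30b, miR-342-3p, miR-520a-5p).
#'
#' @return named list mapping miRNA id to a character vector of gene
#'   symbols (121, 140, 19 and 13 genes respectively).
#' @export
ibc_direct_targets <- function() {
  path <- system.file("extdata", "direct_targets.tsv",
                      package = "mirintegrate", mustWork = TRUE)
  read_target_db(path, source_label = "reference cohort direct targets")
}
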