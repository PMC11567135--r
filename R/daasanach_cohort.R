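#' Daasanach cohort table (packaged fixture)
#'
#' The 34-participant cohort table of anthropometrics, isotope kinetics and
#' derived energetics transcribed from the source publication (three
#' northern-Kenyan Daasanach communities: El Bokoch, Illeret, Roto). Printed
#' columns: age, sex, body mass, TEE, FFM, fat percent, water turnover, mean
#' daily steps and MVPA minutes (accelerometry subsample only), the dilution
#' space ratio, elimination rates kD and kO (per day) and dilution spaces ND
#' and NO (mol). The isotope columns are the pipeline inputs; the derived
#' columns serve as golden values for the DLW equations.
#'
#' One row (fixture id \code{D32}) is internally inconsistent as printed: its
#' dilution-space-ratio column reads 1.041 while its printed ND and NO give
#' 2040.1/1987.9 = 1.026, and its printed FFM/WT/TEE cannot be reproduced
#' from its printed isotope inputs under the equations that reproduce every
#' other row. The \code{consistent} column flags this (TRUE for the 33
#' self-consistent rows).
#'
#' @param path optional alternative CSV path (defaults to the packaged file).
#' @return data.frame with 34 rows and the columns above plus
#'   \code{participant_id} (synthetic ids D01-D34, row order of the
#'   publication) and \code{consistent}.
#' @examples
#' coh <- daasanach_cohort()
#' table(coh$community, coh$sex)
#' @export
daasanach_cohort <- function(path = system.file("extdata",
                                                "daasanach_cohort.csv",
                                                package = "dlwenergetics")) {
  stopifnot(nzchar(path), file.exists(path))
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  # self-consistency of the printed ratio column with printed ND/NO (3 dp)
  d$consistent <- abs(round(d$nd_mol / d$no_mol, 3) - d$nd_no) <= 0.001
  d
}

#' Split the cohort table into pipeline input tables
#'
#' Convenience accessor returning the two input tables that
#' [process_cohort()] consumes, in the schemas the pipeline defines.
#'
#' @param cohort data.frame from [daasanach_cohort()] (or same schema).
#' @return list with elements \code{participants} and \code{isotopes}.
#' @export
cohort_inputs <- function(cohort = daasanach_cohort()) {
  list(
    participants = cohort[, c("participant_id", "community", "age_y", "sex",
                              "body_mass_kg")],
    isotopes = cohort[, c("participant_id", "nd_mol", "no_mol",
                          "kd_perday", "ko_perday")]
  )
}
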