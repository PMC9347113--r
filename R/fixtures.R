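#' Management records of 18 French local chicken breeds
#'
#' The packaged demographic fixture: per-breed founder counts by sex, year
#' the pedigree-recording program started, number of generations to the 2013
#' sampling, sire/dam counts in 2013, mean pedigree inbreeding (percent),
#' pedigree-based realized Ne, founder-based Ne, and the per-generation
#' inbreeding rate (percent), as published for the Group-1 managed breeds.
#' `NA` marks values that were unavailable. The GDV generation count is
#' stored as 6 (consistent with a 2007 start, one generation per year, and
#' every other row of the table); its printed source value is not
#' self-consistent.
#'
#' @return A tibble with one row per breed.
#' @export
breed_management <- function() {
  readr::read_tsv(
    system.file("extdata", "breed_management.tsv", package = "flockdiv"),
    show_col_types = FALSE, na = "NA"
  )
}

#' Geographic origin and sampling size of 24 local chicken populations
#'
#' Mean center-of-origin coordinates (decimal degrees), management group
#' (1 = managed with pedigrees, 2 = fancy breeders) and number of animals
#' genotyped.
#'
#' @return A tibble with one row per population.
#' @export
breed_coordinates <- function() {
  readr::read_tsv(
    system.file("extdata", "breed_coordinates.tsv", package = "flockdiv"),
    show_col_types = FALSE, na = "NA"
  )
}
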