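#' The Harpy Eagle ten-locus microsatellite panel
#'
#' Marker metadata for the ten retained species-specific loci
#' (Hha01--Hha06, Hha08, Hha09, Hha12, Hha18): repeat motif and count,
#' primer sequences, expected PCR product size and annealing temperature.
#' All primers are 18--27 bp, products 120--300 bp and annealing
#' temperatures 57--63 C, the design constraints of the panel.
#'
#' @return Data frame with one row per locus and columns `locus`, `motif`,
#'   `n_repeats`, `primer_forward`, `primer_reverse`, `expected_size`,
#'   `annealing_temp`.
#' @export
load_panel <- function() {
  path <- system.file("extdata", "harpy_panel_markers.csv",
                      package = "msatkin", mustWork = TRUE)
  panel <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(
    all(grepl("^[ACGT]+$", panel$primer_forward)),
    all(grepl("^[ACGT]+$", panel$primer_reverse)),
    all(nchar(panel$primer_forward) >= 18L &
        nchar(panel$primer_forward) <= 27L),
    all(nchar(panel$primer_reverse) >= 18L &
        nchar(panel$primer_reverse) <= 27L),
    all(panel$expected_size >= 120L & panel$expected_size <= 300L),
    all(panel$annealing_temp >= 57 & panel$annealing_temp <= 63)
  )
  panel
}

#' Published per-locus characterization of the Harpy Eagle panel
#'
#' Per-locus diversity and power statistics of the panel as characterized in
#' the captive Brazilian population (22 wild-born individuals in the
#' diversity estimates): number of genotyped individuals, number of alleles,
#' observed and unbiased expected heterozygosity, Hardy-Weinberg exact-test
#' p-value, parentage-exclusion probability Q and genetic-identity
#' probability I. These printed values serve as reference inputs, e.g. for
#' joint panel-power combination and minimal-panel selection.
#'
#' @return Data frame with one row per locus and columns `locus`, `n`,
#'   `n_alleles`, `ho`, `he`, `p_hwe`, `q_exclusion`, `i_identity`.
#' @export
load_panel_stats <- function() {
  path <- system.file("extdata", "harpy_panel_stats.csv",
                      package = "msatkin", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
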