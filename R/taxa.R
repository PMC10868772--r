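#' Bundled taxon tables
#'
#' Two small reference tables ship with the package: the maracuya
#' (Passiflora) species-to-morphotype assignment — seven morphology-based
#' (not phylogenetic) categories A through G spanning 40 species — and the
#' grapevine taxon list, 11 non-hybrid taxa (ten Vitis species plus
#' Ampelopsis glandulosa var. brevipedunculata) and four named Vitis
#' hybrids.
#'
#' @return `morphotype_table()`: data frame with columns `species`,
#'   `morphotype`. `grapevine_taxa()`: data frame with columns `taxon`,
#'   `hybrid` (logical).
#' @export
morphotype_table <- function() {
  utils::read.csv(system.file("extdata", "passiflora_morphotypes.csv",
                              package = "leafmapper"),
                  stringsAsFactors = FALSE)
}

#' @rdname morphotype_table
#' @export
grapevine_taxa <- function() {
  utils::read.csv(system.file("extdata", "grapevine_taxa.csv",
                              package = "leafmapper"),
                  stringsAsFactors = FALSE)
}
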