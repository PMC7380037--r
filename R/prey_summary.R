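#' Published prey-selectivity summary for *Crangon crangon*
#'
#' Reads the packaged summary of brown-shrimp (*Crangon crangon*) prey
#' selectivity across six European estuaries: for each prey MOTU reported at
#' family level or lower with at least 0.5% mean relative read abundance in
#' the stomach samples, its taxonomy, best reference identity, presence (%),
#' mean (± SE) relative read abundance (%), mean (± SE) Jacobs' selectivity
#' `D`, and the High/Medium/Low trophic-significance category. Useful as a
#' worked reference for the reporting rules and for checking
#' [trophic_significance()] against printed inputs.
#'
#' @return Data frame with 21 rows and columns `phylum`, `order`, `family`,
#'   `species` (`"Unassigned"` where the MOTU is not resolved to species),
#'   `best_identity`, `presence_pct`, `mean_abundance_pct`,
#'   `abundance_se_pct`, `mean_D`, `D_se`, `category`.
#' @examples
#' prey <- read_prey_summary()
#' # the species-level reporting rule: >= 0.5% mean abundance, species rank
#' sum(prey$mean_abundance_pct >= 0.5 & prey$species != "Unassigned")
#' @export
read_prey_summary <- function() {
  path <- system.file("extdata", "crangon_prey_summary.tsv",
                      package = "trophodiet", mustWork = TRUE)
  read_tsv_strict(path)
}
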