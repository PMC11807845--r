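#' Published odds-ratio quintets from a white-matter connectivity screen
#'
#' Loads the odds ratios reported by the five estimators for the 13
#' white-matter structural-connectivity exposures (GWAS Catalog accessions
#' GCST90302648-GCST90302853 series) that passed the first IVW screening
#' step against Alzheimer's disease in a published European-ancestry
#' two-sample MR screen. These quintets are the canonical worked input for
#' the odds-ratio direction-consistency rule: three of the thirteen
#' (GCST90302764, GCST90302809, GCST90302837) mix directions across methods
#' and fail the screen.
#'
#' @param path file to read; defaults to the copy shipped with the package.
#' @return data.frame with columns `id_exposure`, `method` (canonical method
#'   codes), `or`.
#' @examples
#' tab <- published_or_quintets()
#' sapply(split(tab$or, tab$id_exposure), direction_consistent)
#' @export
published_or_quintets <- function(path = system.file(
    "extdata", "connectivity_ad_or.tsv", package = "mrscreen")) {
  utils::read.delim(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
}
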