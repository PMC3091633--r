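#' Published primer-pair tables
#'
#' Two small tables bundled with the package: \code{"vertebrate"} — ten
#' mitochondrial barcode primer pairs (COI, cyt-b, 16S regions) commonly
#' evaluated for vertebrate metabarcoding, with their expected insert
#' sizes; \code{"felidae"} — three species-specific 12S pairs for Asiatic
#' cats (leopard, snow leopard, leopard cat) designed for degraded-DNA
#' work. Fragment sizes are insert lengths, excluding the primers.
#'
#' @param set \code{"vertebrate"} or \code{"felidae"}.
#' @return A data.frame with columns \code{barcode_name}, \code{fwd_name},
#'   \code{fwd}, \code{rev_name}, \code{rev}, \code{fragment_size} (and
#'   \code{target_species} for the felidae set).
#' @examples
#' pp <- primer_pairs("vertebrate")
#' primer(pp$fwd_name[9], pp$fwd[9])  # 16Sar
#' @export
primer_pairs <- function(set = c("vertebrate", "felidae")) {
  set <- match.arg(set)
  path <- system.file("extdata", paste0("primers_", set, ".tsv"),
                      package = "ispcr", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}
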