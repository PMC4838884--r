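#' Load the 81-node APL endogenous network
#'
#' The published acute promyelocytic leukemia (APL) endogenous network has
#' 81 nodes in 8 functional modules connected by 416 signed interactions;
#' its full edge list and equations live in the original supplementary
#' material, which is not redistributed with this package. This loader
#' reads a user-supplied transcription of that network in either dialect
#' accepted by [parse_network()] and checks the expected census (81 nodes,
#' 416 edges, 8 modules) with a warning on mismatch. Without a
#' transcription file it stops with an informative notice naming the path
#' it looked in, so analyses depending on the published network fail loudly
#' rather than silently.
#'
#' @param path path to the transcription; defaults to
#'   `apl_network.tsv` under the package's `extdata` directory
#' @param check warn if the parsed census differs from 81/416/8
#' @return an `endo_network`
#' @export
load_apl_network <- function(path = NULL, check = TRUE) {
  if (is.null(path)) {
    path <- system.file("extdata", "apl_network.tsv", package = "endonet")
    if (!nzchar(path))
      path <- file.path("inst", "extdata", "apl_network.tsv")
  }
  if (!file.exists(path)) {
    stop("APL network transcription not available: no file at '", path,
         "'. Supply a transcription of the published 81-node network ",
         "(TSV or JSON dialect, see ?parse_network) via the `path` argument ",
         "or install it as extdata/apl_network.tsv.", call. = FALSE)
  }
  net <- read_network(path)
  if (check) {
    if (n_nodes(net) != 81 || nrow(net$edges) != 416 ||
        length(net$modules) != 8)
      warning(sprintf(
        "parsed census %d nodes / %d edges / %d modules differs from the published 81/416/8",
        n_nodes(net), nrow(net$edges), length(net$modules)))
  }
  net
}
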