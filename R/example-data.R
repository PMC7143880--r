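#' Packaged example inventories and conservation map
#'
#' The package ships the PKS/NRPS cluster inventories of two phylogenetically
#' close *Streptomyces* strains (TP-A0598, 9 clusters; NBRC 3934, 13
#' clusters) transcribed from their published cluster tables, together with
#' the published expert call of their five conserved clusters.
#'
#' @param which `"TP-A0598"` or `"NBRC3934"`.
#' @return [example_inventory()]: a `bgc_inventory`;
#'   [example_conserved_map()]: a `bgc_conservation_map` (source `"given"`).
#' @examples
#' inv <- example_inventory("TP-A0598")
#' length(inv$clusters)
#' @export
example_inventory <- function(which = c("TP-A0598", "NBRC3934")) {
  which <- match.arg(which)
  read_inventory(system.file("extdata", paste0(which, ".tsv"),
                             package = "bgcrep", mustWork = TRUE))
}

#' @rdname example_inventory
#' @export
example_conserved_map <- function() {
  read_conservation_map(system.file("extdata", "conserved-map.tsv",
                                    package = "bgcrep", mustWork = TRUE))
}
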