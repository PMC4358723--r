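#' Taxonomic group labels used by the pipeline
#'
#' Subject proteins are partitioned into one of eight groups. `own_phylum`
#' holds metazoan proteins from the focal species' own phylum (Arthropoda,
#' Nematoda or Chordata); these are conceptually metazoan but are stored under
#' their own label so they can be excluded from the "best metazoan match"
#' reduction, which is what makes ancient transfers detectable.
#'
#' @return Character vector of the eight group labels.
#' @export
#' @examples
#' taxon_groups()
taxon_groups <- function() {
  c("metazoa", "own_phylum", "bacteria", "archaea", "fungi", "plants",
    "protists", "viruses")
}

#' Candidate donor kingdoms, in tie-break order
#'
#' The five non-metazoan cellular kingdoms considered as possible donors of a
#' foreign gene. The order is the documented deterministic tie-break used when
#' two kingdoms achieve the same best bitscore.
#'
#' @return Character vector of kingdom labels.
#' @export
donor_kingdoms <- function() {
  c("bacteria", "archaea", "protists", "fungi", "plants")
}

#' Thresholds controlling HGT classification
#'
#' Bundles the tunable cutoffs of the pipeline. Defaults follow the
#' conservative published scheme: a gene is a candidate (class C) foreign gene
#' when its HGT index satisfies `h >= h_min` and its best non-metazoan
#' bitscore is at least `nonmet_bitscore_min`; class A additionally requires
#' every metazoan match of the gene and of its whole ortholog group to be
#' below `classA_met_bitscore_max`; phylogenetic validation is attempted for
#' genes with any metazoan match of at least
#' `validation_met_bitscore_min`. `orthograph_evalue_max` is the all-vs-all
#' blastp e-value cutoff for similarity-graph edges and `mcl_inflation` the
#' Markov clustering inflation parameter.
#'
#' @param h_min Minimum HGT index for class C (bitscore units). Default 30.
#' @param nonmet_bitscore_min Minimum best non-metazoan bitscore for class C.
#'   Default 100.
#' @param classA_met_bitscore_max Exclusive upper bound on metazoan bitscores
#'   for class A (gene and every group member). Default 100.
#' @param validation_met_bitscore_min Minimum best metazoan bitscore for a
#'   gene tree to be phylogenetically testable. Default 50.
#' @param orthograph_evalue_max E-value cutoff for similarity-graph edges.
#'   Default 1e-5.
#' @param mcl_inflation MCL inflation parameter I. Default 15.
#' @return An object of class `hgt_thresholds` (a named list).
#' @export
#' @examples
#' hgt_thresholds()
#' hgt_thresholds(h_min = 40)
hgt_thresholds <- function(h_min = 30,
                           nonmet_bitscore_min = 100,
                           classA_met_bitscore_max = 100,
                           validation_met_bitscore_min = 50,
                           orthograph_evalue_max = 1e-5,
                           mcl_inflation = 15) {
  t <- list(
    h_min = h_min,
    nonmet_bitscore_min = nonmet_bitscore_min,
    classA_met_bitscore_max = classA_met_bitscore_max,
    validation_met_bitscore_min = validation_met_bitscore_min,
    orthograph_evalue_max = orthograph_evalue_max,
    mcl_inflation = mcl_inflation
  )
  bad <- names(t)[!vapply(t, function(x)
    is.numeric(x) && length(x) == 1L && is.finite(x) && x > 0, logical(1))]
  if (length(bad))
    stop("thresholds must be single positive numbers: ",
         paste(bad, collapse = ", "))
  if (t$mcl_inflation <= 1) stop("mcl_inflation must be > 1")
  structure(t, class = "hgt_thresholds")
}

#' @export
print.hgt_thresholds <- function(x, ...) {
  cat("HGT classification thresholds:\n")
  for (nm in names(x)) cat(sprintf("  %-28s %g\n", nm, x[[nm]]))
  invisible(x)
}

as_thresholds <- function(t) {
  if (inherits(t, "hgt_thresholds")) return(t)
  do.call(hgt_thresholds, as.list(t))
}
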