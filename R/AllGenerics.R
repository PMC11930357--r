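#' @include AllClasses.R
NULL

#' Accessors for ensaxs classes
#'
#' Small accessor generics used across the package: bead coordinates,
#' residue/chain labels, scattering factors, ensemble weights and profile
#' columns.
#'
#' @param object an ensaxs object.
#' @param ... unused.
#' @return The corresponding slot content.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("beadCoords", function(object) standardGeneric("beadCoords"))
#' @rdname accessors
#' @export
setGeneric("residueIds", function(object) standardGeneric("residueIds"))
#' @rdname accessors
#' @export
setGeneric("chainIds", function(object) standardGeneric("chainIds"))
#' @rdname accessors
#' @export
setGeneric("scatterWeights", function(object) standardGeneric("scatterWeights"))
#' @rdname accessors
#' @export
setGeneric("charges", function(object) standardGeneric("charges"))
#' @rdname accessors
#' @export
setGeneric("nBeads", function(object) standardGeneric("nBeads"))
#' @rdname accessors
#' @export
setGeneric("conformers", function(object) standardGeneric("conformers"))
#' @rdname accessors
#' @export
setGeneric("nConformers", function(object) standardGeneric("nConformers"))
#' @rdname accessors
#' @export
setGeneric("ensembleWeights", function(object) standardGeneric("ensembleWeights"))
#' @rdname accessors
#' @export
setGeneric("initialWeights", function(object) standardGeneric("initialWeights"))
#' @rdname accessors
#' @export
setGeneric("setEnsembleWeights",
           function(object, value) standardGeneric("setEnsembleWeights"))
#' @rdname accessors
#' @export
setGeneric("qValues", function(object) standardGeneric("qValues"))
#' @rdname accessors
#' @export
setGeneric("intensities", function(object) standardGeneric("intensities"))
#' @rdname accessors
#' @export
setGeneric("sigmas", function(object) standardGeneric("sigmas"))
#' @rdname accessors
#' @export
setGeneric("contactProbs", function(object) standardGeneric("contactProbs"))
#' @rdname accessors
#' @export
setGeneric("clusterLabels", function(object) standardGeneric("clusterLabels"))
#' @rdname accessors
#' @export
setGeneric("clusterCenters", function(object) standardGeneric("clusterCenters"))
#' @rdname accessors
#' @export
setGeneric("clusterWeights", function(object) standardGeneric("clusterWeights"))

#' Radius of gyration of a conformer
#'
#' @param object a [Conformer-class].
#' @param massWeights optional per-bead weights (non-negative, not all zero).
#' @return Rg in Angstrom: `sqrt(sum(m_i |r_i - rbar|^2) / sum(m_i))` with
#'   `rbar` the weighted centroid.
#' @export
setGeneric("radiusOfGyration",
           function(object, massWeights = NULL) standardGeneric("radiusOfGyration"))
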