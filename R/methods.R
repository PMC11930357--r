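#' @include AllGenerics.R
NULL

#' @rdname accessors
setMethod("beadCoords", "Conformer", function(object) object@coords)
#' @rdname accessors
setMethod("residueIds", "Conformer", function(object) object@residueIds)
#' @rdname accessors
setMethod("chainIds", "Conformer", function(object) object@chainIds)
#' @rdname accessors
setMethod("scatterWeights", "Conformer", function(object) object@scatterWeight)
#' @rdname accessors
setMethod("charges", "Conformer", function(object) object@charge)
#' @rdname accessors
setMethod("nBeads", "Conformer", function(object) nrow(object@coords))

#' @rdname accessors
setMethod("conformers", "Ensemble", function(object) object@conformers)
#' @rdname accessors
setMethod("nConformers", "Ensemble", function(object) length(object@conformers))
#' @rdname accessors
setMethod("ensembleWeights", "Ensemble", function(object) object@weights)
#' @rdname accessors
setMethod("initialWeights", "Ensemble", function(object) object@initialWeights)
#' @rdname accessors
setMethod("setEnsembleWeights", "Ensemble", function(object, value) {
  object@weights <- as.numeric(value)
  validObject(object)
  object
})

#' @rdname accessors
setMethod("qValues", "ScatteringProfile", function(object) object@q)
#' @rdname accessors
setMethod("intensities", "ScatteringProfile", function(object) object@I)
#' @rdname accessors
setMethod("sigmas", "ScatteringProfile", function(object) object@sigma)

#' @rdname accessors
setMethod("ensembleWeights", "ReweightResult", function(object) object@weights)

#' @rdname accessors
setMethod("contactProbs", "ContactMap", function(object) object@probs)

#' @rdname accessors
setMethod("clusterLabels", "ClusterAssignment", function(object) object@labels)
#' @rdname accessors
setMethod("clusterCenters", "ClusterAssignment", function(object) object@centers)
#' @rdname accessors
setMethod("clusterWeights", "ClusterAssignment",
          function(object) object@clusterWeights)

setMethod("show", "Conformer", function(object) {
  ch <- table(object@chainIds)
  cat(sprintf("Conformer: %d beads in %d chain(s) [%s]\n",
              nBeads(object), length(ch),
              paste(sprintf("%s:%d", names(ch), as.integer(ch)),
                    collapse = ", ")))
  cat(sprintf("  Rg = %.2f A\n", radiusOfGyration(object)))
})

setMethod("show", "Ensemble", function(object) {
  cat(sprintf("Ensemble: %d conformers of %d beads (source: %s)\n",
              nConformers(object), nBeads(object@conformers[[1L]]),
              object@source))
  cat(sprintf("  phi_eff(w | w0) = %.3f\n",
              effectiveFraction(object@weights, object@initialWeights)))
})

setMethod("show", "ScatteringProfile", function(object) {
  cat(sprintf("ScatteringProfile: %d points, q in [%.4g, %.4g] 1/A, %s\n",
              length(object@q), min(object@q), max(object@q),
              if (all(is.na(object@sigma))) "no errors" else "with errors"))
})

setMethod("show", "ReweightResult", function(object) {
  cat("ReweightResult (Bayesian maximum entropy)\n")
  cat(sprintf("  theta = %g, chi2 = %.4g (reduced %.3f), S(w) = %.4f\n",
              object@theta, object@chi2,
              object@chi2 / max(1L, length(object@lambda)), object@entropy))
  cat(sprintf("  phi_eff = %.3f, scale = %.4g, c1 = %.3f, c2 = %.3f\n",
              object@phiEff, object@scale, object@c1, object@c2))
})

setMethod("show", "ContactMap", function(object) {
  cat(sprintf("ContactMap (%s): %d residues, cutoff %.1f A, max P = %.3f\n",
              object@mode, length(object@residues), object@cutoff,
              max(object@probs)))
})

setMethod("show", "ClusterAssignment", function(object) {
  k <- length(object@centers)
  cat(sprintf("ClusterAssignment: %d clusters (cutoff %.1f A)\n",
              k, object@cutoff))
  top <- seq_len(min(6L, k))
  cat(sprintf("  top weights: %s\n",
              paste(sprintf("%.3f", object@clusterWeights[top]),
                    collapse = ", ")))
})

#' Plot a contact-probability map as a heatmap
#'
#' @param x a [ContactMap-class].
#' @param y ignored.
#' @param ... passed to [graphics::image()].
#' @return Invisibly, `x`.
#' @export
setMethod("plot", signature(x = "ContactMap", y = "missing"),
  function(x, y, ...) {
    graphics::image(x@residues, x@residues, x@probs,
                    xlab = "residue", ylab = "residue",
                    main = sprintf("%s-chain contact probability (%.0f A)",
                                   x@mode, x@cutoff), ...)
    invisible(x)
  })
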