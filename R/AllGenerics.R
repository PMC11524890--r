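# Accessor generics for the package's S4 classes.

#' @rdname MolecularGraph-class
#' @param object,x an object of the documented class.
#' @export
setGeneric("nAtoms", function(object) standardGeneric("nAtoms"))

#' @rdname MolecularGraph-class
#' @export
setGeneric("nodeFeatures", function(object) standardGeneric("nodeFeatures"))

#' @rdname MolecularGraph-class
#' @export
setGeneric("edgeMatrix", function(object) standardGeneric("edgeMatrix"))

#' @rdname JointGraph-class
#' @export
setGeneric("provenance", function(object) standardGeneric("provenance"))

#' @rdname JointGraph-class
#' @export
setGeneric("joinMethod", function(object) standardGeneric("joinMethod"))

#' @rdname ExpressionScaler-class
#' @export
setGeneric("genePanel", function(object) standardGeneric("genePanel"))

#' @rdname SplitPlan-class
#' @export
setGeneric("strategy", function(object) standardGeneric("strategy"))

#' @rdname SplitPlan-class
#' @export
setGeneric("nFolds", function(object) standardGeneric("nFolds"))

#' @rdname SplitPlan-class
#' @export
setGeneric("foldAssignments", function(object) standardGeneric("foldAssignments"))

#' @rdname SynergyModel-class
#' @export
setGeneric("modelConfig", function(object) standardGeneric("modelConfig"))

#' @rdname SynergyModel-class
#' @export
setGeneric("modelWeights", function(object) standardGeneric("modelWeights"))

#' @rdname SynergyModel-class
#' @export
setGeneric("trainHistory", function(object) standardGeneric("trainHistory"))

#' @rdname MolecularGraph-class
#' @export
setMethod("nAtoms", "MolecularGraph", function(object) nrow(object@nodeFeatures))

#' @rdname MolecularGraph-class
#' @export
setMethod("nodeFeatures", "MolecularGraph", function(object) object@nodeFeatures)

#' @rdname MolecularGraph-class
#' @export
setMethod("edgeMatrix", "MolecularGraph", function(object) object@edges)

#' @rdname JointGraph-class
#' @export
setMethod("provenance", "JointGraph", function(object) object@provenance)

#' @rdname JointGraph-class
#' @export
setMethod("joinMethod", "JointGraph", function(object) object@method)

#' @rdname SynergyModel-class
#' @export
setMethod("joinMethod", "SynergyModel", function(object) object@joinMethod)

#' @rdname ExpressionScaler-class
#' @export
setMethod("genePanel", "ExpressionScaler", function(object) object@panel)

#' @rdname SynergyModel-class
#' @export
setMethod("genePanel", "SynergyModel", function(object) object@scaler@panel)

#' @rdname SplitPlan-class
#' @export
setMethod("strategy", "SplitPlan", function(object) object@strategy)

#' @rdname SplitPlan-class
#' @export
setMethod("nFolds", "SplitPlan", function(object) object@nFolds)

#' @rdname SplitPlan-class
#' @export
setMethod("foldAssignments", "SplitPlan", function(object) object@fold)

#' @rdname SynergyModel-class
#' @export
setMethod("modelConfig", "SynergyModel", function(object) object@config)

#' @rdname SynergyModel-class
#' @export
setMethod("modelWeights", "SynergyModel", function(object) object@weights)

#' @rdname SynergyModel-class
#' @export
setMethod("trainHistory", "SynergyModel", function(object) object@history)
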