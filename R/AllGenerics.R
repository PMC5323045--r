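# Accessor generics for the NeuronGeometry container.

#' Node table of a geometry
#' @param x a [NeuronGeometry-class]
#' @return data.frame of nodes in topological order
#' @export
setGeneric("nodeTable", function(x) standardGeneric("nodeTable"))

#' @rdname nodeTable
#' @export
setMethod("nodeTable", "NeuronGeometry", function(x) x@nodes)

#' Number of nodes
#' @param x a [NeuronGeometry-class]
#' @export
setGeneric("nNodes", function(x) standardGeneric("nNodes"))

#' @rdname nNodes
#' @export
setMethod("nNodes", "NeuronGeometry", function(x) nrow(x@nodes))

#' Soma (root) node id
#' @param x a [NeuronGeometry-class]
#' @export
setGeneric("somaId", function(x) standardGeneric("somaId"))

#' @rdname somaId
#' @export
setMethod("somaId", "NeuronGeometry", function(x) x@somaId)

#' Tagged axon tip ids
#' @param x a [NeuronGeometry-class]
#' @export
setGeneric("axonTips", function(x) standardGeneric("axonTips"))

#' @rdname axonTips
#' @export
setMethod("axonTips", "NeuronGeometry", function(x) x@axonTips)

#' Neuron label
#' @param x a [NeuronGeometry-class]
#' @export
setGeneric("neuronLabel", function(x) standardGeneric("neuronLabel"))

#' @rdname neuronLabel
#' @export
setMethod("neuronLabel", "NeuronGeometry", function(x) x@label)

#' Cell-type label
#' @param x a [NeuronGeometry-class]
#' @export
setGeneric("cellType", function(x) standardGeneric("cellType"))

#' @rdname cellType
#' @export
setMethod("cellType", "NeuronGeometry", function(x) x@cellType)
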