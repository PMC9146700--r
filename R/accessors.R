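#' Accessors for mitotrio classes
#'
#' Small generics giving read access to the slots of
#' \linkS4class{MitoGenome}, \linkS4class{PairAlignment},
#' \linkS4class{AnchoredMSA} and \linkS4class{TrioLedger}.
#'
#' @param x an object of the relevant class.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("genomeId", function(x) standardGeneric("genomeId"))
#' @rdname accessors
#' @export
setMethod("genomeId", "MitoGenome", function(x) x@id)

#' @rdname accessors
#' @export
setGeneric("genomeSeq", function(x) standardGeneric("genomeSeq"))
#' @rdname accessors
#' @export
setMethod("genomeSeq", "MitoGenome", function(x) x@seq)

#' @rdname accessors
#' @export
setGeneric("genomeLength", function(x) standardGeneric("genomeLength"))
#' @rdname accessors
#' @export
setMethod("genomeLength", "MitoGenome", function(x) nchar(x@seq))

#' @rdname accessors
#' @export
setGeneric("isCircular", function(x) standardGeneric("isCircular"))
#' @rdname accessors
#' @export
setMethod("isCircular", "MitoGenome", function(x) x@circular)

#' @rdname accessors
#' @export
setGeneric("featureTable", function(x) standardGeneric("featureTable"))
#' @rdname accessors
#' @export
setMethod("featureTable", "MitoGenome", function(x) x@features)

#' @rdname accessors
#' @export
setGeneric("alnRows", function(x) standardGeneric("alnRows"))
#' @rdname accessors
#' @export
setMethod("alnRows", "PairAlignment", function(x) setNames(x@rows, x@ids))
#' @rdname accessors
#' @export
setMethod("alnRows", "AnchoredMSA", function(x) setNames(x@rows, x@ids))

#' @rdname accessors
#' @export
setGeneric("alnScore", function(x) standardGeneric("alnScore"))
#' @rdname accessors
#' @export
setMethod("alnScore", "PairAlignment", function(x) x@score)

#' @rdname accessors
#' @export
setGeneric("refId", function(x) standardGeneric("refId"))
#' @rdname accessors
#' @export
setMethod("refId", "AnchoredMSA", function(x) x@refId)

#' @rdname accessors
#' @export
setGeneric("ledgerEvents", function(x) standardGeneric("ledgerEvents"))
#' @rdname accessors
#' @export
setMethod("ledgerEvents", "TrioLedger", function(x) x@events)

#' @rdname accessors
#' @export
setGeneric("ledgerRotations", function(x) standardGeneric("ledgerRotations"))
#' @rdname accessors
#' @export
setMethod("ledgerRotations", "TrioLedger", function(x) x@rotations)

#' @rdname accessors
#' @export
setGeneric("ledgerCodons", function(x) standardGeneric("ledgerCodons"))
#' @rdname accessors
#' @export
setMethod("ledgerCodons", "TrioLedger", function(x) x@codons)
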