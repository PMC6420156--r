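#' Accessor generics
#'
#' Standard accessors for the package's S4 containers.
#'
#' @param object An object of one of the package's S4 classes.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("arena", function(object) standardGeneric("arena"))

#' @rdname accessors
#' @export
setGeneric("arenaRadius", function(object) standardGeneric("arenaRadius"))

#' @rdname accessors
#' @export
setGeneric("frameDuration", function(object) standardGeneric("frameDuration"))

#' @rdname accessors
#' @export
setGeneric("agentPositions", function(object) standardGeneric("agentPositions"))

#' @rdname accessors
#' @export
setGeneric("motionStates", function(object) standardGeneric("motionStates"))

#' @rdname accessors
#' @export
setGeneric("headings", function(object) standardGeneric("headings"))

#' @rdname accessors
#' @export
setGeneric("presentMask", function(object) standardGeneric("presentMask"))

#' @rdname accessors
#' @export
setGeneric("nFrames", function(object) standardGeneric("nFrames"))

#' @rdname accessors
#' @export
setGeneric("nAgents", function(object) standardGeneric("nAgents"))

#' @rdname accessors
#' @export
setGeneric("modelKind", function(object) standardGeneric("modelKind"))

#' @rdname accessors
#' @export
setGeneric("bettiMatrix", function(object) standardGeneric("bettiMatrix"))

#' @rdname accessors
#' @export
setGeneric("epsGrid", function(object) standardGeneric("epsGrid"))

#' @rdname accessors
#' @export
setGeneric("crockerTimes", function(object) standardGeneric("crockerTimes"))

#' @rdname accessors
#' @export
setGeneric("homologyDim", function(object) standardGeneric("homologyDim"))

#' @rdname accessors
#' @export
setGeneric("crockerMode", function(object) standardGeneric("crockerMode"))

#' @rdname accessors
#' @export
setGeneric("verdict", function(object) standardGeneric("verdict"))
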