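#' Construct an arena configuration
#'
#' The reference experiments filmed aphids in a 40 cm-diameter circular arena
#' at 0.5 s per frame; those are the defaults.
#'
#' @param radius Arena radius in metres.
#' @param frameDuration Frame duration in seconds.
#' @return An [ArenaConfig-class] object.
#' @examples
#' arenaConfig()
#' arenaConfig(radius = 0.1)
#' @export
arenaConfig <- function(radius = 0.2, frameDuration = 0.5) {
  new("ArenaConfig", radius = as.numeric(radius),
      frameDuration = as.numeric(frameDuration))
}

#' @rdname accessors
#' @export
setMethod("arenaRadius", "ArenaConfig", function(object) object@radius)

#' @rdname accessors
#' @export
setMethod("frameDuration", "ArenaConfig", function(object)
  object@frameDuration)

setMethod("show", "ArenaConfig", function(object) {
  cat("ArenaConfig: circular arena, radius", object@radius, "m,",
      object@frameDuration, "s/frame\n")
})
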