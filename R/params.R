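#' Fitted aphid model parameters
#'
#' Returns a [ModelParams-class] object carrying the published fitted
#' constants of the stop-start correlated random walk. The defaults are the
#' fits reported for pea aphids walking in a 40 cm arena; individual values
#' can be overridden for sensitivity studies.
#'
#' @param kind `"interactive"` (transition probabilities, step length and
#'   turning spread depend on nearest-neighbour distance) or `"control"`
#'   (all four frozen at their infinite-distance limits; no social
#'   interaction).
#' @param pmsInf,pms0,dMs Moving-to-stopped parameters: limit, zero-distance
#'   value, decay length (m).
#' @param psm0,psmInf,dSm,deltaSm Stopped-to-moving parameters: zero-distance
#'   value, limit, decay length (m), saturation length (m).
#' @param ellInf,ell0,dEll Step-length parameters: limit (m), zero-distance
#'   value (m), transition length (m).
#' @param rhoInf,rho0,dRho Wrapped-Cauchy spread parameters: limit,
#'   zero-distance value, transition length (m).
#' @return A validated [ModelParams-class] object.
#' @examples
#' aphidModelParams()
#' aphidModelParams("control")
#' @export
aphidModelParams <- function(kind = c("interactive", "control"),
                             pmsInf = 0.1280, pms0 = 0.5508, dMs = 0.0134,
                             psm0 = 0.1587, psmInf = 0.3552,
                             dSm = 0.0079, deltaSm = 0.0739,
                             ellInf = 0.0013, ell0 = 0.0003, dEll = 0.0074,
                             rhoInf = 0.9013, rho0 = 0.1387, dRho = 0.0044) {
  kind <- match.arg(kind)
  new("ModelParams",
      pmsInf = pmsInf, pms0 = pms0, dMs = dMs,
      psm0 = psm0, psmInf = psmInf, dSm = dSm, deltaSm = deltaSm,
      ellInf = ellInf, ell0 = ell0, dEll = dEll,
      rhoInf = rhoInf, rho0 = rho0, dRho = dRho,
      kind = kind)
}

#' @rdname accessors
#' @export
setMethod("modelKind", "ModelParams", function(object) object@kind)

setMethod("show", "ModelParams", function(object) {
  cat("ModelParams (", object@kind, " model)\n", sep = "")
  cat(sprintf("  P_MS: %0.4f -> %0.4f, d_MS = %0.4f m\n",
              object@pms0, object@pmsInf, object@dMs))
  cat(sprintf("  P_SM: %0.4f -> %0.4f, d_SM = %0.4f m, Delta_SM = %0.4f m\n",
              object@psm0, object@psmInf, object@dSm, object@deltaSm))
  cat(sprintf("  step: %0.4f -> %0.4f m, d_l = %0.4f m\n",
              object@ell0, object@ellInf, object@dEll))
  cat(sprintf("  rho : %0.4f -> %0.4f, d_rho = %0.4f m\n",
              object@rho0, object@rhoInf, object@dRho))
})

.paramFields <- c("pmsInf", "pms0", "dMs", "psm0", "psmInf", "dSm", "deltaSm",
                  "ellInf", "ell0", "dEll", "rhoInf", "rho0", "dRho")

#' Read and write model parameter files
#'
#' Plain-text `key = value` files mirroring the [ModelParams-class] field
#' names, plus a `kind` line. Unknown keys are rejected; missing keys fall
#' back to the published defaults.
#'
#' @param path File path.
#' @param params A [ModelParams-class] object (for writing).
#' @return `readModelParams` returns a [ModelParams-class];
#'   `writeModelParams` returns `path` invisibly.
#' @export
readModelParams <- function(path) {
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- vapply(kv, length, 1L) != 2L
  if (any(bad))
    stop("malformed parameter line: ", lines[bad][1])
  keys <- trimws(vapply(kv, `[`, "", 1L))
  vals <- trimws(vapply(kv, `[`, "", 2L))
  unknown <- setdiff(keys, c(.paramFields, "kind"))
  if (length(unknown))
    stop("unknown parameter key(s): ", paste(unknown, collapse = ", "))
  args <- list()
  if ("kind" %in% keys) args$kind <- vals[keys == "kind"]
  for (f in intersect(keys, .paramFields))
    args[[f]] <- as.numeric(vals[keys == f])
  do.call(aphidModelParams, args)
}

#' @rdname readModelParams
#' @export
writeModelParams <- function(params, path) {
  stopifnot(is(params, "ModelParams"))
  lines <- c(paste("kind =", params@kind),
             vapply(.paramFields, function(f)
               sprintf("%s = %.17g", f, slot(params, f)), ""))
  writeLines(lines, path)
  invisible(path)
}
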