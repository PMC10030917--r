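#' Accessors for BooleanModel objects
#'
#' @param model a \linkS4class{BooleanModel}.
#' @param node a node name.
#' @name model-accessors
NULL

#' @rdname model-accessors
#' @export
nodeNames <- function(model) model@nodes

#' @rdname model-accessors
#' @export
nNodes <- function(model) length(model@nodes)

#' @rdname model-accessors
#' @export
inputNodes <- function(model) model@inputs

#' @rdname model-accessors
#' @return \code{inputDetection}: how each input was identified
#'   (self-loop, no-rule, or declared).
#' @export
inputDetection <- function(model) model@inputDetection

#' @rdname model-accessors
#' @export
regulatorsOf <- function(model, node) model@regulators[[node]]

#' @rdname model-accessors
#' @export
truthTable <- function(model, node) model@tables[[node]]

#' @rdname model-accessors
#' @export
ruleOf <- function(model, node) model@expressions[[node]]

#' @rdname model-accessors
#' @return \code{nLinks}: the number of regulatory links, identity
#'   self-loops on environmental inputs excluded.
#' @export
nLinks <- function(model) {
  sum(vapply(model@nodes, function(v) {
    if (v %in% model@inputs) 0L else length(model@regulators[[v]])
  }, integer(1)))
}

setMethod("show", "BooleanModel", function(object) {
  cat("BooleanModel '", object@name, "': ", length(object@nodes),
      " nodes, ", nLinks(object), " links, ",
      length(object@inputs), " environmental input(s)\n", sep = "")
  if (length(object@inputs))
    cat("  inputs: ", paste(object@inputs, collapse = ", "), "\n", sep = "")
  nb <- nrow(object@bias$start) + nrow(object@bias$end)
  if (nb) cat("  biased-update rules: ", nb, "\n", sep = "")
})

#' Accessors for Attractor objects
#'
#' @param x an \linkS4class{Attractor}.
#' @name attractor-accessors
NULL

#' @rdname attractor-accessors
#' @export
attractorStates <- function(x) x@states

#' @rdname attractor-accessors
#' @export
attractorContext <- function(x) x@context

#' @rdname attractor-accessors
#' @export
attractorId <- function(x) x@id

#' @rdname attractor-accessors
#' @export
attractorPeriod <- function(x) x@period

#' @rdname attractor-accessors
#' @return \code{isFixedPoint}: TRUE if the attractor has period 1.
#' @export
isFixedPoint <- function(x) x@period == 1L

setMethod("show", "Attractor", function(object) {
  kind <- if (object@period == 1L) "fixed point"
          else paste0("cycle of period ", object@period)
  cat("Attractor (", kind, ")\n", sep = "")
  if (length(object@context))
    cat("  context: ",
        paste(names(object@context), object@context, sep = "=",
              collapse = ", "), "\n", sep = "")
  on <- colnames(object@states)[object@states[1, ] == 1L]
  cat("  ON in first state: ",
      if (length(on)) paste(on, collapse = ", ") else "(none)", "\n",
      sep = "")
})

#' Accessors for SamplingReport objects
#'
#' @param report a \linkS4class{SamplingReport}.
#' @name report-accessors
NULL

#' @rdname report-accessors
#' @export
attractors <- function(report) report@attractors

#' @rdname report-accessors
#' @return \code{convergenceHeatmap}: per-run attractor counts over the
#'   sampling grid.
#' @export
convergenceHeatmap <- function(report) report@grid

#' @rdname report-accessors
#' @export
samplingParams <- function(report) report@params

setMethod("show", "SamplingReport", function(object) {
  cat("SamplingReport: ", length(object@attractors),
      " attractor(s) over ", nrow(object@grid), " sampling run(s)\n",
      sep = "")
  per <- table(vapply(object@attractors, function(a) a@period, integer(1)))
  if (length(per))
    cat("  periods: ",
        paste(names(per), per, sep = "x", collapse = ", "), "\n", sep = "")
})

#' Tabulate attractors
#'
#' One column per attractor and one row per node, plus context and period
#' rows -- the layout used for exported attractor tables.
#'
#' @param attractors a list of \linkS4class{Attractor} objects or a
#'   \linkS4class{SamplingReport}.
#' @param path optional CSV path; provenance comments are prepended when
#'   \code{model} is supplied.
#' @param model optional model used to tag the file with its content hash.
#' @param seed optional seed recorded in the provenance header.
#' @return a data.frame, invisibly when \code{path} is given.
#' @export
attractorTable <- function(attractors, path = NULL, model = NULL,
                           seed = NULL) {
  if (is(attractors, "SamplingReport")) attractors <- attractors@attractors
  if (!length(attractors)) stop("no attractors to tabulate")
  nodes <- colnames(attractors[[1]]@states)
  cols <- lapply(attractors, function(a) {
    c(a@states[1, nodes], period = a@period)
  })
  df <- as.data.frame(cols)
  names(df) <- paste0("A", seq_along(attractors))
  ctx <- vapply(attractors, function(a)
    paste(names(a@context), a@context, sep = "=", collapse = ";"),
    character(1))
  df <- rbind(df, context = ctx)
  df <- cbind(row = c(nodes, "period", "context"), df)
  if (!is.null(path)) {
    con <- file(path, "w")
    on.exit(close(con))
    if (!is.null(model))
      writeLines(sprintf("# model_hash=%s", modelHash(model)), con)
    if (!is.null(seed)) writeLines(sprintf("# seed=%s", seed), con)
    write.csv(df, con, row.names = FALSE)
    return(invisible(df))
  }
  df
}
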