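#' BooleanModel: a Boolean regulatory network
#'
#' Ordered nodes, per-node regulators (declaration order), the original
#' rule expressions, compiled truth tables, the set of environmental input
#' nodes, and an optional biased-asynchronous update specification.
#'
#' Truth tables are indexed so that the combination index is the binary
#' number with the \emph{first} regulator as the most significant bit;
#' tables are therefore reproducible across runs and serializations.
#' Environmental inputs are nodes whose only regulator is themselves with
#' identity logic, or nodes referenced as regulators without a rule of
#' their own; their state is held fixed by the environment context during
#' dynamics.
#'
#' @slot name model name.
#' @slot nodes ordered character vector of node names.
#' @slot regulators named list; per-node regulator names in declaration
#'   order.
#' @slot expressions named character vector of rule expressions in the
#'   \code{and/or/not} dialect.
#' @slot tables named list of integer truth tables (length \code{2^k}).
#' @slot inputs character vector of environmental input nodes.
#' @slot inputDetection named character vector recording how each input
#'   was identified (\code{"self-loop"}, \code{"no-rule"} or
#'   \code{"declared"}).
#' @slot bias an update-bias specification as built by
#'   \code{\link{updateBias}} (possibly empty).
#'
#' @seealso \code{\link{parseBooleanNet}}, \code{\link{syncStep}},
#'   \code{\link{sampleAttractors}}
#' @export
setClass("BooleanModel",
  representation(
    name = "character",
    nodes = "character",
    regulators = "list",
    expressions = "character",
    tables = "list",
    inputs = "character",
    inputDetection = "character",
    bias = "list"
  )
)

setValidity("BooleanModel", function(object) {
  msg <- character(0)
  nd <- object@nodes
  if (anyDuplicated(nd)) msg <- c(msg, "node names must be unique")
  if (!identical(sort(names(object@regulators)), sort(nd)) ||
      !identical(sort(names(object@tables)), sort(nd)))
    msg <- c(msg, "regulators and tables must be named by node")
  for (v in nd) {
    regs <- object@regulators[[v]]
    if (length(regs) && !all(regs %in% nd))
      msg <- c(msg, sprintf("node '%s' has undeclared regulator(s): %s", v,
                            paste(setdiff(regs, nd), collapse = ", ")))
    if (length(object@tables[[v]]) != 2^length(regs))
      msg <- c(msg, sprintf("truth table of '%s' must have 2^k entries", v))
    if (!all(object@tables[[v]] %in% c(0L, 1L)))
      msg <- c(msg, sprintf("truth table of '%s' must be 0/1", v))
  }
  if (!all(object@inputs %in% nd))
    msg <- c(msg, "inputs must be declared nodes")
  for (v in object@inputs) {
    regs <- object@regulators[[v]]
    if (!(length(regs) == 0L ||
          (length(regs) == 1L && regs == v &&
           identical(object@tables[[v]], c(0L, 1L)))))
      msg <- c(msg, sprintf(
        "input '%s' must have no regulators or only itself with identity logic", v))
  }
  for (side in c("start", "end")) {
    b <- object@bias[[side]]
    if (!is.null(b) && nrow(b)) {
      if (anyDuplicated(b$node))
        msg <- c(msg, sprintf("a node appears twice in the %s bias list", side))
      if (!all(b$node %in% nd))
        msg <- c(msg, sprintf("%s bias list names unknown node(s)", side))
    }
  }
  if (length(msg)) msg else TRUE
})

#' Attractor: a canonicalized fixed point or cycle
#'
#' The state cycle of a synchronous attractor within a fixed environment
#' context.  States are stored as a \code{period x n} 0/1 matrix with one
#' row per cycle state; \code{syncStep} maps row \code{i} to row
#' \code{i + 1} (mod period).  The identifier is content-addressed: it is a
#' pure function of the state cycle (lexicographically minimal rotation
#' anchored at the minimal state) and the context, so the same attractor
#' found twice collides, and identifiers are stable across independent
#' sampling runs.
#'
#' @slot states integer matrix, \code{period x n}, columns named by node.
#' @slot context named integer vector fixing the environmental inputs.
#' @slot id stable content-addressed identifier.
#' @slot period cycle length (1 for a fixed point).
#' @export
setClass("Attractor",
  representation(
    states = "matrix",
    context = "integer",
    id = "character",
    period = "integer"
  )
)

setValidity("Attractor", function(object) {
  if (nrow(object@states) != object@period)
    return("period must equal the number of cycle states")
  if (!all(object@states %in% c(0L, 1L)))
    return("states must be 0/1")
  TRUE
})

#' SamplingReport: result of an attractor-sampling campaign
#'
#' @slot attractors list of \linkS4class{Attractor} objects (union over
#'   all runs and contexts, deduplicated by canonical id).
#' @slot grid data.frame with one row per sampling run: \code{nRnd},
#'   \code{nSeries} and the number of attractors that run found
#'   (the convergence heatmap).
#' @slot params list of sampling parameters (pNoise, clamps, seed, ...).
#' @export
setClass("SamplingReport",
  representation(
    attractors = "list",
    grid = "data.frame",
    params = "list"
  )
)
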