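#' Update-order bias for asynchronous dynamics
#'
#' Random-order asynchronous update can generate biologically impossible
#' event sequences in cell-cycle logic (e.g., cytokinesis before anaphase).
#' A bias forces a small, condition-dependent list of nodes to the start
#' or end of each step's otherwise random update order.  Conditions are
#' evaluated on the state at the start of the step: \code{IF_ON} places
#' the node only when it is currently ON, \code{IF_OFF} only when OFF,
#' \code{ALWAYS} unconditionally.  Start-listed nodes go first in listed
#' order; end-listed nodes go last with the \emph{first} listed updated
#' \emph{last}.  A node selected by both lists in the same step is placed
#' by its start rule (a warning is issued here if the two rules can ever
#' be satisfied together).
#'
#' @param start,end data.frames with columns \code{node} and
#'   \code{condition} (one of \code{"IF_ON"}, \code{"IF_OFF"},
#'   \code{"ALWAYS"}), or \code{NULL}.
#' @return a bias specification for \code{\link{biasedAsyncStep}} and the
#'   trajectory drivers.
#' @export
updateBias <- function(start = NULL, end = NULL) {
  norm <- function(x) {
    if (is.null(x) || !nrow(x))
      return(data.frame(node = character(0), condition = character(0),
                        stringsAsFactors = FALSE))
    stopifnot(all(c("node", "condition") %in% names(x)))
    if (!all(x$condition %in% c("IF_ON", "IF_OFF", "ALWAYS")))
      stop("bias conditions must be IF_ON, IF_OFF or ALWAYS")
    if (anyDuplicated(x$node))
      stop("a node may appear at most once per bias list")
    x[, c("node", "condition")]
  }
  s <- norm(start); e <- norm(end)
  both <- intersect(s$node, e$node)
  for (v in both) {
    cs <- s$condition[s$node == v]; ce <- e$condition[e$node == v]
    compatible <- cs == "ALWAYS" || ce == "ALWAYS" || cs == ce
    if (compatible)
      warning("node '", v, "' can be selected by both start and end rules ",
              "in the same step; the start rule takes precedence")
  }
  list(start = s, end = e)
}

emptyBias <- function() updateBias()

#' Attach an update bias to a model
#'
#' @param model a \linkS4class{BooleanModel}.
#' @param bias an \code{\link{updateBias}} specification.
#' @return the model with the bias attached (used by default in biased
#'   asynchronous runs).
#' @export
setUpdateBias <- function(model, bias) {
  bad <- setdiff(c(bias$start$node, bias$end$node), model@nodes)
  if (length(bad))
    stop("bias references node(s) not in the model: ",
         paste(bad, collapse = ", "))
  model@bias <- bias
  validObject(model)
  model
}

.biasArrays <- function(model, bias = NULL) {
  if (is.null(bias)) bias <- model@bias
  idx <- setNames(seq_along(model@nodes) - 1L, model@nodes)
  condCode <- c(IF_OFF = 0L, IF_ON = 1L, ALWAYS = 2L)
  list(startIdx = unname(idx[bias$start$node]),
       startCond = unname(condCode[bias$start$condition]),
       endIdx = unname(idx[bias$end$node]),
       endCond = unname(condCode[bias$end$condition]))
}

#' One deterministic synchronous step
#'
#' Every non-input node is set to its gate output evaluated on the
#' previous state; environmental inputs are copied from the context (or
#' carried over unchanged when no context is given).
#'
#' @param model a \linkS4class{BooleanModel}.
#' @param state a complete named 0/1 state.
#' @param context optional named 0/1 vector over input nodes.
#' @return the successor state.
#' @export
syncStep <- function(model, state, context = NULL) {
  s <- .applyContext(model, .fullState(model, state), context)
  syncStepC(.coreList(model), s)
}

#' One noisy synchronous step
#'
#' A synchronous step after which every non-input node is independently
#' flipped with probability \code{pNoise} (the incorrect gate output);
#' inputs are never flipped.  \code{pNoise = 0} reduces exactly to
#' \code{\link{syncStep}}.
#'
#' @inheritParams syncStep
#' @param pNoise per-node flip probability in \code{[0, 1]}; the sampling
#'   default used throughout is 0.02.
#' @export
noisySyncStep <- function(model, state, context = NULL, pNoise = 0.02) {
  stopifnot(pNoise >= 0, pNoise <= 1)
  s <- syncStep(model, state, context)
  if (pNoise > 0) {
    free <- setdiff(model@nodes, model@inputs)
    flip <- free[runif(length(free)) < pNoise]
    s[flip] <- 1L - s[flip]
  }
  s
}

#' One (biased) random-order asynchronous step
#'
#' Builds an update order for the step -- bias-selected nodes first/last,
#' all remaining non-input nodes in uniformly random order in between --
#' then updates nodes sequentially, each seeing all earlier updates within
#' the step.  With an empty bias this is plain random-order asynchronous
#' update.  Fixed points of the synchronous map are invariant under this
#' step for every order.
#'
#' @inheritParams syncStep
#' @param bias an \code{\link{updateBias}}; defaults to the model's own.
#' @export
biasedAsyncStep <- function(model, state, context = NULL, bias = NULL) {
  s <- .applyContext(model, .fullState(model, state), context)
  b <- .biasArrays(model, bias)
  asyncStepC(.coreList(model), s, b$startIdx, b$startCond, b$endIdx,
             b$endCond)
}

#' @rdname biasedAsyncStep
#' @export
asyncStep <- function(model, state, context = NULL) {
  biasedAsyncStep(model, state, context, bias = emptyBias())
}

#' Run a trajectory under any engine
#'
#' Shared driver for all experiments.  The input schedule (see
#' \code{\link{inputSchedule}}) supplies the environment at every step;
#' knockdown/overexpression overrides (see \code{\link{kdoeSpec}}) are
#' applied after the engine update each step, so an override wins within
#' its step.  Given the same engine, seed and schedule the trajectory is
#' bitwise reproducible.
#'
#' @param model a \linkS4class{BooleanModel}.
#' @param init complete named initial state.
#' @param nSteps number of update steps.
#' @param engine one of \code{"sync"}, \code{"noisy"}, \code{"async"},
#'   \code{"biased-async"}.
#' @param schedule an \code{\link{inputSchedule}} or \code{NULL} (inputs
#'   held at their initial values).
#' @param kdoe a \code{\link{kdoeSpec}} or \code{NULL}.
#' @param pNoise flip probability for the \code{"noisy"} engine.
#' @param bias update bias for \code{"biased-async"}; defaults to the
#'   model's own.
#' @param stopSignature optional named 0/1 vector; the run stops at the
#'   first state matching it (used for apoptosis-terminated runs).
#' @return a list with \code{states} (a \code{(steps+1) x n} 0/1 matrix,
#'   columns named by node; row 1 is the initial state), \code{stopped}
#'   and \code{stoppedAt}.
#' @export
runTrajectory <- function(model, init, nSteps,
                          engine = c("sync", "noisy", "async",
                                     "biased-async"),
                          schedule = NULL, kdoe = NULL, pNoise = 0.02,
                          bias = NULL, stopSignature = NULL) {
  engine <- match.arg(engine)
  s0 <- .fullState(model, init)
  idx <- setNames(seq_along(model@nodes) - 1L, model@nodes)

  if (is.null(schedule)) {
    inputIdx <- integer(0)
    probMat <- matrix(numeric(0), nrow = nSteps, ncol = 0)
  } else {
    pm <- scheduleMatrix(schedule, model, nSteps)
    inputIdx <- unname(idx[colnames(pm)])
    probMat <- pm
  }
  if (is.null(kdoe) || !nrow(kdoe)) {
    kdIdx <- integer(0); kdBit <- integer(0); kdProb <- numeric(0)
  } else {
    .checkKdoe(model, kdoe)
    kdIdx <- unname(idx[kdoe$node])
    kdBit <- ifelse(kdoe$mode == "OE", 1L, 0L)
    kdProb <- kdoe$prob
  }
  if (is.null(stopSignature)) {
    stopIdx <- integer(0); stopBit <- integer(0)
  } else {
    stopIdx <- unname(idx[names(stopSignature)])
    stopBit <- as.integer(stopSignature)
  }
  engCode <- switch(engine, sync = 0L, noisy = 0L, async = 1L,
                    `biased-async` = 2L)
  p <- if (engine == "noisy") pNoise else 0
  b <- .biasArrays(model, bias)
  res <- runCourseC(.coreList(model), s0, as.integer(nSteps), inputIdx,
                    probMat, kdIdx, kdBit, kdProb, p, engCode,
                    b$startIdx, b$startCond, b$endIdx, b$endCond,
                    stopIdx, stopBit)
  colnames(res$states) <- model@nodes
  res
}
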