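#' Partition the state space by environment
#'
#' Every unique assignment of the environmental input nodes defines a
#' context within which dynamics holds the inputs fixed.  Clamping a
#' subset of inputs restricts the enumeration (e.g. locking a death
#' ligand OFF halves the input space).
#'
#' @param model a \linkS4class{BooleanModel}.
#' @param clamps named 0/1 vector over input nodes to hold fixed, or
#'   \code{NULL}.
#' @return a list of named integer vectors, one per context, covering all
#'   \code{2^f} assignments of the unclamped inputs (first input = most
#'   significant bit).
#' @export
partitionEnvironments <- function(model, clamps = NULL) {
  inputs <- model@inputs
  if (!is.null(clamps)) {
    bad <- setdiff(names(clamps), inputs)
    if (length(bad))
      stop("clamp on non-input node(s): ", paste(bad, collapse = ", "))
  }
  free <- setdiff(inputs, names(clamps))
  base <- setNames(integer(length(inputs)), inputs)
  if (!is.null(clamps)) base[names(clamps)] <- as.integer(clamps)
  f <- length(free)
  if (f == 0L) return(list(base))
  lapply(seq_len(2^f) - 1L, function(code) {
    bits <- as.integer(intToBits(code))[f:1]
    ctx <- base
    ctx[free] <- bits
    ctx
  })
}

# canonical form: rotate the cycle so the lexicographically minimal state
# comes first; among ties, pick the rotation with minimal concatenation
.canonicalAttractor <- function(states, context, model) {
  states <- matrix(as.integer(states), nrow = nrow(states),
                   dimnames = list(NULL, model@nodes))
  p <- nrow(states)
  enc <- apply(states, 1L, .bitString)
  minIdx <- which(enc == min(enc))
  best <- NULL; bestKey <- NULL
  for (i in minIdx) {
    rot <- c(i:p, if (i > 1) 1:(i - 1))
    key <- paste(enc[rot], collapse = "|")
    if (is.null(bestKey) || key < bestKey) {
      bestKey <- key; best <- rot
    }
  }
  ctx <- setNames(as.integer(context), names(context))
  id <- paste0("ctx[", paste(names(ctx), ctx, sep = "=", collapse = ","),
               "]|", bestKey)
  new("Attractor", states = states[best, , drop = FALSE], context = ctx,
      id = id, period = p)
}

#' Descend deterministically to an attractor
#'
#' Iterates the synchronous map with hash-based cycle detection until a
#' state repeats, then returns the cycle as a canonical
#' \linkS4class{Attractor} -- the attractor basin the given state falls
#' into if dynamics continues deterministically.
#'
#' @param model a \linkS4class{BooleanModel}.
#' @param state a complete named state.
#' @param context optional named 0/1 input assignment (defaults to the
#'   input values in \code{state}).
#' @param maxSteps step budget before signaling a pathological instance.
#' @export
descendToAttractor <- function(model, state, context = NULL,
                               maxSteps = 1e6) {
  s <- .applyContext(model, .fullState(model, state), context)
  cyc <- descendC(.coreList(model), s, maxSteps)
  .canonicalAttractor(cyc, s[model@inputs], model)
}

#' Exhaustively enumerate synchronous attractors
#'
#' Descends from every state of each environment context's subspace and
#' returns the complete deduplicated attractor list.  Intended as the
#' ground-truth oracle for the sampler on small models; refuses subspaces
#' with more than \code{cap} free (non-input) nodes.
#'
#' @param model a \linkS4class{BooleanModel}.
#' @param context a single named input assignment, or \code{NULL} to
#'   enumerate every context compatible with \code{clamps}.
#' @param clamps named 0/1 vector over inputs, as in
#'   \code{\link{partitionEnvironments}}.
#' @param cap maximum number of non-input nodes (default 22).
#' @return a list of \linkS4class{Attractor} objects.
#' @export
enumerateAttractors <- function(model, context = NULL, clamps = NULL,
                                cap = 22L) {
  free <- setdiff(model@nodes, model@inputs)
  if (length(free) > cap)
    stop(length(free), " non-input nodes exceed the enumeration cap (",
         cap, ")")
  contexts <- if (is.null(context)) partitionEnvironments(model, clamps)
              else list(setNames(as.integer(context), names(context)))
  core <- .coreList(model)
  idx <- setNames(seq_along(model@nodes) - 1L, model@nodes)
  out <- list()
  for (ctx in contexts) {
    tmpl <- setNames(integer(nNodes(model)), model@nodes)
    tmpl <- .applyContext(model, tmpl, ctx)
    mats <- enumerateC(core, tmpl, unname(idx[free]))
    for (m in mats) {
      a <- .canonicalAttractor(m, ctx, model)
      out[[a@id]] <- a
    }
  }
  unname(out[order(names(out))])
}

#' Sample attractors by noisy state-space exploration
#'
#' For each environment context compatible with the clamps, runs
#' \code{nRnd} noisy synchronous trajectories of \code{nSeries} steps from
#' uniform random initial states; at every visited state (the initial one
#' included) descends deterministically to the attractor of its basin,
#' and, when \code{scanNeighbors} is on, also from every state reachable
#' by a single non-input-node flip -- which reaches basins the noisy
#' trajectory itself never enters.  Attractors are canonicalized, so
#' repeated finds collide, and collated across contexts.
#'
#' @param model a \linkS4class{BooleanModel}.
#' @param clamps named 0/1 vector over inputs held fixed.
#' @param nRnd random restarts per context (default 200).
#' @param nSeries noisy steps per restart (default 5).
#' @param pNoise per-step flip probability (default 0.02).
#' @param scanNeighbors scan single-flip neighborhoods (default TRUE).
#' @param maxSteps descent budget.
#' @param seed optional seed (otherwise the current RNG stream is used).
#' @return a \linkS4class{SamplingReport}.
#' @export
sampleAttractors <- function(model, clamps = NULL, nRnd = 200L,
                             nSeries = 5L, pNoise = 0.02,
                             scanNeighbors = TRUE, maxSteps = 1e6,
                             seed = NULL) {
  stopifnot(nRnd >= 1L, nSeries >= 0L)
  if (!is.null(seed)) set.seed(seed)
  contexts <- partitionEnvironments(model, clamps)
  core <- .coreList(model)
  found <- list()
  for (ctx in contexts) {
    tmpl <- setNames(integer(nNodes(model)), model@nodes)
    tmpl <- .applyContext(model, tmpl, ctx)
    mats <- sampleContextC(core, tmpl, as.integer(nRnd),
                           as.integer(nSeries), pNoise, scanNeighbors,
                           maxSteps)
    for (m in mats) {
      a <- .canonicalAttractor(m, ctx, model)
      found[[a@id]] <- a
    }
  }
  atts <- unname(found[order(names(found))])
  new("SamplingReport", attractors = atts,
      grid = data.frame(nRnd = nRnd, nSeries = nSeries,
                        nFound = length(atts)),
      params = list(pNoise = pNoise, clamps = clamps,
                    scanNeighbors = scanNeighbors, seed = seed))
}

#' Convergence grid of sampling runs
#'
#' Re-runs the sampler over a grid of \code{(nRnd, nSeries)} values --
#' the default emulates a 15 x 15 grid in steps of 5, i.e. values 5, 10,
#' ..., 75 -- recording the per-run attractor count (a convergence
#' heatmap) and the union attractor table.
#'
#' @param model a \linkS4class{BooleanModel}.
#' @param clamps named clamps over inputs.
#' @param nRow,nCol grid dimensions.
#' @param step grid spacing (cell (i, j) uses nRnd = i*step,
#'   nSeries = j*step).
#' @param pNoise noise level for every run.
#' @param scanNeighbors passed to \code{\link{sampleAttractors}}.
#' @param seed optional seed.
#' @return a \linkS4class{SamplingReport} whose \code{grid} has one row
#'   per cell.
#' @export
convergenceGrid <- function(model, clamps = NULL, nRow = 15L, nCol = 15L,
                            step = 5L, pNoise = 0.02,
                            scanNeighbors = TRUE, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  union <- list(); rows <- list()
  for (i in seq_len(nRow)) {
    for (j in seq_len(nCol)) {
      rep <- sampleAttractors(model, clamps, nRnd = i * step,
                              nSeries = j * step, pNoise = pNoise,
                              scanNeighbors = scanNeighbors)
      for (a in rep@attractors) union[[a@id]] <- a
      rows[[length(rows) + 1L]] <-
        data.frame(nRnd = i * step, nSeries = j * step,
                   nFound = length(rep@attractors))
    }
  }
  new("SamplingReport", attractors = unname(union[order(names(union))]),
      grid = do.call(rbind, rows),
      params = list(pNoise = pNoise, clamps = clamps, step = step,
                    seed = seed))
}

#' Map attractor transitions under single environment flips
#'
#' From each (non-apoptotic) attractor, flips each unclamped environmental
#' input one at a time and descends in the new context, recording the
#' attractor reached.  Targets absent from the supplied table are flagged
#' as newly discovered and appended -- an efficient way to find small live
#' basins the noisy sampler missed.
#'
#' @param model a \linkS4class{BooleanModel}.
#' @param attractors a list of \linkS4class{Attractor}s or a
#'   \linkS4class{SamplingReport}.
#' @param clamps clamped inputs excluded from flipping.
#' @param excludeSignature optional phenotype signature (named bits);
#'   attractors whose first state matches it (e.g. apoptotic ones) are not
#'   used as transition sources.
#' @return a list with \code{transitions} (data.frame: from, input, to,
#'   newlyDiscovered) and the augmented \code{attractors} list.
#' @export
environmentTransitionMap <- function(model, attractors, clamps = NULL,
                                     excludeSignature = NULL) {
  if (is(attractors, "SamplingReport")) attractors <- attractors@attractors
  known <- setNames(attractors,
                    vapply(attractors, function(a) a@id, character(1)))
  flippable <- setdiff(model@inputs, names(clamps))
  rows <- list()
  queue <- attractors
  while (length(queue)) {
    a <- queue[[1]]; queue <- queue[-1]
    if (!is.null(excludeSignature)) {
      st <- a@states[1, ]
      if (all(st[names(excludeSignature)] == excludeSignature)) next
    }
    for (v in flippable) {
      ctx <- a@context
      ctx[v] <- 1L - ctx[v]
      s <- setNames(a@states[1, ], colnames(a@states))
      tgt <- descendToAttractor(model, s, context = ctx)
      fresh <- !(tgt@id %in% names(known))
      if (fresh) {
        known[[tgt@id]] <- tgt
        queue[[length(queue) + 1L]] <- tgt
      }
      rows[[length(rows) + 1L]] <-
        data.frame(from = a@id, input = v, to = tgt@id,
                   newlyDiscovered = fresh)
    }
  }
  list(transitions = do.call(rbind, rows),
       attractors = unname(known[order(names(known))]))
}
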