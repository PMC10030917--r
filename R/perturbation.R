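#' Environmental input schedules
#'
#' Per-input specification of the environment over a run.  Each named
#' argument is one of
#' \itemize{
#'   \item a single number in \code{[0, 1]}: the per-step ON-probability
#'     (0 and 1 are constants; values in between model non-saturating
#'     inputs, drawn i.i.d. each step);
#'   \item \code{pulse(base, tOn, duration)}: baseline bit \code{base},
#'     flipped during steps \code{[tOn, tOn + duration)};
#'   \item a numeric vector of per-step probabilities.
#' }
#'
#' @param ... named per-input specifications.
#' @return an object of class \code{inputSchedule}.
#' @examples
#' inputSchedule(Stiff_ECM = pulse(0, 50, 100), GF_High = 0.95)
#' @export
inputSchedule <- function(...) {
  spec <- list(...)
  if (length(spec) && (is.null(names(spec)) || any(!nzchar(names(spec)))))
    stop("every schedule entry must be named by an input node")
  structure(spec, class = "inputSchedule")
}

#' @rdname inputSchedule
#' @param base baseline bit (0 or 1).
#' @param tOn first flipped step (1-based).
#' @param duration number of flipped steps.
#' @export
pulse <- function(base, tOn, duration) {
  stopifnot(base %in% c(0, 1), tOn >= 1, duration >= 0)
  structure(list(base = as.integer(base), tOn = as.integer(tOn),
                 duration = as.integer(duration)), class = "inputPulse")
}

# expand a schedule into an (nSteps x inputs) ON-probability matrix
scheduleMatrix <- function(schedule, model, nSteps) {
  stopifnot(inherits(schedule, "inputSchedule"))
  bad <- setdiff(names(schedule), model@inputs)
  if (length(bad))
    stop("schedule names non-input node(s): ", paste(bad, collapse = ", "))
  cols <- lapply(names(schedule), function(v) {
    s <- schedule[[v]]
    if (inherits(s, "inputPulse")) {
      if (s$tOn + s$duration - 1L > nSteps)
        stop("pulse window for '", v, "' exceeds the run length")
      out <- rep(as.numeric(s$base), nSteps)
      if (s$duration > 0)
        out[seq(s$tOn, s$tOn + s$duration - 1L)] <- 1 - s$base
      out
    } else {
      s <- as.numeric(s)
      if (any(s < 0 | s > 1)) stop("ON-probabilities must be in [0, 1]")
      if (length(s) == 1L) rep(s, nSteps)
      else if (length(s) == nSteps) s
      else stop("per-step probability vector for '", v,
                "' must have length nSteps")
    }
  })
  m <- do.call(cbind, cols)
  colnames(m) <- names(schedule)
  m
}

#' Knockdown / overexpression specification
#'
#' Partial knockdown (KD) forces a node OFF with a set probability in each
#' time-step; overexpression (OE) forces it ON.  In steps where the node
#' is not forced it obeys its Boolean rule.  Probability 1 is a permanent
#' lock; probability 0 is wild type.
#'
#' @param node target node names.
#' @param mode \code{"KD"} or \code{"OE"}, recycled.
#' @param prob per-step override probability in \code{[0, 1]}, recycled.
#' @return a data.frame with class \code{kdoeSpec}.
#' @export
kdoeSpec <- function(node, mode, prob = 1) {
  df <- data.frame(node = node, mode = mode, prob = prob,
                   stringsAsFactors = FALSE)
  if (!all(df$mode %in% c("KD", "OE")))
    stop("mode must be 'KD' or 'OE'")
  if (any(df$prob < 0 | df$prob > 1))
    stop("override probabilities must be in [0, 1]")
  dup <- df$node[duplicated(df$node)]
  if (length(dup))
    stop("KD and OE requested on the same node: ",
         paste(unique(dup), collapse = ", "))
  class(df) <- c("kdoeSpec", "data.frame")
  df
}

.checkKdoe <- function(model, kdoe) {
  bad <- setdiff(kdoe$node, model@nodes)
  if (length(bad))
    stop("KD/OE targets unknown node(s): ", paste(bad, collapse = ", "))
  inp <- intersect(kdoe$node, model@inputs)
  if (length(inp))
    stop("KD/OE targets must be non-input nodes (use a schedule for ",
         "inputs): ", paste(inp, collapse = ", "))
  invisible(TRUE)
}

#' Apply a schedule / overrides to a single state
#'
#' Single-step building blocks of the trajectory driver, exposed for
#' inspection and testing: \code{applyInputs} draws the environmental
#' inputs for step \code{t}; \code{applyKdoe} applies KD/OE overrides to a
#' post-update state.
#'
#' @param model a \linkS4class{BooleanModel}.
#' @param state a complete named state.
#' @param schedule an \code{\link{inputSchedule}}.
#' @param t the step (1-based).
#' @param nSteps run length the schedule is expanded over.
#' @export
applyInputs <- function(model, state, schedule, t, nSteps = t) {
  s <- .fullState(model, state)
  pm <- scheduleMatrix(schedule, model, nSteps)
  for (v in colnames(pm)) {
    p <- pm[t, v]
    s[v] <- if (p >= 1) 1L else if (p <= 0) 0L
            else as.integer(runif(1) < p)
  }
  s
}

#' @rdname applyInputs
#' @param kdoe a \code{\link{kdoeSpec}}.
#' @export
applyKdoe <- function(model, state, kdoe) {
  .checkKdoe(model, kdoe)
  s <- .fullState(model, state)
  for (i in seq_len(nrow(kdoe))) {
    if (kdoe$prob[i] >= 1 || runif(1) < kdoe$prob[i])
      s[kdoe$node[i]] <- if (kdoe$mode[i] == "OE") 1L else 0L
  }
  s
}

#' Reversible environmental pulse experiment
#'
#' The standard virtual-experiment timeline: the model sits in its initial
#' attractor for 50 baseline steps, one environmental input is flipped
#' for \code{duration} steps, then restored, and the run continues to 400
#' total steps.
#'
#' @param model a \linkS4class{BooleanModel}.
#' @param init initial state, typically the first state of an attractor
#'   (an \linkS4class{Attractor} is also accepted).
#' @param pulsedInput name of the environmental input to flip.
#' @param duration pulse length in steps (at most
#'   \code{totalSteps - baselineSteps}).
#' @param engine update engine, as in \code{\link{runTrajectory}}.
#' @param baselineSteps,totalSteps timeline constants (50 and 400).
#' @param ... passed to \code{\link{runTrajectory}} (e.g. \code{bias}).
#' @return a list with \code{states}, the flipped \code{input} track, the
#'   \code{timeline} (baseline/pulse/recovery step ranges) and a
#'   node-by-step \code{heatmapTable} for figure-style panels.
#' @export
pulseExperiment <- function(model, init, pulsedInput, duration,
                            engine = "sync", baselineSteps = 50L,
                            totalSteps = 400L, ...) {
  if (is(init, "Attractor")) {
    ctx <- init@context
    init <- setNames(init@states[1, ], colnames(init@states))
    init[names(ctx)] <- ctx
  }
  if (!pulsedInput %in% model@inputs)
    stop("'", pulsedInput, "' is not an environmental input")
  if (duration > totalSteps - baselineSteps)
    stop("pulse duration exceeds ", totalSteps - baselineSteps, " steps")
  s0 <- .fullState(model, init)
  sched <- inputSchedule()
  sched[[pulsedInput]] <- pulse(s0[[pulsedInput]], baselineSteps + 1L,
                                duration)
  class(sched) <- "inputSchedule"
  res <- runTrajectory(model, s0, nSteps = totalSteps, engine = engine,
                       schedule = sched, ...)
  ht <- t(res$states)
  colnames(ht) <- paste0("t", seq_len(ncol(ht)) - 1L)
  list(states = res$states,
       input = res$states[, pulsedInput],
       timeline = list(baseline = seq_len(baselineSteps + 1L),
                       pulse = if (duration > 0)
                         baselineSteps + 1L + seq_len(duration)
                       else integer(0),
                       recovery = if (baselineSteps + duration < totalSteps)
                         seq(baselineSteps + duration + 2L, totalSteps + 1L)
                       else integer(0)),
       heatmapTable = ht)
}

#' Scan phenotype statistics over one environmental input
#'
#' Runs \code{\link{runPhenotypeStatistics}} at a grid of ON-probability
#' levels for one scanned input, holding all other inputs at their base
#' probabilities; optionally crossed with a knockdown/overexpression
#' probability axis.
#'
#' @param model a \linkS4class{BooleanModel}.
#' @param init initial state or \linkS4class{Attractor}.
#' @param scannedInput the input whose ON-probability is scanned.
#' @param baseProbs named numeric vector of ON-probabilities for the other
#'   inputs (a base probability given for the scanned input is ignored
#'   with a warning).
#' @param levels ON-probability grid (default 0 to 1 in steps of 0.1).
#' @param kdoe optional \code{\link{kdoeSpec}}; if \code{kdLevels} is
#'   given, its probability is scanned too, producing the grid layout.
#' @param kdLevels optional KD/OE probability grid.
#' @param signatures,detectors,apoptosisSignature,tMinLive,engine,normalization
#'   passed to \code{\link{runPhenotypeStatistics}}.
#' @return a tidy data.frame: one row per (level, kdLevel, metric).
#' @export
scanEnvironment <- function(model, init, scannedInput, baseProbs,
                            levels = seq(0, 1, by = 0.1), kdoe = NULL,
                            kdLevels = NULL, signatures = NULL,
                            detectors = NULL, apoptosisSignature = NULL,
                            tMinLive = 1000L, engine = "sync",
                            normalization = 21L) {
  if (!scannedInput %in% model@inputs)
    stop("'", scannedInput, "' is not an environmental input")
  if (scannedInput %in% names(baseProbs)) {
    warning("base probability for the scanned input '", scannedInput,
            "' is ignored")
    baseProbs <- baseProbs[setdiff(names(baseProbs), scannedInput)]
  }
  if (is.null(kdLevels)) kdLevels <- if (is.null(kdoe)) NA_real_
                                     else unique(kdoe$prob)
  out <- list()
  for (lev in levels) {
    sched <- do.call(inputSchedule,
                     c(as.list(baseProbs), setNames(list(lev), scannedInput)))
    for (kl in kdLevels) {
      kd <- if (is.null(kdoe) || is.na(kl)) NULL
            else { k <- kdoe; k$prob <- kl; k }
      st <- runPhenotypeStatistics(model, init, schedule = sched,
                                   kdoe = kd, engine = engine,
                                   signatures = signatures,
                                   detectors = detectors,
                                   apoptosisSignature = apoptosisSignature,
                                   tMinLive = tMinLive,
                                   normalization = normalization)
      df <- statsToTidy(st)
      df$level <- lev
      df$kdLevel <- kl
      out[[length(out) + 1L]] <- df
    }
  }
  do.call(rbind, out)
}
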