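#' Phenotype signatures
#'
#' A phenotype signature is a named set of (node, required bit)
#' constraints; a state matches iff all constraints hold.  Signatures are
#' parsed from lines of the form
#' \preformatted{Name = (node=bit, node=bit, ...)}
#' (asterisks around node names, as in italic-formatted files, are
#' tolerated).  An empty constraint list matches every state.
#'
#' @param text signature text: a single string or character vector of
#'   lines.
#' @return a named list of named 0/1 integer vectors, class
#'   \code{phenotypeSignatures}.
#' @seealso \code{\link{defaultSignatures}}, \code{\link{classifyState}}
#' @export
loadSignatures <- function(text) {
  lines <- if (length(text) == 1L && grepl("\n", text))
    strsplit(text, "\n", fixed = TRUE)[[1]] else as.character(text)
  sig <- list()
  for (ln in seq_along(lines)) {
    raw <- trimws(lines[ln])
    if (!nzchar(raw) || startsWith(raw, "#") || startsWith(raw, "--")) next
    m <- regmatches(raw,
      regexec("^([A-Za-z_][A-Za-z0-9_-]*)\\s*=\\s*\\((.*)\\)\\s*$", raw))[[1]]
    if (length(m) != 3L)
      stop("line ", ln, ": not a signature line: '", raw, "'")
    nm <- m[2]
    body <- gsub("\\*", "", m[3])
    cons <- setNames(integer(0), character(0))
    if (nzchar(trimws(body))) {
      parts <- strsplit(body, ",", fixed = TRUE)[[1]]
      for (p in parts) {
        kv <- regmatches(p, regexec(
          "^\\s*([A-Za-z_][A-Za-z0-9_]*)\\s*=\\s*([01])\\s*$", p))[[1]]
        if (length(kv) != 3L)
          stop("line ", ln, ": malformed constraint '", trimws(p), "'")
        cons[kv[2]] <- as.integer(kv[3])
      }
    }
    sig[[nm]] <- cons
  }
  structure(sig, class = "phenotypeSignatures")
}

#' @rdname loadSignatures
#' @param path path to a signature file.
#' @export
readSignatures <- function(path) loadSignatures(readLines(path, warn = FALSE))

#' Packaged default phenotype signatures
#'
#' The seven standard signatures used for phenotype statistics: CIP,
#' noCIP, Migratory, Non-migratory, Epithelial, Mesenchymal and
#' Hybrid_EM.  They reference the marker nodes of the mechanosensitive
#' EMT models (contact-inhibition markers, migration marker, and the EMT
#' switch nodes); binding them to a model checks that the referenced
#' nodes exist.
#'
#' @return a \code{phenotypeSignatures} object.
#' @export
defaultSignatures <- function() {
  readSignatures(system.file("extdata", "phenotype_signatures.txt",
                             package = "bnsim", mustWork = TRUE))
}

#' Bind signatures to a model
#'
#' @param signatures a \code{phenotypeSignatures} object.
#' @param model a \linkS4class{BooleanModel}.
#' @return the signatures, after verifying every constrained node exists
#'   (unknown nodes are an error naming them).
#' @export
bindSignatures <- function(signatures, model) {
  for (nm in names(signatures)) {
    bad <- setdiff(names(signatures[[nm]]), model@nodes)
    if (length(bad))
      stop("signature '", nm, "' references unknown node(s): ",
           paste(bad, collapse = ", "))
  }
  signatures
}

#' Classify a state against phenotype signatures
#'
#' @param state a named 0/1 state (or one row of a trajectory matrix).
#' @param signatures a \code{phenotypeSignatures} object.
#' @return the names of all matching signatures (signatures need not be
#'   exclusive; a state may match several or none).
#' @export
classifyState <- function(state, signatures) {
  names(signatures)[vapply(signatures, function(cons) {
    !length(cons) || all(state[names(cons)] == cons)
  }, logical(1))]
}

#' @rdname classifyState
#' @param states a trajectory matrix (steps x nodes).
#' @return for \code{classifyTrajectory}, a logical matrix
#'   (steps x signatures).
#' @export
classifyTrajectory <- function(states, signatures) {
  out <- vapply(signatures, function(cons) {
    if (!length(cons)) return(rep(TRUE, nrow(states)))
    sub <- states[, names(cons), drop = FALSE]
    rowSums(sub == rep(cons, each = nrow(sub))) == length(cons)
  }, logical(nrow(states)))
  if (is.null(dim(out))) out <- matrix(out, nrow = 1,
                                       dimnames = list(NULL, names(signatures)))
  out
}

#' Declarative cell-cycle event detectors
#'
#' An event detector is data, not code: it fires on a rising edge of its
#' \code{trigger} node, subject to (i) \code{at}: required bits of other
#' nodes at the trigger step, (ii) a look-back window reaching to the
#' previous rising edge of the \code{since} node (or the start of the
#' trajectory), within which every \code{requireOn} node must have been ON
#' at least once and every \code{forbidOn} node never ON.
#'
#' @param name event name (counter key).
#' @param trigger node whose rising edge fires the detector.
#' @param at named 0/1 vector of state conditions at the trigger step.
#' @param since node whose previous rising edge opens the window
#'   (default: the trigger node itself).
#' @param requireOn,forbidOn node names checked within the window.
#' @return a list of class \code{eventDetector}.
#' @export
eventDetector <- function(name, trigger, at = NULL, since = trigger,
                          requireOn = character(0),
                          forbidOn = character(0)) {
  structure(list(name = name, trigger = trigger, at = at, since = since,
                 requireOn = requireOn, forbidOn = forbidOn),
            class = "eventDetector")
}

#' Default cell-cycle event detectors
#'
#' Operational definitions of the four cell-cycle outcomes scored in
#' proliferation statistics, over the standard marker-node names of the
#' deposited cell-cycle logic (override the defaults to target other
#' models):
#' \describe{
#'   \item{normal_cycle}{a cytokinesis pulse following cyclin-B activity
#'     with the kinetochore-attachment (spindle-completion) marker seen ON
#'     since the previous cytokinesis.}
#'   \item{g2_reset}{a replication start while the 4N-DNA flag is set and
#'     no cyclin-B pulse occurred since the previous replication --
#'     genome re-duplication from G2 without mitosis.}
#'   \item{aberrant_mitosis}{a metaphase-anaphase transition (Cdc20
#'     pulse) without the kinetochore-attachment marker ON.}
#'   \item{failed_cytokinesis}{a replication start after a cyclin-B pulse
#'     (mitosis happened) but with no cytokinesis pulse in between --
#'     telophase exit straight into the next S phase.}
#' }
#'
#' @param replication,cyclinB,kinetochores,cdc20,cytokinesis,f4N marker
#'   node names.
#' @return a list of \code{\link{eventDetector}}s.
#' @export
defaultCycleDetectors <- function(replication = "Replication",
                                  cyclinB = "CyclinB",
                                  kinetochores = "A_Kinetochores",
                                  cdc20 = "Cdc20",
                                  cytokinesis = "Cytokinesis",
                                  f4N = "f4N_DNA") {
  list(
    eventDetector("normal_cycle", trigger = cytokinesis,
                  since = cytokinesis,
                  requireOn = c(cyclinB, kinetochores)),
    eventDetector("g2_reset", trigger = replication,
                  at = setNames(1L, f4N), since = replication,
                  forbidOn = cyclinB),
    eventDetector("aberrant_mitosis", trigger = cdc20,
                  at = setNames(0L, kinetochores)),
    eventDetector("failed_cytokinesis", trigger = replication,
                  since = replication, requireOn = cyclinB,
                  forbidOn = cytokinesis)
  )
}

#' Count cell-cycle events along a trajectory
#'
#' Scans a trajectory with a set of \code{\link{eventDetector}}s and
#' returns per-event counts.  A quiescent trajectory (no marker edges)
#' yields all zeros.
#'
#' @param states trajectory matrix (steps x nodes, named columns).
#' @param detectors list of \code{\link{eventDetector}}s (default
#'   \code{\link{defaultCycleDetectors}()}).
#' @return named integer vector of event counts.
#' @export
detectCycleEvents <- function(states, detectors = defaultCycleDetectors()) {
  used <- unique(unlist(lapply(detectors, function(d)
    c(d$trigger, names(d$at), d$since, d$requireOn, d$forbidOn))))
  missing <- setdiff(used, colnames(states))
  if (length(missing))
    stop("detector references node(s) absent from the trajectory: ",
         paste(missing, collapse = ", "))
  nT <- nrow(states)
  risesOf <- function(v) {
    x <- states[, v]
    which(x == 1L & c(0L, x[-nT]) == 0L)
  }
  counts <- setNames(integer(length(detectors)),
                     vapply(detectors, `[[`, character(1), "name"))
  if (nT < 2L) return(counts)
  for (d in detectors) {
    trig <- risesOf(d$trigger)
    trig <- trig[trig > 1L]  # an initial ON state is not an edge event
    if (!is.null(d$at) && length(trig)) {
      ok <- vapply(trig, function(t)
        all(states[t, names(d$at)] == d$at), logical(1))
      trig <- trig[ok]
    }
    sinceRises <- risesOf(d$since)
    for (t in trig) {
      prev <- sinceRises[sinceRises < t]
      lo <- if (length(prev)) max(prev) + 1L else 1L
      win <- seq(lo, t)
      okReq <- all(vapply(d$requireOn, function(v)
        any(states[win, v] == 1L), logical(1)))
      okForbid <- !any(vapply(d$forbidOn, function(v)
        any(states[win, v] == 1L), logical(1)))
      if (okReq && okForbid)
        counts[d$name] <- counts[d$name] + 1L
    }
  }
  counts
}

#' Phenotype and event statistics under stochastic conditions
#'
#' Runs (apoptosis-restarted) time courses until at least \code{tMinLive}
#' steps of live-cell dynamics have been sampled, classifying every live
#' step against the phenotype signatures and scoring cell-cycle events
#' with the detectors.  Runs that hit the apoptosis signature stop and
#' restart from the initial condition; the apoptotic state itself is not
#' counted as live time.  Event rates are normalized per minimum cell
#' cycle length (default 21 steps), i.e. \code{count / (live /
#' normalization)}.
#'
#' @param model a \linkS4class{BooleanModel}.
#' @param init initial state or \linkS4class{Attractor}.
#' @param schedule an \code{\link{inputSchedule}} (or NULL: inputs held).
#' @param kdoe a \code{\link{kdoeSpec}} or NULL.
#' @param engine update engine as in \code{\link{runTrajectory}}.
#' @param signatures \code{phenotypeSignatures} for dwell statistics
#'   (default \code{\link{defaultSignatures}()} restricted to signatures
#'   whose nodes exist in the model).
#' @param detectors cell-cycle \code{\link{eventDetector}}s, or NULL to
#'   skip event scoring (used for models without cell-cycle markers).
#' @param apoptosisSignature named bits marking the apoptotic state, or
#'   NULL for no restarts.
#' @param tMinLive minimum live steps to sample (figure-style runs use
#'   1e5).
#' @param pNoise noise for the \code{"noisy"} engine.
#' @param normalization minimum cycle length for event rates.
#' @param maxRestarts guard against environments where every run dies
#'   immediately; exceeded, the result is flagged degenerate with NA
#'   dwell fractions rather than silent zeros.
#' @return a list of class \code{phenotypeStats}: \code{counters} (event
#'   counts, apoptoses, live steps, per-phenotype dwell steps),
#'   \code{dwellFractions}, \code{rates} (per normalization),
#'   \code{apoptosisRate}, \code{degenerate} flag, \code{params}.
#' @export
runPhenotypeStatistics <- function(model, init, schedule = NULL,
                                   kdoe = NULL, engine = "sync",
                                   signatures = NULL, detectors = NULL,
                                   apoptosisSignature = NULL,
                                   tMinLive = 1000L, pNoise = 0.02,
                                   normalization = 21L,
                                   maxRestarts = 10000L) {
  stopifnot(tMinLive >= 1L)
  if (is(init, "Attractor")) {
    ctx <- init@context
    s0 <- setNames(init@states[1, ], colnames(init@states))
    s0[names(ctx)] <- ctx
    init <- s0
  }
  init <- .fullState(model, init)
  if (is.null(signatures)) {
    signatures <- defaultSignatures()
    keep <- vapply(signatures, function(cons)
      all(names(cons) %in% model@nodes), logical(1))
    signatures <- structure(signatures[keep], class = "phenotypeSignatures")
  }
  bindSignatures(signatures, model)
  if (!is.null(apoptosisSignature)) {
    bad <- setdiff(names(apoptosisSignature), model@nodes)
    if (length(bad))
      stop("apoptosis signature references unknown node(s): ",
           paste(bad, collapse = ", "))
  }

  live <- 0L; apopt <- 0L; restarts <- 0L
  dwell <- setNames(numeric(length(signatures)), names(signatures))
  events <- NULL
  degenerate <- FALSE
  while (live < tMinLive) {
    want <- tMinLive - live
    res <- runTrajectory(model, init, nSteps = want, engine = engine,
                         schedule = schedule, kdoe = kdoe,
                         pNoise = pNoise,
                         stopSignature = apoptosisSignature)
    st <- res$states
    liveRows <- if (res$stopped) {
      apopt <- apopt + 1L
      # states 1..stoppedAt-1 after the initial row are live
      if (res$stoppedAt >= 2L) 2:(res$stoppedAt) - 0L else integer(0)
    } else if (nrow(st) >= 2L) 2:nrow(st) else integer(0)
    if (res$stopped && res$stoppedAt >= 1L)
      liveRows <- setdiff(liveRows, nrow(st))  # apoptotic state not live
    if (length(liveRows)) {
      seg <- st[liveRows, , drop = FALSE]
      cls <- classifyTrajectory(seg, signatures)
      dwell <- dwell + colSums(cls)
      live <- live + length(liveRows)
    }
    if (!is.null(detectors)) {
      ev <- detectCycleEvents(st, detectors)
      events <- if (is.null(events)) ev else events + ev
    }
    if (res$stopped) {
      restarts <- restarts + 1L
      if (res$stoppedAt <= 1L && restarts >= maxRestarts) {
        degenerate <- TRUE
        break
      }
      if (restarts >= maxRestarts) { degenerate <- TRUE; break }
    }
  }
  if (is.null(events))
    events <- setNames(integer(0), character(0))
  counters <- list(events = events, apoptoses = apopt,
                   live_steps = live, dwell_steps = dwell)
  dwellFrac <- if (live > 0 && !degenerate) dwell / live
               else setNames(rep(NA_real_, length(dwell)), names(dwell))
  rates <- if (live > 0) events / (live / normalization)
           else setNames(rep(NA_real_, length(events)), names(events))
  structure(list(counters = counters, dwellFractions = dwellFrac,
                 rates = rates,
                 apoptosisRate = if (live > 0)
                   apopt / (live / normalization) else NA_real_,
                 degenerate = degenerate,
                 params = list(tMinLive = tMinLive, engine = engine,
                               normalization = normalization)),
            class = "phenotypeStats")
}

#' @rdname runPhenotypeStatistics
#' @param x a \code{phenotypeStats} object.
#' @return for \code{statsToTidy}, a tidy data.frame (metric, name,
#'   value) ready for stacked-bar CSV export.
#' @export
statsToTidy <- function(x) {
  rbind(
    data.frame(metric = "dwell_fraction",
               name = names(x$dwellFractions),
               value = unname(x$dwellFractions)),
    if (length(x$rates))
      data.frame(metric = "event_rate", name = names(x$rates),
                 value = unname(x$rates)),
    data.frame(metric = "apoptosis_rate", name = "apoptosis",
               value = x$apoptosisRate),
    data.frame(metric = "live_steps", name = "live",
               value = x$counters$live_steps)
  )
}

#' @export
print.phenotypeStats <- function(x, ...) {
  cat("Phenotype statistics over", x$counters$live_steps, "live steps\n")
  if (x$degenerate)
    cat("  DEGENERATE: live-time target not reached (all runs apoptotic)\n")
  if (length(x$dwellFractions)) {
    cat("  dwell fractions:\n")
    for (nm in names(x$dwellFractions))
      cat(sprintf("    %-16s %.3f\n", nm, x$dwellFractions[nm]))
  }
  if (length(x$rates)) {
    cat("  event rates (per", x$params$normalization, "steps):\n")
    for (nm in names(x$rates))
      cat(sprintf("    %-20s %.4f\n", nm, x$rates[nm]))
  }
  cat(sprintf("  apoptosis rate: %.4f\n", x$apoptosisRate))
  invisible(x)
}
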