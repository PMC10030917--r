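#' Reduce a gate by freezing removed regulators
#'
#' When a subset of a gate's regulators is removed (module isolation,
#' link-removal mutants), the removed regulators are assumed frozen ON or
#' OFF.  Among the \code{2^r} frozen assignments the one kept must
#' (a) leave every remaining regulator functional -- able to change the
#' output for some input combination -- if any assignment can, and
#' (b) maximize the entropy of the remaining gate fragment,
#' \deqn{H_G = -p \log p - (1-p) \log(1-p),}
#' where \eqn{p} is the fraction of OFF outputs (natural log; the base
#' does not affect the argmax, and H(0) = H(1) = 0 by continuity).  Ties
#' are broken by the lexicographically smallest frozen assignment
#' (removed regulators in declaration order, 0 before 1), so the
#' reduction is deterministic.  Removing several regulators is a single
#' joint optimization over all \code{2^r} assignments, not a sequence of
#' single removals.
#'
#' @param spec a gate: list with \code{regulators} (declaration order),
#'   \code{table} and optionally \code{expression} (ignored; the result
#'   carries a DNF of the reduced table).
#' @param removed regulator names to remove (non-empty subset).
#' @return the reduced gate spec, with attributes \code{frozen} (the
#'   chosen assignment) and \code{allFunctional}.  Removing every
#'   regulator yields a constant gate frozen to the majority output
#'   (ties broken toward OFF), with a warning.
#' @export
reduceGateFrozenInputs <- function(spec, removed) {
  regs <- spec$regulators
  tab <- as.integer(spec$table)
  if (!length(removed)) stop("'removed' must be non-empty")
  if (!all(removed %in% regs))
    stop("removed regulators must be a subset of the gate's regulators")
  keep <- setdiff(regs, removed)
  removed <- regs[regs %in% removed]  # declaration order
  k <- length(regs)

  if (!length(keep)) {
    out <- as.integer(mean(tab) > 0.5)  # tie (0.5) -> OFF
    warning("all regulators removed; gate frozen to its majority output (",
            out, ")")
    res <- list(regulators = character(0),
                expression = if (out == 1L) "True" else "False",
                table = out)
    attr(res, "frozen") <- setNames(integer(0), character(0))
    attr(res, "allFunctional") <- FALSE
    return(res)
  }

  m <- length(keep); r <- length(removed)
  posAll <- setNames(seq_len(k), regs)
  # table row index for a full assignment (first regulator = MSB)
  rowIndex <- function(assign) sum(assign * 2^(k - posAll)) + 1L

  kc <- vapply(seq_len(2^m) - 1L, function(code)
    as.integer(intToBits(code))[m:1], integer(m))
  keepCombos <- if (m == 1L) matrix(kc, ncol = 1L) else t(kc)
  colnames(keepCombos) <- keep

  best <- NULL
  for (code in seq_len(2^r) - 1L) {
    frozen <- setNames(as.integer(intToBits(code))[r:1], removed)
    red <- vapply(seq_len(2^m), function(i) {
      assign <- setNames(integer(k), regs)
      assign[keep] <- keepCombos[i, ]
      assign[removed] <- frozen
      tab[rowIndex(assign)]
    }, integer(1))
    functional <- vapply(seq_len(m), function(j) {
      block <- 2^(m - j)
      any(vapply(seq_len(2^m) - 1L, function(b) {
        if (bitwAnd(b %/% block, 1L) == 1L) return(FALSE)
        red[b + 1L] != red[b + block + 1L]
      }, logical(1)))
    }, logical(1))
    pOff <- mean(red == 0L)
    H <- if (pOff %in% c(0, 1)) 0 else -pOff * log(pOff) -
      (1 - pOff) * log(1 - pOff)
    cand <- list(frozen = frozen, table = as.integer(red),
                 allFunctional = all(functional), H = H, code = code)
    if (is.null(best) ||
        (cand$allFunctional && !best$allFunctional) ||
        (cand$allFunctional == best$allFunctional &&
         (cand$H > best$H + 1e-12 ||
          (abs(cand$H - best$H) <= 1e-12 && cand$code < best$code))))
      best <- cand
  }
  res <- list(regulators = keep,
              expression = .tableToExpression(keep, best$table),
              table = best$table)
  attr(res, "frozen") <- best$frozen
  attr(res, "allFunctional") <- best$allFunctional
  res
}

#' Isolate a subnetwork module
#'
#' For each module node, regulators outside the module are removed via
#' \code{\link{reduceGateFrozenInputs}} (one joint reduction per node), so
#' the remaining in-module regulation is preserved as faithfully as
#' possible.  Module nodes left with no regulators -- all their inputs
#' were outside the module -- become environmental inputs of the isolated
#' model.
#'
#' @param model a \linkS4class{BooleanModel}.
#' @param moduleNodes node names to keep (non-empty subset).
#' @return a self-contained \linkS4class{BooleanModel}.
#' @export
isolateModule <- function(model, moduleNodes) {
  if (!length(moduleNodes)) stop("empty module")
  bad <- setdiff(moduleNodes, model@nodes)
  if (length(bad))
    stop("module names unknown node(s): ", paste(bad, collapse = ", "))
  moduleNodes <- model@nodes[model@nodes %in% moduleNodes]

  regs <- list(); exprs <- character(0); tabs <- list()
  newInputs <- character(0); detection <- character(0)
  for (v in moduleNodes) {
    r <- model@regulators[[v]]
    outside <- setdiff(r, moduleNodes)
    if (v %in% model@inputs || !length(outside)) {
      regs[[v]] <- r; exprs[v] <- model@expressions[[v]]
      tabs[[v]] <- model@tables[[v]]
      if (v %in% model@inputs) {
        newInputs <- c(newInputs, v)
        detection[v] <- "self-loop"
      }
      next
    }
    if (length(outside) == length(r)) {
      # fully externally driven: becomes an environmental input
      regs[[v]] <- v; exprs[v] <- v; tabs[[v]] <- c(0L, 1L)
      newInputs <- c(newInputs, v)
      detection[v] <- "self-loop"
      next
    }
    red <- reduceGateFrozenInputs(
      list(regulators = r, table = model@tables[[v]]), outside)
    regs[[v]] <- red$regulators; exprs[v] <- red$expression
    tabs[[v]] <- red$table
  }
  newBooleanModel(name = paste0(model@name, "_module"),
                  nodes = moduleNodes, regulators = regs,
                  expressions = exprs, tables = tabs, inputs = newInputs,
                  inputDetection = detection)
}

#' Generate an ensemble of mutant networks
#'
#' Three mutation kinds mimic random errors in model construction:
#' \describe{
#'   \item{node_lock}{\code{errorsPerNetwork} random non-input nodes are
#'     permanently locked ON or OFF (the bit is random too).}
#'   \item{link_removal}{random regulatory links are removed; the target
#'     gates are reduced via \code{\link{reduceGateFrozenInputs}} (links
#'     sharing a target are removed jointly).}
#'   \item{gate_flip}{random non-input nodes each get exactly one random
#'     truth-table row's output flipped (Hamming distance 1 per flip).}
#' }
#' Environmental inputs are never mutated, so the environment remains
#' controllable across the ensemble.
#'
#' @param model a \linkS4class{BooleanModel}.
#' @param kind one of \code{"node_lock"}, \code{"link_removal"},
#'   \code{"gate_flip"}.
#' @param errorsPerNetwork number of errors per mutant.
#' @param ensembleSize number of independent mutants.
#' @param seed optional seed.
#' @return a list of \linkS4class{BooleanModel}s.
#' @export
generateMutantEnsemble <- function(model, kind = c("node_lock",
                                                   "link_removal",
                                                   "gate_flip"),
                                   errorsPerNetwork, ensembleSize,
                                   seed = NULL) {
  kind <- match.arg(kind)
  if (!is.null(seed)) set.seed(seed)
  n <- errorsPerNetwork
  free <- setdiff(model@nodes, model@inputs)
  links <- do.call(rbind, lapply(free, function(v)
    if (length(model@regulators[[v]]))
      data.frame(from = model@regulators[[v]], to = v)))
  if (kind == "node_lock" && n > length(free))
    stop("more locks requested than non-input nodes")
  if (kind == "link_removal" && n > nrow(links))
    stop("more link removals requested than links (", nrow(links), ")")
  if (kind == "gate_flip" && n > length(free))
    stop("more gate flips requested than non-input nodes")

  lapply(seq_len(ensembleSize), function(i) {
    mut <- model
    if (n == 0L) return(mut)
    if (kind == "node_lock") {
      targets <- sample(free, n)
      bits <- sample(c(0L, 1L), n, replace = TRUE)
      for (j in seq_len(n)) {
        v <- targets[j]
        mut@regulators[[v]] <- character(0)
        mut@tables[[v]] <- bits[j]
        mut@expressions[v] <- if (bits[j] == 1L) "True" else "False"
      }
    } else if (kind == "link_removal") {
      sel <- links[sample(nrow(links), n), , drop = FALSE]
      for (v in unique(sel$to)) {
        gone <- sel$from[sel$to == v]
        red <- reduceGateFrozenInputs(
          list(regulators = mut@regulators[[v]],
               table = mut@tables[[v]]), gone)
        mut@regulators[[v]] <- red$regulators
        mut@tables[[v]] <- red$table
        mut@expressions[v] <- red$expression
      }
    } else {
      targets <- sample(free, n)
      for (v in targets) {
        row <- sample(length(mut@tables[[v]]), 1L)
        mut@tables[[v]][row] <- 1L - mut@tables[[v]][row]
        mut@expressions[v] <- .tableToExpression(mut@regulators[[v]],
                                                 mut@tables[[v]])
      }
    }
    mut@name <- sprintf("%s_%s_%d", model@name, kind, i)
    validObject(mut)
    mut
  })
}
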