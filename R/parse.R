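#' Parse a BooleanNet-style rule file
#'
#' Reads rules of the form \code{Target *= expression} (the \code{∗=}
#' glyph is also accepted) with \code{and/or/not} logic, compiles each gate
#' into a truth table, and auto-detects environmental inputs: a node is
#' environmental iff its only regulator is itself with identity logic
#' (\code{A *= A}) or it is referenced as a regulator without a rule of its
#' own.  Explicitly declared inputs override the detection.  Comment lines
#' starting with \code{#} or \code{--} and blank lines are tolerated.
#'
#' @param text rule text: a single string or a character vector of lines.
#' @param name model name.
#' @param inputs optional character vector declaring the environmental
#'   inputs explicitly.
#' @param strict if \code{TRUE}, a regulator without a rule is a parse
#'   error naming the symbol and line instead of becoming an input.
#' @return a validated \linkS4class{BooleanModel}.
#' @examples
#' m <- parseBooleanNet("A *= A\nB *= A and not C\nC *= C")
#' inputNodes(m)  # A and C are self-only inputs
#' @seealso \code{\link{readBooleanNet}}, \code{\link{writeBooleanNet}}
#' @export
parseBooleanNet <- function(text, name = "model", inputs = NULL,
                            strict = FALSE) {
  lines <- if (length(text) == 1L) strsplit(text, "\n", fixed = TRUE)[[1]]
           else as.character(text)
  rules <- list(); ruleLine <- integer(0)
  for (ln in seq_along(lines)) {
    raw <- lines[ln]
    stripped <- sub("#.*$", "", raw)
    stripped <- trimws(stripped)
    if (!nzchar(stripped) || startsWith(stripped, "--")) next
    m <- regmatches(stripped,
      regexec("^([A-Za-z_][A-Za-z0-9_]*)\\s*[*∗]\\s*=\\s*(.+)$", stripped))[[1]]
    if (length(m) != 3L)
      stop("line ", ln, ": not a rule line: '", raw, "'")
    target <- m[2]; expr <- trimws(m[3])
    if (target %in% names(rules))
      stop("line ", ln, ": duplicate definition of node '", target, "'")
    rules[[target]] <- expr
    ruleLine[target] <- ln
  }
  if (!length(rules)) stop("no rules found: empty model file")

  nodes <- names(rules)
  regulators <- lapply(rules, .exprRegulators)
  referenced <- unique(unlist(regulators))
  noRule <- setdiff(referenced, nodes)
  if (length(noRule) && strict) {
    offender <- noRule[1]
    atLine <- ruleLine[nodes[vapply(regulators, function(r)
      offender %in% r, logical(1))][1]]
    stop("line ", atLine, ": undeclared regulator '", offender, "'")
  }

  detection <- setNames(character(0), character(0))
  selfOnly <- nodes[vapply(nodes, function(v) {
    identical(regulators[[v]], v) &&
      identical(compileTruthTable(rules[[v]], v)$table, c(0L, 1L))
  }, logical(1))]
  detection[selfOnly] <- "self-loop"
  detection[noRule] <- "no-rule"
  if (!is.null(inputs)) {
    unknown <- setdiff(inputs, c(nodes, noRule))
    if (length(unknown))
      stop("declared input(s) not present in the model: ",
           paste(unknown, collapse = ", "))
    detection <- setNames(character(0), character(0))
    detection[inputs] <- "declared"
  }
  inputSet <- if (is.null(names(detection))) character(0)
              else names(detection)

  allNodes <- c(nodes, noRule)
  exprs <- character(length(allNodes)); names(exprs) <- allNodes
  regs <- vector("list", length(allNodes)); names(regs) <- allNodes
  tabs <- vector("list", length(allNodes)); names(tabs) <- allNodes
  for (v in nodes) {
    if (v %in% inputSet) {
      exprs[v] <- v; regs[[v]] <- v; tabs[[v]] <- c(0L, 1L)
    } else {
      ct <- compileTruthTable(rules[[v]], regulators[[v]])
      exprs[v] <- rules[[v]]; regs[[v]] <- ct$regulators; tabs[[v]] <- ct$table
    }
  }
  for (v in noRule) {
    exprs[v] <- v; regs[[v]] <- v; tabs[[v]] <- c(0L, 1L)
  }

  newBooleanModel(name = name, nodes = allNodes, regulators = regs,
                  expressions = exprs, tables = tabs, inputs = inputSet,
                  inputDetection = detection)
}

#' @rdname parseBooleanNet
#' @param path path to a rule file.
#' @param ... passed on to \code{parseBooleanNet}.
#' @export
readBooleanNet <- function(path, name = sub("\\.[^.]*$", "", basename(path)),
                           ...) {
  parseBooleanNet(readLines(path, warn = FALSE), name = name, ...)
}

#' Serialize a model to BooleanNet-style rule text
#'
#' Inputs are written as identity self-loops (\code{A *= A}); gates that
#' only exist as truth tables (random or mutated networks) are written in
#' disjunctive normal form, which parses back to an identical table.
#'
#' @param model a \linkS4class{BooleanModel}.
#' @param path optional file path; if given the text is also written there.
#' @return the rule lines, invisibly when \code{path} is given.
#' @export
writeBooleanNet <- function(model, path = NULL) {
  lines <- vapply(model@nodes, function(v) {
    expr <- model@expressions[[v]]
    if (!nzchar(expr)) expr <- .tableToExpression(model@regulators[[v]],
                                                  model@tables[[v]])
    paste0(v, " *= ", expr)
  }, character(1))
  lines <- unname(lines)
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}

# internal constructor used by the parser, fixtures and gate surgery
newBooleanModel <- function(name, nodes, regulators, expressions, tables,
                            inputs, inputDetection = character(0),
                            bias = emptyBias()) {
  obj <- new("BooleanModel", name = name, nodes = nodes,
             regulators = regulators[nodes],
             expressions = expressions[nodes], tables = tables[nodes],
             inputs = inputs, inputDetection = inputDetection, bias = bias)
  validObject(obj)
  obj
}

#' Export the interaction graph to GML
#'
#' Writes the signed interaction graph inferred from gate monotonicity:
#' a link is activating (sign +1) if the gate output is monotone
#' non-decreasing in that regulator, inhibiting (-1) if non-increasing,
#' and unsigned (0) otherwise.  Identity self-loops on input nodes are
#' kept so the environment set is visible in graph editors.
#'
#' @param model a \linkS4class{BooleanModel}.
#' @param path output file path.
#' @return the \pkg{igraph} graph, invisibly.
#' @export
exportGML <- function(model, path) {
  edges <- interactionEdges(model)
  g <- igraph::graph_from_data_frame(
    edges[, c("from", "to")], directed = TRUE,
    vertices = data.frame(name = model@nodes))
  igraph::E(g)$sign <- edges$sign
  igraph::write_graph(g, path, format = "gml")
  invisible(g)
}

#' @rdname exportGML
#' @return for \code{interactionEdges}, a data.frame with columns
#'   \code{from}, \code{to} and \code{sign}.
#' @export
interactionEdges <- function(model) {
  rows <- list()
  for (v in model@nodes) {
    regs <- model@regulators[[v]]
    tab <- model@tables[[v]]
    k <- length(regs)
    for (j in seq_along(regs)) {
      # pair up table entries differing only in regulator j
      block <- 2^(k - j)
      hi <- lo <- integer(0)
      for (base in seq(0L, 2^k - 1L)) {
        if (bitwAnd(base %/% block, 1L) == 1L) next
        lo <- c(lo, base); hi <- c(hi, base + block)
      }
      d <- tab[hi + 1L] - tab[lo + 1L]
      sign <- if (all(d >= 0) && any(d > 0)) 1L
              else if (all(d <= 0) && any(d < 0)) -1L
              else 0L
      rows[[length(rows) + 1L]] <- data.frame(from = regs[j], to = v,
                                              sign = sign)
    }
  }
  do.call(rbind, rows)
}
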