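# Rule expressions use the BooleanNet dialect: case-sensitive node names
# combined with `and`, `or`, `not`, parentheses and the constants
# True/False.  XOR and other operators are rejected.

.KEYWORDS <- c("and", "or", "not", "True", "False", "TRUE", "FALSE")

# identifiers in order of first appearance, keywords excluded
.exprRegulators <- function(expression) {
  toks <- regmatches(expression,
                     gregexpr("[A-Za-z_][A-Za-z0-9_]*", expression))[[1]]
  unique(toks[!toks %in% .KEYWORDS])
}

# translate to an R logical expression and check only Boolean syntax is used
.exprToR <- function(expression) {
  txt <- expression
  txt <- gsub("\\bnot\\b", "!", txt)
  txt <- gsub("\\band\\b", "&", txt)
  txt <- gsub("\\bor\\b", "|", txt)
  txt <- gsub("\\bTrue\\b", "TRUE", txt)
  txt <- gsub("\\bFalse\\b", "FALSE", txt)
  e <- tryCatch(str2lang(txt), error = function(err)
    stop("cannot parse rule expression: ", expression, call. = FALSE))
  .checkBoolAst(e, expression)
  e
}

.checkBoolAst <- function(e, original) {
  if (is.name(e) || isTRUE(e) || isFALSE(e)) return(invisible(TRUE))
  if (is.numeric(e) && e %in% c(0, 1)) return(invisible(TRUE))
  if (is.call(e)) {
    op <- as.character(e[[1]])
    if (!op %in% c("&", "|", "!", "(", "&&", "||"))
      stop("operator '", op, "' is not part of the rule dialect (and/or/not): ",
           original, call. = FALSE)
    for (i in seq_along(e)[-1]) .checkBoolAst(e[[i]], original)
    return(invisible(TRUE))
  }
  stop("unsupported token in rule expression: ", original, call. = FALSE)
}

#' Compile a rule expression into a truth table
#'
#' Evaluates a Boolean rule over all \code{2^k} combinations of its
#' regulators.  The combination index is the binary number with the first
#' regulator as the most significant bit, so tables are reproducible given
#' the regulator declaration order.  Compilation is idempotent and
#' independent of expression formatting: two equivalent formulas over the
#' same regulator order give identical tables.
#'
#' @param expression rule text in the \code{and/or/not} dialect.
#' @param regulators regulator names in declaration order; defaults to the
#'   identifiers in \code{expression} in order of first appearance.
#' @return a list with \code{regulators}, \code{expression} and the
#'   integer \code{table} of length \code{2^k}.
#' @examples
#' compileTruthTable("A and not C")$table  # 0 0 1 0 for (A,C) combinations
#' @export
compileTruthTable <- function(expression, regulators = NULL) {
  if (is.null(regulators)) regulators <- .exprRegulators(expression)
  used <- .exprRegulators(expression)
  if (!all(used %in% regulators))
    stop("expression names symbols outside the declared regulators: ",
         paste(setdiff(used, regulators), collapse = ", "))
  k <- length(regulators)
  if (k > 20L)
    stop("gate has ", k, " regulators; truth tables above 20 inputs are ",
         "refused (2^k entries would be too large)")
  e <- .exprToR(expression)
  if (k == 0L) {
    val <- eval(e, envir = baseenv())
    return(list(regulators = character(0), expression = expression,
                table = as.integer(as.logical(val))))
  }
  env <- list()
  for (j in seq_len(k)) {
    env[[regulators[j]]] <-
      as.logical(rep(rep(c(0L, 1L), each = 2^(k - j)), times = 2^(j - 1)))
  }
  out <- eval(e, envir = env)
  out <- as.integer(as.logical(out))
  if (length(out) == 1L) out <- rep(out, 2^k)
  stopifnot(length(out) == 2^k)
  list(regulators = regulators, expression = expression, table = out)
}

# disjunctive normal form of a truth table; used when serializing gates
# that only exist as tables (random networks, reduced/mutated gates)
.tableToExpression <- function(regulators, table) {
  k <- length(regulators)
  if (k == 0L) return(if (table[1] == 1L) "True" else "False")
  ones <- which(table == 1L) - 1L
  if (!length(ones)) return("False")
  if (length(ones) == 2^k) return("True")
  terms <- vapply(ones, function(code) {
    bits <- as.integer(intToBits(code))[k:1]
    lits <- ifelse(bits == 1L, regulators, paste("not", regulators))
    if (k == 1L) lits else paste0("(", paste(lits, collapse = " and "), ")")
  }, character(1))
  paste(terms, collapse = " or ")
}
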