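# internal helpers shared across modules

# flattened representation handed to the compiled core
.coreList <- function(model) {
  nodes <- model@nodes
  n <- length(nodes)
  idx <- setNames(seq_along(nodes) - 1L, nodes)
  nreg <- integer(n); regs <- integer(0); tabs <- integer(0)
  regOff <- integer(n); tabOff <- integer(n)
  for (i in seq_len(n)) {
    v <- nodes[i]
    r <- model@regulators[[v]]
    regOff[i] <- length(regs)
    tabOff[i] <- length(tabs)
    nreg[i] <- length(r)
    regs <- c(regs, unname(idx[r]))
    tabs <- c(tabs, model@tables[[v]])
  }
  list(n = n, nreg = nreg, regOff = regOff, regs = regs,
       tabOff = tabOff, tabs = tabs,
       isInput = as.integer(nodes %in% model@inputs))
}

.fullState <- function(model, state) {
  nodes <- model@nodes
  if (is.null(names(state))) {
    if (length(state) != length(nodes))
      stop("unnamed state must cover every node")
    return(setNames(as.integer(state), nodes))
  }
  if (!all(nodes %in% names(state)))
    stop("state must assign every node of the model; missing: ",
         paste(setdiff(nodes, names(state)), collapse = ", "))
  setNames(as.integer(state[nodes]), nodes)
}

.applyContext <- function(model, state, context) {
  if (is.null(context) || !length(context)) return(state)
  if (is.null(names(context)))
    stop("context must be a named 0/1 vector over input nodes")
  bad <- setdiff(names(context), model@inputs)
  if (length(bad))
    stop("context fixes non-input node(s): ", paste(bad, collapse = ", "))
  state[names(context)] <- as.integer(context)
  state
}

.bitString <- function(bits) paste(as.integer(bits), collapse = "")

# 32-bit FNV-1a over a character scalar; provenance tag for artifacts.
# Careful 32-bit arithmetic in doubles (R has no unsigned ints).
.fnv1a <- function(text) {
  bytes <- utf8ToInt(paste(text, collapse = "\n"))
  h <- 2166136261
  prime <- 16777619
  for (b in bytes) {
    # xor on the low 32 bits
    h <- .xor32(h, b)
    # multiply mod 2^32 without losing precision: split into 16-bit halves
    lo <- h %% 65536; hi <- (h - lo) / 65536
    h <- ((hi * prime) %% 65536) * 65536 + lo * prime
    h <- h %% 4294967296
  }
  lo <- h %% 65536
  sprintf("%04x%04x", as.integer((h - lo) / 65536), as.integer(lo))
}

.xor32 <- function(a, b) {
  r <- 0; p <- 1
  for (i in 1:32) {
    ab <- a %% 2; bb <- b %% 2
    if (ab != bb) r <- r + p
    a <- (a - ab) / 2; b <- (b - bb) / 2
    p <- p * 2
  }
  r
}

#' Content hash of a model
#'
#' A 32-bit FNV-1a hash of the serialized rule text, used to tag exported
#' artifacts with the exact model they came from and to invalidate cached
#' sampling results when the model changes.
#'
#' @param model a \linkS4class{BooleanModel}.
#' @return an 8-character hex string.
#' @export
modelHash <- function(model) {
  .fnv1a(writeBooleanNet(model))
}
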