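# Independent reference implementations used as oracles.  They evaluate
# rule *expressions* directly in plain R (never the package's compiled
# truth tables or C++ stepping), so implementation and oracle stay on
# separate routes.

oracle_eval <- function(exprText, state) {
  txt <- gsub("\\bnot\\b", "!", exprText)
  txt <- gsub("\\band\\b", "&", txt)
  txt <- gsub("\\bor\\b", "|", txt)
  txt <- gsub("\\bTrue\\b", "TRUE", txt)
  txt <- gsub("\\bFalse\\b", "FALSE", txt)
  env <- lapply(as.list(state), function(b) as.logical(b))
  as.integer(eval(str2lang(txt), envir = env))
}

oracle_sync_step <- function(model, state) {
  out <- state
  for (v in setdiff(nodeNames(model), inputNodes(model)))
    out[v] <- oracle_eval(ruleOf(model, v), state)
  out
}

# exhaustive attractor enumeration by forward walks over the full
# non-input subspace of one context; returns a list of attractors, each a
# sorted character vector of state strings (order-free representation)
oracle_enumerate <- function(model, context = NULL) {
  nodes <- nodeNames(model)
  free <- setdiff(nodes, inputNodes(model))
  m <- length(free)
  base <- setNames(integer(length(nodes)), nodes)
  if (!is.null(context)) base[names(context)] <- as.integer(context)
  key <- function(s) paste(s, collapse = "")
  label <- new.env(parent = emptyenv())
  attractors <- list()
  for (code in seq_len(2^m) - 1L) {
    s <- base
    s[free] <- as.integer(intToBits(code))[m:1]
    path <- character(0)
    repeat {
      k <- key(s)
      if (!is.null(label[[k]])) { id <- label[[k]]; break }
      if (k %in% path) {
        cyc <- path[seq(match(k, path), length(path))]
        attractors[[length(attractors) + 1L]] <- sort(cyc)
        id <- length(attractors)
        break
      }
      path <- c(path, k)
      s <- oracle_sync_step(model, s)
    }
    for (k in path) label[[k]] <- id
  }
  attractors
}

# order-free representation of a package Attractor for comparison
attractor_keyset <- function(a) {
  sort(apply(attractorStates(a), 1L, paste, collapse = ""))
}

# small fixture models -------------------------------------------------

toggle_switch <- function() {
  parseBooleanNet("A *= not B\nB *= not A", name = "toggle")
}

negative_ring <- function() {
  parseBooleanNet("A *= not C\nB *= A\nC *= B", name = "ring3")
}

constant_off_model <- function(n = 5L) {
  parseBooleanNet(paste(sprintf("N%d *= False", seq_len(n)),
                        collapse = "\n"),
                  name = "constOFF")
}

# independent brute-force reference for gate reduction: enumerate every
# frozen assignment, apply the functionality filter, maximize H_G, break
# ties lexicographically -- written from the definition, not the package
brute_reduce <- function(regs, tab, removed) {
  keep <- setdiff(regs, removed)
  removed <- regs[regs %in% removed]
  k <- length(regs); m <- length(keep); r <- length(removed)
  lookup <- function(assign) {
    idx <- sum(assign[regs] * 2^((k - 1):0))
    tab[idx + 1L]
  }
  best <- NULL
  for (code in seq_len(2^r) - 1L) {
    frozen <- setNames(as.integer(intToBits(code))[r:1], removed)
    red <- integer(2^m)
    for (kc in seq_len(2^m) - 1L) {
      assign <- setNames(integer(k), regs)
      assign[keep] <- as.integer(intToBits(kc))[m:1]
      assign[removed] <- frozen
      red[kc + 1L] <- lookup(assign)
    }
    func <- TRUE
    for (j in seq_len(m)) {
      blk <- 2^(m - j); hit <- FALSE
      for (b in seq_len(2^m) - 1L) {
        if ((b %/% blk) %% 2 == 1) next
        if (red[b + 1L] != red[b + blk + 1L]) { hit <- TRUE; break }
      }
      if (!hit) { func <- FALSE; break }
    }
    pOff <- mean(red == 0L)
    H <- if (pOff == 0 || pOff == 1) 0
         else -pOff * log(pOff) - (1 - pOff) * log(1 - pOff)
    cand <- list(frozen = frozen, red = red, func = func, H = H,
                 code = code)
    if (is.null(best) || (cand$func && !best$func) ||
        (cand$func == best$func &&
         (cand$H > best$H + 1e-12 ||
          (abs(cand$H - best$H) <= 1e-12 && cand$code < best$code))))
      best <- cand
  }
  best
}
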