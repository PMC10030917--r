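#' Run a virtual-experiment file
#'
#' Executes a plain-text experiment list against a model, writing CSV
#' artifacts to an output directory.  The format mirrors the
#' virtual-experiment convention of logical-model pipelines: an optional
#' header line naming the model, then one directive per line
#' (\code{--} starts a comment; directives are case-sensitive):
#' \preformatted{
#' Sampling <nRnd> [(Input=bit, ...)]
#' Modules (NodeA, NodeB, ...)
#' Pulse1 <attractorID> <input> <duration>
#' Async_Pulse1 <attractorID> <input> <duration>
#' NonSaturating_Draw <attractorID> (Input=p, ...) [(Node KD|OE [p])]
#' NonSaturating_Stats_Scan_1Env_fnKDOE <attractorID> <input> (Input=p, ...) [(Node KD|OE)]
#' ModelErrors_Pulse1 <attractorID> <input> <duration> <nErrors>
#' }
#' Attractor IDs are 1-based positions in the canonical (sorted) attractor
#' table of the sampling run; sampling results are cached in the output
#' directory keyed by the model's content hash, so IDs remain stable
#' across reruns of an unchanged model and the cache is invalidated when
#' the model changes.  Every artifact embeds the model hash and the seed.
#'
#' @param model a \linkS4class{BooleanModel} or a path to a rule file.
#' @param experimentFile path to the experiment list.
#' @param outDir output directory (created if needed).
#' @param seed integer seed governing all randomness.
#' @param tStats live steps for statistics scans (default 5000; figure
#'   -style runs use 50000).
#' @param ensembleSize mutants per ensemble for ModelErrors directives.
#' @param signatures phenotype signatures for statistics directives.
#' @param apoptosisSignature apoptosis signature for restarts (optional).
#' @return invisibly, a list describing the artifacts written.
#' @export
runExperimentFile <- function(model, experimentFile, outDir, seed = 1L,
                              tStats = 5000L, ensembleSize = 100L,
                              signatures = NULL,
                              apoptosisSignature = NULL) {
  if (is.character(model)) model <- readBooleanNet(model)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  hash <- modelHash(model)
  lines <- readLines(experimentFile, warn = FALSE)
  artifacts <- list()
  report <- NULL
  logLines <- c(sprintf("model=%s", model@name),
                sprintf("model_hash=%s", hash),
                sprintf("seed=%d", seed),
                sprintf("package=bnsim %s",
                        as.character(utils::packageVersion("bnsim"))))

  ensureSampling <- function(clamps = NULL) {
    if (!is.null(report)) return(report)
    cache <- file.path(outDir, sprintf("attractors_%s.csv", hash))
    rep <- sampleAttractors(model, clamps = clamps)
    report <<- rep
    attractorTable(rep, path = cache, model = model, seed = seed)
    artifacts[["attractors"]] <<- cache
    rep
  }
  getAttractor <- function(id) {
    rep <- ensureSampling()
    id <- as.integer(id)
    if (id < 1L || id > length(rep@attractors))
      stop("attractor ID ", id, " not present in the sampling table (",
           length(rep@attractors), " attractors)")
    rep@attractors[[id]]
  }
  writeArtifact <- function(name, df) {
    p <- file.path(outDir, paste0(name, ".csv"))
    con <- file(p, "w")
    writeLines(c(sprintf("# model_hash=%s", hash),
                 sprintf("# seed=%d", seed)), con)
    write.csv(df, con, row.names = FALSE)
    close(con)
    artifacts[[name]] <<- p
    p
  }
  parseClamps <- function(txt) {
    if (is.na(txt) || !nzchar(trimws(txt))) return(NULL)
    txt <- gsub("[()]", "", txt)
    parts <- strsplit(txt, ",", fixed = TRUE)[[1]]
    kv <- strsplit(trimws(parts), "=", fixed = TRUE)
    setNames(as.numeric(vapply(kv, `[`, character(1), 2)),
             vapply(kv, `[`, character(1), 1))
  }

  first <- TRUE
  for (ln in seq_along(lines)) {
    raw <- trimws(lines[ln])
    if (!nzchar(raw) || startsWith(raw, "--") || startsWith(raw, "#")) next
    toks <- strsplit(raw, "\\s+")[[1]]
    dir1 <- toks[1]
    if (first && !grepl("^(Sampling|Modules|Pulse|Async_Pulse|NonSaturating|ModelErrors)",
                        dir1)) {
      # header line: model name (+ optional annotations); recorded only
      logLines <- c(logLines, sprintf("header=%s", raw))
      first <- FALSE
      next
    }
    first <- FALSE
    if (dir1 == "Sampling") {
      clamps <- parseClamps(sub("^Sampling\\s+\\S+\\s*", "", raw))
      nRnd <- as.integer(toks[2])
      cache <- file.path(outDir, sprintf("attractors_%s.csv", hash))
      report <- sampleAttractors(model, clamps = clamps, nRnd = nRnd)
      attractorTable(report, path = cache, model = model, seed = seed)
      artifacts[["attractors"]] <- cache
    } else if (dir1 == "Modules") {
      mods <- strsplit(gsub("[()]", "",
                            sub("^Modules\\s*", "", raw)), ",")[[1]]
      mods <- trimws(mods)
      iso <- isolateModule(model, mods)
      p <- file.path(outDir, "isolated_module.booleannet")
      writeBooleanNet(iso, p)
      artifacts[["isolated_module"]] <- p
      atts <- enumerateAttractors(iso)
      writeArtifact("isolated_module_attractors", attractorTable(atts))
    } else if (grepl("^(Async_)?Pulse[0-9]*$", dir1)) {
      engine <- if (startsWith(dir1, "Async_")) "biased-async" else "sync"
      a <- getAttractor(toks[2])
      px <- pulseExperiment(model, a, pulsedInput = toks[3],
                            duration = as.integer(toks[4]),
                            engine = engine)
      writeArtifact(sprintf("%s_%s_%s", dir1, toks[2], toks[3]),
                    as.data.frame(px$states))
    } else if (dir1 == "ModelErrors_Pulse1") {
      a <- getAttractor(toks[2])
      nerr <- as.integer(toks[5])
      for (kind in c("node_lock", "link_removal", "gate_flip")) {
        ens <- generateMutantEnsemble(model, kind, nerr, ensembleSize)
        acc <- NULL
        for (mut in ens) {
          px <- pulseExperiment(mut, .fullState(mut, a@states[1, ]),
                                pulsedInput = toks[3],
                                duration = as.integer(toks[4]))
          acc <- if (is.null(acc)) px$states else acc + px$states
        }
        writeArtifact(sprintf("ModelErrors_%s_%s", kind, toks[2]),
                      as.data.frame(acc / length(ens)))
      }
    } else if (dir1 == "NonSaturating_Draw") {
      a <- getAttractor(toks[2])
      parens <- regmatches(raw, gregexpr("\\(([^)]*)\\)", raw))[[1]]
      probs <- parseClamps(parens[1])
      sched <- do.call(inputSchedule, as.list(probs))
      kd <- .parseKdoeParen(parens, 2L)
      s0 <- setNames(a@states[1, ], colnames(a@states))
      res <- runTrajectory(model, s0, nSteps = 400L, engine = "sync",
                           schedule = sched, kdoe = kd)
      writeArtifact(sprintf("NonSaturating_Draw_%s", toks[2]),
                    as.data.frame(res$states))
    } else if (dir1 == "NonSaturating_Stats_Scan_1Env_fnKDOE") {
      a <- getAttractor(toks[2])
      scanned <- toks[3]
      parens <- regmatches(raw, gregexpr("\\(([^)]*)\\)", raw))[[1]]
      probs <- parseClamps(parens[1])
      kd <- .parseKdoeParen(parens, 2L)
      df <- scanEnvironment(model, a, scannedInput = scanned,
                            baseProbs = probs, kdoe = kd,
                            kdLevels = if (is.null(kd)) NULL
                                       else seq(0, 1, by = 0.25),
                            signatures = signatures,
                            apoptosisSignature = apoptosisSignature,
                            tMinLive = tStats)
      writeArtifact(sprintf("Stats_Scan_%s_%s", toks[2], scanned), df)
    } else {
      stop("line ", ln, ": unknown directive '", dir1, "'")
    }
  }
  if (is.null(report)) ensureSampling()
  writeLines(logLines, file.path(outDir, "run_log.txt"))
  artifacts[["run_log"]] <- file.path(outDir, "run_log.txt")
  invisible(artifacts)
}

.parseKdoeParen <- function(parens, idx) {
  if (length(parens) < idx) return(NULL)
  body <- gsub("[()]", "", parens[idx])
  toks <- strsplit(trimws(body), "\\s+")[[1]]
  if (length(toks) < 2L || !toks[2] %in% c("KD", "OE")) return(NULL)
  kdoeSpec(node = toks[1], mode = toks[2],
           prob = if (length(toks) >= 3L) as.numeric(toks[3]) else 1)
}
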