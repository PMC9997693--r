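## Plain comma-delimited text as the canonical interchange: trials.csv,
## blocks.csv, spikes.csv, neurons.csv, ground_truth.csv, meta.json.
## Times are seconds on a session clock starting at 0, written at fixed
## 6-decimal precision so write -> read round-trips are stable.

bundleRegions <- function(meta) {
  if (!is.null(meta$regions)) meta$regions else TASK_REGIONS
}

## Schema validation shared by the class validity and readBundle;
## returns a character vector of messages (empty when valid), each
## naming the offending rows.
validateBundleTables <- function(trials, blocks, spikes, neurons,
                                 regions = TASK_REGIONS) {
  msgs <- character()
  needT <- c("trial_idx", "block_idx", "active_sequence", "outcome",
             "t_trial_start", "t_feedback_off")
  missT <- setdiff(needT, names(trials))
  if (length(missT))
    msgs <- c(msgs, paste0("trials: missing column(s) ",
                           paste(missT, collapse = ", ")))
  needS <- c("neuron_id", "region", "spike_time_s")
  missS <- setdiff(needS, names(spikes))
  if (length(missS))
    msgs <- c(msgs, paste0("spikes: missing column(s) ",
                           paste(missS, collapse = ", ")))
  needN <- c("neuron_id", "region")
  missN <- setdiff(needN, names(neurons))
  if (length(missN))
    msgs <- c(msgs, paste0("neurons: missing column(s) ",
                           paste(missN, collapse = ", ")))
  if (length(msgs)) return(msgs)

  if (nrow(spikes)) {
    bad <- unlist(lapply(split(seq_len(nrow(spikes)), spikes$neuron_id),
                         function(ix) {
                           d <- diff(spikes$spike_time_s[ix])
                           ix[which(d <= 0) + 1]
                         }))
    if (length(bad))
      msgs <- c(msgs, paste0("spikes: times not strictly increasing at row(s) ",
                             paste(sort(bad), collapse = ", ")))
    unknown <- which(!spikes$neuron_id %in% neurons$neuron_id)
    if (length(unknown))
      msgs <- c(msgs, paste0("spikes: neuron_id not in neurons table at row(s) ",
                             paste(utils::head(unknown, 10), collapse = ", ")))
  }
  badReg <- which(!neurons$region %in% regions)
  if (length(badReg))
    msgs <- c(msgs, paste0("neurons: unknown region at row(s) ",
                           paste(badReg, collapse = ", ")))
  if (nrow(trials)) {
    span <- max(trials$t_feedback_off)
    tcols <- grep("^t_", names(trials), value = TRUE)
    for (cc in tcols) {
      bad <- which(!is.na(trials[[cc]]) &
                     (trials[[cc]] < 0 | trials[[cc]] > span + 1e-9))
      if (length(bad))
        msgs <- c(msgs, paste0("trials: ", cc,
                               " outside the session span at row(s) ",
                               paste(bad, collapse = ", ")))
    }
  }
  msgs
}

#' Assemble a DatasetBundle from simulated objects
#'
#' @param session a [SeqSession-class].
#' @param trains list of [SpikeTrain-class] objects.
#' @param profiles optional list of [TuningProfile-class] ground truth.
#' @param meta list of provenance fields (seed, config hash, ...);
#'   the package version is added automatically.
#' @return a [DatasetBundle-class].
#' @export
makeBundle <- function(session, trains, profiles = NULL, meta = list()) {
  emptySpikes <- data.frame(neuron_id = character(0), region = character(0),
                            spike_time_s = numeric(0))
  emptyNeurons <- data.frame(neuron_id = character(0), region = character(0))
  spikes <- do.call(rbind, lapply(trains, function(tr) {
    if (!length(tr@times))
      return(data.frame(neuron_id = character(0), region = character(0),
                        spike_time_s = numeric(0)))
    data.frame(neuron_id = tr@neuronId, region = tr@region,
               spike_time_s = tr@times, stringsAsFactors = FALSE)
  }))
  neurons <- do.call(rbind, lapply(trains, function(tr)
    data.frame(neuron_id = tr@neuronId, region = tr@region,
               stringsAsFactors = FALSE)))
  if (is.null(spikes)) spikes <- emptySpikes
  if (is.null(neurons)) neurons <- emptyNeurons
  gt <- if (is.null(profiles)) {
    data.frame(neuron_id = character(0), field = character(0),
               level = character(0), value = numeric(0))
  } else {
    do.call(rbind, lapply(profiles, profileToTable))
  }
  meta$package_version <- as.character(utils::packageVersion("seqpev"))
  new("DatasetBundle", trials = trialTable(session),
      blocks = blockTable(session),
      spikes = spikes, neurons = neurons, groundTruth = gt, meta = meta)
}

## long-format serialization of a tuning profile
profileToTable <- function(p) {
  rows <- list(data.frame(neuron_id = p@neuronId, field = "baseline",
                          level = "", value = p@baseline),
               data.frame(neuron_id = p@neuronId, field = "latency",
                          level = "", value = p@latency),
               data.frame(neuron_id = p@neuronId, field = "duration",
                          level = "", value = p@duration))
  for (f in names(p@gains)) {
    g <- p@gains[[f]]
    if (is.matrix(g)) {
      for (i in rownames(g)) for (j in colnames(g))
        if (abs(g[i, j] - 1) > 1e-12)
          rows[[length(rows) + 1]] <-
            data.frame(neuron_id = p@neuronId, field = f,
                       level = paste0(i, ":", j), value = g[i, j])
    } else {
      for (lv in names(g))
        if (abs(g[[lv]] - 1) > 1e-12)
          rows[[length(rows) + 1]] <-
            data.frame(neuron_id = p@neuronId, field = f, level = lv,
                       value = g[[lv]])
    }
  }
  do.call(rbind, rows)
}

formatTimes <- function(df) {
  for (cc in grep("^(t_|spike_time_s$)", names(df), value = TRUE))
    df[[cc]] <- ifelse(is.na(df[[cc]]), NA,
                       formatC(df[[cc]], format = "f", digits = 6))
  df
}

#' Write a DatasetBundle to a directory of delimited text files
#'
#' Writes `trials.csv`, `blocks.csv`, `spikes.csv`, `neurons.csv`,
#' `ground_truth.csv` (when ground truth is present) and `meta.json`
#' with deterministic column order and times at 6-decimal precision, so
#' two consecutive writes of the same bundle are byte-identical.
#'
#' @param bundle a [DatasetBundle-class].
#' @param dir output directory (created if missing).
#' @param force overwrite existing files (default: refuse).
#' @return invisibly, the paths written.
#' @export
writeBundle <- function(bundle, dir, force = FALSE) {
  stopifnot(is(bundle, "DatasetBundle"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c("trials.csv", "blocks.csv", "spikes.csv",
                            "neurons.csv", "meta.json"))
  if (nrow(bundle@groundTruth))
    paths <- c(paths, file.path(dir, "ground_truth.csv"))
  exists <- file.exists(paths)
  if (any(exists) && !force)
    stop("refusing to overwrite ",
         paste(basename(paths[exists]), collapse = ", "),
         " (use force = TRUE)")
  utils::write.csv(formatTimes(bundle@trials),
                   file.path(dir, "trials.csv"), row.names = FALSE)
  utils::write.csv(bundle@blocks, file.path(dir, "blocks.csv"),
                   row.names = FALSE)
  utils::write.csv(formatTimes(bundle@spikes),
                   file.path(dir, "spikes.csv"), row.names = FALSE)
  utils::write.csv(bundle@neurons, file.path(dir, "neurons.csv"),
                   row.names = FALSE)
  if (nrow(bundle@groundTruth))
    utils::write.csv(bundle@groundTruth,
                     file.path(dir, "ground_truth.csv"), row.names = FALSE)
  jsonlite::write_json(bundle@meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(paths)
}

#' Read and validate a DatasetBundle from a directory
#'
#' Schema violations (missing columns, unsorted spike times, unknown
#' regions, timestamps outside the session span) are reported with the
#' offending row numbers.
#'
#' @param dir directory written by [writeBundle()].
#' @return a [DatasetBundle-class].
#' @export
readBundle <- function(dir) {
  readTab <- function(name, required = TRUE) {
    path <- file.path(dir, name)
    if (!file.exists(path)) {
      if (required) stop("missing file: ", path)
      return(NULL)
    }
    utils::read.csv(path, stringsAsFactors = FALSE)
  }
  trials <- readTab("trials.csv")
  blocks <- readTab("blocks.csv")
  spikes <- readTab("spikes.csv")
  neurons <- readTab("neurons.csv")
  gt <- readTab("ground_truth.csv", required = FALSE)
  metaPath <- file.path(dir, "meta.json")
  meta <- if (file.exists(metaPath))
    jsonlite::read_json(metaPath, simplifyVector = TRUE) else list()
  if (is.null(gt))
    gt <- data.frame(neuron_id = character(0), field = character(0),
                     level = character(0), value = numeric(0))
  for (cc in c("is_block_transition_trial", "is_switch_trial"))
    if (cc %in% names(trials)) trials[[cc]] <- as.logical(trials[[cc]])
  msgs <- validateBundleTables(trials, blocks, spikes, neurons,
                               regions = bundleRegions(meta))
  if (length(msgs))
    stop("bundle validation failed:\n  ", paste(msgs, collapse = "\n  "))
  new("DatasetBundle", trials = trials, blocks = blocks, spikes = spikes,
      neurons = neurons, groundTruth = gt, meta = as.list(meta))
}

#' @describeIn readBundle rebuild the list of [SpikeTrain-class] objects
#'   from a bundle.
#' @param bundle a [DatasetBundle-class].
#' @export
bundleSpikeTrains <- function(bundle) {
  dur <- max(bundle@trials$t_feedback_off)
  ids <- bundle@neurons$neuron_id
  lapply(seq_along(ids), function(i) {
    sel <- bundle@spikes$neuron_id == ids[i]
    spikeTrain(ids[i], bundle@neurons$region[i],
               bundle@spikes$spike_time_s[sel], dur)
  })
}
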