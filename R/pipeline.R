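#' Assemble and validate a pipeline run configuration
#'
#' One hierarchical document holding every stage's parameters. Unknown keys
#' are rejected; every random operation derives its seed from the single
#' `seed` entry.
#'
#' @param ... named overrides, nested by section (`synth`, `analysis`,
#'   `classify`, `response`), plus top-level `seed` and `out_dir`.
#' @return object of class `run_config`.
#' @export
run_config <- function(...) {
  defaults <- list(
    version = "1",
    seed = 1L,
    out_dir = NULL,
    synth = list(n_subjects = 4, durations = c(R = 300, A = 390), fs = 100,
                 render_signals = TRUE,
                 state_shift = default_state_shift()),
    analysis = list(analysis_durations = c(R = 290, A = 390),
                    twin = 90, tslide = 10, reject_head = 10),
    classify = list(scheme = "personalized", model = "knn",
                    feature_set = "all", train_window = 180),
    response = list(pre_s = 5, post_s = 10, rt_bin = 0.1, max_rt = 1))
  ov <- list(...)
  check <- function(def, new, path = "") {
    bad <- setdiff(names(new), names(def))
    if (length(bad))
      stop("unknown config key(s): ",
           paste0(path, bad, collapse = ", "))
  }
  check(defaults, ov)
  for (sec in intersect(names(ov), c("synth", "analysis", "classify",
                                     "response")))
    check(defaults[[sec]], ov[[sec]], paste0(sec, "$"))
  cfg <- modifyList(defaults, ov)
  if (cfg$analysis$twin <= cfg$analysis$tslide)
    stop("invalid epoch spec: twin must exceed tslide")
  structure(cfg, class = "run_config")
}

#' Write a session to a directory of CSV files
#'
#' Lossless plain-text serialization of a [raw_channel_set()] and its event
#' tables: `channels.csv` (four channel columns at full float precision),
#' `meta.csv` (`fs`, `t0`), and optional `truth_beats.csv`,
#' `truth_breaths.csv`, `task_events.csv`.
#'
#' @param raw a [raw_channel_set()].
#' @param path output directory (created if absent).
#' @param task_log optional `task_event_log`.
#' @return `path`, invisibly.
#' @export
write_session <- function(raw, path, task_log = NULL) {
  stopifnot(inherits(raw, "raw_channel_set"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  fmt <- function(x) {
    out <- formatC(x, digits = 17, format = "g")
    out[is.na(x)] <- "NA"
    out
  }
  ch <- as.data.frame(lapply(raw$channels, fmt))
  write.csv(ch, file.path(path, "channels.csv"), row.names = FALSE,
            quote = FALSE)
  write.csv(data.frame(fs = fmt(raw$fs), t0 = fmt(raw$t0)),
            file.path(path, "meta.csv"), row.names = FALSE, quote = FALSE)
  wr_tab <- function(tab, name) {
    num <- vapply(tab, is.numeric, TRUE)
    tab[num] <- lapply(tab[num], fmt)
    write.csv(tab, file.path(path, name), row.names = FALSE, quote = FALSE)
  }
  if (!is.null(raw$truth$beats)) wr_tab(raw$truth$beats, "truth_beats.csv")
  if (!is.null(raw$truth$breaths))
    wr_tab(raw$truth$breaths, "truth_breaths.csv")
  if (!is.null(task_log)) wr_tab(task_log, "task_events.csv")
  invisible(path)
}

#' Read a session written by [write_session()]
#'
#' @param path session directory.
#' @return list with `raw` (a [raw_channel_set()]) and `task_log` (or `NULL`).
#' @export
read_session <- function(path) {
  meta_f <- file.path(path, "meta.csv")
  if (!file.exists(meta_f)) stop("schema error: missing meta.csv")
  meta <- read.csv(meta_f)
  if (!all(c("fs", "t0") %in% names(meta)))
    stop("schema error: meta.csv must name fields 'fs' and 't0'")
  ch <- read.csv(file.path(path, "channels.csv"))
  nm <- c("thorax_amp", "thorax_phase", "abd_amp", "abd_phase")
  miss <- setdiff(nm, names(ch))
  if (length(miss)) stop("schema error: missing channel ",
                         paste(miss, collapse = ", "))
  truth <- list()
  bf <- file.path(path, "truth_beats.csv")
  if (file.exists(bf)) {
    truth$beats <- read.csv(bf)
    class(truth$beats) <- c("beat_truth", "data.frame")
  }
  rf <- file.path(path, "truth_breaths.csv")
  if (file.exists(rf)) {
    truth$breaths <- read.csv(rf)
    class(truth$breaths) <- c("breath_truth", "data.frame")
  }
  tf <- file.path(path, "task_events.csv")
  task_log <- NULL
  if (file.exists(tf)) {
    task_log <- read.csv(tf)
    class(task_log) <- c("task_event_log", "data.frame")
  }
  list(raw = raw_channel_set(as.list(ch[nm]), fs = as.numeric(meta$fs),
                             t0 = as.numeric(meta$t0),
                             truth = if (length(truth)) truth else NULL),
       task_log = task_log)
}

# Signal chain for one rendered session: channel selection, extraction,
# beat/breath detection.
process_session <- function(raw) {
  resp <- select_best_channel(raw, "respiration")
  hb <- select_best_channel(raw, "heartbeat")
  h2 <- refilter_second_harmonic(hb)
  beats <- detect_ibi(h2)
  breaths <- detect_breaths(resp)
  list(resp = resp, heartbeat = hb, h2 = h2, beats = beats,
       breaths = breaths)
}

#' Run the full analysis pipeline
#'
#' Simulate (cohort) -> process (channel selection + extraction) -> events
#' (beat/breath detection) -> features (sliding epochs) -> classify ->
#' respond, under one seeded configuration. Outputs are written as CSV under
#' `config$out_dir` when set, and a manifest of per-stage counts, dropped-item
#' logs and output-file MD5 hashes is returned; re-running an identical
#' configuration reproduces identical hashes.
#'
#' @param config a [run_config()].
#' @return object of class `run_manifest`.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  seed <- config$seed
  cohort <- generate_cohort(config$synth$n_subjects, seed = seed,
                            state_shift_spec = config$synth$state_shift,
                            durations = config$synth$durations,
                            fs = config$synth$fs,
                            render_signals = config$synth$render_signals)
  spec <- epoch_spec(config$analysis$twin, config$analysis$tslide,
                     config$analysis$reject_head)
  dropped <- list()
  tabs <- list()
  for (i in seq_along(cohort)) {
    subj <- cohort[[i]]
    for (lab in c("R", "A")) {
      ses <- subj[[lab]]
      dur <- min(config$analysis$analysis_durations[[lab]],
                 attr(ses$breaths, "duration") %||% Inf)
      ev <- if (!is.null(ses$raw)) process_session(ses$raw)
            else list(beats = truth_beat_series(ses$beats),
                      breaths = truth_breath_series(ses$breaths))
      tab <- feature_matrix(ev$beats, ev$breaths, dur, spec, label = lab,
                            subject_id = subj$profile$subject_id)
      if (length(attr(tab, "dropped")))
        dropped[[paste(subj$profile$subject_id, lab)]] <- attr(tab, "dropped")
      tabs[[paste(i, lab)]] <- tab
      if (lab == "A") subj$events_A <- ev
      if (lab == "R") subj$events_R <- ev
      cohort[[i]] <- subj
    }
  }
  table <- do.call(rbind, tabs)
  class(table) <- c("epoch_features", "data.frame")
  plan <- build_split(table, config$classify$scheme,
                      train_window = config$classify$train_window,
                      twin = config$analysis$twin, seed = child_seed(seed, 91))
  report <- train_eval(table, plan, model_name = config$classify$model,
                       feature_set = config$classify$feature_set,
                       seed = child_seed(seed, 92))
  wspec <- event_window_spec(config$response$pre_s, config$response$post_s,
                             config$response$rt_bin, config$response$max_rt)
  response <- lapply(cohort, function(subj) {
    list(subject_id = subj$profile$subject_id,
         scores = score_events(subj$task_log),
         session = session_hr_ratio(subj$events_R$beats, subj$events_A$beats,
                                    subj$task_log),
         by_rt = hr_ratio_by_event(subj$events_A$beats, subj$task_log, wspec),
         timeline = attention_timeline(subj$task_log))
  })
  files <- character(0)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    fp <- file.path(config$out_dir, "features.csv")
    write.csv(table, fp, row.names = FALSE)
    rp <- file.path(config$out_dir, "report.csv")
    write.csv(data.frame(scheme = report$scheme, model = report$model,
                         accuracy = report$accuracy,
                         sensitivity = report$sensitivity,
                         specificity = report$specificity), rp,
              row.names = FALSE)
    files <- c(fp, rp)
  }
  hashes <- if (length(files)) tools::md5sum(files) else character(0)
  structure(list(
    config = config,
    config_hash = unname(tools::md5sum(write_config_tmp(config))),
    n_sessions = 2L * length(cohort),
    n_epochs = nrow(table),
    n_features = sum(colnames(table) %in% feature_names()),
    dropped = dropped,
    report = report,
    response = response,
    output_hashes = hashes), class = "run_manifest")
}

write_config_tmp <- function(config) {
  f <- tempfile(fileext = ".yaml")
  yaml::write_yaml(unclass(config), f)
  f
}

#' Promote generator truth tables to detection-output containers
#'
#' Wrap a `beat_truth` / `breath_truth` table as the corresponding
#' `beat_series` / `breath_series`, for protocol-level experiments that work
#' from ground-truth events without rendering and re-detecting waveforms.
#'
#' @param bt a [generate_beat_truth()] or [generate_breath_truth()] table.
#' @return a `beat_series` / `breath_series`.
#' @export
truth_beat_series <- function(bt) {
  keep <- !is.na(bt$ibi)
  new_beat_series(bt$time[keep], bt$ibi[keep])
}

#' @rdname truth_beat_series
#' @export
truth_breath_series <- function(bt) {
  keep <- !is.na(bt$iri)
  out <- data.frame(tb = bt$tb[keep], te = bt$te[keep],
                    r_tb = 0, r_te = bt$iv[keep],
                    iri = bt$iri[keep], ii = bt$ii[keep], ei = bt$ei[keep],
                    iv = bt$iv[keep])
  attr(out, "n_dropped") <- 0L
  class(out) <- c("breath_series", "data.frame")
  out
}

#' @export
print.run_manifest <- function(x, ...) {
  cat(sprintf(
    "run_manifest: %d sessions, %d epochs x %d features\n",
    x$n_sessions, x$n_epochs, x$n_features))
  print(x$report)
  invisible(x)
}
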