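#' Write calcium line-scan pairs to a directory
#'
#' Writes each ROI/background trace pair as CSVs plus a `manifest.json`
#' (protocol `ca_linescan`) recording the pairing and the stimulus time, in
#' the same dialect [read_trace()] consumes.
#'
#' @param scans List of `list(roi = trace, background = trace)` pairs, as
#'   produced by [simulate_ca_linescan()].
#' @param dir Output directory.
#' @param stim_time_s Stimulus time, s.
#' @return Invisibly, the manifest path.
#' @export
write_ca_scans <- function(scans, dir, stim_time_s) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  pairs <- vector("list", length(scans))
  for (i in seq_along(scans)) {
    rf <- sprintf("roi_%03d.csv", i)
    bf <- sprintf("bg_%03d.csv", i)
    write_trace(scans[[i]]$roi, file.path(dir, rf))
    write_trace(scans[[i]]$background, file.path(dir, bf))
    pairs[[i]] <- list(roi = rf, background = bf)
  }
  man <- list(protocol = "ca_linescan", stimulus_times = stim_time_s,
              pairs = pairs)
  mp <- file.path(dir, "manifest.json")
  jsonlite::write_json(man, mp, auto_unbox = TRUE, digits = NA)
  invisible(mp)
}

#' Read calcium line-scan pairs from a manifest
#'
#' @param manifest Path to a `manifest.json` written by [write_ca_scans()].
#' @return A list with `scans` (roi/background trace pairs) and
#'   `stim_time_s`.
#' @export
read_ca_scans <- function(manifest) {
  man <- jsonlite::read_json(manifest, simplifyVector = FALSE)
  dir <- dirname(manifest)
  scans <- lapply(man$pairs, function(p)
    list(roi = read_trace(file.path(dir, p$roi)),
         background = read_trace(file.path(dir, p$background))))
  list(scans = scans, stim_time_s = man$stimulus_times[[1]])
}

analyze_manifest <- function(manifest, config) {
  man <- jsonlite::read_json(manifest, simplifyVector = TRUE)
  protocol <- man$protocol
  if (protocol == "ca_linescan") {
    cs <- read_ca_scans(manifest)
    qc <- lapply(cs$scans, function(p) imaging_qc(p$roi, cs$stim_time_s))
    keep <- !vapply(qc, `[[`, logical(1), "excluded")
    if (!any(keep))
      stop("all line scans excluded by imaging QC in ", manifest)
    dffs <- lapply(cs$scans[keep], function(p)
      dff(p$roi, p$background, cs$stim_time_s))
    avg <- average_transients(dffs, cs$stim_time_s)
    return(list(protocol = protocol, peak_dff = avg$peak_dff,
                n_scans_averaged = avg$n_scans_averaged,
                n_excluded = sum(!keep), flag = avg$flag))
  }
  ss <- read_sweep_set(manifest)
  if (protocol == "train_60Hz_30") {
    qsize <- config$quantal_size
    if (is.null(qsize)) stop("config$quantal_size required for train analysis")
    tr <- analyze_train(ss, quantal_size = qsize,
                        n_fit = if (is.null(config$n_fit)) 10
                                else config$n_fit)
    return(list(protocol = protocol,
                amplitudes = unname(tr$amplitudes),
                cumulative = unname(tr$cumulative),
                fit_slope = tr$fit_slope,
                fit_intercept_nA = tr$fit_intercept_nA,
                rrp_quanta = tr$rrp_quanta, p_train = tr$p_train,
                decay_tau = tr$decay$tau, flags = as.list(tr$flags)))
  }
  if (protocol == "paired_pulse") {
    pprs <- vapply(ss$sweeps, function(s)
      paired_pulse_ratio(s, ss$stimulus_times)$ppr, numeric(1))
    pprs <- pprs[is.finite(pprs)]
    return(list(protocol = protocol, ppr_mean = mean(pprs),
                ppr_sem = if (length(pprs) > 1)
                  stats::sd(pprs) / sqrt(length(pprs)) else NA_real_,
                n = length(pprs)))
  }
  if (protocol == "single_AP") {
    amps <- vapply(ss$sweeps, function(s)
      train_amplitudes(s, ss$stimulus_times)[1], numeric(1))
    out <- list(protocol = protocol, amp_mean = mean(amps),
                amp_sem = if (length(amps) > 1)
                  stats::sd(amps) / sqrt(length(amps)) else NA_real_,
                n = length(amps))
    if (!is.null(config$quantal_size))
      out$quantal_content <- mean(amps) / config$quantal_size
    return(out)
  }
  if (protocol == "arch_spot") {
    stim <- ss$stimulus_times[1]
    res <- lapply(ss$sweeps, subtract_photobleach, stim_time_s = stim)
    acc <- reject_extra_ap(res, stim)
    if (!length(acc$accepted)) stop("no accepted sweeps in ", manifest)
    ap <- average_ap(acc$accepted)
    return(list(protocol = protocol, full_width_ms = unname(ap$full_width_ms),
                whm_ms = unname(ap$whm_ms), n_sweeps = ap$n_sweeps,
                n_rejected = acc$n_rejected))
  }
  stop("unknown protocol in manifest: ", protocol)
}

#' Run the full analysis pipeline over a data directory
#'
#' Finds every `manifest.json` under `config$input_dir` and dispatches each
#' to the stage its protocol names (train, paired-pulse, single-AP, calcium
#' line-scan, Arch spot imaging). Per-manifest results are written as JSON
#' under `config$output_dir` (mirroring the input layout) together with a
#' `summary.json`. A stage failure is recorded in a `<name>.failed` marker
#' and the run is flagged; already-computed outputs are preserved.
#'
#' Outputs contain no timestamps, so re-running with the same inputs and
#' configuration reproduces byte-identical JSON.
#'
#' @param config A list (or path to a JSON config file) with `input_dir`,
#'   `output_dir`, and optional analysis parameters (`quantal_size` in nA
#'   for train/single-AP stages, `n_fit`).
#' @return Invisibly, a list with `results` (per-manifest), `failures`, and
#'   `ok` (TRUE iff no stage errored).
#' @export
run_pipeline <- function(config) {
  if (is.character(config))
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  if (is.null(config$input_dir) || !dir.exists(config$input_dir))
    stop("config$input_dir must name an existing directory")
  if (is.null(config$output_dir)) stop("config$output_dir is required")
  manifests <- sort(list.files(config$input_dir, pattern = "^manifest\\.json$",
                               recursive = TRUE, full.names = TRUE))
  if (!length(manifests))
    stop("no manifest.json found under ", config$input_dir)
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  results <- list()
  failures <- character(0)
  for (mp in manifests) {
    name <- basename(dirname(mp))
    out <- tryCatch(analyze_manifest(mp, config), error = function(e) e)
    if (inherits(out, "error")) {
      failures <- c(failures, name)
      writeLines(conditionMessage(out),
                 file.path(config$output_dir, paste0(name, ".failed")))
      message("stage failed: ", name, ": ", conditionMessage(out))
    } else {
      results[[name]] <- out
      jsonlite::write_json(out,
                           file.path(config$output_dir,
                                     paste0(name, ".json")),
                           auto_unbox = TRUE, digits = NA, null = "null")
    }
  }
  summary <- list(n_manifests = length(manifests),
                  n_failed = length(failures), failed = failures,
                  config = config[setdiff(names(config),
                                          c("input_dir", "output_dir"))])
  jsonlite::write_json(summary, file.path(config$output_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(results = results, failures = failures,
                 ok = length(failures) == 0))
}
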