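config_keys <- list(
  # snippeting
  block_size_s = c("detection", "blockLen"),
  end_padding_ms = c("detection", "pad", 1e-3),
  pre_samples = c("detection", "prePeak"),
  post_samples = c("detection", "postPeak"),
  detect_threshold_uv = c("detection", "detectThreshold"),
  detect_threshold_mad = c("detection", "thresholdMadMultiple"),
  return_threshold_mad = c("detection", "returnThreshold"),
  return_samples = c("detection", "returnSamples"),
  band_low_hz = c("detection", "band", NA, 1),
  band_high_hz = c("detection", "band", NA, 2),
  # step 1
  spikes_per_block = c("step1", "blockSize"),
  spc_t_max = c("step1", "tMax"),
  merge_threshold_a = c("step1", "mergeThreshold"),
  min_cluster_size = c("step1", "minClusterSize"),
  n_scales = c("step1", "nScales"),
  # step 2
  centroids_per_block = c("step2", "centroidsPerBlock"),
  trees_per_block = c("step2", "treesPerIlp"),
  block_overlap = c("step2", "ilpOverlap"),
  sigmoid_s = c("step2", "sigmoidS"),
  sigmoid_k = c("step2", "sigmoidK"),
  link_threshold = c("step2", "linkThreshold"),
  straggler_threshold = c("step2", "stragglerThreshold"),
  spc_t_max_step2 = c("step2", "tMax"),
  dist_scale = c("step2", "distScale"),
  # simulator
  duration_s = c("sim", "duration"),
  n_tetrodes = c("sim", "nTetrodes"),
  units_per_tetrode = c("sim", "unitsPerTetrode"),
  alpha = c("sim", "alpha"),
  beta_per_s = c("sim", "beta"),
  b_min_uv = c("sim", "bMin"),
  refractory_ms = c("sim", "refractory", 1e-3),
  background_units = c("sim", "backgroundUnits"),
  background_rate_hz = c("sim", "backgroundRate"),
  noise_mad_uv = c("sim", "noiseMad"),
  sample_rate_hz = c("sim", "sampleRate"),
  # misc
  seed = c("misc", "seed"),
  spc_method = c("misc", "method")
)

#' Read a flat pipeline configuration file
#'
#' Human-editable \code{key = value} lines (\code{#} comments allowed), with
#' keys named after the algorithm's parameter table (e.g.
#' \code{spikes_per_block}, \code{merge_threshold_a}, \code{sigmoid_k}).
#' Unknown keys are rejected, and every value is validated through the
#' corresponding parameter class.
#'
#' @param path config file path, or \code{NULL} for defaults.
#' @return list with \code{detection}, \code{step1}, \code{step2} parameter
#'   objects, a \code{sim} settings list, plus \code{seed} and \code{method}.
#' @export
readPipelineConfig <- function(path = NULL) {
  vals <- list()
  if (!is.null(path)) {
    lines <- readLines(path, warn = FALSE)
    lines <- sub("#.*$", "", lines)
    lines <- trimws(lines)
    lines <- lines[nzchar(lines)]
    for (ln in lines) {
      kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
      if (length(kv) != 2) stop("malformed config line: ", ln)
      key <- trimws(kv[1])
      if (!key %in% names(config_keys)) stop("unknown config key: ", key)
      vals[[key]] <- trimws(kv[2])
    }
  }
  det <- detectionParams()
  s1 <- collapseParams()
  s2 <- fusionParams()
  sim <- list()
  misc <- list(seed = NULL, method = "spc")
  for (key in names(vals)) {
    spec <- config_keys[[key]]
    target <- spec[1]
    slot_name <- spec[2]
    mult <- if (length(spec) >= 3 && !is.na(spec[3])) as.numeric(spec[3]) else 1
    raw <- vals[[key]]
    v <- if (key == "spc_method") raw else as.numeric(raw) * mult
    if (target == "detection") {
      cur <- slot(det, slot_name)
      if (length(spec) >= 4) cur[as.integer(spec[4])] <- v else
        cur <- if (is.integer(cur)) as.integer(v) else v
      slot(det, slot_name) <- cur
    } else if (target == "step1") {
      cur <- slot(s1, slot_name)
      slot(s1, slot_name) <- if (is.integer(cur)) as.integer(v) else v
    } else if (target == "step2") {
      cur <- slot(s2, slot_name)
      slot(s2, slot_name) <- if (is.integer(cur)) as.integer(v) else v
    } else if (target == "sim") {
      sim[[slot_name]] <- v
    } else {
      misc[[slot_name]] <- if (key == "seed") as.integer(v) else v
    }
  }
  validObject(det)
  validObject(s1)
  validObject(s2)
  list(detection = det, step1 = s1, step2 = s2, sim = sim,
       seed = misc$seed, method = misc$method)
}
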