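#' Write a synthetic dataset to disk in standard formats
#'
#' Volumes as one 4D NIfTI per run, events as tab-separated text
#' (onset_s, run, task, item), motion as whitespace-delimited 6-column
#' text, ROI labels and gray mask as integer NIfTI, physiological traces as
#' tab-separated text with a trigger column, and ground truth as JSON.
#'
#' @param dataset a `speech_dataset`.
#' @param dir output directory (created if needed).
#' @param write_volumes write the (large) 4D volumes (default TRUE).
#' @param write_physio write the physiological traces (default FALSE; they
#'   are large at 1000 Hz).
#' @return invisibly, the vector of files written.
#' @export
write_dataset <- function(dataset, dir, write_volumes = TRUE,
                          write_physio = FALSE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- dataset$config
  files <- character(0)
  vd <- rep(cfg$voxel_mm, 3)
  f <- file.path(dir, "gray_mask.nii")
  RNifti::writeNifti(RNifti::asNifti(array(as.integer(dataset$gray_mask),
                                           dim(dataset$gray_mask)),
                                     pixdim = vd), f)
  files <- c(files, f)
  f <- file.path(dir, "roi_labels.nii")
  lab <- dataset$roi_labels
  RNifti::writeNifti(RNifti::asNifti(array(as.integer(lab), dim(lab)),
                                     pixdim = vd), f)
  files <- c(files, f)
  for (s in seq_along(dataset$subjects)) {
    sub <- dataset$subjects[[s]]
    f <- file.path(dir, sprintf("sub%02d_events.tsv", s))
    utils::write.table(sub$events, f, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    files <- c(files, f)
    for (r in seq_along(sub$volumes)) {
      f <- file.path(dir, sprintf("sub%02d_run%d_motion.txt", s, r))
      utils::write.table(format(sub$motion[[r]], digits = 8), f,
                         sep = " ", quote = FALSE, row.names = FALSE,
                         col.names = FALSE)
      files <- c(files, f)
      if (write_volumes) {
        f <- file.path(dir, sprintf("sub%02d_run%d_bold.nii", s, r))
        RNifti::writeNifti(RNifti::asNifti(sub$volumes[[r]], pixdim = vd), f)
        files <- c(files, f)
      }
      if (write_physio) {
        p <- sub$physio[[r]]
        trig <- integer(length(p$respiration))
        trig[p$tr_triggers] <- 1L
        f <- file.path(dir, sprintf("sub%02d_run%d_physio.tsv", s, r))
        utils::write.table(
          data.frame(respiration = p$respiration,
                     chin_pressure = p$chin_pressure, trigger = trig),
          f, sep = "\t", quote = FALSE, row.names = FALSE)
        files <- c(files, f)
      }
    }
  }
  f <- file.path(dir, "ground_truth.json")
  gt <- dataset$ground_truth
  jsonlite::write_json(
    list(effect_size = gt$effect_size,
         resp_irf_peak_s = gt$resp_irf_peak_s,
         pattern_voxels = gt$pattern_voxels,
         pattern_maps = gt$pattern_maps,
         seed_regions = gt$seed_regions,
         coupled_regions = gt$coupled_regions),
    f, auto_unbox = TRUE, digits = NA)
  files <- c(files, f)
  invisible(files)
}

#' Read a trial event table
#' @param path tab-separated file with columns onset_s, run, task, item.
#' @return data frame.
#' @export
read_events <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}

#' Read a motion-parameter table
#' @param path whitespace-delimited 6-column text file.
#' @return n_vol x 6 numeric matrix.
#' @export
read_motion <- function(path) {
  m <- as.matrix(utils::read.table(path, header = FALSE))
  if (ncol(m) != 6) stop("motion file must have 6 columns")
  colnames(m) <- c("tx", "ty", "tz", "rx", "ry", "rz")
  m
}
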