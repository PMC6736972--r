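#' Write a trial table as per-subject TSV files
#'
#' One tab-separated file per subject (`sub-XX_trials.tsv`) plus a JSON
#' column dictionary.
#'
#' @param trials trial table.
#' @param dir output directory (created if needed).
#' @return invisibly, the written file paths.
#' @export
write_trials_tsv <- function(trials, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (s in sort(unique(trials$subject))) {
    f <- file.path(dir, sprintf("sub-%02d_trials.tsv", s))
    utils::write.table(trials[trials$subject == s, , drop = FALSE], f,
                       sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, f)
  }
  dict <- list(
    subject = "subject index", run = "run index (1-6)",
    trial = "trial index within subject",
    social = "social cue code (-1 low, +1 high)",
    cs = "conditioned stimulus code (-1 low, +1 high)",
    temp = "stimulation temperature (degrees C)",
    temp_code = "temperature coded -1/0/+1",
    t_social = "within-social-condition trial counter",
    t_cs = "within-CS-condition trial counter",
    expect = "expectation rating (0-100)", pain = "pain rating (0-100)",
    pain_raw = "pain before clipping", pain_eps = "pain residual noise",
    scr = "single-trial SCR amplitude (a.u.)")
  jf <- file.path(dir, "trials_columns.json")
  jsonlite::write_json(dict, jf, auto_unbox = TRUE, pretty = TRUE)
  invisible(c(paths, jf))
}

#' Write brain data as NIfTI volumes
#'
#' Per subject, a 4-D NIfTI with trials along the 4th axis; plus the 3-D
#' mask, the ground-truth label image, and a JSON sidecar recording the
#' generative parameters and seeds.
#'
#' @param brain a `brain_data` object.
#' @param dir output directory.
#' @param sidecar optional named list appended to the JSON sidecar.
#' @return invisibly, the written file paths.
#' @export
write_brain_nifti <- function(brain, dir, sidecar = list()) {
  stopifnot(inherits(brain, "brain_data"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dm <- dim(brain$mask)
  paths <- character(0)
  for (k in seq_along(brain$datasets)) {
    vol <- array(0, c(dm, nrow(brain$datasets[[k]])))
    for (t in seq_len(nrow(brain$datasets[[k]]))) {
      v3 <- array(0, dm)
      v3[brain$mask] <- brain$datasets[[k]][t, ]
      vol[, , , t] <- v3
    }
    f <- file.path(dir, sprintf("sub-%02d_betas.nii.gz", k))
    RNifti::writeNifti(RNifti::asNifti(vol), f)
    paths <- c(paths, f)
  }
  fm <- file.path(dir, "mask.nii.gz")
  RNifti::writeNifti(RNifti::asNifti(array(as.integer(brain$mask), dm)), fm)
  fl <- file.path(dir, "truth_labels.nii.gz")
  RNifti::writeNifti(RNifti::asNifti(brain$labels), fl)
  side <- c(list(dim = dm,
                 params = brain$params[!vapply(brain$params, is.function,
                                               TRUE)]),
            sidecar)
  fj <- file.path(dir, "generative_params.json")
  jsonlite::write_json(side, fj, auto_unbox = TRUE, pretty = TRUE,
                       force = TRUE)
  invisible(c(paths, fm, fl, fj))
}

#' Read a 4-D NIfTI beta series into a trials x voxels matrix
#'
#' @param file path to a 4-D NIfTI file.
#' @param mask logical 3-D array (or path to a NIfTI mask).
#' @return trials x voxels matrix over in-mask voxels.
#' @export
read_beta_series <- function(file, mask) {
  vol <- RNifti::readNifti(file)
  if (is.character(mask)) mask <- RNifti::readNifti(mask) > 0
  dm <- dim(vol)
  stopifnot(length(dm) == 4, identical(dm[1:3], dim(mask)))
  n <- dm[4]
  out <- matrix(NA_real_, n, sum(mask))
  for (t in seq_len(n)) out[t, ] <- vol[, , , t][mask]
  out
}

#' Write a thresholded map as NIfTI tier and effect images
#'
#' @param tmap a `thresholded_map`.
#' @param prefix output path prefix; writes `<prefix>_tier.nii.gz`
#'   (0 none, 1 p05, 2 p01, 3 fdr) and `<prefix>_effect.nii.gz` (signed
#'   estimates, zero outside surviving tiers).
#' @return invisibly, the written paths.
#' @export
write_thresholded_nifti <- function(tmap, prefix) {
  ta <- tier_array(tmap)
  eff <- map_values(tmap, tier = "p05")
  f1 <- paste0(prefix, "_tier.nii.gz")
  f2 <- paste0(prefix, "_effect.nii.gz")
  RNifti::writeNifti(RNifti::asNifti(ta), f1)
  RNifti::writeNifti(RNifti::asNifti(eff), f2)
  invisible(c(f1, f2))
}
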