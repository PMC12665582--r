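#' Write a recording as a plain-text bundle
#'
#' One CSV holding the channels x samples matrix (row names = channel
#' labels) plus a JSON sidecar with subject, condition, sampling rate and
#' any artifact-burst metadata.
#'
#' @param recording An `eeg_recording`.
#' @param path Basename (without extension); writes `<path>.csv` and
#'   `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_recording <- function(recording, path) {
  stopifnot(inherits(recording, "eeg_recording"))
  utils::write.table(recording$data, paste0(path, ".csv"), sep = ",",
                     col.names = FALSE, row.names = TRUE, quote = FALSE)
  side <- list(subject_id = recording$subject_id,
               condition = recording$condition,
               fs = recording$fs,
               channel_names = recording$channel_names,
               artifacts = recording$artifacts)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a recording bundle written by [write_recording()]
#' @param path Basename used at write time.
#' @return An `eeg_recording`.
#' @export
read_recording <- function(path) {
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  tab <- utils::read.table(paste0(path, ".csv"), sep = ",", row.names = 1)
  data <- as.matrix(tab)
  colnames(data) <- NULL
  art <- side$artifacts
  if (!is.null(art) && length(art) == 0) art <- NULL
  structure(list(subject_id = side$subject_id,
                 condition = as.integer(side$condition),
                 channel_names = side$channel_names,
                 fs = side$fs, data = data, artifacts = art),
            class = "eeg_recording")
}

#' Write a feature matrix as wide CSV plus JSON schema
#'
#' One row per epoch: `label`, `subject_id`, `epoch_index`, then the 2481
#' feature columns; the JSON schema records the canonical feature-name
#' order.
#'
#' @param fm A `feature_matrix`.
#' @param path Basename; writes `<path>.csv` and `<path>.schema.json`.
#' @return `path`, invisibly.
#' @export
write_feature_matrix <- function(fm, path) {
  stopifnot(inherits(fm, "feature_matrix"))
  df <- cbind(fm$meta, as.data.frame(fm$X, check.names = FALSE))
  utils::write.csv(df, paste0(path, ".csv"), row.names = FALSE)
  jsonlite::write_json(list(feature_order = colnames(fm$X)),
                       paste0(path, ".schema.json"))
  invisible(path)
}

#' Read a feature matrix written by [write_feature_matrix()]
#' @param path Basename used at write time.
#' @return A `feature_matrix`.
#' @export
read_feature_matrix <- function(path) {
  df <- utils::read.csv(paste0(path, ".csv"), check.names = FALSE)
  schema <- jsonlite::read_json(paste0(path, ".schema.json"),
                                simplifyVector = TRUE)
  meta <- df[, c("label", "subject_id", "epoch_index")]
  X <- as.matrix(df[, schema$feature_order, drop = FALSE])
  structure(list(X = X, meta = meta), class = "feature_matrix")
}
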