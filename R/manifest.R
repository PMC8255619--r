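# Cohort manifests: one row per subject with diagnostic group and file paths.

persi_groups <- function() c("HC", "MCI", "AD")

#' Read and validate a cohort manifest
#'
#' The manifest is a CSV with header
#' `subject_id,group,pet_path,gm_path,wm_path,csf_path`. Relative paths are
#' resolved against the manifest's own directory. Subject ids must be unique
#' and every referenced file must exist.
#'
#' @param path path to the manifest CSV.
#' @param check_files if `TRUE` (default) verify that every referenced file
#'   exists.
#' @return A `data.frame` of class `cohort_manifest` with absolute paths.
#' @export
read_manifest <- function(path, check_files = TRUE) {
  if (!file.exists(path))
    persi_error(sprintf("manifest not found: %s", path), "persi_io_error")
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_manifest(df, base_dir = dirname(normalizePath(path)),
                    check_files = check_files)
}

#' Validate an in-memory cohort manifest
#'
#' @param df data.frame with the manifest columns.
#' @param base_dir directory against which relative paths are resolved.
#' @param check_files verify file existence.
#' @return The validated manifest (class `cohort_manifest`).
#' @export
validate_manifest <- function(df, base_dir = ".", check_files = TRUE) {
  needed <- c("subject_id", "group", "pet_path", "gm_path", "wm_path", "csf_path")
  missing <- setdiff(needed, names(df))
  if (length(missing) > 0L)
    persi_error(sprintf("manifest is missing columns: %s",
                        paste(missing, collapse = ", ")), "persi_manifest_error")
  if (anyDuplicated(df$subject_id))
    persi_error("subject_id values must be unique", "persi_manifest_error")
  bad_grp <- setdiff(unique(df$group), persi_groups())
  if (length(bad_grp) > 0L)
    persi_error(sprintf("unknown group labels: %s (expected %s)",
                        paste(bad_grp, collapse = ", "),
                        paste(persi_groups(), collapse = "/")),
                "persi_manifest_error")
  path_cols <- c("pet_path", "gm_path", "wm_path", "csf_path")
  for (col in path_cols) {
    rel <- !grepl("^(/|[A-Za-z]:)", df[[col]])
    df[[col]][rel] <- file.path(base_dir, df[[col]][rel])
  }
  if (check_files) {
    all_paths <- unlist(df[path_cols], use.names = FALSE)
    absent <- all_paths[!file.exists(all_paths)]
    if (length(absent) > 0L)
      persi_error(sprintf("manifest references %d missing file(s), e.g. %s",
                          length(absent), absent[1]), "persi_io_error")
  }
  class(df) <- c("cohort_manifest", "data.frame")
  df
}

#' Write a cohort manifest CSV
#'
#' @param manifest a `cohort_manifest` or compatible data.frame.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  utils::write.csv(as.data.frame(manifest), path, row.names = FALSE)
  invisible(path)
}
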