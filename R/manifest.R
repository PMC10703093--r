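VALID_LABELS <- c("AD", "MCI", "NC")

#' Read a label manifest
#'
#' A manifest is a CSV with header columns `path,label` listing one volume
#' per row; labels must be drawn from AD / MCI / NC.
#'
#' @param path path to the CSV file.
#' @param check_paths verify that every listed volume file exists
#'   (resolved relative to the manifest's directory when not absolute).
#' @return data.frame with columns `path`, `label`.
#' @export
loadManifest <- function(path, check_paths = FALSE) {
  if (!file.exists(path)) stop("I/O error: cannot read '", path, "'",
                               call. = FALSE)
  if (file.size(path) == 0L)
    stop("validation error: manifest '", path, "' is empty", call. = FALSE)
  m <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("path", "label") %in% names(m)))
    stop("validation error: manifest must have columns path,label",
         call. = FALSE)
  if (nrow(m) == 0L)
    stop("validation error: manifest '", path, "' has no rows", call. = FALSE)
  bad <- which(!m$label %in% VALID_LABELS)
  if (length(bad))
    stop("validation error: row ", bad[1], " has label '", m$label[bad[1]],
         "' (allowed: ", paste(VALID_LABELS, collapse = ", "), ")",
         call. = FALSE)
  if (check_paths) {
    full <- ifelse(grepl("^(/|[A-Za-z]:)", m$path), m$path,
                   file.path(dirname(path), m$path))
    miss <- which(!file.exists(full))
    if (length(miss))
      stop("validation error: row ", miss[1], " path not found: '",
           m$path[miss[1]], "'", call. = FALSE)
  }
  m[, c("path", "label")]
}

#' Write a label manifest
#'
#' @param manifest data.frame with columns `path`, `label`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeManifest <- function(manifest, path) {
  stopifnot(all(c("path", "label") %in% names(manifest)))
  bad <- which(!manifest$label %in% VALID_LABELS)
  if (length(bad))
    stop("validation error: row ", bad[1], " has label '",
         manifest$label[bad[1]], "'", call. = FALSE)
  write.csv(manifest[, c("path", "label")], path, row.names = FALSE,
            quote = FALSE)
  invisible(path)
}

# Resolve manifest paths relative to a base directory.
resolveManifestPaths <- function(manifest, base) {
  full <- ifelse(grepl("^(/|[A-Za-z]:)", manifest$path), manifest$path,
                 file.path(base, manifest$path))
  manifest$path <- full
  manifest
}
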