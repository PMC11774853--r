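# Manifest CSV: the canonical interchange format for stimulus sets. MIDI
# and WAV files are derived views; the manifest round-trips every record
# field losslessly, with patterns encoded as space-separated integers.

manifest_required_cols <- c(
  "stimulus_id", "domain", "target_id", "variant", "manipulation_size",
  "manipulation_sign", "manipulation_position", "manipulation_delta",
  "contour_class", "referent", "root", "pattern", "framework_class"
)
manifest_sync_cols <- c("sync_target", "sync_variant", "sync_diff",
                        "min_shift")

#' Write / read a stimulus manifest CSV
#'
#' `write_manifest()` writes a stimulus set (as built by
#' [build_stimulus_set()]) to CSV; `read_manifest()` reads it back and
#' validates it, reporting malformed rows with their file line numbers. The
#' round trip is lossless.
#'
#' @param set A stimulus manifest data frame.
#' @param path CSV file path.
#' @return `write_manifest()`: `path`, invisibly. `read_manifest()`: the
#'   validated manifest data frame.
#' @export
write_manifest <- function(set, path) {
  missing <- setdiff(manifest_required_cols, names(set))
  if (length(missing) > 0) {
    stop("manifest is missing required column(s): ",
         paste(missing, collapse = ", "))
  }
  utils::write.csv(set, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  set <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(pattern = "character"))
  missing <- setdiff(manifest_required_cols, names(set))
  if (length(missing) > 0) {
    stop("manifest ", path, " is missing required column(s): ",
         paste(missing, collapse = ", "))
  }
  # header is line 1, so data row i sits on file line i + 1
  bad <- character(0)
  for (i in seq_len(nrow(set))) {
    line <- i + 1L
    if (!set$domain[i] %in% c("rhythm", "melody")) {
      bad <- c(bad, sprintf("line %d: unknown domain '%s'", line,
                            set$domain[i]))
      next
    }
    vals <- suppressWarnings(
      as.integer(strsplit(trimws(set$pattern[i]), "\\s+")[[1]])
    )
    if (length(vals) == 0 || anyNA(vals)) {
      bad <- c(bad, sprintf("line %d: malformed pattern string", line))
    }
    if (!set$variant[i] %in% c("target", "manipulated")) {
      bad <- c(bad, sprintf("line %d: unknown variant '%s'", line,
                            set$variant[i]))
    }
  }
  if (length(bad) > 0) {
    stop("malformed manifest rows:\n", paste(bad, collapse = "\n"))
  }
  set$referent <- as.logical(set$referent)
  # all-NA columns come back logical from read.csv; restore integer types
  for (col in c("target_id", "manipulation_position", "manipulation_delta",
                "root", intersect(manifest_sync_cols, names(set)))) {
    set[[col]] <- as.integer(set[[col]])
  }
  set
}
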