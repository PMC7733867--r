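#' Create or read an occurrence record
#'
#' `occurrenceRecord()` builds the record from vectors; `readOccurrences()`
#' parses the TSV interchange format with columns `time` and `removed`
#' (0 = non-removed, 1 = removed, NA = unknown).  Rows are sorted by time
#' (stable sort).
#'
#' @param time occurrence times (before present), >= 0.
#' @param removed integer/logical vector (0/1/NA) or character status
#'   vector (`"removed"`, `"non_removed"`, `"unknown"`).
#' @return an [OccurrenceRecord-class] object.
#' @examples
#' occurrenceRecord(c(1.2, 0.4), c(0, 1))
#' @export
occurrenceRecord <- function(time = numeric(), removed = integer()) {
  stopifnot(length(time) == length(removed))
  if (is.character(removed)) {
    status <- removed
  } else {
    status <- ifelse(is.na(removed), "unknown",
                     ifelse(as.integer(removed) == 1L, "removed",
                            "non_removed"))
  }
  ord <- order(time)
  new("OccurrenceRecord",
      record = data.frame(time = time[ord], status = status[ord],
                          stringsAsFactors = FALSE))
}

#' @rdname occurrenceRecord
#' @param text TSV text (exclusive with `file`).
#' @param file path to a TSV file.
#' @export
readOccurrences <- function(text = NULL, file = NULL) {
  df <- utils::read.delim(if (is.null(text)) file else textConnection(text),
                          header = TRUE)
  if (!all(c("time", "removed") %in% names(df)))
    stop("occurrence TSV needs columns 'time' and 'removed'")
  occurrenceRecord(df$time, df$removed)
}

#' Write an occurrence record to TSV
#'
#' @param occ an [OccurrenceRecord-class] object.
#' @param file path; when NULL the TSV text is returned.
#' @return the TSV text, invisibly when written to a file.
#' @export
writeOccurrences <- function(occ, file = NULL) {
  rec <- occ@record
  removed <- ifelse(rec$status == "unknown", NA_integer_,
                    as.integer(rec$status == "removed"))
  lines <- c("time\tremoved",
             if (nrow(rec)) paste(format(rec$time, digits = 15, trim = TRUE),
                                  removed, sep = "\t"))
  out <- paste(lines, collapse = "\n")
  if (!is.null(file)) { writeLines(out, file); return(invisible(out)) }
  out
}

#' Discard removal labels
#'
#' Returns a copy of the object with every removal status set to
#' `"unknown"` (sampled ancestors stay non-removed, as their label is
#' implied by their sampled descent).  Mirrors the data situation where
#' the removal outcome of sampling is never observed; the traversals then
#' sum the two labeled updates at every event.
#'
#' @param x a [ReconTree-class] or [OccurrenceRecord-class].
#' @return an object of the same class.
#' @export
setGeneric("blindRemovalStatus", function(x) standardGeneric("blindRemovalStatus"))

#' @rdname blindRemovalStatus
#' @export
setMethod("blindRemovalStatus", "ReconTree", function(x) {
  nd <- x@nodes
  nd$status[nd$role == "leaf"] <- "unknown"
  new("ReconTree", nodes = nd, presentOffset = x@presentOffset)
})

#' @rdname blindRemovalStatus
#' @export
setMethod("blindRemovalStatus", "OccurrenceRecord", function(x) {
  rec <- x@record
  rec$status[] <- "unknown"
  new("OccurrenceRecord", record = rec)
})
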