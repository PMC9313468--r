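#' @include AllClasses.R
NULL

## collapse sorted indices into contiguous [start, end] runs
indexRuns <- function(idx) {
  idx <- sort(unique(as.integer(idx)))
  brk <- c(0L, which(diff(idx) > 1L), length(idx))
  data.frame(start = idx[brk[-length(brk)] + 1L], end = idx[brk[-1L]])
}

#' Export residue subsets as BED-like TSV
#'
#' One row per contiguous sequential-index run: unit_label, label,
#' start_index, end_index (1-based, inclusive). The format round-trips
#' through [importSubsets()].
#'
#' @param subsets a [SubsetSpec-class] or list of them.
#' @param unitLabel label of the unit the masks refer to.
#' @param file output TSV path.
#' @return The exported data.frame, invisibly.
#' @export
exportSubsets <- function(subsets, unitLabel, file) {
  if (methods::is(subsets, "SubsetSpec")) subsets <- list(subsets)
  rows <- lapply(subsets, function(s) {
    if (!length(subsetMask(s)))
      return(NULL)
    r <- indexRuns(subsetMask(s))
    data.frame(unit_label = unitLabel, label = subsetLabel(s),
               start_index = r$start, end_index = r$end,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  utils::write.table(out, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out)
}

#' Import residue subsets from BED-like TSV
#'
#' @param file TSV written by [exportSubsets()] (columns unit_label, label,
#'   start_index, end_index; 1-based inclusive).
#' @return Named list of [SubsetSpec-class] (one per distinct label).
#' @export
importSubsets <- function(file) {
  df <- utils::read.delim(file, stringsAsFactors = FALSE)
  need <- c("unit_label", "label", "start_index", "end_index")
  if (!all(need %in% names(df)))
    stop("subset table must have columns ", paste(need, collapse = ", "))
  out <- lapply(split(df, df$label), function(d) {
    mask <- unlist(mapply(seq, d$start_index, d$end_index, SIMPLIFY = FALSE))
    newSubset(d$label[1], mask, list(unit_label = d$unit_label[1]))
  })
  out[unique(df$label)]
}
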