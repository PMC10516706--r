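# Capture-target intervals.  A target is a data.frame with columns
# contig / start / end in BED convention (0-based, half-open).

new_target <- function(contig, start, end) {
  data.frame(contig = as.character(contig), start = as.integer(start),
             end = as.integer(end), stringsAsFactors = FALSE)
}

validate_target <- function(target) {
  stopifnot(is.data.frame(target),
            all(c("contig", "start", "end") %in% names(target)))
  if (nrow(target) && any(target$end <= target$start))
    stopf("target has empty or inverted intervals")
  target
}

#' Read a BED3 file of target intervals
#'
#' Minimal validated reader for three-column BED (0-based, half-open).
#' Malformed lines are reported with their line number.
#'
#' @param path path to a BED file.
#' @return data.frame with columns `contig`, `start`, `end`.
#' @export
read_targets <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(lines)
  out <- vector("list", sum(keep))
  j <- 0L
  for (i in seq_along(lines)) {
    if (!keep[i]) next
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L || is.na(suppressWarnings(as.integer(f[2]))) ||
        is.na(suppressWarnings(as.integer(f[3]))))
      stopf("malformed BED line %d: %s", i, lines[i])
    j <- j + 1L
    out[[j]] <- new_target(f[1], as.integer(f[2]), as.integer(f[3]))
  }
  if (j == 0L) return(new_target(character(), integer(), integer()))
  validate_target(do.call(rbind, out[seq_len(j)]))
}

#' Write target intervals as BED3
#' @param target target data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_targets <- function(target, path) {
  write.table(validate_target(target), path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Pad and merge capture intervals
#'
#' Extends every interval by `pad` bases on both sides (the exome capture
#' convention of adding flanking sequence at the 5' and 3' ends of each
#' capture range), clips to contig bounds and merges overlapping results.
#'
#' @param target data.frame of intervals (`contig`, `start`, `end`;
#'   0-based half-open) or a BED3 path.
#' @param pad non-negative integer number of bases added to each side.
#'   Default 100, the usual capture-range padding.
#' @param contig_lengths named integer vector used for clipping; optional.
#' @return merged target data.frame; attribute `total_length` holds the
#'   number of covered bases.
#' @export
#' @examples
#' pad_target(data.frame(contig = "c", start = 100, end = 200), pad = 100,
#'            contig_lengths = c(c = 1000))
pad_target <- function(target, pad = 100L, contig_lengths = NULL) {
  if (is.character(target)) target <- read_targets(target)
  target <- validate_target(target)
  stopifnot(pad >= 0)
  if (!nrow(target)) {
    out <- target
    attr(out, "total_length") <- 0L
    return(out)
  }
  start <- pmax(0L, target$start - as.integer(pad))
  end <- target$end + as.integer(pad)
  if (!is.null(contig_lengths)) {
    end <- pmin(end, as.integer(contig_lengths[target$contig]))
  }
  gr <- GenomicRanges::reduce(GenomicRanges::GRanges(
    target$contig, IRanges::IRanges(start + 1L, end)))
  out <- new_target(as.character(GenomicRanges::seqnames(gr)),
                    GenomicRanges::start(gr) - 1L, GenomicRanges::end(gr))
  out <- out[order(out$contig, out$start), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "total_length") <- sum(out$end - out$start)
  out
}

target_length <- function(target) sum(target$end - target$start)

# All reference positions (0-based) covered by a target, per contig.
target_positions <- function(target) {
  if (!nrow(target)) return(data.frame(contig = character(), pos0 = integer()))
  do.call(rbind, lapply(seq_len(nrow(target)), function(i) {
    data.frame(contig = target$contig[i],
               pos0 = seq.int(target$start[i], target$end[i] - 1L),
               stringsAsFactors = FALSE)
  }))
}
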