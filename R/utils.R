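# Internal helpers shared across modules.  Coordinates: VCF positions are
# 1-based, BED intervals 0-based half-open, internal representation 0-based
# half-open throughout; conversions happen only at I/O boundaries.

BASES <- c("A", "C", "G", "T")

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
revcomp <- function(x) {
  vapply(x, function(s) {
    chartr("ACGTacgt", "TGCAtgca",
           paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = ""))
  }, character(1), USE.NAMES = FALSE)
}

comp_base <- function(x) chartr("ACGT", "TGCA", x)

#' Round half away from zero
#'
#' Base `round()` is half-to-even, which does not reproduce printed
#' arithmetic like 0.5 -> 1; display values use this convention instead.
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Derive reproducible child seeds below 2^31 from a master seed.
child_seeds <- function(master, n) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(master)
  s <- sample.int(.Machine$integer.max - 1L, n)
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  s
}

maybe_seed <- function(seed) {
  if (!is.null(seed)) set.seed(seed)
  invisible(NULL)
}

# Phred quality characters (offset 33) for a per-cycle error-rate vector.
phred_chars <- function(rate) {
  q <- ifelse(rate <= 0, 40L, pmin(40L, as.integer(round(-10 * log10(rate)))))
  rawToChar(as.raw(q + 33L))
}

# Load sequences as a plain named character vector of upper-case strings.
as_seq_vector <- function(x) {
  if (is.character(x) && length(x) == 1L && file.exists(x)) {
    x <- Biostrings::readDNAStringSet(x)
  }
  if (methods::is(x, "DNAStringSet")) {
    out <- as.character(x)
    names(out) <- sub("\\s.*$", "", names(x))
    return(toupper(out))
  }
  if (is.character(x)) {
    if (is.null(names(x))) stop("reference sequences must be named")
    return(toupper(x))
  }
  stop("unsupported reference input: ", class(x)[1])
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
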