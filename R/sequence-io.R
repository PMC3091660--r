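#' Read chromosome sequences from a FASTA file
#'
#' Reads a (possibly multi-record, wrapped or unwrapped) FASTA file and
#' normalizes each record to the alphabet `{A, C, G, T, N}`: case is folded,
#' `U` is mapped to `T`, and every other IUPAC ambiguity code is collapsed
#' to `N`. Only G and C are ever counted downstream, so finer ambiguity
#' semantics carry no information for GC profiling.
#'
#' Each FASTA record is treated as an independent chromosome; record ids are
#' the first whitespace-delimited token of the header, and duplicated ids
#' are suffixed deterministically (`id`, `id.1`, `id.2`, ...).
#'
#' @param path Path to a FASTA file.
#' @return A [Biostrings::DNAStringSet], one element per record in file
#'   order, named by chromosome id.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">chr1 some description", "acgu", ">chr2", "ACGRYT"), fa)
#' readGenomeFasta(fa)
#' @importFrom Biostrings readBStringSet DNAStringSet replaceAmbiguities
#' @export
readGenomeFasta <- function(path) {
  if (!file.exists(path))
    stop("cannot read FASTA file: ", path)
  raw <- tryCatch(readBStringSet(path, format = "fasta"),
                  error = function(e)
                    stop("failed to parse FASTA '", path, "': ",
                         conditionMessage(e)))
  if (length(raw) == 0L)
    stop("FASTA file '", path, "' contains no records")
  ids <- sub("\\s.*$", "", names(raw))
  empty <- S4Vectors::width(raw) == 0L
  if (any(empty))
    stop("zero-length sequence for record(s): ",
         paste(ids[empty], collapse = ", "))
  if (anyDuplicated(ids)) ids <- make.unique(ids, sep = ".")
  chars <- toupper(as.character(raw))
  chars <- chartr("U", "T", chars)
  # anything outside the DNA alphabet (rare in practice) becomes N up front
  chars <- gsub("[^ACGTURYSWKMBDHVN.-]", "N", chars)
  chars <- chartr(".-", "NN", chars)
  seqs <- replaceAmbiguities(DNAStringSet(chars), new = "N")
  names(seqs) <- ids
  seqs
}

#' Write a window profile as a bedGraph track
#'
#' Serializes the retained windows of a [WindowProfile-class] as a
#' four-column bedGraph (chrom, start, end, value) with 0-based half-open
#' coordinates, one line per window in genomic order. The value column is
#' the window GC fraction (`kind = "gc"`) or the residual against the
#' chromosome mean (`kind = "residual"`), written with six significant
#' digits.
#'
#' @param profile A [WindowProfile-class].
#' @param path Output file path.
#' @param kind `"gc"` or `"residual"`.
#' @return Invisibly, the number of lines written.
#' @examples
#' p <- scanWindows(Biostrings::DNAString("GGGGAAAA"), windowLength = 4,
#'                  chromosomeId = "toy")
#' f <- tempfile(fileext = ".bedGraph")
#' writeWindowTrack(p, f, kind = "gc")
#' readLines(f)
#' @export
writeWindowTrack <- function(profile, path, kind = c("gc", "residual")) {
  stopifnot(is(profile, "WindowProfile"))
  kind <- match.arg(kind)
  gr <- windowRanges(profile)
  if (length(gr) == 0L)
    stop("profile has no retained windows to write")
  value <- if (kind == "gc") gcValues(profile) else gcResiduals(profile)
  lines <- sprintf("%s\t%d\t%d\t%.6g",
                   chromosomeId(profile),
                   start(gr) - 1L, end(gr), value)
  ok <- tryCatch({ writeLines(lines, path); TRUE },
                 error = function(e)
                   stop("cannot write track to '", path, "': ",
                        conditionMessage(e)))
  invisible(length(lines))
}

#' Write a tab-delimited table
#'
#' Standard TSV output used throughout the package: tab-delimited, header
#' row, no quoting, missing values written as ".".
#'
#' @param x A data.frame.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
writeTsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = ".")
  invisible(path)
}

#' Read a tab-delimited table written by [writeTsv()]
#'
#' @param path Input path.
#' @return A data.frame with `"."` read back as `NA`.
#' @export
readTsv <- function(path) {
  if (!file.exists(path)) stop("cannot read table: ", path)
  utils::read.table(path, sep = "\t", header = TRUE, na.strings = ".",
                    stringsAsFactors = FALSE, check.names = FALSE)
}
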