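#' Read a FASTA file
#'
#' Thin wrapper around \code{Biostrings::readBStringSet} that uppercases
#' sequences, preserves record order and turns malformed input into format
#' errors that name the offending line.
#'
#' @param path file path.
#' @return named character vector of sequences (names are the full header
#'   text up to the first whitespace; descriptions kept as an attribute).
#' @export
readFasta <- function(path) {
  stopifnot_scalar_string(path, "path")
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) == 0L)
    stop("FASTA format error at line 1: empty file ", path, call. = FALSE)
  if (!startsWith(trimws(lines[nonblank[1]]), ">"))
    stop("FASTA format error at line ", nonblank[1],
         ": expected '>' header", call. = FALSE)
  ss <- Biostrings::readBStringSet(path)
  headers <- names(ss)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  out <- toupper(as.character(ss))
  names(out) <- ids
  attr(out, "description") <- setNames(desc, ids)
  out
}

#' Write sequences as FASTA
#'
#' @param sequences named character vector (or \code{DNAStringSet}).
#' @param path output file.
#' @param width line-wrap width.
#' @return invisibly, the path.
#' @export
writeFasta <- function(sequences, path, width = 70L) {
  if (methods::is(sequences, "XStringSet"))
    sequences <- setNames(as.character(sequences), names(sequences))
  if (is.null(names(sequences)) || any(!nzchar(names(sequences))))
    stop("all sequences must be named", call. = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(sequences)) {
    writeLines(paste0(">", names(sequences)[i]), con)
    s <- sequences[[i]]
    starts <- seq(1L, max(nchar(s), 1L), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read FASTQ (Phred+33) into a ReadSet
#'
#' Only Phred+33 ("Sanger") quality encoding is accepted; qualities outside
#' the printable Phred+33 range raise a format error rather than being
#' reinterpreted. When \code{mate_path} is given, records are cross-linked
#' by id: mate ids are assigned pairwise by position after verifying the two
#' files carry matching read names (ignoring a trailing /1 or /2).
#'
#' @param path FASTQ file (R1 or single-end).
#' @param mate_path optional FASTQ file of mates (R2).
#' @param platform read platform tag for the resulting set.
#' @return A \linkS4class{ReadSet}; with a mate file, both files' reads
#'   concatenated with mate links.
#' @export
readFastq <- function(path, mate_path = NULL, platform = "short_paired") {
  one <- parseFastqFile(path)
  if (is.null(mate_path)) {
    if (is.null(one$mate)) one$mate <- rep(NA_character_, length(one$id))
    return(new("ReadSet", id = one$id, sequence = one$sequence,
               quality = one$quality, mate = one$mate, platform = platform))
  }
  two <- parseFastqFile(mate_path)
  base1 <- sub("/[12]$", "", one$id)
  base2 <- sub("/[12]$", "", two$id)
  if (length(base1) != length(base2) || any(base1 != base2))
    stop("mate files do not pair record-by-record", call. = FALSE)
  id1 <- ifelse(one$id == two$id, paste0(one$id, "/1"), one$id)
  id2 <- ifelse(one$id == two$id, paste0(two$id, "/2"), two$id)
  new("ReadSet",
      id = c(id1, id2),
      sequence = c(one$sequence, two$sequence),
      quality = c(one$quality, two$quality),
      mate = c(id2, id1),
      platform = platform)
}

parseFastqFile <- function(path) {
  stopifnot_scalar_string(path, "path")
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) && !nzchar(lines[length(lines)]))
    lines <- lines[-length(lines)]
  if (length(lines) %% 4L != 0L)
    stop("FASTQ format error at line ", length(lines),
         ": record count not a multiple of 4", call. = FALSE)
  n <- length(lines) %/% 4L
  if (n == 0L) return(list(id = character(0), sequence = character(0),
                           quality = list()))
  hidx <- seq(1L, length(lines), by = 4L)
  heads <- lines[hidx]
  bad <- which(!startsWith(heads, "@"))
  if (length(bad))
    stop("FASTQ format error at line ", hidx[bad[1]],
         ": header must start with '@'", call. = FALSE)
  seqs <- toupper(lines[hidx + 1L])
  quals <- lines[hidx + 3L]
  mism <- which(nchar(seqs) != nchar(quals))
  if (length(mism))
    stop("FASTQ format error at line ", hidx[mism[1]] + 3L,
         ": quality length differs from sequence length", call. = FALSE)
  qlist <- lapply(quals, function(q) utf8ToInt(q) - 33L)
  qall <- unlist(qlist, use.names = FALSE)
  if (length(qall) && (any(qall < 0L) || any(qall > 60L)))
    stop("quality scores outside Phred+33 range [0,60]; ",
         "only Phred+33 encoding is supported", call. = FALSE)
  list(id = sub("\\s.*$", "", sub("^@", "", heads)),
       sequence = seqs, quality = qlist)
}

#' Write a ReadSet as FASTQ (Phred+33)
#'
#' @param reads a \linkS4class{ReadSet}.
#' @param path output file.
#' @return invisibly, the path.
#' @export
writeFastq <- function(reads, path) {
  quals <- vapply(reads@quality, function(q) intToUtf8(q + 33L), "")
  out <- as.vector(rbind(paste0("@", reads@id), reads@sequence, "+", quals))
  writeLines(out, path)
  invisible(path)
}

#' Write a labelled table as TSV
#'
#' Writes a rectangular labelled matrix or data.frame as tab-separated text
#' with a header row and row labels, rendering numbers at full precision
#' (>= 6 significant digits survive a round trip).
#'
#' @param x matrix or data.frame with row and column names.
#' @param path output file.
#' @return invisibly, the path.
#' @export
writeTable <- function(x, path) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x)) stop("x must be a matrix or data.frame", call. = FALSE)
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
  if (is.null(rownames(x)) && nrow(x) > 0L)
    rownames(x) <- paste0("R", seq_len(nrow(x)))
  body <- x
  if (is.numeric(x)) body <- format(x, digits = 15, trim = TRUE,
                                    scientific = FALSE)
  lines <- c(paste(c("", colnames(x)), collapse = "\t"),
             if (nrow(x)) paste(rownames(x),
                                apply(body, 1L, paste, collapse = "\t"),
                                sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Read a TSV written by writeTable
#'
#' @param path file path.
#' @param numeric coerce the body to a numeric matrix.
#' @return matrix with row and column labels.
#' @export
readTable <- function(path, numeric = TRUE) {
  df <- read.delim(path, row.names = 1L, check.names = FALSE)
  m <- as.matrix(df)
  if (numeric) storage.mode(m) <- "double"
  m
}
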