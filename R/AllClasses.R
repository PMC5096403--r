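#' @import methods
#' @importClassesFrom Biostrings DNAStringSet
#' @importFrom stats median cor prcomp cmdscale dist rbinom rnbinom rnorm runif
#'   rpois setNames quantile var sd hclust as.dist
#' @importFrom utils head tail read.delim write.table combn
NULL

#' Set of sequencing reads
#'
#' Container for short paired-end or long single-end reads: sequence,
#' per-base Phred qualities, optional mate link and the platform type.
#' Per-base qualities are stored as a list of integer vectors so that
#' 3'-trimming can operate base-wise.
#'
#' @slot id character, read identifiers (unique).
#' @slot sequence character, nucleotide strings over A/C/G/T/N.
#' @slot quality list of integer vectors, Phred scores, one per base.
#' @slot mate character, identifier of the mate read (NA for unpaired).
#' @slot platform scalar, \code{"short_paired"} or \code{"long_single"}.
#' @exportClass ReadSet
setClass("ReadSet", representation(
  id = "character",
  sequence = "character",
  quality = "list",
  mate = "character",
  platform = "character"
))

setValidity("ReadSet", function(object) {
  n <- length(object@id)
  if (length(object@sequence) != n || length(object@quality) != n ||
      length(object@mate) != n)
    return("id, sequence, quality and mate must have equal length")
  if (length(object@platform) != 1L ||
      !object@platform %in% c("short_paired", "long_single"))
    return("platform must be 'short_paired' or 'long_single'")
  if (n > 0) {
    lens <- nchar(object@sequence)
    qlens <- lengths(object@quality)
    if (any(lens != qlens))
      return("sequence length and quality length differ for some reads")
    qall <- unlist(object@quality, use.names = FALSE)
    if (length(qall) && (any(qall < 0L) || any(qall > 60L)))
      return("Phred scores must lie in [0, 60]")
  }
  TRUE
})

#' Construct a ReadSet
#'
#' @param id character vector of read ids.
#' @param sequence character vector of nucleotide strings.
#' @param quality list of integer Phred vectors (or a single integer recycled
#'   per base).
#' @param mate character vector of mate ids (NA when unpaired).
#' @param platform \code{"short_paired"} or \code{"long_single"}.
#' @return A \linkS4class{ReadSet}.
#' @export
ReadSet <- function(id, sequence, quality, mate = rep(NA_character_, length(id)),
                    platform = "short_paired") {
  if (!is.list(quality))
    quality <- lapply(nchar(sequence), function(l) rep(as.integer(quality), l))
  quality <- lapply(quality, as.integer)
  new("ReadSet", id = as.character(id), sequence = toupper(sequence),
      quality = quality, mate = as.character(mate), platform = platform)
}

#' @describeIn ReadSet number of reads
#' @param x a ReadSet
#' @export
setMethod("length", "ReadSet", function(x) length(x@id))

#' @describeIn ReadSet subset reads
#' @param i index
#' @param j,drop ignored
#' @param ... ignored
#' @export
setMethod("[", "ReadSet", function(x, i, j, ..., drop = TRUE) {
  new("ReadSet", id = x@id[i], sequence = x@sequence[i],
      quality = x@quality[i], mate = x@mate[i], platform = x@platform)
})

setMethod("show", "ReadSet", function(object) {
  cat("ReadSet of", length(object), object@platform, "reads\n")
  if (length(object) > 0) {
    lens <- nchar(object@sequence)
    cat("  length range:", min(lens), "-", max(lens), "bases;",
        sum(!is.na(object@mate)), "with mate links\n")
  }
})

#' Read accessors
#'
#' @param x a \linkS4class{ReadSet}
#' @return \code{readIds}: character ids; \code{readSequences}: named
#'   character vector; \code{readQualities}: named list of integer vectors;
#'   \code{mateIds}: character vector of mate ids.
#' @export
readIds <- function(x) x@id
#' @rdname readIds
#' @export
readSequences <- function(x) setNames(x@sequence, x@id)
#' @rdname readIds
#' @export
readQualities <- function(x) setNames(x@quality, x@id)
#' @rdname readIds
#' @export
mateIds <- function(x) setNames(x@mate, x@id)

#' Pileup of mapped reads over a reference
#'
#' Per-column base counts (A/C/G/T) plus the individual read placements that
#' produced them. Coordinates are 0-based half-open on the reference strand;
#' reverse-strand placements contribute reference-strand bases.
#'
#' @slot refname reference identifier.
#' @slot reference reference sequence (character scalar).
#' @slot counts 4 x L integer matrix, rows A,C,G,T.
#' @slot placements data.frame with columns read_id, start (0-based), end
#'   (exclusive), strand, mismatches, bases (reference-strand aligned bases).
#' @slot n_unmapped number of reads that failed to place.
#' @exportClass Pileup
setClass("Pileup", representation(
  refname = "character",
  reference = "character",
  counts = "matrix",
  placements = "data.frame",
  n_unmapped = "integer"
))

setValidity("Pileup", function(object) {
  if (nrow(object@counts) != 4L) return("counts must have 4 rows (A,C,G,T)")
  if (ncol(object@counts) != nchar(object@reference))
    return("counts must have one column per reference base")
  TRUE
})

setMethod("show", "Pileup", function(object) {
  cat("Pileup on", object@refname, "(", nchar(object@reference), "bp ):",
      nrow(object@placements), "placed reads,", object@n_unmapped,
      "unmapped; median depth", median(colSums(object@counts)), "\n")
})

#' Pileup accessors
#'
#' @param x a \linkS4class{Pileup}
#' @return \code{pileupCounts}: the 4 x L base-count matrix;
#'   \code{pileupDepth}: integer vector of per-column depths;
#'   \code{placements}: the placement data.frame.
#' @export
pileupCounts <- function(x) x@counts
#' @rdname pileupCounts
#' @export
pileupDepth <- function(x) colSums(x@counts)
#' @rdname pileupCounts
#' @export
placements <- function(x) x@placements

#' Reconstructed homeolog set for one gene
#'
#' Up to three subgenome-specific consensus sequences, labelled
#' \code{<gene>_1} (most divergent copy) / \code{_2} / \code{_3}, plus any
#' extra sequences (partial assemblies, putative paralogs or pseudogenes)
#' demoted for low completeness or because more than three clusters survived.
#'
#' @slot gene gene name.
#' @slot members \code{DNAStringSet} of labelled homeolog consensus sequences.
#' @slot extra_members \code{DNAStringSet} of demoted sequences.
#' @slot completeness numeric, fraction of the template covered per member.
#' @slot cluster_sizes integer, reads supporting each member.
#' @exportClass HomeologSet
setClass("HomeologSet", representation(
  gene = "character",
  members = "DNAStringSet",
  extra_members = "DNAStringSet",
  completeness = "numeric",
  cluster_sizes = "integer"
))

setValidity("HomeologSet", function(object) {
  if (length(object@members) > 3L) return("at most 3 labelled members")
  if (length(object@completeness) != length(object@members))
    return("one completeness value per member")
  TRUE
})

setMethod("show", "HomeologSet", function(object) {
  cat("HomeologSet for", object@gene, ":", length(object@members),
      "homeologs", if (length(object@extra_members))
        paste0("(+", length(object@extra_members), " extra)") else "", "\n")
  for (i in seq_along(object@members))
    cat("  ", names(object@members)[i], ": ",
        Biostrings::width(object@members)[i], " bp, completeness ",
        round(object@completeness[i], 3), "\n", sep = "")
})

#' HomeologSet accessors
#' @param x a \linkS4class{HomeologSet}
#' @return \code{homeologMembers}: labelled \code{DNAStringSet};
#'   \code{extraMembers}: demoted sequences; \code{geneName}: the gene.
#' @export
homeologMembers <- function(x) x@members
#' @rdname homeologMembers
#' @export
extraMembers <- function(x) x@extra_members
#' @rdname homeologMembers
#' @export
geneName <- function(x) x@gene
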