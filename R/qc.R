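#' Quality-control parameters
#'
#' Defaults follow the read-cleaning rules the pipeline implements: short
#' reads are 3'-trimmed at Q20 (bases with quality strictly above 20 are
#' kept) and must remain >= 90 bases with no N; long reads are 3'-trimmed
#' the same way and kept if >= 90 bases with mean quality >= Q25, no N, and
#' deduplicated.
#'
#' @param trim_quality_threshold Phred threshold for 3' trimming (a base is
#'   kept only if its quality is strictly above this).
#' @param min_length_short minimum short-read length after trimming.
#' @param min_mean_quality_long minimum arithmetic mean Phred of a long read
#'   (computed after trimming).
#' @param min_length_long minimum long-read length after trimming.
#' @param forbid_N reject reads containing undefined bases.
#' @param adapter_tags character vector of 5' tag sequences; reads whose
#'   sequence starts with a tag are flagged adapter-contaminated and
#'   rejected (exact-prefix matching).
#' @return a \code{QCParams} list.
#' @export
qcParams <- function(trim_quality_threshold = 20L, min_length_short = 90L,
                     min_mean_quality_long = 25, min_length_long = 90L,
                     forbid_N = TRUE, adapter_tags = character(0)) {
  stopifnot(trim_quality_threshold > 0, min_length_short >= 1,
            min_length_long >= 1, min_mean_quality_long > 0)
  structure(list(trim_quality_threshold = as.integer(trim_quality_threshold),
                 min_length_short = as.integer(min_length_short),
                 min_mean_quality_long = min_mean_quality_long,
                 min_length_long = as.integer(min_length_long),
                 forbid_N = isTRUE(forbid_N),
                 adapter_tags = toupper(adapter_tags)),
            class = "QCParams")
}

## keep 1..last position with quality strictly above the threshold
trimmedLength <- function(qual, threshold) {
  above <- which(qual > threshold)
  if (length(above) == 0L) 0L else above[length(above)]
}

#' 3'-trim short reads by base quality
#'
#' Removes the maximal 3' suffix beyond the last base whose quality is
#' strictly above the threshold, then rejects reads shorter than
#' \code{min_length_short}, containing N, or starting with a configured
#' adapter tag. Retained bases are never altered.
#'
#' @param reads a \linkS4class{ReadSet} of short reads.
#' @param params a \code{\link{qcParams}}.
#' @return list: \code{kept} (trimmed \linkS4class{ReadSet}),
#'   \code{rejected_ids}, \code{n_trimmed} (reads that lost >= 1 base).
#' @export
trimShortReads <- function(reads, params = qcParams()) {
  n <- length(reads)
  if (n == 0L) return(list(kept = reads, rejected_ids = character(0),
                           n_trimmed = 0L))
  thr <- params$trim_quality_threshold
  newlen <- vapply(reads@quality, trimmedLength, 0L, threshold = thr)
  oldlen <- nchar(reads@sequence)
  seqs <- substr(reads@sequence, 1L, newlen)
  quals <- lapply(seq_len(n), function(i) reads@quality[[i]][seq_len(newlen[i])])
  keep <- newlen >= params$min_length_short
  if (params$forbid_N) keep <- keep & !grepl("N", seqs, fixed = TRUE)
  if (length(params$adapter_tags)) {
    tagged <- Reduce(`|`, lapply(params$adapter_tags, function(tg)
      startsWith(reads@sequence, tg)), rep(FALSE, n))
    keep <- keep & !tagged
  }
  kept <- new("ReadSet", id = reads@id[keep], sequence = seqs[keep],
              quality = quals[keep], mate = reads@mate[keep],
              platform = reads@platform)
  list(kept = kept, rejected_ids = reads@id[!keep],
       n_trimmed = sum(newlen < oldlen & keep))
}

#' Rescue singletons from QC'd pairs
#'
#' After mates have been QC'd independently: pairs where both mates survive
#' stay paired; where exactly one survives, it is kept as a singleton with
#' its mate link cleared; where neither survives, both are dropped.
#'
#' @param kept a \linkS4class{ReadSet} of QC survivors (mate links intact).
#' @param all_ids ids of all reads that entered QC (to identify lost mates).
#' @return list: \code{paired} (ReadSet with both mates),
#'   \code{singletons} (ReadSet, mate cleared), \code{n_pairs},
#'   \code{n_singletons}.
#' @export
rescueSingletons <- function(kept, all_ids) {
  if (length(kept) == 0L)
    return(list(paired = kept, singletons = kept, n_pairs = 0L,
                n_singletons = 0L))
  if (any(is.na(kept@mate)))
    stop("rescueSingletons expects paired reads with mate links",
         call. = FALSE)
  if (!all(kept@mate %in% all_ids))
    stop("mate ids not found among input reads", call. = FALSE)
  mate_survived <- kept@mate %in% kept@id
  paired <- kept[mate_survived]
  singles <- kept[!mate_survived]
  singles@mate <- rep(NA_character_, length(singles))
  list(paired = paired, singletons = singles,
       n_pairs = length(paired) %/% 2L, n_singletons = length(singles))
}

#' Filter long single-end reads
#'
#' 3'-trims at the short-read quality threshold, then keeps reads that are
#' at least \code{min_length_long} bases with arithmetic mean quality >=
#' \code{min_mean_quality_long} and no undefined bases; exact duplicate
#' sequences are removed keeping the first occurrence.
#'
#' @param reads a \linkS4class{ReadSet} of long reads.
#' @param params a \code{\link{qcParams}}.
#' @return list: \code{kept} (ReadSet), \code{rejected_ids},
#'   \code{n_duplicates}.
#' @export
filterLongReads <- function(reads, params = qcParams()) {
  n <- length(reads)
  if (n == 0L) return(list(kept = reads, rejected_ids = character(0),
                           n_duplicates = 0L))
  thr <- params$trim_quality_threshold
  newlen <- vapply(reads@quality, trimmedLength, 0L, threshold = thr)
  seqs <- substr(reads@sequence, 1L, newlen)
  quals <- lapply(seq_len(n), function(i) reads@quality[[i]][seq_len(newlen[i])])
  meanq <- vapply(quals, function(q) if (length(q)) mean(q) else 0, 0)
  keep <- newlen >= params$min_length_long &
    meanq >= params$min_mean_quality_long
  if (params$forbid_N) keep <- keep & !grepl("N", seqs, fixed = TRUE)
  idx <- which(keep)
  dup_idx <- idx[duplicated(seqs[idx])]
  n_dup <- length(dup_idx)
  keep[dup_idx] <- FALSE
  kept <- new("ReadSet", id = reads@id[keep], sequence = seqs[keep],
              quality = quals[keep], mate = reads@mate[keep],
              platform = reads@platform)
  list(kept = kept, rejected_ids = reads@id[!keep], n_duplicates = n_dup)
}

#' Run full read QC
#'
#' Applies the short-read trimmer + singleton rescue to paired reads and the
#' long-read filter to long reads, returning cleaned sets and a QC report.
#'
#' @param pairs \linkS4class{ReadSet} of mate-linked short reads (or NULL).
#' @param long \linkS4class{ReadSet} of long reads (or NULL).
#' @param params a \code{\link{qcParams}}.
#' @return list: \code{paired}, \code{singletons}, \code{long}, and
#'   \code{report} (data.frame of input/kept/trimmed/singleton counts).
#' @export
runReadQC <- function(pairs = NULL, long = NULL, params = qcParams()) {
  out <- list(paired = NULL, singletons = NULL, long = NULL)
  rep_rows <- list()
  if (!is.null(pairs) && length(pairs)) {
    tr <- trimShortReads(pairs, params)
    rs <- rescueSingletons(tr$kept, readIds(pairs))
    out$paired <- rs$paired; out$singletons <- rs$singletons
    rep_rows$short <- data.frame(set = "short_paired", input = length(pairs),
                                 kept = length(tr$kept),
                                 trimmed = tr$n_trimmed,
                                 pairs = rs$n_pairs,
                                 singletons = rs$n_singletons)
  }
  if (!is.null(long) && length(long)) {
    fl <- filterLongReads(long, params)
    out$long <- fl$kept
    rep_rows$long <- data.frame(set = "long_single", input = length(long),
                                kept = length(fl$kept),
                                trimmed = NA_integer_, pairs = NA_integer_,
                                singletons = NA_integer_)
  }
  out$report <- do.call(rbind, rep_rows)
  out
}
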