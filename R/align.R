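#' Read-mapping parameters
#'
#' Relaxed defaults (0.75/0.75) are used during iterative consensus
#' assembly; strict (1.0/1.0, "zero tolerance") settings are used for
#' homeolog-specific expression counting.
#'
#' @param min_length_fraction fraction of the read that must align.
#' @param min_identity_fraction identity over the aligned region.
#' @param kmer_size seed k-mer length (>= 8).
#' @param probe_step distance between seed probes along the read.
#' @param max_hits_reported cap on candidate placements evaluated per read.
#' @return a \code{MappingParams} list.
#' @export
mappingParams <- function(min_length_fraction = 0.75,
                          min_identity_fraction = 0.75,
                          kmer_size = 15L, probe_step = 10L,
                          max_hits_reported = 50L) {
  stopifnot(min_length_fraction > 0, min_length_fraction <= 1,
            min_identity_fraction > 0, min_identity_fraction <= 1,
            kmer_size >= 8)
  structure(list(min_length_fraction = min_length_fraction,
                 min_identity_fraction = min_identity_fraction,
                 kmer_size = as.integer(kmer_size),
                 probe_step = as.integer(probe_step),
                 max_hits_reported = as.integer(max_hits_reported)),
            class = "MappingParams")
}

#' @export
strictParams <- function() mappingParams(1.0, 1.0)

kmerIndex <- function(ref, k) {
  L <- nchar(ref)
  if (L < k) return(list())
  starts <- seq_len(L - k + 1L)
  kmers <- substring(ref, starts, starts + k - 1L)
  split(starts, kmers)
}

getReadSeqs <- function(reads) {
  if (methods::is(reads, "ReadSet")) readSequences(reads)
  else if (is.character(reads)) {
    if (is.null(names(reads))) names(reads) <- paste0("read", seq_along(reads))
    reads
  } else stop("reads must be a ReadSet or named character vector",
              call. = FALSE)
}

candidateStarts <- function(seq, index, k, probe_step, L_ref, min_overlap) {
  len <- nchar(seq)
  if (len < k) return(integer(0))
  probes <- unique(c(seq(1L, len - k + 1L, by = probe_step), len - k + 1L))
  starts <- integer(0)
  for (p in probes) {
    hit <- index[[substr(seq, p, p + k - 1L)]]
    if (!is.null(hit)) starts <- c(starts, hit - p + 1L)
  }
  starts <- unique(starts)
  # overlap with the reference must reach the minimum aligned length
  ov_start <- pmax(starts, 1L)
  ov_end <- pmin(starts + len - 1L, L_ref)
  starts[ov_end - ov_start + 1L >= min_overlap]
}

## gapless comparison of a read placed at `start` (may hang off either end)
alignAt <- function(read_int, ref_int, start) {
  len <- length(read_int)
  L <- length(ref_int)
  r_from <- max(1L, start); r_to <- min(L, start + len - 1L)
  q_from <- r_from - start + 1L; q_to <- r_to - start + 1L
  q <- read_int[q_from:q_to]
  r <- ref_int[r_from:r_to]
  eq <- q == r & q != 0L
  list(ref_start = r_from, ref_end = r_to, q_from = q_from, q_to = q_to,
       aligned_len = length(q), matches = sum(eq))
}

#' Homology filter against ortholog templates
#'
#' Retains a read for a template when a shared k-mer seed extends (gapless,
#' match +1 / mismatch -2) to a local alignment scoring at least
#' \code{min_score} on either strand -- a fixed-score surrogate for a
#' BLASTN e-value cutoff. Reads may be retained for several templates;
#' reads matching none are discarded.
#'
#' @param reads \linkS4class{ReadSet} or named character vector.
#' @param templates named character vector of ortholog CDS.
#' @param min_score minimum local alignment score (default 40).
#' @param word_size seed k-mer length (default 15).
#' @return list: \code{by_template} (named list of retained read ids),
#'   \code{discarded} (ids matching no template).
#' @export
homologyFilter <- function(reads, templates, min_score = 40L,
                           word_size = 15L) {
  if (length(templates) == 0L) stop("empty template set", call. = FALSE)
  seqs <- getReadSeqs(reads)
  by_template <- vector("list", length(templates))
  names(by_template) <- names(templates)
  hit_any <- rep(FALSE, length(seqs))
  for (tn in names(templates)) {
    ref <- templates[[tn]]
    idx <- kmerIndex(ref, word_size)
    ref_int <- baseToInt(ref)
    L <- length(ref_int)
    keep <- logical(length(seqs))
    for (i in seq_along(seqs)) {
      for (s in c(seqs[[i]], reverseComplement_(seqs[[i]]))) {
        starts <- candidateStarts(s, idx, word_size, 10L, L, word_size)
        if (!length(starts)) next
        q_int <- baseToInt(s)
        found <- FALSE
        for (st in starts) {
          al <- alignAt(q_int, ref_int, st)
          v <- ifelse(q_int[al$q_from:al$q_to] == ref_int[al$ref_start:al$ref_end] &
                        q_int[al$q_from:al$q_to] != 0L, 1, -2)
          best <- 0; cur <- 0
          for (x in v) { cur <- max(0, cur + x); best <- max(best, cur) }
          if (best >= min_score) { found <- TRUE; break }
        }
        if (found) { keep[i] <- TRUE; break }
      }
    }
    by_template[[tn]] <- names(seqs)[keep]
    hit_any <- hit_any | keep
  }
  list(by_template = by_template, discarded = names(seqs)[!hit_any])
}

#' Map reads to a reference by gapless seed-and-extend
#'
#' Seeds each read (both strands) by shared k-mers, evaluates every
#' candidate diagonal gaplessly, discards placements failing the
#' length-fraction or identity-fraction thresholds, picks the
#' highest-scoring placement (co-optimal placements broken by seeded RNG),
#' and accumulates a base-count pileup on the reference strand.
#'
#' @param reads \linkS4class{ReadSet} or named character vector.
#' @param reference single reference sequence (character) or a named
#'   length-1 vector.
#' @param params a \code{\link{mappingParams}}.
#' @param seed RNG seed for co-optimal placement choice.
#' @return a \linkS4class{Pileup}.
#' @export
mapReads <- function(reads, reference, params = mappingParams(), seed = 1L) {
  refname <- if (!is.null(names(reference))) names(reference)[1] else "ref"
  ref <- toupper(unname(reference[[1]]))
  if (!nzchar(ref)) stop("reference must be non-empty", call. = FALSE)
  seqs <- getReadSeqs(reads)
  ref_int <- baseToInt(ref)
  L <- length(ref_int)
  idx <- kmerIndex(ref, params$kmer_size)
  counts <- matrix(0L, 4L, L, dimnames = list(DNA_BASES_, NULL))
  place <- vector("list", length(seqs))
  n_unmapped <- 0L
  set.seed(seed)
  for (i in seq_along(seqs)) {
    best <- NULL; best_score <- -1L; n_co <- 0L
    for (strand in c("+", "-")) {
      s <- if (strand == "+") seqs[[i]] else reverseComplement_(seqs[[i]])
      len <- nchar(s)
      min_overlap <- ceiling(params$min_length_fraction * len)
      starts <- candidateStarts(s, idx, params$kmer_size, params$probe_step,
                                L, min_overlap)
      if (length(starts) > params$max_hits_reported)
        starts <- starts[seq_len(params$max_hits_reported)]
      if (!length(starts)) next
      q_int <- baseToInt(s)
      for (st in starts) {
        al <- alignAt(q_int, ref_int, st)
        if (al$aligned_len < min_overlap) next
        if (al$matches / al$aligned_len < params$min_identity_fraction) next
        if (al$matches > best_score) {
          best_score <- al$matches
          best <- c(al, list(strand = strand, seq = s))
          n_co <- 1L
        } else if (al$matches == best_score) {
          # reservoir choice among co-optimal placements
          n_co <- n_co + 1L
          if (runif(1) < 1 / n_co) best <- c(al, list(strand = strand, seq = s))
        }
      }
    }
    if (is.null(best)) { n_unmapped <- n_unmapped + 1L; next }
    aligned <- substr(best$seq, best$q_from, best$q_to)
    b_int <- baseToInt(aligned)
    pos <- best$ref_start:best$ref_end
    ok <- b_int != 0L
    if (any(ok)) {
      flat <- (pos[ok] - 1L) * 4L + b_int[ok]
      tab <- tabulate(flat, nbins = 4L * L)
      counts <- counts + matrix(tab, 4L, L)
    }
    place[[i]] <- data.frame(read_id = names(seqs)[i],
                             start = best$ref_start - 1L,
                             end = best$ref_end,
                             strand = best$strand,
                             mismatches = best$aligned_len - best$matches,
                             bases = aligned)
  }
  placements <- do.call(rbind, place[!vapply(place, is.null, TRUE)])
  if (is.null(placements))
    placements <- data.frame(read_id = character(0), start = integer(0),
                             end = integer(0), strand = character(0),
                             mismatches = integer(0), bases = character(0))
  new("Pileup", refname = refname, reference = ref, counts = counts,
      placements = placements, n_unmapped = n_unmapped)
}

#' Call a consensus sequence from a pileup
#'
#' Per column, the majority base; ties are broken in fixed alphabetical
#' order (A < C < G < T); zero-depth columns keep the reference base.
#'
#' @param pileup a \linkS4class{Pileup}.
#' @return named character scalar (name = reference name).
#' @export
callConsensus <- function(pileup) {
  m <- pileup@counts
  L <- ncol(m)
  if (L == 0L) stop("empty pileup", call. = FALSE)
  top <- max.col(t(m), ties.method = "first")  # rows are A,C,G,T
  depth <- colSums(m)
  cons <- DNA_BASES_[top]
  refv <- strsplit(pileup@reference, "", fixed = TRUE)[[1]]
  cons[depth == 0L] <- refv[depth == 0L]
  setNames(paste(cons, collapse = ""), pileup@refname)
}

#' Iterative consensus assembly to a fixed point
#'
#' Maps reads to the current reference (the ortholog template on the first
#' cycle), calls the consensus, and remaps to the new consensus until the
#' consensus stops changing or \code{max_iter} cycles are reached.
#'
#' @param reads \linkS4class{ReadSet} or named character vector.
#' @param template starting reference (named character scalar).
#' @param params a \code{\link{mappingParams}} (relaxed defaults).
#' @param max_iter iteration cap (default 20).
#' @param seed RNG seed (per-iteration streams derived from it).
#' @return list: \code{consensus} (final sequence), \code{pileup} (final),
#'   \code{converged} (logical), \code{history} (data.frame iteration,
#'   n_mapped, changed_positions).
#' @export
iterateToConvergence <- function(reads, template, params = mappingParams(),
                                 max_iter = 20L, seed = 1L) {
  stopifnot(max_iter >= 1L)
  refname <- if (!is.null(names(template))) names(template)[1] else "ref"
  current <- setNames(toupper(unname(template[[1]])), refname)
  history <- list()
  pileup <- NULL
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    pileup <- mapReads(reads, current, params, seed = deriveSeed(seed, it))
    cons <- callConsensus(pileup)
    changed <- sum(strsplit(unname(cons), "")[[1]] !=
                     strsplit(unname(current), "")[[1]])
    n_mapped <- nrow(pileup@placements)
    history[[it]] <- data.frame(iteration = it, n_mapped = n_mapped,
                                changed_positions = changed)
    current <- cons
    if (changed == 0L) { converged <- TRUE; break }
  }
  if (!converged)
    warning("consensus did not converge within ", max_iter, " iterations")
  list(consensus = current, pileup = pileup, converged = converged,
       history = do.call(rbind, history))
}
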