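#' Homeolog-specific count container
#'
#' A \code{SummarizedExperiment} with assay layers \code{raw} (integer
#' fragment counts), and after normalization \code{normalized} and
#' \code{vst}; per-sample size factors live in \code{colData$sizeFactor}.
#'
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @exportClass HomeologCounts
setClass("HomeologCounts", contains = "SummarizedExperiment")

#' Build a HomeologCounts object
#'
#' @param counts homeolog x sample matrix of non-negative integer fragment
#'   counts (rownames \code{gene_label}, colnames \code{stage_replicate}).
#' @param stage character vector of stage labels per sample (default parsed
#'   from column names as the text before \code{_R<k>}).
#' @param replicate character vector of replicate labels per sample.
#' @return a \linkS4class{HomeologCounts}.
#' @export
homeologCounts <- function(counts, stage = NULL, replicate = NULL) {
  if (any(counts < 0) || any(counts != round(counts)))
    stop("raw counts must be non-negative integers", call. = FALSE)
  storage.mode(counts) <- "integer"
  if (is.null(stage)) stage <- sub("_R[0-9]+$", "", colnames(counts))
  if (is.null(replicate)) replicate <- sub("^.*_(R[0-9]+)$", "\\1",
                                           colnames(counts))
  cd <- S4Vectors::DataFrame(stage = stage, replicate = replicate,
                             row.names = colnames(counts))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(raw = counts), colData = cd)
  new("HomeologCounts", se)
}

#' @rdname homeologCounts
#' @param x a \linkS4class{HomeologCounts}
#' @export
rawCounts <- function(x) SummarizedExperiment::assay(x, "raw")
#' @rdname homeologCounts
#' @export
normalizedCounts <- function(x) SummarizedExperiment::assay(x, "normalized")
#' @rdname homeologCounts
#' @export
vstValues <- function(x) SummarizedExperiment::assay(x, "vst")
#' @rdname homeologCounts
#' @export
sampleSizeFactors <- function(x)
  setNames(SummarizedExperiment::colData(x)$sizeFactor, colnames(x))
#' @rdname homeologCounts
#' @export
sampleStages <- function(x)
  setNames(SummarizedExperiment::colData(x)$stage, colnames(x))

setMethod("show", "HomeologCounts", function(object) {
  cat("HomeologCounts:", nrow(object), "homeologs x", ncol(object),
      "samples; layers:",
      paste(SummarizedExperiment::assayNames(object), collapse = ", "), "\n")
})

#' Median-of-ratios size factors
#'
#' For each sample, the median across zero-free rows of the ratio of its
#' count to the row's geometric mean (the scaling normalization of Anders &
#' Huber). Rows containing any zero are excluded from the median. With
#' \code{rescale = TRUE} the factors are divided by their geometric mean so
#' they multiply to one; under that convention the estimator is exactly
#' idempotent (the factors of the normalized matrix are all 1), whereas the
#' literal factors of a normalized matrix equal the geometric mean of the
#' original factors.
#'
#' @param raw homeolog x sample count matrix.
#' @param rescale divide the factors by their geometric mean.
#' @return named numeric vector of per-sample size factors.
#' @export
medianOfRatios <- function(raw, rescale = FALSE) {
  zero_free <- rowSums(raw == 0) == 0L
  if (!any(zero_free))
    stop("no zero-free rows; median-of-ratios undefined (consider a ",
         "pseudo-reference fallback)", call. = FALSE)
  m <- raw[zero_free, , drop = FALSE]
  geo <- exp(rowMeans(log(m)))
  sf <- apply(m, 2L, function(col) median(col / geo))
  if (rescale) sf <- sf / exp(mean(log(sf)))
  sf
}

#' Normalize counts by size factors
#'
#' Computes median-of-ratios size factors, rescales them to geometric mean
#' one (so the normalized layer is scale-neutral: its own size factors are
#' exactly 1), stores them in the column data and adds the
#' \code{normalized} assay (raw / size factor).
#'
#' @param x a \linkS4class{HomeologCounts}.
#' @return the updated object.
#' @export
normalizeCounts <- function(x) {
  sf <- medianOfRatios(rawCounts(x), rescale = TRUE)
  SummarizedExperiment::colData(x)$sizeFactor <- unname(sf)
  SummarizedExperiment::assay(x, "normalized") <-
    sweep(rawCounts(x), 2L, sf, "/")
  x
}

#' Closed-form negative-binomial variance-stabilizing transform
#'
#' v(x) = (2 / sqrt(a)) * asinh(sqrt(a x)) for common dispersion a,
#' degenerating to the Poisson limit 2 sqrt(x) as a -> 0.
#'
#' @param x non-negative values (normalized counts).
#' @param dispersion common NB dispersion a (>= 0).
#' @return transformed values, same shape as \code{x}.
#' @export
vstClosedForm <- function(x, dispersion) {
  if (any(x < 0)) stop("vst input must be non-negative", call. = FALSE)
  if (dispersion <= 1e-12) return(2 * sqrt(x))
  (2 / sqrt(dispersion)) * asinh(sqrt(dispersion * x))
}

#' Method-of-moments common dispersion
#'
#' Across rows of a normalized count matrix: per-row dispersion
#' (var - mean) / mean^2, pooled as the median over rows with positive mean
#' (negative estimates floored at zero).
#'
#' @param normalized homeolog x sample matrix.
#' @return scalar dispersion estimate.
#' @export
estimateDispersion <- function(normalized) {
  m <- rowMeans(normalized)
  v <- apply(normalized, 1L, var)
  ok <- m > 0
  if (!any(ok)) return(0)
  alpha <- pmax((v[ok] - m[ok]) / m[ok]^2, 0)
  median(alpha)
}

#' Add the VST layer
#'
#' @param x a normalized \linkS4class{HomeologCounts}.
#' @param dispersion common NB dispersion (default: method-of-moments
#'   estimate from the normalized layer).
#' @return the updated object.
#' @export
vstCounts <- function(x, dispersion = NULL) {
  nc <- normalizedCounts(x)
  if (is.null(dispersion)) dispersion <- estimateDispersion(nc)
  SummarizedExperiment::assay(x, "vst") <- vstClosedForm(nc, dispersion)
  S4Vectors::metadata(x)$vst_dispersion <- dispersion
  x
}

#' Standardize rows to their mean
#'
#' Divides each row by its mean so profiles become fold-of-mean; zero-mean
#' rows are returned as zeros and flagged in the \code{degenerate}
#' attribute.
#'
#' @param m numeric matrix with >= 2 columns.
#' @return standardized matrix with attribute \code{degenerate} (logical
#'   per row).
#' @export
standardizeRows <- function(m) {
  if (ncol(m) < 2L) stop("need >= 2 columns", call. = FALSE)
  mu <- rowMeans(m)
  out <- m / mu
  deg <- mu == 0
  out[deg, ] <- 0
  attr(out, "degenerate") <- deg
  out
}

#' Sample ordination diagnostics (PCA + classical MDS)
#'
#' PCA on column-centered VST values with samples as observations (scores
#' of the first two components and per-component variance fractions), plus
#' classical multidimensional scaling of the Euclidean sample distance
#' matrix, and the distance matrix itself for heat-map export.
#'
#' @param vst_matrix homeolog x sample matrix of VST values.
#' @return list: \code{pca_scores} (samples x 2), \code{variance_fraction}
#'   (per component), \code{mds_points} (samples x 2), \code{distances}
#'   (sample x sample matrix).
#' @export
ordinateSamples <- function(vst_matrix) {
  if (ncol(vst_matrix) < 3L) stop("need >= 3 samples", call. = FALSE)
  X <- t(vst_matrix)
  pc <- prcomp(X, center = TRUE, scale. = FALSE)
  varfrac <- pc$sdev^2 / sum(pc$sdev^2)
  d <- as.matrix(dist(X))
  mds <- cmdscale(as.dist(d), k = 2L)
  list(pca_scores = pc$x[, 1:2, drop = FALSE],
       variance_fraction = varfrac,
       mds_points = mds,
       distances = d)
}

#' Pearson correlation of homeolog expression with tocol accumulation
#'
#' Replicates are averaged by stage first; each homeolog's stage profile is
#' then correlated with each tocol compound curve across the (>= 3)
#' developmental stages. Degenerate profiles (zero variance) yield NA.
#'
#' @param counts homeolog x sample matrix (normalized counts).
#' @param stages stage label per sample column.
#' @param tocols data.frame with a \code{stage} column and one column per
#'   compound (e.g. T, T3, total).
#' @return list: \code{r} (homeolog x compound correlation matrix),
#'   \code{stage_means} (homeolog x stage matrix).
#' @export
correlateWithTocols <- function(counts, stages, tocols) {
  stage_levels <- unique(tocols$stage)
  if (length(stage_levels) < 3L)
    stop("correlation undefined with fewer than 3 stages", call. = FALSE)
  if (!all(stage_levels %in% stages))
    stop("tocol stages missing from the count matrix", call. = FALSE)
  sm <- vapply(stage_levels, function(st)
    rowMeans(counts[, stages == st, drop = FALSE]), numeric(nrow(counts)))
  compounds <- setdiff(colnames(tocols), "stage")
  r <- matrix(NA_real_, nrow(counts), length(compounds),
              dimnames = list(rownames(counts), compounds))
  for (cp in compounds) {
    y <- tocols[[cp]][match(stage_levels, tocols$stage)]
    for (i in seq_len(nrow(sm))) {
      if (sd(sm[i, ]) > 0 && sd(y) > 0) r[i, cp] <- cor(sm[i, ], y)
    }
  }
  list(r = r, stage_means = sm)
}

## ---- strict ("zero tolerance") fragment counting ----

strictCandidateIndex <- function(homeologs, read_lengths) {
  envs <- list()
  for (len in sort(unique(read_lengths))) {
    e <- new.env(parent = emptyenv(), size = 4096L)
    for (h in names(homeologs)) {
      s <- homeologs[[h]]
      L <- nchar(s)
      if (L < len) next
      starts <- seq_len(L - len + 1L)
      subs <- substring(s, starts, starts + len - 1L)
      for (x in unique(subs)) {
        cur <- e[[x]]
        if (is.null(cur)) e[[x]] <- h
        else if (!(h %in% cur)) e[[x]] <- c(cur, h)
      }
    }
    envs[[as.character(len)]] <- e
  }
  envs
}

lookupStrict <- function(seq, envs) {
  e <- envs[[as.character(nchar(seq))]]
  if (is.null(e)) return(character(0))
  fwd <- e[[seq]]
  rev <- e[[reverseComplement_(seq)]]
  unique(c(fwd, rev))
}

#' Strict full-length matching of fragments to homeologs
#'
#' Implements the zero-tolerance mapping used for expression counting: a
#' read matches a homeolog only end-to-end and mismatch-free (length and
#' identity fractions of 1), on either strand. For a pair, the fragment's
#' candidates are the homeologs matched by both mates; one mapped mate is a
#' broken pair; singletons use their own matches.
#'
#' @param pairs \linkS4class{ReadSet} of mate-linked reads (or NULL).
#' @param singletons \linkS4class{ReadSet} of single reads (or NULL).
#' @param homeologs named character vector of homeolog sequences.
#' @return data.frame: fragment, status (pair_both_mapped /
#'   singleton_mapped / broken_pair / unmapped), n_candidate_placements,
#'   candidates (comma-separated homeolog ids).
#' @export
strictMap <- function(pairs = NULL, singletons = NULL, homeologs) {
  lens <- integer(0)
  if (!is.null(pairs)) lens <- c(lens, nchar(pairs@sequence))
  if (!is.null(singletons)) lens <- c(lens, nchar(singletons@sequence))
  envs <- strictCandidateIndex(homeologs, lens)
  frg <- character(0); sts <- character(0); ncand <- integer(0)
  cnd <- character(0)
  if (!is.null(pairs) && length(pairs)) {
    frag <- fragmentOf(pairs@id)
    cands <- lapply(pairs@sequence, lookupStrict, envs = envs)
    by_frag <- split(seq_along(frag), frag)
    n <- length(by_frag)
    frg_p <- names(by_frag)
    sts_p <- character(n); ncand_p <- integer(n); cnd_p <- character(n)
    for (k in seq_len(n)) {
      idx <- by_frag[[k]]
      mapped <- lengths(cands[idx]) > 0L
      if (length(idx) == 2L) {
        if (all(mapped)) {
          joint <- intersect(cands[[idx[1]]], cands[[idx[2]]])
          if (length(joint)) {
            sts_p[k] <- "pair_both_mapped"
            ncand_p[k] <- length(joint)
            cnd_p[k] <- paste(joint, collapse = ",")
          } else sts_p[k] <- "unmapped"
        } else if (any(mapped)) sts_p[k] <- "broken_pair"
        else sts_p[k] <- "unmapped"
      } else {  # unpaired member of a nominal pair: treat as singleton
        cc <- cands[[idx[1]]]
        sts_p[k] <- if (length(cc)) "singleton_mapped" else "unmapped"
        ncand_p[k] <- length(cc)
        cnd_p[k] <- paste(cc, collapse = ",")
      }
    }
    frg <- c(frg, frg_p); sts <- c(sts, sts_p)
    ncand <- c(ncand, ncand_p); cnd <- c(cnd, cnd_p)
  }
  if (!is.null(singletons) && length(singletons)) {
    cands <- lapply(singletons@sequence, lookupStrict, envs = envs)
    frg <- c(frg, singletons@id)
    sts <- c(sts, ifelse(lengths(cands) > 0L, "singleton_mapped", "unmapped"))
    ncand <- c(ncand, lengths(cands))
    cnd <- c(cnd, vapply(cands, paste, "", collapse = ","))
  }
  data.frame(fragment = frg, status = sts, n_candidate_placements = ncand,
             candidates = cnd)
}

#' Count fragments per homeolog with the multimap assignment rule
#'
#' A mapped pair contributes one fragment, a mapped singleton one, a broken
#' pair zero. Fragments with a single candidate are assigned directly;
#' fragments matching several homeologs are assigned randomly with
#' probability proportional to each candidate's unique-fragment count
#' divided by its length (equal weights when no unique counts exist).
#'
#' @param hits data.frame from \code{\link{strictMap}}.
#' @param homeolog_lengths named numeric, length of each homeolog.
#' @param seed RNG seed for the random assignment.
#' @return list: \code{counts} (named integer per homeolog),
#'   \code{assignment} (hits with an \code{assigned} column),
#'   \code{status_tally} (table of fragment statuses).
#' @export
countFragments <- function(hits, homeolog_lengths, seed = 1L) {
  counts <- setNames(integer(length(homeolog_lengths)),
                     names(homeolog_lengths))
  assigned <- rep(NA_character_, nrow(hits))
  countable <- hits$status %in% c("pair_both_mapped", "singleton_mapped")
  cand_list <- strsplit(hits$candidates, ",", fixed = TRUE)
  unique_idx <- which(countable & hits$n_candidate_placements == 1L)
  for (i in unique_idx) {
    h <- cand_list[[i]]
    counts[h] <- counts[h] + 1L
    assigned[i] <- h
  }
  unique_counts <- counts
  multi_idx <- which(countable & hits$n_candidate_placements > 1L)
  set.seed(seed)
  for (i in multi_idx) {
    cand <- cand_list[[i]]
    w <- unique_counts[cand] / homeolog_lengths[cand]
    if (sum(w) <= 0) w <- rep(1, length(cand))
    h <- cand[sample.int(length(cand), 1L, prob = w)]
    counts[h] <- counts[h] + 1L
    assigned[i] <- h
  }
  hits$assigned <- assigned
  list(counts = counts, assignment = hits,
       status_tally = table(hits$status))
}
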