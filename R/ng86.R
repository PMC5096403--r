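## Nei-Gojobori (1986) synonymous/nonsynonymous rates.
##
## Sites: each codon position contributes the fraction of its possible
## single-nucleotide changes that are synonymous, with changes to stop codons
## excluded from the denominator. Differences: for codon pairs differing at k
## positions, all k! mutational pathways are enumerated, pathways passing
## through a stop codon are discarded, and synonymous/nonsynonymous step
## counts are averaged over the surviving pathways (equal weights).
## Distances are Jukes-Cantor corrected: d = -3/4 ln(1 - 4p/3).
##
## The implementation is table-driven: per-codon site fractions and the
## 64 x 64 pairwise (Sd, Nd) matrices are computed once and cached, so
## per-alignment work is a vector lookup.

.ng86_cache <- new.env(parent = emptyenv())

allCodons <- function() {
  b <- DNA_BASES_
  as.vector(outer(outer(b, b, paste0), b, paste0))  # fast-varying 3rd pos last
}

codonAA <- function() {
  gc <- Biostrings::GENETIC_CODE
  setNames(unname(gc[allCodons()]), allCodons())
}

isStopCodon <- function(codons) codonAA()[codons] == "*"

ng86Tables <- function() {
  if (!is.null(.ng86_cache$tables)) return(.ng86_cache$tables)
  codons <- allCodons()
  aa <- codonAA()
  nc <- length(codons)
  splitc <- strsplit(codons, "", fixed = TRUE)

  # per-codon synonymous site count
  S <- rep(NA_real_, nc)
  names(S) <- codons
  for (i in seq_len(nc)) {
    if (aa[i] == "*") next
    s <- 0
    for (pos in 1:3) {
      alts <- setdiff(DNA_BASES_, splitc[[i]][pos])
      alt_codons <- vapply(alts, function(b) {
        cd <- splitc[[i]]; cd[pos] <- b; paste(cd, collapse = "")
      }, "")
      valid <- alt_codons[aa[alt_codons] != "*"]
      if (length(valid))
        s <- s + sum(aa[valid] == aa[i]) / length(valid)
    }
    S[i] <- s
  }

  # pairwise pathway-averaged differences
  Sd <- matrix(NA_real_, nc, nc, dimnames = list(codons, codons))
  Nd <- Sd
  blocked <- matrix(FALSE, nc, nc, dimnames = list(codons, codons))
  perms <- list(`1` = list(1L),
                `2` = list(c(1L, 2L), c(2L, 1L)),
                `3` = list(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
                           c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L)))
  for (i in seq_len(nc)) {
    if (aa[i] == "*") next
    for (j in seq_len(nc)) {
      if (aa[j] == "*") next
      diffpos <- which(splitc[[i]] != splitc[[j]])
      k <- length(diffpos)
      if (k == 0L) { Sd[i, j] <- 0; Nd[i, j] <- 0; next }
      tot_s <- 0; tot_n <- 0; n_ok <- 0L
      for (ord in perms[[as.character(k)]]) {
        cur <- splitc[[i]]
        s_steps <- 0L; n_steps <- 0L; ok <- TRUE
        prev <- paste(cur, collapse = "")
        for (step in seq_len(k)) {
          p <- diffpos[ord[step]]
          cur[p] <- splitc[[j]][p]
          nxt <- paste(cur, collapse = "")
          if (step < k && aa[nxt] == "*") { ok <- FALSE; break }
          if (aa[nxt] == aa[prev]) s_steps <- s_steps + 1L
          else n_steps <- n_steps + 1L
          prev <- nxt
        }
        if (ok) { tot_s <- tot_s + s_steps; tot_n <- tot_n + n_steps
                  n_ok <- n_ok + 1L }
      }
      if (n_ok == 0L) { Sd[i, j] <- 0; Nd[i, j] <- 0; blocked[i, j] <- TRUE }
      else { Sd[i, j] <- tot_s / n_ok; Nd[i, j] <- tot_n / n_ok }
    }
  }
  .ng86_cache$tables <- list(codons = codons, aa = aa, S = S,
                             Sd = Sd, Nd = Nd, blocked = blocked)
  .ng86_cache$tables
}

splitCodons <- function(seq) {
  seq <- toupper(seq)
  n <- nchar(seq)
  if (n %% 3L != 0L)
    stop("sequence length ", n, " is not a multiple of 3", call. = FALSE)
  if (grepl("[^ACGT]", seq))
    stop("sequence contains non-ACGT characters (ambiguity codes are not ",
         "valid input for codon-level rate estimation)", call. = FALSE)
  substring(seq, seq(1L, n, 3L), seq(3L, n, 3L))
}

#' Strip gapped codon columns from a pairwise alignment
#'
#' Removes every codon column in which either sequence carries a gap
#' character, so downstream site and difference counts only see ungapped
#' codons. Gaps must respect the reading frame (the alignment is codon
#' aware).
#'
#' @param seq_a,seq_b aligned sequences of equal length, multiple of 3;
#'   gaps as \code{-}.
#' @return list with gap-free \code{seq_a}, \code{seq_b} and
#'   \code{n_removed} codon columns removed.
#' @export
stripGapColumns <- function(seq_a, seq_b) {
  seq_a <- toupper(seq_a); seq_b <- toupper(seq_b)
  if (nchar(seq_a) != nchar(seq_b))
    stop("aligned sequences must have equal length", call. = FALSE)
  if (nchar(seq_a) %% 3L != 0L)
    stop("alignment length must be a multiple of 3", call. = FALSE)
  ca <- substring(seq_a, seq(1L, nchar(seq_a), 3L), seq(3L, nchar(seq_a), 3L))
  cb <- substring(seq_b, seq(1L, nchar(seq_b), 3L), seq(3L, nchar(seq_b), 3L))
  keep <- !grepl("-", ca, fixed = TRUE) & !grepl("-", cb, fixed = TRUE)
  if (!any(keep))
    stop("no ungapped codon columns remain after gap stripping", call. = FALSE)
  a2 <- paste(ca[keep], collapse = "")
  b2 <- paste(cb[keep], collapse = "")
  aa_a <- codonAA()[splitCodons(a2)]
  aa_b <- codonAA()[splitCodons(b2)]
  if (any(head(aa_a, -1L) == "*") || any(head(aa_b, -1L) == "*"))
    stop("internal stop codon after gap stripping", call. = FALSE)
  list(seq_a = a2, seq_b = b2, n_removed = sum(!keep))
}

#' Drop codon columns containing stop codons
#'
#' Removes every codon column in which any of the aligned sequences carries
#' a stop codon. Reconstructed consensus sequences can carry artifactual
#' in-frame stops at miscalled columns; rate estimation excludes those
#' columns, mirroring the exclusion of gapped positions.
#'
#' @param seqs named character vector of equal-length, in-frame sequences.
#' @return list: \code{seqs} (cleaned), \code{n_removed} codon columns.
#' @export
maskStopCodonColumns <- function(seqs) {
  if (length(unique(nchar(seqs))) != 1L)
    stop("sequences must have equal length", call. = FALSE)
  n <- nchar(seqs[[1]])
  if (n %% 3L != 0L)
    stop("alignment length must be a multiple of 3", call. = FALSE)
  aa <- codonAA()
  codon_mat <- vapply(seqs, function(s)
    substring(s, seq(1L, n, 3L), seq(3L, n, 3L)), character(n %/% 3L))
  codon_mat <- matrix(codon_mat, ncol = length(seqs),
                      dimnames = list(NULL, names(seqs)))
  has_stop <- apply(codon_mat, 1L, function(row)
    any(aa[row] == "*", na.rm = TRUE) || any(grepl("[^ACGT]", row)))
  keep <- !has_stop
  if (!any(keep))
    stop("no stop-free codon columns remain", call. = FALSE)
  cleaned <- apply(codon_mat[keep, , drop = FALSE], 2L, paste, collapse = "")
  list(seqs = setNames(cleaned, names(seqs)), n_removed = sum(has_stop))
}

#' Synonymous and nonsynonymous site counts (NG86)
#'
#' @param seq gap-free coding sequence (length a multiple of 3, no internal
#'   stops, no ambiguity codes).
#' @return named numeric \code{c(S=, N=)}: fractional synonymous and
#'   nonsynonymous sites; \code{S + N} equals 3 x codons minus the
#'   stop-change exclusions.
#' @export
ng86Sites <- function(seq) {
  tb <- ng86Tables()
  codons <- splitCodons(seq)
  if (any(tb$aa[codons] == "*"))
    stop("sequence contains a stop codon", call. = FALSE)
  S <- sum(tb$S[codons])
  c(S = S, N = 3 * length(codons) - S)
}

#' Pathway-averaged synonymous/nonsynonymous differences (NG86)
#'
#' @param seq_a,seq_b gap-free aligned coding sequences of equal length.
#' @return named numeric \code{c(Sd=, Nd=, n_blocked=)}; \code{n_blocked}
#'   counts codon pairs whose every mutational pathway crosses a stop codon
#'   (contributing zero differences).
#' @export
ng86Differences <- function(seq_a, seq_b) {
  tb <- ng86Tables()
  ca <- splitCodons(seq_a); cb <- splitCodons(seq_b)
  if (length(ca) != length(cb))
    stop("sequences must have equal codon length", call. = FALSE)
  if (any(tb$aa[ca] == "*") || any(tb$aa[cb] == "*"))
    stop("sequence contains a stop codon", call. = FALSE)
  idx <- cbind(match(ca, tb$codons), match(cb, tb$codons))
  c(Sd = sum(tb$Sd[idx]), Nd = sum(tb$Nd[idx]),
    n_blocked = sum(tb$blocked[idx]))
}

#' NG86 distance between two coding sequences
#'
#' Counts sites and pathway-averaged differences, then applies the
#' Jukes-Cantor multiple-hit correction to the synonymous and nonsynonymous
#' proportions. Saturated proportions (p >= 3/4) yield \code{NA} distances
#' with \code{saturated = TRUE} rather than an error.
#'
#' @param seq_a,seq_b gap-free aligned coding sequences (pass gapped
#'   alignments through \code{\link{stripGapColumns}} first).
#' @return one-row data.frame: S, N, Sd, Nd, ps, pn, dS, dN,
#'   saturated_s, saturated_n, n_blocked.
#' @export
ng86Distance <- function(seq_a, seq_b) {
  sa <- ng86Sites(seq_a)
  sb <- ng86Sites(seq_b)
  S <- (sa["S"] + sb["S"]) / 2
  N <- (sa["N"] + sb["N"]) / 2
  d <- ng86Differences(seq_a, seq_b)
  ps <- unname(d["Sd"] / S)
  pn <- unname(d["Nd"] / N)
  jc <- function(p) if (p >= 0.75) NA_real_ else -0.75 * log(1 - 4 * p / 3)
  data.frame(S = unname(S), N = unname(N),
             Sd = unname(d["Sd"]), Nd = unname(d["Nd"]),
             ps = ps, pn = pn,
             dS = jc(ps), dN = jc(pn),
             saturated_s = ps >= 0.75, saturated_n = pn >= 0.75,
             n_blocked = unname(d["n_blocked"]))
}

#' Gene-averaged synonymous rate
#'
#' Arithmetic mean of per-gene dS for one genome pair; saturated genes
#' (undefined dS) are dropped with a warning.
#'
#' @param ds numeric vector of per-gene dS values (NA = saturated).
#' @return scalar mean dS.
#' @export
averageKs <- function(ds) {
  sat <- is.na(ds)
  if (all(sat)) stop("all genes saturated; average Ks undefined", call. = FALSE)
  if (any(sat))
    warning(sum(sat), " saturated gene(s) excluded from the Ks average")
  mean(ds[!sat])
}

#' Divergence time from a synonymous rate under a molecular clock
#'
#' T = Ks / (2 lambda), reported in million years, rounded half-up to one
#' decimal. Default clock: 6.1e-9 synonymous substitutions per synonymous
#' site per year.
#'
#' @param ks synonymous substitutions per synonymous site (>= 0).
#' @param lambda clock rate per site per year.
#' @param digits decimals of the reported MYA (NULL = unrounded).
#' @return divergence time in MYA.
#' @export
divergenceTime <- function(ks, lambda = 6.1e-9, digits = 1L) {
  if (any(ks < 0)) stop("ks must be non-negative", call. = FALSE)
  if (lambda <= 0) stop("lambda must be positive", call. = FALSE)
  t_mya <- ks / (2 * lambda) / 1e6
  if (is.null(digits)) t_mya else roundHalfUp(t_mya, digits)
}
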