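#' Published grass synonymous-rate divergence table
#'
#' The printed pairwise Ks estimates and divergence times (MYA) between the
#' three oat subgenome homeolog groups and reference grass genomes, under
#' three Ks estimators: Yang-Nielsen (\code{yn}), Nei-Gojobori (\code{ng})
#' and maximum likelihood (\code{ml}). Shipped as plain text; used as input
#' to the molecular-clock dating arithmetic, which this package recomputes
#' (the non-NG86 Ks columns are treated purely as printed inputs, not
#' re-derived).
#'
#' @return data.frame with columns pair, ks_yn, mya_yn, ks_ng, mya_ng,
#'   ks_ml, mya_ml (36 genome pairs).
#' @export
divergenceTable <- function() {
  path <- system.file("extdata", "grass_ks_divergence.tsv",
                      package = "hexaphase", mustWork = TRUE)
  read.delim(path, check.names = FALSE)
}

#' Recompute clock dating over the published table
#'
#' Applies T = Ks / (2 lambda), rounded half-up to one decimal, to every
#' (Ks, MYA) cell of \code{\link{divergenceTable}} and compares with the
#' printed MYA.
#'
#' @param lambda molecular clock (default 6.1e-9 per site per year).
#' @return data.frame: pair, method, ks, mya_printed, mya_computed, match.
#' @export
datingRegression <- function(lambda = 6.1e-9) {
  tb <- divergenceTable()
  out <- list()
  for (method in c("yn", "ng", "ml")) {
    ks <- tb[[paste0("ks_", method)]]
    printed <- tb[[paste0("mya_", method)]]
    out[[method]] <- data.frame(pair = tb$pair, method = method, ks = ks,
                                mya_printed = printed,
                                mya_computed = divergenceTime(ks, lambda))
  }
  res <- do.call(rbind, out)
  res$match <- abs(res$mya_printed - res$mya_computed) < 1e-9
  rownames(res) <- NULL
  res
}
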