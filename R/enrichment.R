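#' Hypergeometric motif enrichment of a CpG set
#'
#' Tests, for each transcription-factor motif, whether its matches are
#' over-represented in a foreground CpG set (typically top age-associated
#' CpGs in promoters/5'UTRs) relative to a background of array CpGs. With
#' `N` background CpGs, of which `K` match the motif, and a foreground of
#' size `n` containing `k` matches, the upper-tail p-value is
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`, and the fold enrichment
#' is `(k/n) / (K/N)`. No adjustment for CG content or probe composition is
#' made (a known limitation of this style of enrichment test).
#'
#' @param foreground Character vector of CpG ids; must be a subset of
#'   `background`.
#' @param motifs Motif match table with columns `cpg_id`, `motif_id`.
#' @param background Character vector of CpG ids defining the universe.
#' @param min_overlap Report only motifs with at least this many foreground
#'   matches (default 1).
#' @return `data.frame` sorted by p ascending with columns `motif`, `N`,
#'   `K`, `n`, `k`, `p`, `fold`. Motifs absent from the background are
#'   skipped with a warning. Empty when `motifs` is empty.
#' @examples
#' motifs <- data.frame(cpg_id = c("a", "b", "c"), motif_id = "M1")
#' motif_enrichment(c("a", "b"), motifs, background = letters[1:10])
#' @export
motif_enrichment <- function(foreground, motifs, background,
                             min_overlap = 1) {
  stopifnot(is.data.frame(motifs),
            all(c("cpg_id", "motif_id") %in% names(motifs)))
  foreground <- unique(foreground)
  background <- unique(background)
  if (!all(foreground %in% background)) {
    stop("foreground must be a subset of the background CpGs")
  }
  empty <- data.frame(motif = character(0), N = integer(0), K = integer(0),
                      n = integer(0), k = integer(0), p = numeric(0),
                      fold = numeric(0), stringsAsFactors = FALSE)
  if (nrow(motifs) == 0) return(empty)
  motifs <- motifs[motifs$cpg_id %in% background, , drop = FALSE]
  N <- length(background)
  n <- length(foreground)
  rows <- lapply(unique(motifs$motif_id), function(m) {
    hits <- unique(motifs$cpg_id[motifs$motif_id == m])
    K <- length(hits)
    if (K == 0) {
      warning("motif '", m, "' has no background matches; skipped")
      return(NULL)
    }
    k <- sum(foreground %in% hits)
    if (k < min_overlap) return(NULL)
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    fold <- if (n > 0) (k / n) / (K / N) else NA_real_
    data.frame(motif = m, N = N, K = K, n = n, k = k, p = p, fold = fold,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) return(empty)
  out <- out[order(out$p, out$motif), ]
  rownames(out) <- NULL
  out
}

#' Direction-split motif enrichment
#'
#' Runs [motif_enrichment()] separately for the hypermethylating and
#' hypomethylating top-CpG sets, each first restricted to CpGs annotated to
#' the given region classes (promoter and 5'UTR by default, where
#' age-related methylation change concentrates).
#'
#' @param top A list with `hyper` and `hypo` elements as returned by
#'   [select_top()] (data frames with a `cpg` column, or plain character
#'   vectors).
#' @param motifs Motif match table (`cpg_id`, `motif_id`).
#' @param annotation Annotation table (`cpg_id`, `region`).
#' @param background Character vector of CpG ids; defaults to all annotated.
#' @param regions Region classes to which the foreground is restricted.
#' @param min_overlap Passed to [motif_enrichment()].
#' @return Named list with `hyper` and `hypo` enrichment tables (possibly
#'   empty), each with a `direction` column prepended.
#' @export
direction_split_enrichment <- function(top, motifs, annotation,
                                       background = annotation$cpg_id,
                                       regions = c("promoter", "5'UTR"),
                                       min_overlap = 1) {
  as_ids <- function(x) if (is.data.frame(x)) x$cpg else as.character(x)
  keep <- annotation$cpg_id[annotation$region %in% regions]
  out <- lapply(c(hyper = "hyper", hypo = "hypo"), function(dir) {
    fg <- intersect(as_ids(top[[dir]]), keep)
    res <- motif_enrichment(fg, motifs, background, min_overlap)
    if (nrow(res) > 0) cbind(direction = dir, res, stringsAsFactors = FALSE)
    else cbind(direction = character(0), res)
  })
  out
}
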