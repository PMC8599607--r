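#' Per-tissue epigenome-wide correlation screen against age
#'
#' For each CpG, computes the Pearson correlation `r` of its beta values
#' with chronological age, the two-sided p-value from the correlation t-test
#' (`t = r * sqrt(n-2) / sqrt(1-r^2)`, n-2 degrees of freedom), and the
#' signed association statistic `Z = sign(r) * qnorm(1 - p/2)`. `Z` is
#' computed in log space so that p-values far below double precision still
#' give finite values, and is capped at `|Z| <= z_cap` (default 40).
#' Constant CpGs have undefined correlation and are reported as `NA`, which
#' downstream steps drop.
#'
#' @param beta Samples x CpGs beta matrix (one tissue's samples).
#' @param ages Chronological ages in years, one per row of `beta`.
#' @param z_cap Cap on `|Z|` for underflowing p-values.
#' @return `data.frame` with columns `cpg`, `n`, `r`, `z`, `p`.
#' @examples
#' sim <- generate_dataset(sim_config(n_cpgs = 300, seed = 3))
#' blood <- sim$sheet$tissue == "blood"
#' head(screen_age_association(sim$beta[blood, ], sim$sheet$age[blood]))
#' @export
screen_age_association <- function(beta, ages, z_cap = 40) {
  stopifnot(is.matrix(beta), nrow(beta) == length(ages))
  n <- nrow(beta)
  if (n < 4) stop("at least 4 samples are required per tissue")
  if (stats::sd(ages) == 0) stop("ages are constant; screen undefined")
  sds <- apply(beta, 2, stats::sd)
  r <- rep(NA_real_, ncol(beta))
  ok <- sds > 0
  r[ok] <- drop(stats::cor(ages, beta[, ok, drop = FALSE]))
  df <- n - 2
  tstat <- r * sqrt(df) / sqrt(pmax(1 - r^2, .Machine$double.eps))
  # two-sided p and its Z-score, via log probabilities to survive underflow
  logp_half <- stats::pt(-abs(tstat), df, log.p = TRUE)
  p <- pmin(2 * exp(logp_half), 1)
  z <- -stats::qnorm(logp_half, log.p = TRUE)
  z <- sign(r) * pmin(abs(z), z_cap)
  z[!is.na(r) & r == 0] <- 0
  data.frame(cpg = colnames(beta), n = n, r = r, z = z, p = p,
             stringsAsFactors = FALSE)
}

#' Stouffer combination of per-tissue Z statistics
#'
#' Combines signed Z statistics across strata as
#' `Z_meta = sum(w_t * Z_t) / sqrt(sum(w_t^2))`. The default weights are
#' `sqrt(n_t)`, the standard sample-size-weighted variant, which keeps a
#' 199-sample tissue from being diluted by several 5-sample tissues;
#' `weights = "equal"` gives the unweighted form. Strata with missing Z are
#' dropped from both sums.
#'
#' @param z Numeric vector of per-stratum Z statistics (may contain `NA`).
#' @param n Per-stratum sample sizes (same length as `z`).
#' @param weights `"sqrt_n"` or `"equal"`.
#' @return List with `z_meta` and the two-sided normal `p_meta`; both `NA`
#'   if every stratum is missing.
#' @examples
#' stouffer_meta(c(2, 2, 2, 2), n = c(10, 10, 10, 10)) # z_meta = 4
#' @export
stouffer_meta <- function(z, n, weights = c("sqrt_n", "equal")) {
  weights <- match.arg(weights)
  stopifnot(length(z) == length(n))
  ok <- !is.na(z)
  if (!any(ok)) return(list(z_meta = NA_real_, p_meta = NA_real_))
  w <- if (weights == "sqrt_n") sqrt(n[ok]) else rep(1, sum(ok))
  z_meta <- sum(w * z[ok]) / sqrt(sum(w^2))
  list(z_meta = z_meta, p_meta = 2 * stats::pnorm(-abs(z_meta)))
}

#' Tissue-stratified EWAS of age with meta-analysis
#'
#' Runs [screen_age_association()] separately in every tissue with at least
#' `min_n` samples and non-constant age, then combines the per-tissue Z
#' statistics per CpG with [stouffer_meta()]. Association is computed
#' against raw chronological age. No multiple-testing correction is applied
#' to the per-tissue or meta p-values — selection downstream uses a fixed
#' nominal threshold — but Benjamini-Hochberg q-values for the meta p are
#' emitted as a convenience column.
#'
#' @param beta Samples x CpGs beta matrix (all tissues together).
#' @param sheet Sample sheet aligned with `beta`.
#' @param annotation Optional annotation table to join (`gene`, `region`).
#' @param min_n Minimum samples for a tissue to be screened.
#' @param weights Stouffer weighting, `"sqrt_n"` or `"equal"`.
#' @param z_cap Passed to [screen_age_association()].
#' @return An EWAS table: one row per CpG with per-tissue column groups
#'   `<tissue>_r`, `<tissue>_z`, `<tissue>_p`, then `meta_z`, `meta_p`,
#'   `meta_q` and (if annotation is given) `gene`, `region`. The screened
#'   tissues and their sample sizes are attached as attributes
#'   `"tissues"` / `"tissue_n"`.
#' @export
run_ewas <- function(beta, sheet, annotation = NULL, min_n = 4,
                     weights = c("sqrt_n", "equal"), z_cap = 40) {
  weights <- match.arg(weights)
  check_beta_sheet(beta, sheet)
  tissues <- unique(sheet$tissue)
  screens <- list()
  for (t in tissues) {
    idx <- which(sheet$tissue == t)
    if (length(idx) < min_n) {
      warning("tissue '", t, "' has fewer than ", min_n,
              " samples; skipped")
      next
    }
    if (stats::sd(sheet$age[idx]) == 0) {
      warning("tissue '", t, "' has constant age; skipped")
      next
    }
    screens[[t]] <- screen_age_association(beta[idx, , drop = FALSE],
                                           sheet$age[idx], z_cap = z_cap)
  }
  if (length(screens) == 0) stop("no tissue could be screened")

  cpgs <- screens[[1]]$cpg
  out <- data.frame(cpg = cpgs, stringsAsFactors = FALSE)
  zmat <- matrix(NA_real_, length(cpgs), length(screens),
                 dimnames = list(cpgs, names(screens)))
  nvec <- vapply(screens, function(s) s$n[1], 0)
  for (t in names(screens)) {
    s <- screens[[t]]
    out[[paste0(t, "_r")]] <- s$r
    out[[paste0(t, "_z")]] <- s$z
    out[[paste0(t, "_p")]] <- s$p
    zmat[, t] <- s$z
  }
  # vectorized Stouffer across tissue columns with NA masking
  w <- if (weights == "sqrt_n") sqrt(nvec) else rep(1, length(nvec))
  wmat <- matrix(w, nrow(zmat), ncol(zmat), byrow = TRUE)
  wmat[is.na(zmat)] <- NA
  num <- rowSums(wmat * zmat, na.rm = TRUE)
  den <- sqrt(rowSums(wmat^2, na.rm = TRUE))
  z_meta <- ifelse(rowSums(!is.na(zmat)) > 0, num / den, NA_real_)
  out$meta_z <- z_meta
  out$meta_p <- 2 * stats::pnorm(-abs(z_meta))
  out$meta_q <- stats::p.adjust(out$meta_p, method = "BH")
  if (!is.null(annotation)) {
    j <- match(out$cpg, annotation$cpg_id)
    out$gene <- annotation$gene[j]
    out$region <- annotation$region[j]
  }
  attr(out, "tissues") <- names(screens)
  attr(out, "tissue_n") <- nvec
  out
}

#' Select top age-associated CpGs per direction
#'
#' Applies the selection rule used for downstream characterization: CpGs
#' passing a nominal p-value threshold (default `1e-4`), split by the sign
#' of the association Z (hypermethylated with age, `Z > 0`; hypomethylated,
#' `Z < 0`), ordered by `|Z|` descending, and truncated to at most `cap`
#' (default 500) per direction. Ties in `|Z|` at the boundary are broken
#' lexicographically by CpG id.
#'
#' @param screen `data.frame` with columns `cpg`, `z`, `p` (e.g. one
#'   tissue's columns of [run_ewas()] output, or `meta_z` / `meta_p`).
#' @param p_threshold Nominal p-value threshold.
#' @param cap Maximum CpGs per direction (`Inf` for all passing).
#' @return List with `hyper` and `hypo`: `data.frame`s of `cpg`, `z`
#'   ordered by `|z|` descending. Either may be empty.
#' @export
select_top <- function(screen, p_threshold = 1e-4, cap = 500) {
  stopifnot(all(c("cpg", "z", "p") %in% names(screen)))
  pick <- function(sgn) {
    d <- screen[!is.na(screen$p) & screen$p < p_threshold &
                  sign(screen$z) == sgn, c("cpg", "z")]
    d <- d[order(-abs(d$z), d$cpg), , drop = FALSE]
    d <- utils::head(d, cap)
    rownames(d) <- NULL
    d
  }
  list(hyper = pick(1), hypo = pick(-1))
}

#' Exact overlap partition of CpG sets (upset analysis)
#'
#' Partitions the union of several named CpG sets into disjoint membership
#' patterns — the tabular form of an upset plot, generalizing a Venn
#' diagram. Used to find CpGs that are age-associated in many tissues at
#' once.
#'
#' @param sets Named list (>= 2) of character vectors of CpG ids.
#' @return `data.frame` with columns `pattern` (set names joined by `&`),
#'   `degree` (number of member sets), `count`, and a list-column `members`;
#'   counts sum to the size of the union. Sorted by degree then count,
#'   descending.
#' @examples
#' upset_overlap(list(A = c("x", "y"), B = c("y", "z")))
#' @export
upset_overlap <- function(sets) {
  stopifnot(is.list(sets), length(sets) >= 2, !is.null(names(sets)))
  universe <- unique(unlist(sets))
  if (length(universe) == 0) {
    return(data.frame(pattern = character(0), degree = integer(0),
                      count = integer(0)))
  }
  member <- vapply(sets, function(s) universe %in% s,
                   logical(length(universe)))
  if (length(universe) == 1) member <- matrix(member, nrow = 1)
  pattern <- apply(member, 1, function(m) {
    paste(names(sets)[m], collapse = "&")
  })
  degree <- rowSums(member)
  split_ids <- split(universe, pattern)
  out <- data.frame(pattern = names(split_ids),
                    degree = vapply(split_ids, function(ids) {
                      degree[match(ids[1], universe)]
                    }, 0),
                    count = lengths(split_ids),
                    stringsAsFactors = FALSE)
  out$members <- I(unname(split_ids))
  out <- out[order(-out$degree, -out$count, out$pattern), ]
  rownames(out) <- NULL
  out
}

#' Region-class distribution of a CpG set versus background
#'
#' Compares the genomic-context composition (promoter, 5'UTR, exon, intron,
#' 3'UTR, distal intergenic) of a foreground CpG set with a background set,
#' as fractions and their ratio. A promoter ratio above 1 means age-related
#' methylation change concentrates in promoters relative to the array.
#'
#' @param foreground Character vector of CpG ids (e.g. a top set).
#' @param annotation Annotation table with `cpg_id` and `region`.
#' @param background Character vector of CpG ids; defaults to every
#'   annotated CpG.
#' @return `data.frame` with `region`, `fg_n`, `fg_frac`, `bg_n`,
#'   `bg_frac`, `ratio` (`NA` where the background fraction is 0).
#'   Foreground CpGs missing from the annotation are tallied under an
#'   `"unannotated"` row, with a warning.
#' @export
region_distribution <- function(foreground, annotation,
                                background = annotation$cpg_id) {
  classes <- c(region_classes, "unannotated")
  lookup <- function(ids) {
    reg <- annotation$region[match(ids, annotation$cpg_id)]
    reg[is.na(reg)] <- "unannotated"
    factor(reg, levels = classes)
  }
  fg <- lookup(foreground)
  if (any(fg == "unannotated")) {
    warning(sum(fg == "unannotated"),
            " foreground CpG(s) missing from the annotation")
  }
  bg <- lookup(background)
  fg_n <- table(fg)
  bg_n <- table(bg)
  fg_frac <- if (length(foreground) > 0) as.numeric(fg_n) / length(foreground)
             else rep(0, length(classes))
  bg_frac <- if (length(background) > 0) as.numeric(bg_n) / length(background)
             else rep(0, length(classes))
  data.frame(region = classes, fg_n = as.integer(fg_n), fg_frac = fg_frac,
             bg_n = as.integer(bg_n), bg_frac = bg_frac,
             ratio = ifelse(bg_frac > 0, fg_frac / bg_frac, NA_real_),
             stringsAsFactors = FALSE)
}
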