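#' Apply a clock to another species and quantify concordance
#'
#' Evaluates a fitted clock on samples it was not trained on — typically a
#' related species profiled on the same array — reporting, per tissue, the
#' age correlation `R`, the median absolute error, and the median signed
#' error. The signed error is the calibration diagnostic: a clock can rank a
#' new species' samples almost perfectly (high `R`) yet sit systematically
#' off the diagonal, as when a macaque-trained clock overestimates ages in
#' another primate's cortex by several years.
#'
#' @param model A `clock_model` from [fit_clock()].
#' @param beta Samples x CpGs beta matrix for the target samples.
#' @param sheet Sample sheet for the target samples.
#' @param group_by Sheet column defining evaluation groups (default tissue).
#' @param impute_missing If `TRUE`, clock CpGs absent from `beta` are
#'   zero-imputed (a message reports how many) instead of raising an error.
#' @return `data.frame` with one row per group plus an `"all"` row:
#'   `group, n, R, mae, medse`. Groups with no samples are skipped with a
#'   warning; `R` is `NA` for groups of fewer than 3 samples.
#' @export
cross_species_eval <- function(model, beta, sheet, group_by = "tissue",
                               impute_missing = FALSE) {
  stopifnot(inherits(model, "clock_model"))
  check_beta_sheet(beta, sheet)
  need <- names(model$weights)
  absent <- setdiff(need, colnames(beta))
  if (length(absent) > 0 && impute_missing) {
    message("zero-imputing ", length(absent), " clock CpG(s) absent from beta")
    fill <- matrix(0, nrow(beta), length(absent),
                   dimnames = list(rownames(beta), absent))
    beta <- cbind(beta, fill)
  }
  pred <- predict_age(model, beta, sheet)
  groups <- sheet[[group_by]]
  rows <- lapply(unique(groups), function(g) {
    idx <- which(groups == g)
    if (length(idx) == 0) {
      warning("group '", g, "' is empty; skipped")
      return(NULL)
    }
    m <- evaluate_predictions(sheet$age[idx], pred[idx])
    data.frame(group = g, n = m$n, R = m$R, mae = m$mae, medse = m$medse,
               stringsAsFactors = FALSE)
  })
  all_m <- evaluate_predictions(sheet$age, pred)
  out <- rbind(do.call(rbind, rows),
               data.frame(group = "all", n = all_m$n, R = all_m$R,
                          mae = all_m$mae, medse = all_m$medse,
                          stringsAsFactors = FALSE))
  rownames(out) <- NULL
  out
}
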