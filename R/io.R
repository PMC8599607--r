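# All on-disk formats are tab-separated UTF-8 text with '.' decimals and a
# header row naming every column; readers reject ragged (truncated) files.

read_tsv_checked <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  nf <- utils::count.fields(path, sep = "\t", quote = "")
  if (length(unique(nf)) > 1) {
    stop("ragged/truncated file (inconsistent column counts): ", path)
  }
  utils::read.delim(path, sep = "\t", check.names = FALSE,
                    stringsAsFactors = FALSE)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

require_columns <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss) > 0) {
    stop(what, " is missing required column(s): ",
         paste(miss, collapse = ", "))
  }
  invisible(df)
}

#' Read / write a beta-value matrix
#'
#' The canonical layout is samples x CpGs: an `id` column of sample ids and
#' one column per CpG. The transposed dialect (CpGs x samples) is selected
#' with `orientation = "cpgs_by_samples"`, or auto-detected when a sample
#' sheet is supplied and the file's row ids overlap its sample ids. Values
#' are validated to lie in `[0, 1]` (the offending cell is named) and ids
#' must be unique.
#'
#' @param path File path.
#' @param orientation `"samples_by_cpgs"`, `"cpgs_by_samples"`, or
#'   `"auto"` (requires `sheet`).
#' @param sheet Optional sample sheet used for auto-detection.
#' @return Numeric matrix, samples as rows (sample ids as rownames), CpGs
#'   as columns.
#' @export
read_beta <- function(path, orientation = c("samples_by_cpgs",
                                            "cpgs_by_samples", "auto"),
                      sheet = NULL) {
  orientation <- match.arg(orientation)
  df <- read_tsv_checked(path)
  ids <- df[[1]]
  if (anyDuplicated(ids)) {
    stop("duplicate row id(s) in ", path, ": ",
         paste(unique(ids[duplicated(ids)])[1:1], collapse = ", "))
  }
  if (anyDuplicated(names(df)[-1])) stop("duplicate column id(s) in ", path)
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric beta values in ", path)
  rownames(m) <- ids
  bad <- which(m < 0 | m > 1 | is.na(m), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop("beta value out of [0,1] at row '", rownames(m)[bad[1, 1]],
         "', column '", colnames(m)[bad[1, 2]], "'")
  }
  if (orientation == "auto") {
    if (is.null(sheet)) stop("orientation 'auto' requires a sample sheet")
    orientation <- if (mean(rownames(m) %in% sheet$sample_id) >=
                       mean(colnames(m) %in% sheet$sample_id)) {
      "samples_by_cpgs"
    } else {
      "cpgs_by_samples"
    }
  }
  if (orientation == "cpgs_by_samples") m <- t(m)
  m
}

#' @rdname read_beta
#' @param beta Samples x CpGs matrix to write.
#' @export
write_beta <- function(beta, path,
                       orientation = c("samples_by_cpgs",
                                       "cpgs_by_samples")) {
  orientation <- match.arg(orientation)
  m <- if (orientation == "cpgs_by_samples") t(beta) else beta
  df <- data.frame(id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv(df, path)
}

sheet_columns <- c("sample_id", "species", "tissue", "age", "sex",
                   "max_lifespan", "maturity_age")

#' Read / write a sample sheet
#'
#' Required columns: `sample_id`, `species`, `tissue`, `age`, `sex`,
#' `max_lifespan`, `maturity_age`. Ages above the species maximum lifespan
#' are retained with a warning (they are legitimate for predicted ages).
#'
#' @param path File path.
#' @return `data.frame` with the required columns.
#' @export
read_sheet <- function(path) {
  df <- read_tsv_checked(path)
  require_columns(df, sheet_columns, "sample sheet")
  if (anyDuplicated(df$sample_id)) stop("duplicate sample_id in ", path)
  if (any(df$age < 0)) stop("negative age in ", path)
  if (any(df$max_lifespan <= 0) || any(df$maturity_age <= 0)) {
    stop("species constants must be positive in ", path)
  }
  if (any(df$age > df$max_lifespan)) {
    warning("sample(s) with age > max_lifespan retained")
  }
  df
}

#' @rdname read_sheet
#' @param sheet Sample sheet to write.
#' @export
write_sheet <- function(sheet, path) {
  require_columns(sheet, sheet_columns, "sample sheet")
  write_tsv(sheet, path)
}

#' Read / write a CpG annotation table
#'
#' BED-like columns (`chr`, `start`, `end`) plus `cpg_id`, `gene`, `region`
#' (one of the six fixed region classes) and signed `dist_to_tss` in bp.
#'
#' @param path File path.
#' @return Annotation `data.frame`.
#' @export
read_annotation <- function(path) {
  df <- read_tsv_checked(path)
  require_columns(df, c("cpg_id", "gene", "region", "dist_to_tss"),
                  "annotation")
  if (anyDuplicated(df$cpg_id)) stop("duplicate cpg_id in ", path)
  unknown <- setdiff(unique(df$region), region_classes)
  if (length(unknown) > 0) {
    stop("unknown region class(es) in ", path, ": ",
         paste(unknown, collapse = ", "))
  }
  df
}

#' @rdname read_annotation
#' @param annotation Annotation table to write.
#' @export
write_annotation <- function(annotation, path) {
  require_columns(annotation, c("cpg_id", "gene", "region", "dist_to_tss"),
                  "annotation")
  write_tsv(annotation, path)
}

#' Read / write a motif match table
#'
#' Two columns, `cpg_id` and `motif_id`; duplicate pairs are dropped with a
#' warning.
#'
#' @param path File path.
#' @return Motif match `data.frame`.
#' @export
read_motifs <- function(path) {
  df <- read_tsv_checked(path)
  require_columns(df, c("cpg_id", "motif_id"), "motif table")
  dup <- duplicated(df[, c("cpg_id", "motif_id")])
  if (any(dup)) {
    warning(sum(dup), " duplicate (cpg, motif) pair(s) dropped")
    df <- df[!dup, , drop = FALSE]
  }
  df
}

#' @rdname read_motifs
#' @param motifs Motif table to write.
#' @export
write_motifs <- function(motifs, path) {
  require_columns(motifs, c("cpg_id", "motif_id"), "motif table")
  write_tsv(motifs, path)
}

#' Read / write a fitted clock model
#'
#' A clock file is structured text: `#`-prefixed header lines
#' (`key<TAB>value`) carrying the transform kind and constants, alpha, the
#' selected lambda and the training scope, followed by a two-column
#' coefficient table (`cpg_id`, `weight`) in which the intercept occupies
#' the reserved id `(Intercept)`. Coefficients are written with 17
#' significant digits, so a write/read round trip reproduces the model
#' exactly.
#'
#' @param path File path.
#' @return A `clock_model`.
#' @export
read_clock <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  hdr <- grep("^#", lines, value = TRUE)
  kv <- strsplit(sub("^#\\s*", "", hdr), "\t", fixed = TRUE)
  meta <- stats::setNames(vapply(kv, `[`, "", 2), vapply(kv, `[`, "", 1))
  body <- utils::read.delim(text = lines[!grepl("^#", lines)], sep = "\t",
                            stringsAsFactors = FALSE)
  require_columns(body, c("cpg_id", "weight"), "clock file")
  i <- body$cpg_id == "(Intercept)"
  if (sum(i) != 1) stop("clock file must contain exactly one intercept row")
  w <- body$weight[!i]
  names(w) <- body$cpg_id[!i]
  structure(list(
    intercept = body$weight[i],
    weights = w,
    transform = age_transform(meta[["transform"]],
                              offset = as.numeric(meta[["offset"]] %||% 1)),
    alpha = as.numeric(meta[["alpha"]]),
    lambda = as.numeric(meta[["lambda"]]),
    scope = list(species = strsplit(meta[["species"]], ",")[[1]],
                 tissues = strsplit(meta[["tissues"]], ",")[[1]]),
    n_train = as.integer(meta[["n_train"]])
  ), class = "clock_model")
}

#' @rdname read_clock
#' @param model A `clock_model` to write.
#' @export
write_clock <- function(model, path) {
  stopifnot(inherits(model, "clock_model"))
  hdr <- c(
    paste0("# transform\t", model$transform$kind),
    paste0("# offset\t", sprintf("%.17g", model$transform$offset)),
    paste0("# alpha\t", sprintf("%.17g", model$alpha)),
    paste0("# lambda\t", sprintf("%.17g", model$lambda)),
    paste0("# species\t", paste(model$scope$species, collapse = ",")),
    paste0("# tissues\t", paste(model$scope$tissues, collapse = ",")),
    paste0("# n_train\t", model$n_train)
  )
  body <- c("cpg_id\tweight",
            paste0("(Intercept)\t", sprintf("%.17g", model$intercept)),
            paste0(names(model$weights), "\t",
                   sprintf("%.17g", model$weights)))
  writeLines(c(hdr, body), path, useBytes = TRUE)
  invisible(path)
}

#' Run the full analysis pipeline on synthetic data
#'
#' Simulate -> fit a clock -> cross-validate -> tissue-stratified EWAS with
#' meta-analysis -> top-CpG selection, overlap and region distribution ->
#' motif enrichment, writing every table plus a run log (seed, shapes,
#' stage timings) into `out_dir`. With a fixed config the output tables are
#' byte-identical across reruns. Any stage failure aborts with the stage
#' name.
#'
#' The clock transform defaults to relative age when the config holds more
#' than one species (the dual-species design) and the identity otherwise;
#' EWAS is run within the first species' samples.
#'
#' @param config A [sim_config()].
#' @param out_dir Output directory (created if needed).
#' @param cv_scheme `"kfold"` (default; k = 10) or `"loocv"`.
#' @param p_threshold,cap Top-CpG selection parameters.
#' @param enriched_motif,enrichment_factor Optional planted motif passed to
#'   [generate_motifs()].
#' @return Invisibly, a list with the main in-memory artifacts (clock, CV
#'   result, EWAS table, top sets, enrichment).
#' @export
run_pipeline <- function(config, out_dir, cv_scheme = c("kfold", "loocv"),
                         p_threshold = 1e-4, cap = 500,
                         enriched_motif = NULL, enrichment_factor = 1) {
  stopifnot(inherits(config, "sim_config"))
  cv_scheme <- match.arg(cv_scheme)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "run_log.txt")
  cat(sprintf("pipeline seed=%d n_cpgs=%d | R %s | rhesusclocks %s\n",
              config$seed, config$n_cpgs,
              as.character(getRversion()),
              as.character(utils::packageVersion("rhesusclocks"))),
      file = log_path)
  log_stage <- function(name, info) {
    cat(sprintf("%s\t%s\n", name, info), file = log_path, append = TRUE)
  }
  stage <- function(name, expr) {
    t0 <- Sys.time()
    res <- tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
    log_stage(name, sprintf("ok (%.2fs)",
                            as.numeric(Sys.time() - t0, units = "secs")))
    res
  }

  sim <- stage("simulate", {
    s <- generate_dataset(config)
    write_beta(s$beta, file.path(out_dir, "beta.tsv"))
    write_sheet(s$sheet, file.path(out_dir, "sample_sheet.tsv"))
    s
  })
  annotation <- stage("annotate", {
    a <- generate_annotation(config, sim$truth)
    write_annotation(a, file.path(out_dir, "annotation.tsv"))
    a
  })
  motifs <- stage("motifs", {
    m <- generate_motifs(config, annotation, sim$truth,
                         enriched_motif = enriched_motif,
                         enrichment_factor = enrichment_factor)
    write_motifs(m, file.path(out_dir, "motifs.tsv"))
    m
  })

  transform <- if (length(config$species) > 1) age_transform("relative")
               else age_transform("identity")
  clock <- stage("fit", {
    cl <- fit_clock(sim$beta, sim$sheet, transform, seed = config$seed)
    write_clock(cl, file.path(out_dir, "clock.tsv"))
    cl
  })
  cv <- stage("cv", {
    cv <- if (cv_scheme == "loocv") {
      loocv_clock(sim$beta, sim$sheet, transform, seed = config$seed)
    } else {
      kfold_clock(sim$beta, sim$sheet, transform, k = 10,
                  seed = config$seed)
    }
    write_tsv(cv$predictions, file.path(out_dir, "cv_predictions.tsv"))
    metrics <- rbind(
      data.frame(species = "all", n = cv$n, R = cv$R, mae = cv$mae,
                 medse = cv$medse, stringsAsFactors = FALSE),
      cv$by_species)
    write_tsv(metrics, file.path(out_dir, "cv_metrics.tsv"))
    cv
  })

  first_species <- config$species[[1]]$name
  ewas <- stage("ewas", {
    idx <- sim$sheet$species == first_species
    e <- suppressWarnings(
      run_ewas(sim$beta[idx, , drop = FALSE],
               sim$sheet[idx, , drop = FALSE], annotation))
    write_tsv(e, file.path(out_dir, "ewas.tsv"))
    e
  })
  tops <- stage("select_top", {
    scopes <- c(attr(ewas, "tissues"), "meta")
    tops <- lapply(scopes, function(sc) {
      cols <- if (sc == "meta") c("meta_z", "meta_p")
              else paste0(sc, c("_z", "_p"))
      scr <- data.frame(cpg = ewas$cpg, z = ewas[[cols[1]]],
                        p = ewas[[cols[2]]], stringsAsFactors = FALSE)
      ts <- select_top(scr, p_threshold = p_threshold, cap = cap)
      for (dir in c("hyper", "hypo")) {
        write_tsv(ts[[dir]],
                  file.path(out_dir, sprintf("%s_%s.tsv", sc, dir)))
      }
      ts
    })
    names(tops) <- scopes
    tops
  })
  stage("upset", {
    sets <- lapply(tops, function(ts) c(ts$hyper$cpg, ts$hypo$cpg))
    up <- upset_overlap(sets)
    up$members <- vapply(up$members, paste, "", collapse = ",")
    write_tsv(up, file.path(out_dir, "upset.tsv"))
    up
  })
  stage("region_distribution", {
    fg <- c(tops$meta$hyper$cpg, tops$meta$hypo$cpg)
    rd <- region_distribution(fg, annotation)
    write_tsv(rd, file.path(out_dir, "region_distribution.tsv"))
    rd
  })
  enrich <- stage("enrichment", {
    en <- direction_split_enrichment(tops$meta, motifs, annotation)
    for (dir in names(en)) {
      write_tsv(en[[dir]], file.path(out_dir,
                                     sprintf("enrichment_%s.tsv", dir)))
    }
    en
  })
  invisible(list(clock = clock, cv = cv, ewas = ewas, tops = tops,
                 enrichment = enrich))
}
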