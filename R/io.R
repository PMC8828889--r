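condition_aliases <- function() {
  list(
    N = c("n", "normal", "non-stress", "nonstress", "non_stress", "control",
          "irrigated", "well-watered"),
    D = c("d", "s", "stress", "drought", "drought-stress", "drought_stress")
  )
}

normalize_condition <- function(x) {
  al <- condition_aliases()
  lx <- tolower(trimws(x))
  out <- rep(NA_character_, length(x))
  out[lx %in% al$N] <- "N"
  out[lx %in% al$D] <- "D"
  if (anyNA(out)) {
    bad <- unique(x[is.na(out)])
    stop("unknown condition label(s): ", paste(bad, collapse = ", "),
         " (recognized: ", paste(unlist(al), collapse = ", "), ")")
  }
  out
}

#' Read a genotype-by-environment yield trial from CSV
#'
#' Long format: columns `genotype`, `entry_type`, `year`, `condition`,
#' `yield` (comma-separated, header mandatory, `.` decimal). Condition
#' labels are normalized to `N`/`D` via an alias table (`normal`,
#' `non-stress`, `control` ... vs `stress`, `drought`, `S` ...). Wide
#' format: one row per genotype with an optional `entry_type` column and
#' one `year_condition` column per environment (e.g. `2017_N`, `2017_D`).
#'
#' @param path CSV file path.
#' @param format `"long"` (default) or `"wide"`.
#' @return A validated long-format trial data frame of class `ril_trial`.
#'   Duplicate (genotype, year, condition) rows are averaged with a
#'   warning; non-numeric yields and missing columns raise an error naming
#'   the row/column.
#' @export
read_trial <- function(path, format = c("long", "wide")) {
  format <- match.arg(format)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         check.names = FALSE, colClasses = "character")
  if (format == "long") {
    need <- c("genotype", "year", "condition", "yield")
    miss <- setdiff(need, names(raw))
    if (length(miss) > 0L) {
      stop("missing required column(s): ", paste(miss, collapse = ", "))
    }
    if (!"entry_type" %in% names(raw)) raw$entry_type <- "line"
    yield <- suppressWarnings(as.numeric(raw$yield))
    bad <- which(is.na(yield) & !is.na(raw$yield) & nzchar(raw$yield))
    if (length(bad) > 0L) {
      stop("non-numeric yield '", raw$yield[bad[1]], "' at data row ",
           bad[1])
    }
    if (anyNA(yield)) stop("missing yield at data row ",
                           which(is.na(yield))[1])
    out <- data.frame(
      genotype = raw$genotype,
      entry_type = raw$entry_type,
      year = as.character(raw$year),
      condition = normalize_condition(raw$condition),
      yield = yield,
      stringsAsFactors = FALSE
    )
  } else {
    if (!"genotype" %in% names(raw)) stop("missing required column: genotype")
    env_cols <- grep("^.+_[^_]+$", setdiff(names(raw),
                                           c("genotype", "entry_type")),
                     value = TRUE)
    if (length(env_cols) == 0L) {
      stop("wide format needs year_condition columns such as 2017_N")
    }
    if (!"entry_type" %in% names(raw)) raw$entry_type <- "line"
    recs <- lapply(env_cols, function(cn) {
      parts <- strsplit(cn, "_")[[1]]
      cond <- parts[length(parts)]
      yr <- paste(parts[-length(parts)], collapse = "_")
      yield <- suppressWarnings(as.numeric(raw[[cn]]))
      bad <- which(is.na(yield) & nzchar(raw[[cn]]))
      if (length(bad) > 0L) {
        stop("non-numeric yield '", raw[[cn]][bad[1]], "' in column ", cn,
             " at data row ", bad[1])
      }
      data.frame(genotype = raw$genotype, entry_type = raw$entry_type,
                 year = yr, condition = normalize_condition(cond),
                 yield = yield, stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, recs)
    out <- out[!is.na(out$yield), , drop = FALSE]
  }
  if (any(out$yield < 0)) {
    stop("negative yield at data row ", which(out$yield < 0)[1])
  }
  key <- paste(out$genotype, out$year, out$condition)
  if (anyDuplicated(key)) {
    warning("duplicate (genotype, year, condition) rows averaged")
    out <- stats::aggregate(yield ~ genotype + entry_type + year + condition,
                            data = out, FUN = mean)
  }
  out <- out[order(out$year, out$condition, out$genotype), ]
  rownames(out) <- NULL
  class(out) <- c("ril_trial", "data.frame")
  out
}

#' Write a trial table to long-format CSV
#'
#' @param trial A long-format trial data frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trial <- function(trial, path) {
  cols <- c("genotype", "entry_type", "year", "condition", "yield")
  stopifnot(all(cols %in% names(trial)))
  utils::write.csv(as.data.frame(trial)[, cols], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Run the full screening pipeline and write a report bundle
#'
#' End-to-end orchestration: read (or simulate) a trial, then per scope
#' compute the index table, the yield correlations, the CSI weights, scores
#' and ranking; fit the GT biplot (tester-focused: vector angles and ideal
#' tester; symmetric: which-won-where) and the GGE which-won-where view;
#' detect transgressive segregants; and write everything as CSV files plus
#' a JSON summary.
#'
#' @param input Path to a trial CSV, or a trial data frame, or `NULL` to
#'   simulate from `spec`.
#' @param out_dir Output directory (created if needed).
#' @param scope `"both"`, `"pooled"` or `"per_year"`.
#' @param alpha Significance level for index selection.
#' @param entry_types Entry types entering means/correlations.
#' @param top_k Ranking length echoed in the JSON summary.
#' @param spec A [sim_spec()] used when `input` is `NULL`.
#' @param format Input CSV format (`"long"`/`"wide"`).
#' @return Invisibly, a list with the fitted `csi_screen`, the biplots, the
#'   segregant report and the summary. All file outputs live in `out_dir`.
#' @export
run_pipeline <- function(input = NULL, out_dir = "csiscreen-out",
                         scope = c("both", "pooled", "per_year"),
                         alpha = 0.05,
                         entry_types = c("line", "parent", "check"),
                         top_k = 10, spec = sim_spec(),
                         format = c("long", "wide")) {
  scope <- match.arg(scope)
  format <- match.arg(format)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  warnings_log <- character(0)
  collect <- function(expr) {
    withCallingHandlers(expr, warning = function(w) {
      warnings_log <<- c(warnings_log, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  }
  trial <- if (is.null(input)) {
    collect(simulate_ril_trial(spec))
  } else if (is.character(input)) {
    collect(read_trial(input, format = format))
  } else {
    input
  }
  write_trial(trial, file.path(out_dir, "trial.csv"))

  fit <- collect(csi_screen(trial, scope = scope, alpha = alpha,
                            entry_types = entry_types))
  for (sc in names(fit$scopes)) {
    s <- fit$scopes[[sc]]
    utils::write.csv(as.data.frame(s$indices),
                     file.path(out_dir, paste0("indices_", sc, ".csv")),
                     row.names = FALSE)
    utils::write.csv(as.data.frame(s$correlations),
                     file.path(out_dir, paste0("correlations_", sc, ".csv")),
                     row.names = FALSE)
    scores <- as.data.frame(s$scores)
    scores$rank <- match(scores$genotype, s$ranking)
    utils::write.csv(scores[order(scores$rank), ],
                     file.path(out_dir, paste0("csi_", sc, ".csv")),
                     row.names = FALSE)
  }

  # biplots on the last scope (pooled when present)
  sc_main <- names(fit$scopes)[length(fit$scopes)]
  s <- fit$scopes[[sc_main]]
  gt <- build_two_way(s$indices, mode = "GT", csi = s$scores)
  bp_tester <- collect(fit_biplot(gt, partitioning = "tester"))
  bp_sym <- collect(fit_biplot(gt, partitioning = "symmetric"))
  utils::write.csv(data.frame(genotype = rownames(bp_sym$rows),
                              bp_sym$rows),
                   file.path(out_dir, "gt_biplot_rows.csv"),
                   row.names = FALSE)
  utils::write.csv(data.frame(tester = rownames(bp_tester$cols),
                              bp_tester$cols),
                   file.path(out_dir, "gt_biplot_testers.csv"),
                   row.names = FALSE)
  sm <- collect(which_won_where(bp_sym))
  utils::write.csv(sm$testers, file.path(out_dir, "gt_sector_map.csv"),
                   row.names = FALSE)
  ideal <- collect(ideal_tester_ranking(bp_tester))
  utils::write.csv(ideal, file.path(out_dir, "gt_ideal_testers.csv"),
                   row.names = FALSE)

  gge_sm <- NULL
  if (length(unique(paste0(trial$year, trial$condition))) >= 2) {
    gge_sm <- tryCatch({
      gge <- build_two_way(trial, mode = "GGE")
      bp_gge <- collect(fit_biplot(gge, partitioning = "symmetric"))
      sm_gge <- collect(which_won_where(bp_gge))
      utils::write.csv(sm_gge$testers,
                       file.path(out_dir, "gge_sector_map.csv"),
                       row.names = FALSE)
      sm_gge
    }, error = function(e) {
      warnings_log <<- c(warnings_log,
                         paste("GGE biplot skipped:", conditionMessage(e)))
      NULL
    })
  }

  seg <- NULL
  if (sum(trial$entry_type == "parent") > 0) {
    seg <- collect(try(transgressive_segregants(trial), silent = TRUE))
    if (!inherits(seg, "try-error")) {
      seg_rows <- lapply(names(seg$per_env), function(e) {
        do.call(rbind, lapply(c("positive", "negative"), function(dir) {
          ids <- seg$per_env[[e]][[dir]]
          if (length(ids) == 0L) return(NULL)
          data.frame(environment = e, direction = dir, genotype = ids,
                     stringsAsFactors = FALSE)
        }))
      })
      seg_df <- do.call(rbind, seg_rows)
      if (is.null(seg_df)) {
        seg_df <- data.frame(environment = character(0),
                             direction = character(0),
                             genotype = character(0))
      }
      utils::write.csv(seg_df, file.path(out_dir, "segregants.csv"),
                       row.names = FALSE)
    } else {
      seg <- NULL
    }
  }

  summary_obj <- list(
    package = "csiscreen",
    version = as.character(utils::packageVersion("csiscreen")),
    config = list(scope = scope, alpha = alpha, entry_types = entry_types,
                  top_k = top_k,
                  input = if (is.character(input)) input else
                    if (is.null(input)) "simulated" else "in-memory"),
    scopes = lapply(fit$scopes, function(s) list(
      n_genotypes = nrow(s$scores),
      ybar_p = s$means$ybar_p,
      ybar_s = s$means$ybar_s,
      yield_reduction_pct = yield_reduction(s$means),
      significant_indices = s$weights$index,
      weights = as.data.frame(s$weights),
      top = utils::head(s$ranking, top_k)
    )),
    gt_biplot = list(
      var_explained = bp_tester$var_explained[1:2],
      ideal_nearest = ideal$tester[1:3],
      winners = unique(sm$testers$winner)
    ),
    gge_winners = if (!is.null(gge_sm)) unique(gge_sm$testers$winner),
    segregants_overall = if (!is.null(seg)) seg$overall,
    warnings = warnings_log
  )
  jsonlite::write_json(summary_obj, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(list(fit = fit, gt_tester = bp_tester, gt_symmetric = bp_sym,
                 sector_map = sm, ideal = ideal, gge_sectors = gge_sm,
                 segregants = seg, summary = summary_obj))
}

#' Load a pipeline configuration file
#'
#' Reads a structured key-value (YAML) configuration whose keys mirror the
#' arguments of [run_pipeline()]; unknown keys raise an error. Values given
#' directly to [run_pipeline()] override the file.
#'
#' @param path YAML file path.
#' @return Named list of configuration values.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  allowed <- c("input", "out_dir", "scope", "alpha", "entry_types",
               "top_k", "format", "seed")
  bad <- setdiff(names(cfg), allowed)
  if (length(bad) > 0L) {
    stop("unknown configuration key(s): ", paste(bad, collapse = ", "))
  }
  if (!is.null(cfg$alpha) && (cfg$alpha <= 0 || cfg$alpha >= 1)) {
    stop("alpha must lie in (0, 1)")
  }
  if (!is.null(cfg$top_k) && cfg$top_k < 1) stop("top_k must be >= 1")
  cfg
}
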