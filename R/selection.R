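#' Correlate indices with yield under both conditions
#'
#' Pearson correlation of each index column with non-stress yield (`yp`) and
#' stress yield (`ys`) over genotypes, with two-sided p-values from the
#' t statistic \eqn{t = r\sqrt{n-2}/\sqrt{1-r^2}} on \eqn{n-2} degrees of
#' freedom. An index is flagged `significant_both` when its p-value is below
#' `alpha` under both conditions — the gate used to admit indices into the
#' composite selection index.
#'
#' @param index_table An `index_table` from [tolerance_indices()].
#' @param alpha Significance level in (0, 1); default 0.05.
#' @return A data frame of class `correlation_report` with one row per index:
#'   `index`, `r_yp`, `p_yp`, `r_ys`, `p_ys`, `n`, `significant_both`;
#'   `alpha` and `scope` attached as attributes. Zero-variance index columns
#'   are reported as `NA` with a warning.
#' @export
correlate_with_yield <- function(index_table, alpha = 0.05) {
  stopifnot(is.data.frame(index_table),
            all(c("yp", "ys", index_names()) %in% names(index_table)))
  if (!(is.numeric(alpha) && length(alpha) == 1L && alpha > 0 && alpha < 1)) {
    stop("alpha must be a single number in (0, 1)")
  }
  cc <- index_table[stats::complete.cases(index_table[, index_names()]), ]
  n <- nrow(cc)
  if (n < 3L) stop("need at least 3 complete genotypes for correlations")
  corr_one <- function(x, y) {
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
      return(c(r = NA_real_, p = NA_real_))
    }
    r <- stats::cor(x, y)
    if (abs(r) >= 1) return(c(r = r, p = 0))
    t_stat <- r * sqrt(n - 2) / sqrt(1 - r^2)
    c(r = r, p = 2 * stats::pt(-abs(t_stat), df = n - 2))
  }
  rows <- lapply(index_names(), function(idx) {
    a <- corr_one(cc[[idx]], cc$yp)
    b <- corr_one(cc[[idx]], cc$ys)
    data.frame(
      index = idx, r_yp = a[["r"]], p_yp = a[["p"]],
      r_ys = b[["r"]], p_ys = b[["p"]], n = n,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  if (any(is.na(out$r_yp) | is.na(out$r_ys))) {
    warning("zero-variance column(s): correlation undefined for ",
            paste(out$index[is.na(out$r_yp) | is.na(out$r_ys)],
                  collapse = ", "))
  }
  out$significant_both <- !is.na(out$p_yp) & !is.na(out$p_ys) &
    out$p_yp < alpha & out$p_ys < alpha
  attr(out, "alpha") <- alpha
  attr(out, "scope") <- attr(index_table, "scope")
  class(out) <- c("correlation_report", "data.frame")
  out
}

#' Select the significant indices and their correlation weights
#'
#' Keeps the indices significantly correlated with yield under both the
#' non-stress and the stress condition, in conventional index order,
#' carrying their correlation coefficients as CSI weights. Signs are
#' retained; `require_positive = TRUE` additionally restricts the selection
#' to indices positively correlated with yield under both conditions.
#'
#' @param report A `correlation_report`.
#' @param require_positive Keep only positively correlated indices
#'   (default `FALSE`).
#' @return A data frame of class `csi_weights` with columns `index`, `r_yp`,
#'   `r_ys`; attributes `alpha` and `scope`.
#' @export
select_significant <- function(report, require_positive = FALSE) {
  stopifnot(inherits(report, "correlation_report"))
  keep <- report$significant_both
  if (require_positive) keep <- keep & report$r_yp > 0 & report$r_ys > 0
  out <- report[keep, c("index", "r_yp", "r_ys"), drop = FALSE]
  out <- out[order(match(out$index, index_names())), , drop = FALSE]
  if (nrow(out) == 0L) {
    stop("no index is significantly correlated with yield under both ",
         "conditions at alpha = ", attr(report, "alpha"),
         ": CSI is undefined for this scope")
  }
  rownames(out) <- NULL
  attr(out, "alpha") <- attr(report, "alpha")
  attr(out, "scope") <- attr(report, "scope")
  class(out) <- c("csi_weights", "data.frame")
  out
}

#' Manually specified CSI weights
#'
#' Builds a `csi_weights` object from explicit correlation coefficients,
#' e.g. weights taken from a published correlation table rather than
#' re-estimated from data.
#'
#' @param index Character vector of index names (subset of [index_names()]).
#' @param r_yp,r_ys Correlation coefficients with non-stress and stress
#'   yield, same length as `index`.
#' @param scope Optional scope label.
#' @return A `csi_weights` data frame.
#' @export
csi_weights <- function(index, r_yp, r_ys, scope = NA) {
  stopifnot(length(index) == length(r_yp), length(index) == length(r_ys),
            length(index) > 0L)
  bad <- setdiff(index, index_names())
  if (length(bad) > 0L) {
    stop("unknown index name(s): ", paste(bad, collapse = ", "))
  }
  out <- data.frame(index = index, r_yp = r_yp, r_ys = r_ys,
                    stringsAsFactors = FALSE)
  attr(out, "scope") <- scope
  class(out) <- c("csi_weights", "data.frame")
  out
}

#' Composite selection index scores
#'
#' The composite selection index of genotype \eqn{i} over the selected
#' indices \eqn{j = 1..n}:
#' \deqn{CSI_i = \tfrac12\Big(\sum_j r_{YP,j}\,x_{ij} +
#'       \sum_j r_{YS,j}\,x_{ij}\Big)
#'     = \tfrac12 \sum_j (r_{YP,j} + r_{YS,j})\,x_{ij},}
#' where \eqn{x_{ij}} is genotype \eqn{i}'s value of index \eqn{j} and the
#' \eqn{r} are the correlation weights. Higher CSI identifies genotypes
#' performing well under both water regimes.
#'
#' @param index_table An `index_table`.
#' @param weights A `csi_weights` object (from [select_significant()] or
#'   [csi_weights()]).
#' @return A data frame of class `csi_scores` with columns `genotype` and
#'   `csi`; the weights used are attached as attribute `weights`. A genotype
#'   missing any weighted index gets `NA`.
#' @export
compute_csi <- function(index_table, weights) {
  stopifnot(is.data.frame(index_table), inherits(weights, "csi_weights"))
  miss <- setdiff(weights$index, names(index_table))
  if (length(miss) > 0L) {
    stop("index table lacks weighted column(s): ", paste(miss, collapse = ", "))
  }
  x <- as.matrix(index_table[, weights$index, drop = FALSE])
  w <- (weights$r_yp + weights$r_ys) / 2
  out <- data.frame(
    genotype = index_table$genotype,
    csi = as.numeric(x %*% w),
    stringsAsFactors = FALSE
  )
  attr(out, "weights") <- weights
  class(out) <- c("csi_scores", "data.frame")
  out
}

#' Rank genotypes by a score
#'
#' Descending order, deterministic ties broken lexicographically by genotype
#' id.
#'
#' @param scores A `csi_scores` data frame, or a named numeric vector.
#' @param top_k Number of genotypes to return; defaults to all. If larger
#'   than the population the full ranking is returned with a warning.
#' @return Character vector of genotype ids, best first.
#' @export
rank_by_score <- function(scores, top_k = NULL) {
  if (is.data.frame(scores)) {
    score_col <- setdiff(names(scores), "genotype")[1]
    v <- stats::setNames(scores[[score_col]], scores$genotype)
  } else {
    stopifnot(is.numeric(scores), !is.null(names(scores)))
    v <- scores
  }
  v <- v[!is.na(v)]
  if (is.null(top_k)) top_k <- length(v)
  if (!(is.numeric(top_k) && length(top_k) == 1L && top_k >= 1)) {
    stop("top_k must be a single count >= 1")
  }
  if (top_k > length(v)) {
    warning("top_k = ", top_k, " exceeds population size ", length(v),
            "; returning all")
    top_k <- length(v)
  }
  ord <- order(-v, names(v))
  names(v)[ord][seq_len(top_k)]
}

#' Transgressive segregants relative to the parents
#'
#' Per environment (year x condition), positive segregants are lines whose
#' yield strictly exceeds the better parent; negative segregants fall
#' strictly below the worse parent. A line tying a parent is not
#' transgressive. With `require_all_envs`, the overall per-condition lists
#' keep only lines qualifying in every environment of that condition.
#'
#' @param trial A long-format trial table.
#' @param parent_ids Character vector of the two parent genotype ids;
#'   defaults to the entries with `entry_type == "parent"`.
#' @param require_all_envs Logical (default `TRUE`): overall lists require
#'   qualification in every environment of the condition.
#' @return A list of class `segregant_report`: `per_env` (named list with
#'   `positive`/`negative` id vectors per environment), `overall` (per
#'   condition `N`, `D`, and `both`), and `parents`. Environments where a
#'   parent is missing are skipped with a warning.
#' @export
transgressive_segregants <- function(trial, parent_ids = NULL,
                                     require_all_envs = TRUE) {
  stopifnot(is.data.frame(trial),
            all(c("genotype", "entry_type", "year", "condition", "yield")
                %in% names(trial)))
  if (is.null(parent_ids)) {
    parent_ids <- unique(trial$genotype[trial$entry_type == "parent"])
  }
  if (length(parent_ids) != 2L) {
    stop("exactly two parent ids are required (got ", length(parent_ids), ")")
  }
  agg <- stats::aggregate(yield ~ genotype + entry_type + year + condition,
                          data = trial, FUN = mean)
  agg$env <- paste0(agg$year, agg$condition)
  envs <- sort(unique(agg$env))
  per_env <- list()
  for (e in envs) {
    sub <- agg[agg$env == e, , drop = FALSE]
    py <- sub$yield[match(parent_ids, sub$genotype)]
    if (any(is.na(py))) {
      warning("parent(s) missing in environment ", e, "; skipped")
      next
    }
    lines <- sub[sub$entry_type == "line", , drop = FALSE]
    per_env[[e]] <- list(
      positive = sort(lines$genotype[lines$yield > max(py)]),
      negative = sort(lines$genotype[lines$yield < min(py)])
    )
  }
  if (length(per_env) == 0L) stop("no environment retained both parents")
  overall_for <- function(cond, dir) {
    keep <- grepl(paste0(cond, "$"), names(per_env))
    sets <- lapply(per_env[keep], `[[`, dir)
    if (length(sets) == 0L) return(character(0))
    if (require_all_envs) Reduce(intersect, sets) else
      sort(unique(unlist(sets)))
  }
  overall <- list(
    N = list(positive = overall_for("N", "positive"),
             negative = overall_for("N", "negative")),
    D = list(positive = overall_for("D", "positive"),
             negative = overall_for("D", "negative"))
  )
  overall$both <- list(
    positive = intersect(overall$N$positive, overall$D$positive),
    negative = intersect(overall$N$negative, overall$D$negative)
  )
  out <- list(per_env = per_env, overall = overall, parents = parent_ids)
  class(out) <- "segregant_report"
  out
}

#' @export
print.segregant_report <- function(x, ...) {
  cat("Transgressive segregants (parents: ",
      paste(x$parents, collapse = ", "), ")\n", sep = "")
  for (e in names(x$per_env)) {
    cat(sprintf("  %s: %d positive, %d negative\n", e,
                length(x$per_env[[e]]$positive),
                length(x$per_env[[e]]$negative)))
  }
  cat("  overall (both conditions): positive ",
      length(x$overall$both$positive), ", negative ",
      length(x$overall$both$negative), "\n", sep = "")
  invisible(x)
}

#' Fit a composite-selection-index screen to a yield trial
#'
#' The central fitting function: from a long-format multi-environment trial
#' it derives paired yields per scope (each year and/or pooled over years),
#' computes the nine tolerance/susceptibility indices, correlates them with
#' yield under both water regimes, selects the indices significant under
#' both at level `alpha`, and scores every genotype with the composite
#' selection index (CSI). The result is a classed model object with
#' `print()`, `summary()`, `coef()` (the learned correlation weights),
#' `predict()` (CSI for new paired yields under the stored weights and
#' population means) and `plot()` methods.
#'
#' @param trial A long-format trial table (see [read_trial()]).
#' @param scope `"pooled"`, `"per_year"`, or `"both"` (default).
#' @param alpha Significance level for the index-selection gate.
#' @param entry_types Entry types entering the population means and
#'   correlations (default all: lines, parents, checks).
#' @param require_positive Restrict CSI to positively correlated indices.
#' @return An object of class `csi_screen`: a list with one element per
#'   scope, each holding `pairs`, `means`, `indices`, `correlations`,
#'   `weights`, `scores` and `ranking`.
#' @examples
#' trial <- simulate_ril_trial(sim_spec(seed = 1))
#' fit <- csi_screen(trial, scope = "pooled")
#' coef(fit)
#' head(rank_by_score(fit$scopes$pooled$scores, top_k = 5))
#' @export
csi_screen <- function(trial, scope = c("both", "pooled", "per_year"),
                       alpha = 0.05,
                       entry_types = c("line", "parent", "check"),
                       require_positive = FALSE) {
  scope <- match.arg(scope)
  years <- sort(unique(as.character(trial$year)))
  scopes <- switch(scope,
    pooled = "pooled",
    per_year = years,
    both = c(years, "pooled")
  )
  fit_one <- function(sc) {
    pairs <- paired_yields(trial, scope = sc, entry_types = entry_types)
    means <- population_means(pairs)
    idx <- tolerance_indices(pairs, means)
    rep <- correlate_with_yield(idx, alpha = alpha)
    w <- select_significant(rep, require_positive = require_positive)
    sc_scores <- compute_csi(idx, w)
    list(pairs = pairs, means = means, indices = idx, correlations = rep,
         weights = w, scores = sc_scores,
         ranking = rank_by_score(sc_scores))
  }
  out <- list(
    scopes = stats::setNames(lapply(scopes, fit_one), scopes),
    alpha = alpha,
    entry_types = entry_types,
    call = match.call()
  )
  class(out) <- "csi_screen"
  out
}

#' @export
print.csi_screen <- function(x, ...) {
  cat("Composite selection index screen\n")
  cat("  scopes:", paste(names(x$scopes), collapse = ", "), "\n")
  for (sc in names(x$scopes)) {
    s <- x$scopes[[sc]]
    cat(sprintf(
      "  %s: %d genotypes; significant indices: %s; top line: %s\n",
      sc, nrow(s$scores), paste(toupper(s$weights$index), collapse = ", "),
      s$ranking[1]
    ))
  }
  invisible(x)
}

#' @export
summary.csi_screen <- function(object, top_k = 10, ...) {
  for (sc in names(object$scopes)) {
    s <- object$scopes[[sc]]
    cat("== scope:", sc, "==\n")
    cat(sprintf("population means: %.3f (non-stress), %.3f (stress) t/ha; ",
                s$means$ybar_p, s$means$ybar_s))
    cat(sprintf("yield reduction %.2f%%\n", yield_reduction(s$means)))
    cat("correlation of indices with yield (alpha =",
        attr(s$correlations, "alpha"), "):\n")
    print(format(as.data.frame(s$correlations), digits = 3),
          row.names = FALSE)
    cat("top", min(top_k, length(s$ranking)), "genotypes by CSI:",
        paste(utils::head(s$ranking, top_k), collapse = ", "), "\n\n")
  }
  invisible(object)
}

#' @export
coef.csi_screen <- function(object, scope = NULL, ...) {
  if (is.null(scope)) scope <- names(object$scopes)[length(object$scopes)]
  object$scopes[[scope]]$weights
}

#' @export
predict.csi_screen <- function(object, newdata = NULL, scope = NULL, ...) {
  if (is.null(scope)) scope <- names(object$scopes)[length(object$scopes)]
  s <- object$scopes[[scope]]
  if (is.null(newdata)) return(s$scores)
  stopifnot(is.data.frame(newdata),
            all(c("genotype", "yp", "ys") %in% names(newdata)))
  idx <- tolerance_indices(newdata, means = s$means)
  compute_csi(idx, s$weights)
}

#' @export
plot.csi_screen <- function(x, scope = NULL, top_k = 25, ...) {
  if (is.null(scope)) scope <- names(x$scopes)[length(x$scopes)]
  s <- x$scopes[[scope]]
  ids <- utils::head(s$ranking, top_k)
  v <- s$scores$csi[match(ids, s$scores$genotype)]
  graphics::barplot(rev(v), names.arg = rev(ids), horiz = TRUE, las = 1,
                    xlab = "CSI", main = paste("CSI ranking —", scope), ...)
  invisible(x)
}
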