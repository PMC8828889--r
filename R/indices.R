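#' Canonical index names
#'
#' The nine tolerance/susceptibility indices, in their conventional order:
#' stress susceptibility index (SSI), relative stress index (RSI), tolerance
#' (TOL), mean productivity (MP), yield stability index (YSI), harmonic mean
#' (HM), geometric mean productivity (GMP), stress tolerance index (STI) and
#' yield index (YI).
#'
#' @return Character vector of the nine lower-case index names.
#' @export
index_names <- function() {
  c("ssi", "rsi", "tol", "mp", "ysi", "hm", "gmp", "sti", "yi")
}

#' Extract paired non-stress/stress yields from a trial table
#'
#' Reduces a long-format trial table to one row per genotype with its mean
#' yield under the non-stress (`yp`) and stress (`ys`) condition, for a single
#' year or pooled over years. Pooling is the arithmetic mean of per-year
#' genotype means, so years contribute equally regardless of replication.
#'
#' @param trial A trial table as returned by [read_trial()] or
#'   [simulate_ril_trial()]: a data frame with columns `genotype`,
#'   `entry_type`, `year`, `condition` (`"N"`/`"D"`) and `yield`.
#' @param scope `"pooled"` (default) or a single year label present in the
#'   trial.
#' @param entry_types Entry types to keep (default all of `"line"`,
#'   `"parent"`, `"check"`).
#' @return A data frame of class `paired_yields` with columns `genotype`,
#'   `entry_type`, `yp`, `ys` and `scope`. Genotypes missing either condition
#'   in the scope are dropped with a warning; in the pooled scope a genotype
#'   is kept as long as each condition is observed in at least one year.
#' @export
paired_yields <- function(trial, scope = "pooled",
                          entry_types = c("line", "parent", "check")) {
  stopifnot(is.data.frame(trial))
  need <- c("genotype", "entry_type", "year", "condition", "yield")
  miss <- setdiff(need, names(trial))
  if (length(miss) > 0L) {
    stop("trial table is missing column(s): ", paste(miss, collapse = ", "))
  }
  if (any(!is.finite(trial$yield))) stop("non-finite yield in trial table")
  if (any(trial$yield < 0)) stop("negative yield in trial table")
  trial <- trial[trial$entry_type %in% entry_types, , drop = FALSE]
  if (length(scope) != 1L || is.na(scope) || !nzchar(scope)) {
    stop("scope must be a single non-empty label")
  }
  if (!identical(scope, "pooled")) {
    if (!scope %in% as.character(trial$year)) {
      stop("year '", scope, "' not present in trial table")
    }
    trial <- trial[as.character(trial$year) == scope, , drop = FALSE]
  }
  # per-year genotype x condition means, then average over years
  per_year <- stats::aggregate(
    yield ~ genotype + entry_type + condition + year,
    data = trial, FUN = mean
  )
  agg <- stats::aggregate(
    yield ~ genotype + entry_type + condition,
    data = per_year, FUN = mean
  )
  yp <- agg[agg$condition == "N", c("genotype", "entry_type", "yield")]
  ys <- agg[agg$condition == "D", c("genotype", "yield")]
  names(yp)[3] <- "yp"
  names(ys)[2] <- "ys"
  out <- merge(yp, ys, by = "genotype", all = TRUE)
  incomplete <- is.na(out$yp) | is.na(out$ys)
  if (any(incomplete)) {
    warning(
      "dropping ", sum(incomplete), " genotype(s) missing one condition in ",
      "scope '", scope, "': ",
      paste(utils::head(out$genotype[incomplete], 5L), collapse = ", ")
    )
    out <- out[!incomplete, , drop = FALSE]
  }
  out$scope <- scope
  out <- out[order(out$genotype), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("paired_yields", "data.frame")
  out
}

#' Population mean yields
#'
#' Arithmetic mean yield over all supplied entries under each condition
#' (the denominators of SSI, RSI, STI and YI). By default all entries —
#' lines, parents and checks — enter the means, matching the convention of
#' computing the total mean over the full trial entry list; restrict with
#' `entry_types`.
#'
#' @param pairs A `paired_yields` data frame.
#' @param entry_types Entry types to include (default all).
#' @return A list of class `population_means` with `ybar_p`, `ybar_s` and
#'   `n_entries`.
#' @export
population_means <- function(pairs,
                             entry_types = c("line", "parent", "check")) {
  stopifnot(is.data.frame(pairs), all(c("yp", "ys") %in% names(pairs)))
  if ("entry_type" %in% names(pairs)) {
    pairs <- pairs[pairs$entry_type %in% entry_types, , drop = FALSE]
  }
  if (nrow(pairs) < 2L) stop("need at least 2 entries to form population means")
  if (any(!is.finite(pairs$yp)) || any(!is.finite(pairs$ys))) {
    stop("non-finite yields")
  }
  if (any(pairs$yp < 0) || any(pairs$ys < 0)) stop("negative yields")
  out <- list(
    ybar_p = mean(pairs$yp),
    ybar_s = mean(pairs$ys),
    n_entries = nrow(pairs)
  )
  class(out) <- "population_means"
  out
}

#' @export
print.population_means <- function(x, ...) {
  cat(sprintf(
    "Population means over %d entries: non-stress %.3f, stress %.3f t/ha\n",
    x$n_entries, x$ybar_p, x$ybar_s
  ))
  invisible(x)
}

#' Tolerance and susceptibility indices
#'
#' Computes the nine classical indices for each genotype from its paired
#' yields `YP` (non-stress) and `YS` (stress) and the population means
#' `Ybar_P`, `Ybar_S`:
#' \deqn{TOL = YP - YS,\quad MP = (YP+YS)/2,\quad GMP = \sqrt{YP\,YS},}
#' \deqn{HM = 2\,YP\,YS/(YP+YS),\quad YSI = YS/YP,\quad
#'       SSI = \frac{1 - YS/YP}{1 - \bar Y_S/\bar Y_P},}
#' \deqn{RSI = \frac{YS/YP}{\bar Y_S/\bar Y_P},\quad
#'       STI = \frac{YS\,YP}{\bar Y_P^2},\quad YI = YS/\bar Y_S.}
#'
#' @param pairs A `paired_yields` data frame (or any data frame with
#'   `genotype`, `yp`, `ys`).
#' @param means A `population_means` object; defaults to the means over all
#'   entries of `pairs`.
#' @return A data frame of class `index_table` with columns `genotype`, `yp`,
#'   `ys` and the nine indices, carrying `means` and `scope` attributes.
#'   Ratio indices (YSI/SSI/RSI) are `NA` with a warning for genotypes with
#'   `YP = 0`.
#' @export
tolerance_indices <- function(pairs, means = population_means(pairs)) {
  stopifnot(is.data.frame(pairs),
            all(c("genotype", "yp", "ys") %in% names(pairs)))
  stopifnot(inherits(means, "population_means"))
  if (means$ybar_p <= 0) stop("population mean under non-stress must be > 0")
  if (means$ybar_s <= 0) stop("population mean under stress must be > 0")
  ratio_bar <- means$ybar_s / means$ybar_p
  if (abs(1 - ratio_bar) < .Machine$double.eps^0.5) {
    stop("SSI undefined: population mean ratio Ybar_S/Ybar_P equals 1, ",
         "its denominator 1 - Ybar_S/Ybar_P is zero")
  }
  yp <- pairs$yp
  ys <- pairs$ys
  if (any(yp < 0) || any(ys < 0)) stop("negative yields")
  out <- data.frame(
    genotype = pairs$genotype,
    yp = yp, ys = ys,
    ssi = NA_real_, rsi = NA_real_,
    tol = yp - ys,
    mp = (yp + ys) / 2,
    ysi = NA_real_,
    hm = ifelse(yp + ys > 0, 2 * yp * ys / (yp + ys), 0),
    gmp = sqrt(yp * ys),
    sti = yp * ys / means$ybar_p^2,
    yi = ys / means$ybar_s,
    stringsAsFactors = FALSE
  )
  ok <- yp > 0
  if (any(!ok)) {
    warning(sum(!ok), " genotype(s) with YP = 0: YSI, SSI and RSI reported ",
            "as missing")
  }
  out$ysi[ok] <- ys[ok] / yp[ok]
  out$ssi[ok] <- (1 - out$ysi[ok]) / (1 - ratio_bar)
  out$rsi[ok] <- out$ysi[ok] / ratio_bar
  out <- out[, c("genotype", "yp", "ys", index_names())]
  attr(out, "means") <- means
  attr(out, "scope") <- if ("scope" %in% names(pairs)) pairs$scope[1] else NA
  class(out) <- c("index_table", "data.frame")
  out
}

#' Percent yield reduction caused by stress
#'
#' `100 * (YP - YS) / YP`, either for a genotype or for population means.
#'
#' @param yp Non-stress yield (or a `population_means` object, in which case
#'   `ys` is ignored).
#' @param ys Stress yield.
#' @return Percent reduction.
#' @export
yield_reduction <- function(yp, ys = NULL) {
  if (inherits(yp, "population_means")) {
    ys <- yp$ybar_s
    yp <- yp$ybar_p
  }
  stopifnot(is.numeric(yp), is.numeric(ys))
  if (any(yp <= 0)) stop("non-stress yield must be > 0")
  100 * (yp - ys) / yp
}
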