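#' Assemble a genotype-by-tester two-way table
#'
#' Builds the complete two-way matrix underlying a biplot. Three modes:
#' \describe{
#'   \item{GT}{genotype-by-trait: columns are non-stress yield `YP`, stress
#'     yield `YS` and the nine indices, from an `index_table`; optionally a
#'     CSI column.}
#'   \item{GGE}{genotype-by-environment: columns are the year-by-condition
#'     environments (e.g. `2017N`, `2017D`, ...), from a long trial table.}
#'   \item{PCA}{like GT but restricted to the nine indices, standardized to
#'     mean 0 and sd 1 per column.}
#' }
#'
#' @param x An `index_table` (GT/PCA modes) or long trial table (GGE mode).
#' @param mode `"GT"`, `"GGE"` or `"PCA"`.
#' @param csi Optional `csi_scores` to append as a `CSI` column (GT mode).
#' @return A numeric matrix (genotypes x testers) with attribute `mode`.
#'   Missing cells are an error naming the offending genotype/tester.
#' @export
build_two_way <- function(x, mode = c("GT", "GGE", "PCA"), csi = NULL) {
  mode <- match.arg(mode)
  if (mode %in% c("GT", "PCA")) {
    stopifnot(is.data.frame(x),
              all(c("genotype", "yp", "ys", index_names()) %in% names(x)))
    cols <- if (mode == "GT") c("yp", "ys", index_names()) else index_names()
    m <- as.matrix(x[, cols])
    rownames(m) <- x$genotype
    colnames(m) <- toupper(cols)
    if (mode == "GT" && !is.null(csi)) {
      stopifnot(is.data.frame(csi), all(c("genotype", "csi") %in% names(csi)))
      m <- cbind(m, CSI = csi$csi[match(x$genotype, csi$genotype)])
    }
    if (mode == "PCA") {
      m <- scale(m)
      attr(m, "scaled:center") <- NULL
      attr(m, "scaled:scale") <- NULL
    }
  } else {
    stopifnot(is.data.frame(x),
              all(c("genotype", "year", "condition", "yield") %in% names(x)))
    agg <- stats::aggregate(yield ~ genotype + year + condition,
                            data = x, FUN = mean)
    agg$env <- paste0(agg$year, agg$condition)
    genos <- sort(unique(agg$genotype))
    envs <- sort(unique(agg$env))
    m <- matrix(NA_real_, length(genos), length(envs),
                dimnames = list(genos, envs))
    m[cbind(match(agg$genotype, genos), match(agg$env, envs))] <- agg$yield
  }
  if (anyNA(m)) {
    holes <- which(is.na(m), arr.ind = TRUE)
    stop("missing cell(s) in two-way table, e.g. genotype '",
         rownames(m)[holes[1, 1]], "' x tester '",
         colnames(m)[holes[1, 2]], "'")
  }
  if (nrow(m) < 3L || ncol(m) < 2L) {
    stop("two-way table needs >= 3 genotypes and >= 2 testers")
  }
  attr(m, "mode") <- mode
  m
}

#' Fit a rank-2 SVD biplot
#'
#' Column-centers (and optionally column-standardizes) a two-way table and
#' takes its singular value decomposition \eqn{X = U D V'}. Two singular
#' value partitionings are supported:
#' \describe{
#'   \item{tester-focused}{(column-metric preserving) testers get
#'     \eqn{V D}, genotypes \eqn{U}; tester vector lengths and angles then
#'     represent column standard deviations and correlations — used for
#'     comparing indices and finding the ideal tester.}
#'   \item{symmetric}{both sides get the square-rooted singular values
#'     (\eqn{U D^{1/2}}, \eqn{V D^{1/2}}) — used for the which-won-where
#'     polygon view.}
#' }
#' Axis signs are fixed so that the largest-magnitude tester loading on each
#' axis is positive.
#'
#' @param table A numeric matrix from [build_two_way()] (or any complete
#'   genotypes-by-testers matrix).
#' @param scaling `"none"` or `"sd"` (divide centered columns by their sd).
#'   Default: `"sd"` for GT tables (heterogeneous index units), `"none"`
#'   otherwise.
#' @param partitioning `"tester"` (tester-focused) or `"symmetric"`.
#' @return An object of class `gt_biplot` with rank-2 `rows` and `cols`
#'   coordinate matrices, full-rank `rows_full`/`cols_full`, singular values
#'   `d`, per-axis `var_explained`, and the processing metadata.
#' @export
fit_biplot <- function(table, scaling = NULL,
                       partitioning = c("tester", "symmetric")) {
  partitioning <- match.arg(partitioning)
  stopifnot(is.matrix(table), is.numeric(table), !anyNA(table))
  if (nrow(table) < 3L || ncol(table) < 2L) {
    stop("need >= 3 rows and >= 2 columns")
  }
  mode <- attr(table, "mode")
  if (is.null(scaling)) {
    scaling <- if (identical(mode, "GT")) "sd" else "none"
  }
  scaling <- match.arg(scaling, c("none", "sd"))
  x <- sweep(table, 2, colMeans(table))
  if (scaling == "sd") {
    s <- apply(table, 2, stats::sd)
    if (any(s == 0)) {
      stop("zero-variance tester(s): ",
           paste(colnames(table)[s == 0], collapse = ", "))
    }
    x <- sweep(x, 2, s, "/")
  }
  sv <- svd(x)
  d <- sv$d
  r <- sum(d > max(d[1], .Machine$double.eps) * 1e-12)
  if (r < 2L) warning("processed table has rank < 2; axis-2 coordinates are 0")
  k <- ncol(sv$v)
  # SVD sign ambiguity: flip each axis so the largest |loading| is positive
  for (a in seq_len(k)) {
    j <- which.max(abs(sv$v[, a]))
    if (sv$v[j, a] < 0) {
      sv$v[, a] <- -sv$v[, a]
      sv$u[, a] <- -sv$u[, a]
    }
  }
  if (partitioning == "tester") {
    rows_full <- sv$u
    cols_full <- sv$v %*% diag(d, k)
  } else {
    rows_full <- sv$u %*% diag(sqrt(d), k)
    cols_full <- sv$v %*% diag(sqrt(d), k)
  }
  dimnames(rows_full) <- list(rownames(table), paste0("PC", seq_len(k)))
  dimnames(cols_full) <- list(colnames(table), paste0("PC", seq_len(k)))
  out <- list(
    rows = rows_full[, 1:2, drop = FALSE],
    cols = cols_full[, 1:2, drop = FALSE],
    rows_full = rows_full,
    cols_full = cols_full,
    d = d,
    var_explained = d^2 / sum(d^2),
    scaling = scaling,
    partitioning = partitioning,
    centering = "tester",
    mode = if (is.null(mode)) NA_character_ else mode
  )
  class(out) <- "gt_biplot"
  out
}

#' @export
print.gt_biplot <- function(x, ...) {
  cat(sprintf(
    "Rank-2 biplot (%s partitioning, %s scaling): %d genotypes x %d testers\n",
    x$partitioning, x$scaling, nrow(x$rows), nrow(x$cols)
  ))
  cat(sprintf("  PC1 %.1f%%, PC2 %.1f%% of variation\n",
              100 * x$var_explained[1], 100 * x$var_explained[2]))
  invisible(x)
}

#' @export
summary.gt_biplot <- function(object, ...) {
  print(object)
  cat("tester coordinates (PC1, PC2):\n")
  print(round(object$cols, 3))
  invisible(object)
}

#' Cosines of the angles between tester vectors
#'
#' On a tester-focused biplot the cosine of the angle between two tester
#' vectors approximates the correlation between the testers (exactly, when
#' the rank-2 approximation is exact and columns were standardized).
#'
#' @param model A tester-focused `gt_biplot`.
#' @return Symmetric matrix of cosines with unit diagonal; `NA` (with a
#'   warning) for zero-length vectors.
#' @export
vector_angles <- function(model) {
  stopifnot(inherits(model, "gt_biplot"))
  if (model$partitioning != "tester") {
    stop("vector angles are read from a tester-focused biplot")
  }
  v <- model$cols
  len <- sqrt(rowSums(v^2))
  if (any(len == 0)) {
    warning("zero-length tester vector(s): ",
            paste(rownames(v)[len == 0], collapse = ", "))
  }
  cosm <- (v %*% t(v)) / outer(len, len)
  cosm[!is.finite(cosm)] <- NA_real_
  diag(cosm)[len > 0] <- 1
  cosm
}

#' Which-won-where sector map
#'
#' From a symmetric-partitioning biplot, draws the convex hull of the
#' genotype points; perpendiculars from the origin to the hull edges divide
#' the plane into sectors, each "owned" by a hull-vertex genotype. A tester
#' falls in the sector of the vertex maximizing the inner product with the
#' tester vector — that vertex is the winner for the tester. A tester
#' exactly on a boundary joins the counter-clockwise sector.
#'
#' @param model A symmetric-partitioning `gt_biplot`.
#' @return A list of class `sector_map`: `hull` (vertex ids,
#'   counter-clockwise), `boundaries` (ray angles in radians delimiting each
#'   vertex's sector), `testers` (data frame tester / winner / sector).
#' @export
which_won_where <- function(model) {
  stopifnot(inherits(model, "gt_biplot"))
  if (model$partitioning != "symmetric") {
    stop("which-won-where is read from a symmetric-partitioning biplot")
  }
  pts <- model$rows
  hull_idx <- grDevices::chull(pts[, 1], pts[, 2])  # clockwise order
  if (length(hull_idx) < 3L) {
    stop("genotype points are collinear: polygon view is degenerate")
  }
  hull_idx <- rev(hull_idx)  # counter-clockwise
  hv <- pts[hull_idx, , drop = FALSE]
  nh <- nrow(hv)
  # boundary ray between ccw-consecutive vertices i and i+1: directions t
  # with t.v_i = t.v_{i+1}, i.e. perpendicular to the edge, outward side
  boundaries <- vapply(seq_len(nh), function(i) {
    j <- if (i == nh) 1L else i + 1L
    e <- hv[j, ] - hv[i, ]
    ray <- c(-e[2], e[1])                      # perpendicular to the edge
    if (sum(ray * hv[i, ]) < 0) ray <- -ray    # point toward the winners
    atan2(ray[2], ray[1])
  }, numeric(1))
  winner_of <- function(t_vec) {
    prods <- as.numeric(hv %*% t_vec)
    mx <- max(prods)
    tied <- which(prods >= mx - 1e-12 * max(1, abs(mx)))
    if (length(tied) == 1L) return(tied)
    # boundary tie: take the counter-clockwise sector (later in ccw order;
    # a wrap-around tie between last and first belongs to the first)
    if (1L %in% tied && nh %in% tied) 1L else max(tied)
  }
  win_idx <- vapply(seq_len(nrow(model$cols)), function(i) {
    winner_of(model$cols[i, ])
  }, integer(1))
  testers <- data.frame(
    tester = rownames(model$cols),
    winner = rownames(hv)[win_idx],
    sector = win_idx,
    stringsAsFactors = FALSE
  )
  out <- list(
    hull = rownames(hv),
    hull_coords = hv,
    boundaries = boundaries,
    testers = testers
  )
  class(out) <- "sector_map"
  out
}

#' @export
print.sector_map <- function(x, ...) {
  cat("Which-won-where sector map:", length(x$hull), "hull vertices\n")
  won <- split(x$testers$tester, x$testers$winner)
  for (w in names(won)) {
    cat("  ", w, "wins:", paste(won[[w]], collapse = ", "), "\n")
  }
  invisible(x)
}

#' Rank testers by distance to the ideal tester
#'
#' The ideal tester lies on the average-tester axis (the mean of all tester
#' vectors, normalized) at the length of the longest tester vector: it is
#' maximally discriminating (long vector) and maximally representative
#' (average direction). Real testers are ranked by ascending Euclidean
#' distance to it.
#'
#' @param model A tester-focused `gt_biplot`.
#' @return Data frame (`tester`, `distance`) sorted nearest-first; the ideal
#'   point is attached as attribute `ideal`. Ties keep input order.
#' @export
ideal_tester_ranking <- function(model) {
  stopifnot(inherits(model, "gt_biplot"))
  if (model$partitioning != "tester") {
    stop("the ideal-tester view requires a tester-focused biplot")
  }
  v <- model$cols
  avg <- colMeans(v)
  if (sqrt(sum(avg^2)) < .Machine$double.eps^0.5) {
    stop("average tester vector is zero: ideal tester undefined")
  }
  ideal <- avg / sqrt(sum(avg^2)) * max(sqrt(rowSums(v^2)))
  d <- sqrt(colSums((t(v) - ideal)^2))
  out <- data.frame(tester = rownames(v), distance = d,
                    stringsAsFactors = FALSE)
  out <- out[order(out$distance), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "ideal") <- ideal
  out
}

#' Rank genotypes by principal-component scores
#'
#' Sorts genotypes by the requested axis score, or by the sum of scores over
#' several axes, descending; ties break lexicographically by id. High PC1 on
#' an index-based biplot identifies stress-tolerant, high-yielding
#' genotypes.
#'
#' @param model A `gt_biplot`.
#' @param axes Integer axis number(s), default 1.
#' @return Character vector of genotype ids, best first.
#' @export
pc_score_ranking <- function(model, axes = 1) {
  stopifnot(inherits(model, "gt_biplot"))
  if (!all(axes %in% seq_len(ncol(model$rows_full)))) {
    stop("invalid axis: model has ", ncol(model$rows_full), " axes")
  }
  sc <- rowSums(model$rows_full[, axes, drop = FALSE])
  if (all(abs(sc) < 1e-8 * max(1, max(abs(model$rows_full))))) {
    warning("all scores on the requested axis/axes are ~0")
  }
  names(sc)[order(-sc, names(sc))]
}

#' @export
plot.gt_biplot <- function(x, polygon = NULL, label_rows = FALSE, ...) {
  if (is.null(polygon)) polygon <- x$partitioning == "symmetric"
  xl <- sprintf("PC1 (%.1f%%)", 100 * x$var_explained[1])
  yl <- sprintf("PC2 (%.1f%%)", 100 * x$var_explained[2])
  lim <- range(c(x$rows[, 1:2], x$cols[, 1:2], 0))
  graphics::plot(x$rows[, 1], x$rows[, 2], pch = 20, col = "grey40",
                 xlab = xl, ylab = yl, xlim = lim, ylim = lim, asp = 1, ...)
  graphics::abline(h = 0, v = 0, col = "grey80", lty = 3)
  if (label_rows) {
    graphics::text(x$rows[, 1], x$rows[, 2], rownames(x$rows),
                   cex = 0.6, pos = 3, col = "grey40")
  }
  graphics::arrows(0, 0, x$cols[, 1], x$cols[, 2], length = 0.08,
                   col = "blue")
  graphics::text(x$cols[, 1], x$cols[, 2], rownames(x$cols),
                 col = "blue", pos = 3, cex = 0.8)
  if (polygon && x$partitioning == "symmetric") {
    sm <- which_won_where(x)
    hc <- sm$hull_coords
    graphics::polygon(hc[, 1], hc[, 2], border = "red")
    far <- 2 * max(abs(lim))
    for (ang in sm$boundaries) {
      graphics::segments(0, 0, far * cos(ang), far * sin(ang),
                         col = "red", lty = 2)
    }
  }
  invisible(x)
}
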