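# shared fixture builders: everything generated in code, nothing on disk

# small long-format trial from a genotype x environment yield matrix;
# environments are "year_condition" labels like "2017_N"
make_trial <- function(yields, entry_type = NULL) {
  stopifnot(is.matrix(yields), !is.null(rownames(yields)),
            !is.null(colnames(yields)))
  if (is.null(entry_type)) {
    entry_type <- stats::setNames(rep("line", nrow(yields)),
                                  rownames(yields))
  }
  recs <- lapply(colnames(yields), function(env) {
    parts <- strsplit(env, "_")[[1]]
    data.frame(genotype = rownames(yields),
               entry_type = unname(entry_type[rownames(yields)]),
               year = parts[1], condition = parts[2],
               yield = yields[, env], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  class(out) <- c("ril_trial", "data.frame")
  out
}

# random positive yield pairs
random_pairs <- function(n, seed = 1) {
  set.seed(seed)
  data.frame(genotype = sprintf("G%03d", seq_len(n)),
             yp = stats::runif(n, 0.5, 8),
             ys = stats::runif(n, 0.1, 5),
             stringsAsFactors = FALSE)
}

# the published pooled-analysis correlation weights for MP, GMP, HM, STI
pooled_weights <- function() {
  csi_weights(index = c("mp", "gmp", "hm", "sti"),
              r_yp = c(0.96, 0.85, 0.72, 0.83),
              r_ys = c(0.79, 0.92, 0.98, 0.91),
              scope = "pooled")
}

# two-sided p-value for a Pearson r by numerical integration of the
# t density written from its closed form (independent of stats::pt)
p_from_r_numeric <- function(r, n) {
  df <- n - 2
  if (1 - r^2 < 1e-12) return(0) # |r| = 1: infinite t statistic
  t_stat <- abs(r) * sqrt(df) / sqrt(1 - r^2)
  dens <- function(x) {
    gamma((df + 1) / 2) / (sqrt(df * pi) * gamma(df / 2)) *
      (1 + x^2 / df)^(-(df + 1) / 2)
  }
  2 * stats::integrate(dens, t_stat, Inf, rel.tol = 1e-10)$value
}
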