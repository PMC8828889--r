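make_index_table <- function(pairs, ybar_p = NULL, ybar_s = NULL) {
  means <- population_means(pairs)
  if (!is.null(ybar_p)) means$ybar_p <- ybar_p
  if (!is.null(ybar_s)) means$ybar_s <- ybar_s
  tolerance_indices(pairs, means)
}

test_that("Pearson r and its two-sided p match the closed form", {
  # x = 1..5, y = (2,1,4,3,5): r = 0.8, t = 2.309 on 3 df, p ~ 0.104
  x <- 1:5
  y <- c(2, 1, 4, 3, 5)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(r, 0.8)
  t_stat <- r * sqrt(3) / sqrt(1 - r^2)
  expect_equal(t_stat, 2.309, tolerance = 1e-3)
  p <- p_from_r_numeric(r, 5)
  expect_equal(p, 0.104, tolerance = 1e-3)
  expect_gt(p, 0.05) # not significant at alpha = 0.05

  # the same numbers through the package path, via an index table in which
  # one index column is forced to y against yp = x
  pairs <- data.frame(genotype = letters[1:5], yp = as.numeric(x),
                      ys = c(1, 1.2, 0.8, 1.1, 0.9))
  it <- make_index_table(pairs)
  it$mp <- y
  rep <- correlate_with_yield(it, alpha = 0.05)
  expect_equal(rep$r_yp[rep$index == "mp"], 0.8, tolerance = 1e-12)
  expect_equal(rep$p_yp[rep$index == "mp"], p, tolerance = 1e-6)
})

test_that("p-values agree with the numeric t-density oracle across n", {
  for (n in c(5, 10, 17, 30)) {
    set.seed(n)
    pairs <- data.frame(genotype = sprintf("g%02d", 1:n),
                        yp = runif(n, 1, 6), ys = runif(n, 0.5, 3))
    it <- make_index_table(pairs)
    rep <- correlate_with_yield(it)
    for (k in seq_len(nrow(rep))) {
      expect_equal(rep$p_yp[k], p_from_r_numeric(rep$r_yp[k], n),
                   tolerance = 1e-6)
      expect_equal(rep$p_ys[k], p_from_r_numeric(rep$r_ys[k], n),
                   tolerance = 1e-6)
    }
    # cross-check r itself against stats::cor.test
    ct <- stats::cor.test(it$gmp, it$ys)
    expect_equal(rep$r_ys[rep$index == "gmp"], unname(ct$estimate),
                 tolerance = 1e-12)
    expect_equal(rep$p_ys[rep$index == "gmp"], ct$p.value, tolerance = 1e-9)
  }
})

test_that("self-correlation and zero-variance columns behave", {
  pairs <- random_pairs(10, seed = 3)
  it <- make_index_table(pairs)
  it$gmp <- it$ys # force perfect correlation
  rep <- correlate_with_yield(it)
  expect_equal(rep$r_ys[rep$index == "gmp"], 1)
  expect_lt(rep$p_ys[rep$index == "gmp"], 1e-12)

  it2 <- make_index_table(pairs)
  it2$tol <- 1 # constant column
  expect_warning(rep2 <- correlate_with_yield(it2), "zero-variance")
  expect_true(is.na(rep2$r_yp[rep2$index == "tol"]))
  expect_false(rep2$significant_both[rep2$index == "tol"])
})

test_that("significance gate keeps indices significant in both conditions", {
  pairs <- random_pairs(40, seed = 5)
  it <- make_index_table(pairs)
  rep <- correlate_with_yield(it, alpha = 0.05)
  w <- select_significant(rep)
  # brute-force filter oracle, in canonical order
  expected <- rep$index[rep$p_yp < 0.05 & rep$p_ys < 0.05]
  expect_identical(w$index, intersect(index_names(), expected))
  expect_identical(w$r_yp, rep$r_yp[match(w$index, rep$index)])

  # all nine significant -> all retained with signed weights
  rep_all <- rep
  rep_all$p_yp <- rep_all$p_ys <- 1e-6
  rep_all$significant_both <- TRUE
  w_all <- select_significant(rep_all)
  expect_identical(w_all$index, index_names())

  # none significant -> CSI undefined
  rep_none <- rep
  rep_none$significant_both <- FALSE
  expect_error(select_significant(rep_none), "CSI is undefined")
})

test_that("CSI reproduces the published L53 worked example", {
  it <- data.frame(genotype = "L53", mp = 4.286, gmp = 3.553,
                   hm = 2.945, sti = 0.788)
  sc <- compute_csi(it, pooled_weights())
  expect_equal(sc$csi, 10.083, tolerance = 1e-3)
})

test_that("CSI is the half-sum of correlation-weighted indices", {
  # unit weights on a single index return the index itself
  it <- data.frame(genotype = c("a", "b"), mp = c(2.5, 4.0))
  w1 <- csi_weights("mp", r_yp = 1, r_ys = 1)
  expect_equal(compute_csi(it, w1)$csi, it$mp)
  # r_yp = r_ys = 1/2 on MP reproduces MP/2
  wh <- csi_weights("mp", r_yp = 0.5, r_ys = 0.5)
  expect_equal(compute_csi(it, wh)$csi, it$mp / 2)

  # arbitrary weights vs an elementwise brute-force re-summation
  set.seed(9)
  it5 <- data.frame(genotype = letters[1:5],
                    gmp = runif(5, 1, 4), sti = runif(5, 0, 1))
  w <- csi_weights(c("gmp", "sti"), r_yp = c(0.4, -0.3),
                   r_ys = c(0.9, 0.2))
  got <- compute_csi(it5, w)$csi
  want <- vapply(1:5, function(i) {
    0.5 * (0.4 * it5$gmp[i] + (-0.3) * it5$sti[i] +
             0.9 * it5$gmp[i] + 0.2 * it5$sti[i])
  }, numeric(1))
  expect_equal(got, want, tolerance = 1e-12)

  # linearity: scaling one index column by c scales its contribution by c
  it5b <- it5
  it5b$sti <- 3 * it5$sti
  delta <- compute_csi(it5b, w)$csi - got
  expect_equal(delta, 0.5 * ((-0.3) + 0.2) * (3 - 1) * it5$sti,
               tolerance = 1e-12)

  # missing index value -> missing CSI for that genotype only
  it5c <- it5
  it5c$gmp[2] <- NA
  sc <- compute_csi(it5c, w)
  expect_true(is.na(sc$csi[2]))
  expect_false(anyNA(sc$csi[-2]))
})

test_that("ranking is descending with lexicographic tie-break", {
  expect_identical(rank_by_score(c(A = 2, B = 3, C = 1), top_k = 2),
                   c("B", "A"))
  expect_identical(rank_by_score(c(B = 1, A = 1), top_k = 1), "A")
  expect_warning(all3 <- rank_by_score(c(A = 2, B = 3, C = 1), top_k = 9),
                 "exceeds")
  expect_identical(all3, c("B", "A", "C"))
  sc <- data.frame(genotype = c("x", "y"), csi = c(1, 2))
  class(sc) <- c("csi_scores", "data.frame")
  expect_identical(rank_by_score(sc), c("y", "x"))
})

test_that("CSI ranking tracks GMP under the published weight pattern", {
  trial <- simulate_ril_trial(sim_spec(seed = 21))
  pairs <- paired_yields(trial, "pooled")
  it <- tolerance_indices(pairs)
  sc <- compute_csi(it, pooled_weights())
  rho <- stats::cor(sc$csi, it$gmp, method = "spearman")
  expect_gt(rho, 0.9)
})

test_that("transgressive segregants use strict inequalities per environment", {
  y <- matrix(c(5, 2, 4, 4, 3.0,   # 2017_N (mid ties the better parent)
                2, 0.5, 1.5, 1, 1, # 2017_D
                6, 2, 5, 4, 4,     # 2018_N
                3, 0.4, 2, 1.5, 1.5), # 2018_D
              nrow = 5,
              dimnames = list(c("hi", "lo", "mid", "P1", "P2"),
                              c("2017_N", "2017_D", "2018_N", "2018_D")))
  et <- c(hi = "line", lo = "line", mid = "line",
          P1 = "parent", P2 = "parent")
  trial <- make_trial(y, et)
  seg <- transgressive_segregants(trial)
  # hi beats both parents everywhere; lo is below both everywhere;
  # mid ties the worse parent in 2017_N (strict rule: not transgressive)
  for (e in names(seg$per_env)) {
    expect_true("hi" %in% seg$per_env[[e]]$positive)
    expect_true("lo" %in% seg$per_env[[e]]$negative)
  }
  expect_false("mid" %in% seg$per_env[["2017N"]]$positive)
  expect_identical(seg$overall$both$positive, "hi")
  expect_identical(seg$overall$both$negative, "lo")
  # positive and negative sets are disjoint per environment
  for (e in names(seg$per_env)) {
    expect_length(intersect(seg$per_env[[e]]$positive,
                            seg$per_env[[e]]$negative), 0)
  }

  # a parent missing from one environment skips it with a warning
  trial_miss <- trial[!(trial$genotype == "P1" & trial$year == "2018" &
                          trial$condition == "D"), ]
  expect_warning(seg2 <- transgressive_segregants(trial_miss), "skipped")
  expect_false("2018D" %in% names(seg2$per_env))

  expect_error(transgressive_segregants(trial, parent_ids = "P1"),
               "exactly two")
})

test_that("csi_screen fits per scope and predicts new genotypes", {
  trial <- simulate_ril_trial(sim_spec(seed = 4))
  fit <- csi_screen(trial, scope = "both")
  expect_setequal(names(fit$scopes), c("2017", "2018", "2019", "pooled"))
  s <- fit$scopes$pooled
  expect_equal(nrow(s$scores), 157)
  expect_true(all(is.finite(s$scores$csi)))
  expect_identical(s$ranking[1],
                   rank_by_score(s$scores, top_k = 1))
  # coef returns the learned weights for the pooled scope by default
  expect_s3_class(coef(fit), "csi_weights")
  # predict on held-out pairs agrees with direct computation
  new <- data.frame(genotype = "new", yp = 5, ys = 2)
  pred <- predict(fit, newdata = new)
  direct <- compute_csi(tolerance_indices(new, s$means), s$weights)
  expect_equal(pred$csi, direct$csi)

  # CSI-selected genotypes overlap the truly best genotypes above chance
  tr <- truth_report(trial)$truth
  true_rank <- tr$genotype[order(-(tr$g_p + tr$g_s) / 2)]
  top <- 20
  overlap <- length(intersect(s$ranking[1:top], true_rank[1:top]))
  expect_gt(overlap, 6) # chance expectation ~ 20 * 20 / 157 = 2.5
})
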