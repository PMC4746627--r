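# Pearson/Spearman association scores, permutation p-values and the CARS
# penalty calibration.

test_that("absolute Pearson scores carry the association sign", {
  expect_equal(pearson_abs(c(1, 2, 3), c(2, 4, 6)),
               list(score = 1, sign = "+", valid = TRUE))
  expect_equal(pearson_abs(c(1, 2, 3), c(3, 2, 1)),
               list(score = 1, sign = "-", valid = TRUE))
  r <- pearson_abs(c(1, 2, 3, 4), c(1, 3, 2, 4))
  expect_equal(r$score, 0.8)     # covariance 4 over sd product 5
  expect_equal(r$sign, "+")
})

test_that("absolute Spearman ranks first, with mean ranks for ties", {
  expect_equal(spearman_abs(c(1, 2, 3, 4), c(1, 4, 9, 16))$score, 1)
  expect_equal(spearman_abs(c(1, 2, 3, 4), c(10, 5, 2, 1))$sign, "-")
  expect_equal(spearman_abs(c(1, 2, 3, 4), c(10, 5, 2, 1))$score, 1)
  tied <- spearman_abs(c(1, 2, 3, 4), c(1, 1, 2, 3))
  expect_equal(tied$score, 0.948683298050514)  # ranks (1,2,3,4) vs (1.5,1.5,3,4)
})

test_that("constant profiles are invalid with score 0 for PC and SC", {
  for (f in list(pearson_abs, spearman_abs)) {
    r <- f(c(2, 2, 2, 2), c(1, 5, 3, 4))
    expect_false(r$valid)
    expect_equal(r$score, 0)
    expect_equal(r$sign, "n/a")
  }
})

test_that("PC and SC match direct-formula oracles on random vectors", {
  set.seed(99)
  naive_pearson <- function(x, y) {
    sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  }
  for (i in 1:200) {
    t_len <- sample(3:20, 1)
    x <- rnorm(t_len)
    y <- rnorm(t_len)
    expect_equal(pearson_abs(x, y)$score, abs(naive_pearson(x, y)),
                 tolerance = 1e-12)
    expect_equal(spearman_abs(x, y)$score,
                 abs(naive_pearson(rank(x), rank(y))), tolerance = 1e-12)
  }
})

test_that("PC and SC are invariant under positive affine transforms", {
  set.seed(5)
  for (i in 1:20) {
    x <- rnorm(10); y <- rnorm(10)
    a <- runif(1, 0.1, 5); b <- rnorm(1)
    expect_equal(pearson_abs(a * x + b, y)$score, pearson_abs(x, y)$score)
    expect_equal(spearman_abs(x, a * y + b)$score, spearman_abs(x, y)$score)
  }
})

test_that("score_associations flags degenerate profiles per method", {
  binding <- rbind(g1 = c(1, 5, 2, 8), g2 = c(3, 3, 3, 3))
  expr <- rbind(g1 = c(0.5, 2, 1, 4), g2 = c(1, 2, 3, 4))
  colnames(binding) <- colnames(expr) <- paste0("c", 1:4)
  sc <- score_associations(binding, expr)
  con <- sc[sc$gene_id == "g2", ]
  expect_false(con$valid[con$method == "PC"])
  expect_false(con$valid[con$method == "SC"])
  expect_true(con$valid[con$method == "CARS"])   # degenerate but scored
  # matrix path agrees with the scalar scorers
  g1 <- sc[sc$gene_id == "g1", ]
  expect_equal(g1$score[g1$method == "PC"],
               pearson_abs(expr["g1", ], binding["g1", ])$score)
  expect_equal(g1$score[g1$method == "SC"],
               spearman_abs(expr["g1", ], binding["g1", ])$score)
  expect_equal(g1$score[g1$method == "CARS"],
               cars(expr["g1", ], binding["g1", ])$score)
})

test_that("empirical p-values follow the add-one estimator", {
  set.seed(21)
  G <- 8; t_len <- 10
  B <- matrix(rpois(G * t_len, 4), G, t_len,
              dimnames = list(paste0("g", 1:G), paste0("c", 1:t_len)))
  E <- matrix(rgamma(G * t_len, 2), G, t_len, dimnames = dimnames(B))
  n_perm <- 25
  p <- empirical_pvalues(B, E, method = "CARS", B = n_perm, seed = 9)
  n_null <- n_perm * G
  expect_true(all(p >= 1 / (n_null + 1) & p <= 1))
  # p-values sit exactly on the add-one grid
  expect_true(all(abs(p * (n_null + 1) - round(p * (n_null + 1))) < 1e-9))
  # an observed score exceeding every null score reaches the floor
  huge <- stats::setNames(rep(1e9, G), rownames(B))
  p_hi <- empirical_pvalues(B, E, method = "CARS", B = n_perm, seed = 9,
                            observed = huge)
  expect_equal(unname(p_hi), rep(1 / (n_null + 1), G))
  # observed score 0 is never beaten: p = 1
  zero <- stats::setNames(rep(0, G), rownames(B))
  p_lo <- empirical_pvalues(B, E, method = "CARS", B = n_perm, seed = 9,
                            observed = zero)
  expect_equal(unname(p_lo), rep(1, G))
  # deterministic under a fixed seed
  expect_identical(p, empirical_pvalues(B, E, method = "CARS", B = n_perm,
                                        seed = 9))
})

test_that("pooled null p-values match a direct count recomputation", {
  set.seed(31)
  G <- 5; t_len <- 8; n_perm <- 12
  B <- matrix(rpois(G * t_len, 3), G, t_len,
              dimnames = list(paste0("g", 1:G), paste0("c", 1:t_len)))
  E <- matrix(rgamma(G * t_len, 2), G, t_len, dimnames = dimnames(B))
  p <- empirical_pvalues(B, E, method = "PC", B = n_perm, seed = 4)
  # rebuild the same pooled null by hand from the same seeded permutations
  obs <- vapply(rownames(B), function(g) {
    pearson_abs(E[g, ], B[g, ])$score
  }, numeric(1))
  set.seed(4)
  null_scores <- unlist(lapply(seq_len(n_perm), function(b) {
    vapply(seq_len(G), function(i) {
      pearson_abs(E[i, ], B[i, sample.int(t_len)])$score
    }, numeric(1))
  }))
  manual <- vapply(obs, function(o) {
    (1 + sum(null_scores >= o)) / (1 + length(null_scores))
  }, numeric(1))
  expect_equal(unname(p[names(obs)]), unname(manual), tolerance = 1e-12)
})

test_that("penalty calibration selects a c with a uniform upper tail", {
  cal1 <- calibrate_cars_c(
    matrix(rpois(40, 3), 5, 8, dimnames = list(paste0("g", 1:5),
                                               paste0("c", 1:8))),
    matrix(rgamma(40, 2), 5, 8, dimnames = list(paste0("g", 1:5),
                                                paste0("c", 1:8))),
    grid = 0.3, B = 20, seed = 2
  )
  expect_equal(cal1$c_star, 0.3)            # singleton grid returns itself
  expect_equal(nrow(cal1$diagnostics), 1L)

  # a very narrow penalty collapses most scores and grossly distorts the
  # upper tail; a wide penalty keeps it uniform, so the wide one is chosen
  set.seed(12)
  G <- 120; t_len <- 12
  B <- matrix(rgamma(G * t_len, 2, 1), G, t_len,
              dimnames = list(sprintf("g%03d", 1:G), paste0("c", 1:t_len)))
  E <- matrix(rgamma(G * t_len, 2, 1), G, t_len, dimnames = dimnames(B))
  cal <- calibrate_cars_c(B, E, grid = c(0.02, 0.4), B = 60, seed = 8)
  expect_equal(cal$c_star, 0.4)
  d <- cal$diagnostics
  expect_gt(d$ks_stat[d$c == 0.02], d$ks_stat[d$c == 0.4])
  # deterministic under the seed
  cal2 <- calibrate_cars_c(B, E, grid = c(0.02, 0.4), B = 60, seed = 8)
  expect_identical(cal$diagnostics, cal2$diagnostics)
})
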