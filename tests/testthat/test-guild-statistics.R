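test_that("Jaccard similarity is intersection over union, symmetric", {
  expect_equal(jaccard_similarity(c("a", "b"), c("a", "b")), 1)
  expect_equal(jaccard_similarity(c("a", "b"), c("c", "d")), 0)
  expect_equal(jaccard_similarity(c("a", "b", "c"), c("b", "c", "d")), 0.5)
  expect_equal(jaccard_similarity(c("a", "b", "c"), c("b", "c", "d")),
               jaccard_similarity(c("b", "c", "d"), c("a", "b", "c")))
  # binary-vector interface agrees with the set interface and with vegan
  a <- c(1, 1, 0, 1, 0)
  b <- c(0, 1, 1, 1, 0)
  expect_equal(jaccard_similarity(a, b), 2 / 4)
  vd <- 1 - as.numeric(vegan::vegdist(rbind(a, b), method = "jaccard",
                                      binary = TRUE))
  expect_equal(jaccard_similarity(a, b), vd)
  expect_error(jaccard_similarity(character(0), character(0)), "empty")
})

test_that("PCoA reconstructs Euclidean configurations", {
  # three collinear points
  d <- as.matrix(dist(c(0, 1, 3)))
  ord <- diet_pcoa(d)
  expect_equal(ncol(ord$coordinates), 1L)
  expect_equal(as.matrix(dist(ord$coordinates)), unname(d),
               ignore_attr = TRUE, tolerance = 1e-9)
  # equidistant points form a simplex with equal pairwise distances
  d3 <- matrix(1, 3, 3) - diag(3)
  ord3 <- diet_pcoa(d3)
  rec <- as.matrix(dist(ord3$coordinates))
  expect_equal(rec[upper.tri(rec)], rep(1, 3), tolerance = 1e-9)
  # random 4-point Euclidean distances are reproduced exactly
  set.seed(8)
  pts <- matrix(rnorm(8), 4, 2)
  d4 <- as.matrix(dist(pts))
  ord4 <- diet_pcoa(d4)
  expect_equal(as.matrix(dist(ord4$coordinates)), unname(d4),
               ignore_attr = TRUE, tolerance = 1e-9)
  expect_true(all(diff(ord4$eigenvalues) <= 1e-9)) # descending
})

test_that("Pianka's index matches its formula and invariances", {
  expect_equal(pianka_pair(c(2, 4, 6), c(1, 2, 3)), 1) # proportional
  expect_equal(pianka_pair(c(1, 0), c(0, 1)), 0)       # orthogonal
  u <- c(75, 25, 0); v <- c(50, 25, 25)
  oracle <- sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  expect_equal(pianka_pair(u, v), oracle)
  expect_equal(pianka_pair(v, u), pianka_pair(u, v))        # symmetric
  expect_equal(pianka_pair(u / sum(u), v * 7), pianka_pair(u, v)) # scale-free
})

test_that("guild mean overlap averages all unordered pairs", {
  m2 <- rbind(c(75, 25, 0), c(50, 25, 25))
  expect_equal(guild_mean_overlap(m2), pianka_pair(m2[1, ], m2[2, ]))
  m_same <- rbind(c(1, 2, 3), c(2, 4, 6), c(10, 20, 30))
  expect_equal(guild_mean_overlap(m_same), 1)
  m3 <- rbind(c(75, 25, 0), c(50, 25, 25), c(10, 80, 10))
  oracle <- mean(c(pianka_pair(m3[1, ], m3[2, ]),
                   pianka_pair(m3[1, ], m3[3, ]),
                   pianka_pair(m3[2, ], m3[3, ])))
  expect_equal(guild_mean_overlap(m3), oracle)
  expect_error(guild_mean_overlap(m3[1, , drop = FALSE]), "two species")
})

test_that("RA3 shuffle permutes within rows uniformly", {
  m <- rbind(c(5, 3, 2, 0), c(1, 1, 8, 4))
  set.seed(10)
  for (i in 1:20) {
    s <- ra3_shuffle(m)
    expect_equal(rowSums(s), rowSums(m), ignore_attr = TRUE)
    expect_equal(apply(s, 1, sort), apply(m, 1, sort)) # row multisets kept
  }
  # distribution over the 6 orderings of a 1x3 row is uniform (chi-squared)
  set.seed(11)
  row <- matrix(c(1, 2, 3), 1)
  keys <- replicate(6000, paste(ra3_shuffle(row), collapse = ""))
  tab <- table(keys)
  expect_equal(length(tab), 6L)
  chi <- sum((tab - 1000)^2 / 1000)
  expect_lt(chi, qchisq(0.999, df = 5))
})

test_that("niche null model p-values are calibrated bounds with fixed seed", {
  m_same <- rbind(c(5, 3, 2), c(10, 6, 4)) # proportional rows: overlap 1
  nm <- niche_null_model(m_same, iterations = 199, seed = 42)
  expect_equal(nm$observed_index, 1)
  expect_lte(nm$p_upper, 0.05)
  expect_gte(nm$p_upper, 1 / 200)
  # fixed seed reproduces the full simulated vector
  nm2 <- niche_null_model(m_same, iterations = 199, seed = 42)
  expect_identical(nm$simulated, nm2$simulated)
  expect_identical(nm$p_upper, nm2$p_upper)

  # 2x2 exhaustive oracle: each row has 2 equally likely arrangements, so
  # the null distribution has 4 equally likely outcomes
  m22 <- rbind(c(3, 1), c(1, 2))
  outcomes <- c()
  for (p1 in list(c(1, 2), c(2, 1))) {
    for (p2 in list(c(1, 2), c(2, 1))) {
      outcomes <- c(outcomes,
                    guild_mean_overlap(rbind(m22[1, p1], m22[2, p2])))
    }
  }
  obs <- guild_mean_overlap(m22)
  p_exact <- mean(outcomes >= obs)
  nm22 <- niche_null_model(m22, iterations = 999, seed = 5)
  expect_equal(nm22$p_upper, p_exact, tolerance = 0.06)
})

test_that("Friedman test matches base R when tie-free and handles ties", {
  y <- matrix(c(1.2, 2.3, 3.1,
                2.2, 1.1, 3.3,
                1.5, 2.8, 3.9,
                3.1, 1.9, 2.0), nrow = 4, byrow = TRUE)
  ours <- friedman_rank_test(y)
  base <- stats::friedman.test(y)
  expect_equal(ours$chi2, unname(base$statistic))
  expect_equal(ours$df, unname(base$parameter))
  expect_equal(ours$p, base$p.value)
  # complete ties give a zero statistic
  expect_equal(friedman_rank_test(matrix(5, 3, 3))$chi2, 0)
  # monotone effect in every block maximizes the statistic at b(k-1)... via
  # the closed form 12/(bk(k+1)) * sum Rj^2 - 3b(k+1)
  b <- 4; k <- 3
  mono <- matrix(rep(1:k, each = b), nrow = b)
  Rj <- b * seq_len(k)
  max_stat <- 12 / (b * k * (k + 1)) * sum(Rj^2) - 3 * b * (k + 1)
  expect_equal(friedman_rank_test(mono)$chi2, max_stat)
  # tie-corrected statistic on a tied example, hand-computed:
  # block ranks (1.5, 1.5, 3) and (1, 2, 3): A = sum r^2, C = bk(k+1)^2/4
  yt <- matrix(c(2, 2, 5,
                 1, 3, 9), nrow = 2, byrow = TRUE)
  r <- rbind(c(1.5, 1.5, 3), c(1, 2, 3))
  A <- sum(r^2); C <- 2 * 3 * 16 / 4
  expected <- (3 - 1) * sum((colSums(r) - 2 * (3 + 1) / 2)^2) / (A - C)
  expect_equal(friedman_rank_test(yt)$chi2, expected)
})

test_that("exact Friedman p matches exhaustive within-block permutation", {
  y <- matrix(c(1, 2, 3,
                2, 3, 1,
                1, 3, 2), nrow = 3, byrow = TRUE)
  ours <- friedman_rank_test(y, exact = TRUE)
  expect_equal(ours$p, friedman_enum_oracle(y))
  y2 <- matrix(c(0.5, 1.2, 0.1,
                 2.0, 2.5, 1.0,
                 0.3, 0.9, 0.2), nrow = 3, byrow = TRUE)
  expect_equal(friedman_rank_test(y2, exact = TRUE)$p,
               friedman_enum_oracle(y2))
})

test_that("Wilcoxon signed-rank follows conventions and the exact law", {
  # all-zero differences are undefined
  expect_error(wilcoxon_signed_rank(1:4, 1:4), "zero")
  # antisymmetric differences give Z = 0
  x <- c(5, 5); y <- c(4, 6)
  w <- wilcoxon_signed_rank(x, y)
  expect_equal(w$Z, 0)
  expect_equal(w$p, 1)
  # agreement with base R's normal approximation (no continuity correction)
  set.seed(12)
  a <- rnorm(12); b <- a + rnorm(12, 0.4)
  ours <- wilcoxon_signed_rank(a, b)
  base <- suppressWarnings(stats::wilcox.test(a, b, paired = TRUE,
                                              exact = FALSE, correct = FALSE))
  expect_equal(ours$W, unname(base$statistic))
  expect_equal(ours$p, base$p.value)
  # exact enumeration on n = 6 toy pairs vs the 2^6 oracle
  x6 <- c(1.1, 2.0, 3.2, 4.1, 5.7, 6.3)
  y6 <- c(0.8, 2.6, 2.1, 4.9, 5.0, 5.1)
  expect_equal(wilcoxon_signed_rank(x6, y6, exact = TRUE)$p,
               wilcoxon_enum_oracle(x6, y6))
  # and on tied absolute differences (midranks) with n = 8
  x8 <- c(1, 2, 3, 4, 5, 6, 7, 8)
  y8 <- c(2, 1, 5, 2, 7, 4, 6, 9)
  expect_equal(wilcoxon_signed_rank(x8, y8, exact = TRUE)$p,
               wilcoxon_enum_oracle(x8, y8))
})
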