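# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: the aligner oracle is a plain-R dynamic program,
# the statistics oracles are exhaustive enumerations.

# Brute-force Smith-Waterman DP with linear gap costs; same deterministic
# tie-break convention as documented for the package aligner (diagonal >
# deletion > insertion, optimum = first maximum in row-major order).
sw_oracle <- function(q, t, match = 1, mismatch = 2, ins = 3, del = 3) {
  qc <- strsplit(q, "")[[1]]
  tc <- strsplit(t, "")[[1]]
  n <- length(qc); m <- length(tc)
  H <- matrix(0L, n + 1, m + 1)
  D <- matrix(0L, n + 1, m + 1)
  best <- 0L; bi <- 0L; bj <- 0L
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      sub <- if (qc[i] == tc[j]) match else -mismatch
      d <- H[i, j] + sub
      up <- H[i, j + 1] - ins
      lf <- H[i + 1, j] - del
      v <- max(0L, d, lf, up)
      dv <- 0L
      if (v > 0L) dv <- if (d == v) 1L else if (lf == v) 2L else 3L
      H[i + 1, j + 1] <- v
      D[i + 1, j + 1] <- dv
      if (v > best) { best <- v; bi <- i; bj <- j }
    }
  }
  matches <- mismatches <- ins_n <- del_n <- cols <- 0L
  i <- bi; j <- bj
  if (best > 0L) {
    repeat {
      dv <- D[i + 1, j + 1]
      if (dv == 0L) break
      if (dv == 1L) {
        if (qc[i] == tc[j]) matches <- matches + 1L else mismatches <- mismatches + 1L
        i <- i - 1L; j <- j - 1L
      } else if (dv == 2L) {
        del_n <- del_n + 1L; j <- j - 1L
      } else {
        ins_n <- ins_n + 1L; i <- i - 1L
      }
      cols <- cols + 1L
    }
  }
  list(score = best, matches = matches, mismatches = mismatches,
       insertions = ins_n, deletions = del_n, aligned_cols = cols,
       q_start = i, q_end = bi, t_start = j, t_end = bj)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# mutate a sequence with `k` substitutions at distinct positions
mutate_seq <- function(seq, k) {
  chars <- strsplit(seq, "")[[1]]
  pos <- sample(length(chars), k)
  for (i in pos) chars[i] <- sample(setdiff(c("A", "C", "G", "T"), chars[i]), 1)
  paste(chars, collapse = "")
}

# Exact Wilcoxon signed-rank p by enumerating all 2^n sign assignments
# (two-sided via |W - mu|), independent of the package implementation.
wilcoxon_enum_oracle <- function(x, y) {
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  W_obs <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  Ws <- as.vector(signs %*% r)
  mean(abs(Ws - mu) >= abs(W_obs - mu) - 1e-12)
}

# all permutations of 1..k, built by repeated selection (independent of the
# package's insertion-based generator)
perms_oracle <- function(k) {
  if (k == 1) return(matrix(1L, 1, 1))
  do.call(rbind, lapply(seq_len(k), function(first) {
    rest <- perms_oracle(k - 1)
    rest_vals <- setdiff(seq_len(k), first)
    cbind(first, matrix(rest_vals[rest], nrow(rest), k - 1))
  }))
}

# Exact Friedman permutation p: permute treatments within each block and
# count statistics >= observed; the statistic is delegated to base R's
# friedman.test (valid for tie-free permuted data).
friedman_enum_oracle <- function(y) {
  k <- ncol(y); b <- nrow(y)
  stat <- function(m) unname(stats::friedman.test(m)$statistic)
  obs <- stat(y)
  perms <- perms_oracle(k)
  grid <- expand.grid(rep(list(seq_len(nrow(perms))), b))
  cnt <- 0L
  for (g in seq_len(nrow(grid))) {
    m <- y
    for (i in seq_len(b)) m[i, ] <- y[i, perms[grid[g, i][[1]], ]]
    if (stat(m) >= obs - 1e-12) cnt <- cnt + 1L
  }
  cnt / nrow(grid)
}

# Exhaustive incidence rarefaction: average richness over all m-subsets of
# sampling units.
rarefaction_enum_oracle <- function(incidence, m) {
  n <- nrow(incidence)
  subsets <- utils::combn(n, m)
  mean(apply(subsets, 2, function(rows) {
    sum(colSums(incidence[rows, , drop = FALSE]) > 0)
  }))
}
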