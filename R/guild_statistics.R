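#' Presence/absence matrix from a diet matrix slice
#'
#' @param matrix a `diet_matrix`.
#' @param season season slice, default `"Overall"`.
#' @param drop_undetermined exclude the `"Undetermined"` prey row
#'   (default TRUE; unidentified prey carries no taxon identity, so it
#'   cannot participate in set-based similarity).
#' @return binary matrix, predators x prey items.
#' @export
presence_matrix <- function(matrix, season = "Overall",
                            drop_undetermined = TRUE) {
  m <- t(matrix$counts[, , season])
  if (drop_undetermined) m <- m[, colnames(m) != "Undetermined", drop = FALSE]
  (m > 0) * 1L
}

#' Jaccard dietary similarity
#'
#' Intersection over union of two prey presence sets; higher values mean
#' greater dietary similarity.
#'
#' @param a,b prey presence sets: character vectors of prey labels, or
#'   binary vectors of equal length.
#' @return similarity in `[0, 1]`.
#' @export
jaccard_similarity <- function(a, b) {
  if (is.numeric(a) || is.logical(a)) {
    stopifnot(length(a) == length(b))
    a <- which(a > 0); b <- which(b > 0)
  }
  u <- union(a, b)
  if (length(u) == 0L) stop("both presence sets are empty")
  length(intersect(a, b)) / length(u)
}

#' Pairwise Jaccard similarity matrix
#'
#' @param presence binary predators x prey matrix
#'   (see [presence_matrix()]).
#' @return symmetric similarity matrix with unit diagonal.
#' @export
jaccard_matrix <- function(presence) {
  k <- nrow(presence)
  out <- diag(1, k)
  dimnames(out) <- list(rownames(presence), rownames(presence))
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (i < j) {
        out[i, j] <- out[j, i] <-
          jaccard_similarity(presence[i, ], presence[j, ])
      }
    }
  }
  out
}

#' Principal coordinates analysis of a dissimilarity matrix
#'
#' Classical (Torgerson) scaling: double-center `-D^2/2`, eigendecompose,
#' and scale eigenvectors by the square roots of the eigenvalues.
#' Axes with negative eigenvalues are dropped with a warning.
#'
#' @param dissimilarity square symmetric matrix with zero diagonal
#'   (e.g. `1 - jaccard_matrix(p)`).
#' @param k maximum number of axes to return.
#' @return An `ordination_result`: list with `coordinates` (points x
#'   axes) and `eigenvalues` (descending, positive axes only).
#' @export
diet_pcoa <- function(dissimilarity, k = nrow(dissimilarity) - 1L) {
  stopifnot(isSymmetric(unname(as.matrix(dissimilarity))),
            all(abs(diag(as.matrix(dissimilarity))) < 1e-12))
  fit <- cmdscale(stats::as.dist(dissimilarity), k = k, eig = TRUE)
  eig <- fit$eig
  if (any(eig < -1e-8)) {
    warning(sum(eig < -1e-8), " negative eigenvalue(s) dropped")
  }
  pos <- which(eig > 1e-8)
  coords <- fit$points[, seq_len(min(length(pos), ncol(fit$points))),
                       drop = FALSE]
  colnames(coords) <- paste0("Axis", seq_len(ncol(coords)))
  structure(list(coordinates = coords, eigenvalues = eig[pos]),
            class = "ordination_result")
}

#' Pianka's niche overlap index for two utilization vectors
#'
#' `O = sum(p q) / sqrt(sum(p^2) sum(q^2))`: the cosine similarity of the
#' two resource-utilization vectors, ranging 0 (no shared resources) to 1
#' (proportional use). Scale-invariant, so raw counts and FOO percentages
#' give the same value.
#'
#' @param u,v non-negative utilization vectors with positive sums.
#' @return overlap in `[0, 1]`.
#' @export
pianka_pair <- function(u, v) {
  stopifnot(length(u) == length(v), all(u >= 0), all(v >= 0),
            sum(u) > 0, sum(v) > 0)
  sum(u * v) / sqrt(sum(u^2) * sum(v^2))
}

#' Mean pairwise niche overlap of a guild
#'
#' @param mat species x resource utilization matrix (>= 2 rows).
#' @return mean of [pianka_pair()] over all unordered species pairs.
#' @export
guild_mean_overlap <- function(mat) {
  mat <- as.matrix(mat)
  if (nrow(mat) < 2L) stop("need at least two species rows")
  norm <- mat / sqrt(rowSums(mat^2))
  cp <- tcrossprod(norm)
  mean(cp[upper.tri(cp)])
}

#' RA3 randomization of a utilization matrix
#'
#' Independently permutes each species' utilization values across
#' resource columns: niche breadth (the multiset of values in each row)
#' is retained while which resource carries which value is scrambled.
#'
#' @param mat non-negative species x resource matrix.
#' @return the shuffled matrix.
#' @export
ra3_shuffle <- function(mat) {
  mat <- as.matrix(mat)
  stopifnot(all(mat >= 0))
  t(apply(mat, 1L, sample))
}

#' Niche-overlap randomization null model
#'
#' Compares the observed guild mean Pianka overlap to its distribution
#' under `iterations` RA3 randomizations. The upper-tail probability uses
#' the add-one convention
#' `p = (1 + #\{simulated >= observed\}) / (iterations + 1)`, so the
#' smallest attainable p is `1/(iterations + 1)`.
#'
#' @param mat species x resource utilization matrix (>= 2 rows and
#'   columns), e.g. FOO percentages per predator.
#' @param iterations number of null simulations (default 999).
#' @param seed RNG seed; fixing it reproduces the simulated vector
#'   exactly. The caller's RNG state is restored on exit.
#' @return A `null_model_result`: `observed_index`, `simulated`,
#'   `p_upper`, `iterations`, `seed`.
#' @export
niche_null_model <- function(mat, iterations = 999L, seed = NULL) {
  mat <- as.matrix(mat)
  stopifnot(nrow(mat) >= 2L, ncol(mat) >= 2L)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  observed <- guild_mean_overlap(mat)
  simulated <- vapply(seq_len(iterations),
                      function(i) guild_mean_overlap(ra3_shuffle(mat)),
                      numeric(1))
  structure(list(observed_index = observed, simulated = simulated,
                 p_upper = (1 + sum(simulated >= observed)) / (iterations + 1),
                 iterations = as.integer(iterations), seed = seed),
            class = "null_model_result")
}

#' @export
print.null_model_result <- function(x, ...) {
  cat(sprintf("Niche-overlap null model: observed %.3f, null mean %.3f, p (upper) = %.4g [%d iterations]\n",
              x$observed_index, mean(x$simulated), x$p_upper, x$iterations))
  invisible(x)
}

#' Friedman rank test for repeated measures
#'
#' Within-block ranks (midranks for ties), tie-corrected statistic
#' `chi2 = (k - 1) * sum((R_j - b(k+1)/2)^2) / (A - C)` with
#' `A = sum(r_ij^2)` and `C = b k (k+1)^2 / 4`; under complete ties the
#' statistic is defined as 0. The p-value comes from the chi-squared
#' distribution with `k - 1` df, or from exhaustive within-block
#' permutation when `exact = TRUE` (feasible for small `b`, `k`).
#'
#' @param y blocks x treatments matrix (e.g. prey taxa x seasons of FOO
#'   values for one predator).
#' @param exact enumerate all `(k!)^b` within-block permutations for the
#'   p-value.
#' @return list with `chi2`, `df`, `p`, and `method`.
#' @export
friedman_rank_test <- function(y, exact = FALSE) {
  y <- as.matrix(y)
  b <- nrow(y); k <- ncol(y)
  stopifnot(b >= 2L, k >= 2L)
  stat <- function(m) {
    r <- t(apply(m, 1L, rank))
    Rj <- colSums(r)
    A <- sum(r^2)
    C <- b * k * (k + 1)^2 / 4
    if (abs(A - C) < 1e-12) return(0)
    (k - 1) * sum((Rj - b * (k + 1) / 2)^2) / (A - C)
  }
  chi2 <- stat(y)
  if (exact) {
    perms <- all_permutations(k)
    idx <- rep(1L, b)
    n_per <- nrow(perms)
    count <- 0L; total <- 0L
    repeat {
      m <- y
      for (i in seq_len(b)) m[i, ] <- y[i, perms[idx[i], ]]
      if (stat(m) >= chi2 - 1e-12) count <- count + 1L
      total <- total + 1L
      j <- 1L
      while (j <= b) {
        idx[j] <- idx[j] + 1L
        if (idx[j] <= n_per) break
        idx[j] <- 1L
        j <- j + 1L
      }
      if (j > b) break
    }
    p <- count / total
    method <- "exact within-block permutation"
  } else {
    p <- pchisq(chi2, df = k - 1, lower.tail = FALSE)
    method <- "chi-squared approximation"
  }
  list(chi2 = chi2, df = k - 1L, p = p, method = method)
}

# all permutations of 1..k as a matrix (rows)
all_permutations <- function(k) {
  if (k == 1L) return(matrix(1L, 1, 1))
  sub <- all_permutations(k - 1L)
  out <- matrix(0L, nrow = factorial(k), ncol = k)
  # insert k into each position of each sub-permutation
  row <- 1L
  for (r in seq_len(nrow(sub))) {
    for (pos in seq_len(k)) {
      out[row, ] <- append(sub[r, ], k, after = pos - 1L)
      row <- row + 1L
    }
  }
  out
}

#' Wilcoxon signed-rank test for paired samples
#'
#' Zero differences are dropped (the classical Wilcoxon convention, not
#' Pratt); tied absolute differences receive midranks. `W` is the sum of
#' positive-difference ranks; the large-sample statistic is
#' `Z = (W - n(n+1)/4) / sigma` with the tie-corrected variance
#' `n(n+1)(2n+1)/24 - sum(t^3 - t)/48`, and the two-sided p comes from
#' the normal approximation (no continuity correction) or, with
#' `exact = TRUE`, from enumeration of all `2^n` sign assignments
#' (two-sided via `|W - mu|`).
#'
#' @param x,y paired numeric vectors of equal length.
#' @param exact enumerate the exact sign-flip distribution (n <= ~20).
#' @param correct apply a 0.5 continuity correction to Z (default FALSE).
#' @return list with `W`, `Z`, `p`, `n` (non-zero pairs), `method`.
#' @export
wilcoxon_signed_rank <- function(x, y, exact = FALSE, correct = FALSE) {
  stopifnot(length(x) == length(y), length(x) >= 2L)
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) stop("all differences are zero; test undefined")
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  if (exact) {
    # enumerate all 2^n sign assignments of the midranks
    Ws <- 0
    for (i in seq_len(n)) {
      Ws <- as.vector(outer(Ws, c(0, r[i]), "+"))
    }
    p <- mean(abs(Ws - mu) >= abs(W - mu) - 1e-12)
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    Z <- if (sigma2 > 0) (W - mu) / sqrt(sigma2) else 0
    method <- "exact sign enumeration"
  } else {
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    if (sigma2 <= 0) stop("zero variance (all |differences| tied at one value and n too small)")
    num <- W - mu
    if (correct) num <- num - sign(num) * 0.5
    Z <- num / sqrt(sigma2)
    p <- 2 * pnorm(-abs(Z))
    method <- "normal approximation"
  }
  list(W = W, Z = Z, p = min(p, 1), n = n, method = method)
}
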