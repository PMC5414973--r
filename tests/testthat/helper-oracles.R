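# Independent oracles: naive per-pixel loops and textbook rank formulas,
# deliberately written without reusing the package's internals.

naive_mean <- function(px, mask) {
  tot <- 0; n <- 0
  for (i in seq_len(nrow(px))) for (j in seq_len(ncol(px))) {
    if (mask[i, j]) { tot <- tot + px[i, j]; n <- n + 1 }
  }
  tot / n
}

naive_hist10 <- function(px, mask) {
  counts <- numeric(10)
  for (i in seq_len(nrow(px))) for (j in seq_len(ncol(px))) {
    if (mask[i, j]) {
      b <- floor(px[i, j] * 10 / 4096) + 1
      counts[b] <- counts[b] + 1
    }
  }
  counts
}

naive_pct_brightest <- function(px, mask, bright_bins = 8:10) {
  h <- naive_hist10(px, mask)
  100 * sum(h[bright_bins]) / sum(h)
}

# Kruskal-Wallis H from the textbook rank-sum formula with tie correction.
kw_H_formula <- function(samples) {
  x <- unlist(samples)
  N <- length(x)
  r <- rank(x)
  n <- vapply(samples, length, integer(1))
  grp <- rep(seq_along(samples), n)
  Rsum <- tapply(r, grp, sum)
  H <- 12 / (N * (N + 1)) * sum(Rsum^2 / n) - 3 * (N + 1)
  ties <- table(x)
  C <- 1 - sum(ties^3 - ties) / (N^3 - N)
  H / C
}

# Exact permutation p-value of H by exhaustive enumeration of all distinct
# group assignments (feasible for total N <= 8).
exact_kw_perm_p <- function(samples) {
  x <- unlist(samples)
  n <- vapply(samples, length, integer(1))
  H_obs <- kw_H_formula(samples)
  idx_all <- seq_along(x)
  count <- 0L
  total <- 0L
  assign_rec <- function(remaining, gi, chosen) {
    if (gi > length(n)) {
      grps <- lapply(chosen, function(ii) x[ii])
      H <- kw_H_formula(grps)
      total <<- total + 1L
      if (H >= H_obs - 1e-9) count <<- count + 1L
      return(invisible())
    }
    sets <- utils::combn(remaining, n[gi], simplify = FALSE)
    for (s in sets) assign_rec(setdiff(remaining, s), gi + 1L,
                               c(chosen, list(s)))
  }
  assign_rec(idx_all, 1L, list())
  count / total
}

# Dunn z statistics coded directly from the reference formula.
dunn_z_formula <- function(samples) {
  x <- unlist(samples)
  N <- length(x)
  r <- rank(x)
  n <- vapply(samples, length, integer(1))
  grp <- rep(seq_along(samples), n)
  rbar <- tapply(r, grp, mean)
  ties <- table(x)
  Tsum <- sum(ties^3 - ties)
  k <- length(samples)
  out <- c()
  for (i in 1:(k - 1)) for (j in (i + 1):k) {
    se <- sqrt((N * (N + 1) / 12 - Tsum / (12 * (N - 1))) *
                 (1 / n[i] + 1 / n[j]))
    out <- c(out, (rbar[i] - rbar[j]) / se)
  }
  unname(out)
}

# Small deterministic test image.
make_image <- function(values, nr, nc) {
  gray_image(matrix(values, nr, nc))
}
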