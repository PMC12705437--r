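# Independent brute-force oracles used to cross-check the package's
# statistics on small instances. These are deliberately written as explicit
# loops over textbook formulas, sharing no code with the implementation.

oracle_pearson <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n
  my <- sum(y) / n
  num <- 0; dx <- 0; dy <- 0
  for (i in seq_len(n)) {
    num <- num + (x[i] - mx) * (y[i] - my)
    dx <- dx + (x[i] - mx)^2
    dy <- dy + (y[i] - my)^2
  }
  num / sqrt(dx * dy)
}

oracle_colmeans <- function(vectors) {
  out <- numeric(length(vectors[[1]]))
  for (j in seq_along(out)) {
    s <- 0
    for (v in vectors) s <- s + v[j]
    out[j] <- s / length(vectors)
  }
  out
}

# explicit left-to-right scan; plateau contributes its first index; edges
# behave as -Inf flanks; only positive values can be peaks
oracle_peaks <- function(v) {
  n <- length(v)
  peaks <- integer(0)
  i <- 1L
  while (i <= n) {
    j <- i
    while (j < n && v[j + 1L] == v[i]) j <- j + 1L
    left <- if (i == 1L) -Inf else v[i - 1L]
    right <- if (j == n) -Inf else v[j + 1L]
    if (v[i] > 0 && v[i] > left && v[i] > right) peaks <- c(peaks, i - 1L)
    i <- j + 1L
  }
  peaks
}

oracle_match_prop <- function(a, b) {
  matched <- 0L
  for (x in a) if (x %in% b) matched <- matched + 1L
  matched / min(length(a), length(b))
}

# pixel-center bilinear interpolation with edge clamping, cell by cell
oracle_bilinear <- function(m, n) {
  src <- function(i, nin) {
    p <- (i - 0.5) * nin / n - 0.5
    min(max(p, 0), nin - 1)
  }
  out <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      y <- src(i, nrow(m)); x <- src(j, ncol(m))
      y0 <- floor(y); x0 <- floor(x)
      y1 <- min(y0 + 1, nrow(m) - 1); x1 <- min(x0 + 1, ncol(m) - 1)
      fy <- y - y0; fx <- x - x0
      out[i, j] <- (1 - fy) * (1 - fx) * m[y0 + 1, x0 + 1] +
        (1 - fy) * fx * m[y0 + 1, x1 + 1] +
        fy * (1 - fx) * m[y1 + 1, x0 + 1] +
        fy * fx * m[y1 + 1, x1 + 1]
    }
  }
  pmin(pmax(out, -1), 1)
}

# one-sample and pooled-variance two-sample t statistics, textbook formulas
oracle_t_one <- function(x, mu = 0) {
  (mean(x) - mu) / sqrt(sum((x - mean(x))^2) / (length(x) - 1) / length(x))
}
oracle_t_two <- function(x, y) {
  sp2 <- (sum((x - mean(x))^2) + sum((y - mean(y))^2)) /
    (length(x) + length(y) - 2)
  (mean(x) - mean(y)) / sqrt(sp2 * (1 / length(x) + 1 / length(y)))
}
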