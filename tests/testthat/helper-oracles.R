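# Independent oracles used by the tests: deliberately naive implementations
# that share no code with the package internals.

# per-site loop tally of TN93 site patterns for two character strings
oracle_tally <- function(sa, sb) {
  a <- strsplit(sa, "")[[1]]
  b <- strsplit(sb, "")[[1]]
  stopifnot(length(a) == length(b))
  acgt <- c("A", "C", "G", "T")
  n <- 0L; ts_ag <- 0L; ts_ct <- 0L; tv <- 0L
  counts <- c(A = 0L, C = 0L, G = 0L, T = 0L)
  for (i in seq_along(a)) {
    if (a[i] %in% acgt && b[i] %in% acgt) {
      n <- n + 1L
      counts[a[i]] <- counts[a[i]] + 1L
      counts[b[i]] <- counts[b[i]] + 1L
      if (a[i] != b[i]) {
        pair <- sort(c(a[i], b[i]))
        if (identical(pair, c("A", "G"))) ts_ag <- ts_ag + 1L
        else if (identical(pair, c("C", "T"))) ts_ct <- ts_ct + 1L
        else tv <- tv + 1L
      }
    }
  }
  list(n = n, P1 = ts_ag / n, P2 = ts_ct / n, Q = tv / n,
       freqs = counts / (2 * n))
}

# plain-arithmetic evaluation of the TN93 closed form from tallies
oracle_tn93 <- function(P1, P2, Q, f) {
  gA <- f[["A"]]; gC <- f[["C"]]; gG <- f[["G"]]; gT <- f[["T"]]
  gR <- gA + gG; gY <- gC + gT
  w1 <- 1 - gR * P1 / (2 * gA * gG) - Q / (2 * gR)
  w2 <- 1 - gY * P2 / (2 * gT * gC) - Q / (2 * gY)
  w3 <- 1 - Q / (2 * gR * gY)
  if (w1 <= 0 || w2 <= 0 || w3 <= 0) return(NA_real_)
  -(2 * gA * gG / gR) * log(w1) -
    (2 * gT * gC / gY) * log(w2) -
    2 * (gR * gY - gA * gG * gY / gR - gT * gC * gR / gY) * log(w3)
}

# random pair of aligned sequences with controllable divergence and coverage
random_seq_pair <- function(n_sites = 300, sub_prob = 0.08,
                           cov_b = c(0, n_sites)) {
  bases <- c("A", "C", "G", "T")
  a <- sample(bases, n_sites, replace = TRUE)
  b <- a
  mut <- which(runif(n_sites) < sub_prob)
  b[mut] <- vapply(b[mut], function(x) sample(setdiff(bases, x), 1), character(1))
  b_str <- rep("?", n_sites)
  idx <- seq.int(cov_b[1] + 1, cov_b[2])
  b_str[idx] <- b[idx]
  list(a = paste(a, collapse = ""), b = paste(b_str, collapse = ""))
}

# brute-force Procrustes: grid + local search over rotation angle and
# reflection, analytic least-squares scale at each angle
oracle_procrustes_m2 <- function(X, Y) {
  ss_at <- function(theta, reflect) {
    R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
    if (reflect) R <- R %*% diag(c(1, -1))
    YR <- Y %*% R
    cs <- sum(X * YR) / sum(YR^2)
    sum((X - cs * YR)^2)
  }
  best <- Inf
  for (reflect in c(FALSE, TRUE)) {
    grid <- seq(0, 2 * pi, length.out = 721)
    vals <- vapply(grid, ss_at, numeric(1), reflect = reflect)
    i <- which.min(vals)
    lo <- grid[max(i - 1, 1)]; hi <- grid[min(i + 1, length(grid))]
    opt <- stats::optimize(ss_at, c(lo, hi), reflect = reflect,
                           tol = 1e-12)
    best <- min(best, opt$objective)
  }
  best
}

# 2-D rotation matrix
rot2 <- function(theta) {
  matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
}

# random labeled Euclidean distance matrix from points in `k` dimensions
random_euclid_dm <- function(n, k) {
  pts <- matrix(rnorm(n * k), n, k)
  D <- as.matrix(dist(pts))
  dimnames(D) <- list(sprintf("x%02d", 1:n), sprintf("x%02d", 1:n))
  dist_matrix(D)
}
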