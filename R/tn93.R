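NUC_CODE <- c(A = 1L, C = 2L, G = 3L, T = 4L)

# integer-coded view of an alignment: A=1, C=2, G=3, T=4, anything else NA
aln_code_matrix <- function(aln) {
  m <- aln_char_matrix(aln)
  out <- matrix(NUC_CODE[m], nrow = nrow(m), ncol = ncol(m))
  rownames(out) <- rownames(m)
  out
}

pair_stats_codes <- function(xi, xj) {
  ok <- !is.na(xi) & !is.na(xj)
  n <- sum(ok)
  if (n == 0L) return(NULL)
  a <- xi[ok]; b <- xj[ok]
  ts1 <- sum((a == 1L & b == 3L) | (a == 3L & b == 1L))   # A<->G
  ts2 <- sum((a == 2L & b == 4L) | (a == 4L & b == 2L))   # C<->T
  ndiff <- sum(a != b)
  freqs <- tabulate(c(a, b), nbins = 4L) / (2 * n)
  names(freqs) <- names(NUC_CODE)
  structure(list(n = n, P1 = ts1 / n, P2 = ts2 / n,
                 Q = (ndiff - ts1 - ts2) / n, freqs = freqs),
            class = "tn93_pair_stats")
}

#' Site-pattern tallies for a pair of partially overlapping sequences
#'
#' Counts, over the columns where both sequences carry an unambiguous base
#' (`A`, `C`, `G` or `T`), the proportions of the two transition types and of
#' transversions, together with base frequencies pooled over the comparable
#' sites of both sequences. Gaps (`-`), `N` and padding (`?`) are excluded
#' pairwise ("pairwise deletion"), so fragments of different lengths are
#' compared over their shared coverage only. Frequencies are pooled per pair
#' rather than taken from the whole alignment, which keeps the estimate
#' meaningful when fragments cover different regions.
#'
#' @param aln A [partial_alignment].
#' @param a,b Sequence labels (or integer indices) of the pair.
#' @return A `tn93_pair_stats` list: `n` comparable sites, `P1` proportion of
#'   A/G differences, `P2` proportion of C/T differences, `Q` proportion of
#'   transversion differences, and `freqs` (pooled A, C, G, T frequencies).
#' @export
#' @examples
#' aln <- partial_alignment(c(x = "ACGTACGT", y = "ACGTACGC"))
#' tn93_pair_stats(aln, "x", "y")$P2  # one C<->T difference over 8 sites
tn93_pair_stats <- function(aln, a, b) {
  stopifnot(inherits(aln, "partial_alignment"))
  codes <- aln_code_matrix(aln)
  ia <- if (is.character(a)) match(a, aln$labels) else as.integer(a)
  ib <- if (is.character(b)) match(b, aln$labels) else as.integer(b)
  if (is.na(ia) || is.na(ib)) stop_format("unknown sequence label")
  st <- pair_stats_codes(codes[ia, ], codes[ib, ])
  if (is.null(st))
    stop_format("no comparable sites between '%s' and '%s' (disjoint coverage?)",
                aln$labels[ia], aln$labels[ib])
  st
}

#' Tamura-Nei (TN93) distance from site-pattern tallies
#'
#' Evaluates the TN93 maximum-likelihood distance, which distinguishes the
#' two transition types (A/G and C/T) and transversions under unequal base
#' frequencies. With `gR = gA + gG` and `gY = gC + gT`:
#' \deqn{d = -\frac{2 g_A g_G}{g_R}\ln w_1 - \frac{2 g_T g_C}{g_Y}\ln w_2
#'   - 2\left(g_R g_Y - \frac{g_A g_G g_Y}{g_R} - \frac{g_T g_C g_R}{g_Y}\right)\ln w_3}
#' where \eqn{w_1 = 1 - g_R P_1/(2 g_A g_G) - Q/(2 g_R)},
#' \eqn{w_2 = 1 - g_Y P_2/(2 g_T g_C) - Q/(2 g_Y)} and
#' \eqn{w_3 = 1 - Q/(2 g_R g_Y)}.
#'
#' Saturated pairs (any logarithm argument non-positive) and degenerate
#' frequency configurations yield `NA` with a warning by default, so a full
#' distance matrix remains computable; downstream steps that need a complete
#' matrix fail loudly if `NA`s remain.
#'
#' @param stats A `tn93_pair_stats` object from [tn93_pair_stats()].
#' @param on_saturation `"missing"` (default) returns `NA` with a warning;
#'   `"error"` stops.
#' @return Distance in substitutions/site (non-negative), or `NA`.
#' @export
tn93_distance <- function(stats, on_saturation = c("missing", "error")) {
  on_saturation <- match.arg(on_saturation)
  stopifnot(inherits(stats, "tn93_pair_stats"))
  f <- stats$freqs
  gA <- f[["A"]]; gC <- f[["C"]]; gG <- f[["G"]]; gT <- f[["T"]]
  gR <- gA + gG; gY <- gC + gT
  P1 <- stats$P1; P2 <- stats$P2; Q <- stats$Q

  fail <- function(msg) {
    if (on_saturation == "error") stop_format("TN93 undefined: %s", msg)
    warning(sprintf("TN93 undefined (%s); returning NA", msg), call. = FALSE)
    NA_real_
  }

  # a term vanishes when its difference proportions are zero, even if the
  # corresponding frequency product is zero
  if ((gA * gG == 0 && P1 > 0) || (gT * gC == 0 && P2 > 0) ||
      (gR * gY == 0 && Q > 0))
    return(fail("a required base-frequency product is zero"))

  t1 <- if (gA * gG == 0) 0 else {
    w1 <- 1 - gR * P1 / (2 * gA * gG) - Q / (2 * gR)
    if (w1 <= 0) return(fail(sprintf("saturation in A/G term (arg=%g)", w1)))
    -(2 * gA * gG / gR) * log(w1)
  }
  t2 <- if (gT * gC == 0) 0 else {
    w2 <- 1 - gY * P2 / (2 * gT * gC) - Q / (2 * gY)
    if (w2 <= 0) return(fail(sprintf("saturation in C/T term (arg=%g)", w2)))
    -(2 * gT * gC / gY) * log(w2)
  }
  t3 <- if (gR * gY == 0) 0 else {
    w3 <- 1 - Q / (2 * gR * gY)
    if (w3 <= 0) return(fail(sprintf("saturation in transversion term (arg=%g)", w3)))
    k3 <- 2 * (gR * gY - gA * gG * gY / gR - gT * gC * gR / gY)
    -k3 * log(w3)
  }
  d <- t1 + t2 + t3
  max(d, 0)
}

#' TN93 distance matrix of a partial alignment
#'
#' Computes all pairwise TN93 distances under pairwise deletion (see
#' [tn93_pair_stats()]). Pairs with no comparable sites, or saturated pairs,
#' become `NA` with a warning unless `strict = TRUE`, in which case they are
#' an error naming the pair.
#'
#' @param aln A [partial_alignment] with at least two sequences.
#' @param strict If `TRUE`, any undefined pair aborts the computation.
#' @return A [dist_matrix] (substitutions/site).
#' @export
tn93_matrix <- function(aln, strict = FALSE) {
  stopifnot(inherits(aln, "partial_alignment"))
  n <- length(aln$labels)
  if (n < 2L) stop_format("need at least 2 sequences, got %d", n)
  codes <- aln_code_matrix(aln)
  d <- matrix(0, n, n, dimnames = list(aln$labels, aln$labels))
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      st <- pair_stats_codes(codes[i, ], codes[j, ])
      if (is.null(st)) {
        if (strict)
          stop_format("no comparable sites between '%s' and '%s'",
                      aln$labels[i], aln$labels[j])
        warning(sprintf("no comparable sites between '%s' and '%s'; NA",
                        aln$labels[i], aln$labels[j]), call. = FALSE)
        dij <- NA_real_
      } else {
        dij <- tn93_distance(st, on_saturation = if (strict) "error" else "missing")
      }
      d[i, j] <- d[j, i] <- dij
    }
  }
  dist_matrix(d)
}
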