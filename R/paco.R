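#' Principal coordinates analysis of a distance matrix
#'
#' Classical metric scaling: the squared distances are double-centered
#' (Gower transformation, \eqn{-\tfrac12 J D^{(2)} J} with
#' \eqn{J = I - \mathbf{1}\mathbf{1}^\top/n}) and eigendecomposed. Axes with
#' eigenvalue greater than `tolerance * max(eigenvalue)` are retained and
#' scaled by the square root of their eigenvalue, so Euclidean distances
#' among the returned coordinates reproduce the input distances whenever the
#' input is Euclidean. Negative eigenvalues (non-Euclidean input) are
#' dropped by default; `correction = "cailliez"` instead adds the smallest
#' constant to all off-diagonal distances that makes the matrix Euclidean.
#'
#' @param d A [dist_matrix] (complete: no `NA` entries).
#' @param tolerance Relative eigenvalue threshold for axis retention.
#' @param correction `"none"` (drop negative eigenvalues) or `"cailliez"`.
#' @return A `pcoa_result`: list with `labels`, `coordinates` (rows =
#'   labels, columns = retained axes), `eigenvalues` (all, descending) and
#'   `correction`.
#' @export
pcoa <- function(d, tolerance = 1e-8, correction = c("none", "cailliez")) {
  correction <- match.arg(correction)
  stopifnot(inherits(d, "dist_matrix"))
  if (anyNA(d))
    stop_format("distance matrix has %d missing entr%s; ordination needs a complete matrix",
                sum(is.na(d)) / 2, if (sum(is.na(d)) / 2 == 1) "y" else "ies")
  dm <- unclass(d)
  if (correction == "cailliez") {
    cc <- cailliez_constant(dm)
    if (cc > 0) {
      dm <- dm + cc
      diag(dm) <- 0
    }
  }
  n <- nrow(dm)
  B <- gower_center(dm^2)
  e <- eigen(B, symmetric = TRUE)
  emax <- max(e$values)
  if (emax <= 0)
    stop_format("degenerate distance matrix: no positive eigenvalue (all points coincide?)")
  keep <- which(e$values > tolerance * emax)
  coords <- e$vectors[, keep, drop = FALSE] %*%
    diag(sqrt(e$values[keep]), nrow = length(keep))
  rownames(coords) <- rownames(dm)
  colnames(coords) <- paste0("Axis", seq_along(keep))
  structure(list(labels = rownames(dm), coordinates = coords,
                 eigenvalues = e$values, correction = correction),
            class = "pcoa_result")
}

gower_center <- function(d2) {
  n <- nrow(d2)
  A <- -0.5 * d2
  rm_ <- rowMeans(A)
  A - outer(rm_, rep(1, n)) - outer(rep(1, n), rm_) + mean(A)
}

# smallest additive constant making a distance matrix Euclidean
cailliez_constant <- function(dm) {
  n <- nrow(dm)
  d1 <- gower_center(dm^2)
  d2 <- gower_center(dm)
  M <- rbind(cbind(matrix(0, n, n), 2 * d1),
             cbind(-diag(n), -4 * d2))
  ev <- eigen(M, only.values = TRUE)$values
  max(Re(ev[abs(Im(ev)) < 1e-8]), 0)
}

#' Host-parasite association data with ambiguity alternatives
#'
#' Builds the bipartite association structure a co-phylogeny test consumes:
#' the host and parasite label sets and one or more alternative link lists.
#' When built from an infection table containing ambiguous observations
#' (short fragments compatible with several haplogroups), one alternative is
#' generated per combination of candidate choices — the paper-style "one
#' binary matrix for each hypothesis" — and downstream analysis reports the
#' most conservative (largest-P) alternative.
#'
#' @param infections An `infection_table` (see [read_infection_table()]), or
#'   a plain data frame with columns `host` and `parasite` describing an
#'   unambiguous link list.
#' @param max_alternatives Refuse to enumerate more than this many
#'   alternatives (default 64); reduce ambiguity manually beyond that.
#' @return An `association_data`: list with `hosts`, `parasites` (unions
#'   over alternatives), `alternatives` (list of data frames with columns
#'   `host`, `parasite`) and `n_ambiguous`.
#' @export
association_data <- function(infections, max_alternatives = 64L) {
  if (inherits(infections, "infection_table")) {
    cand <- infections$candidates
    n_alt <- prod(lengths(cand))
    if (n_alt > max_alternatives)
      stop_format("%d ambiguity alternatives exceed the cap of %d; reduce ambiguous observations manually",
                  n_alt, max_alternatives)
    choice_grid <- expand.grid(lapply(cand, seq_along))
    alternatives <- lapply(seq_len(nrow(choice_grid)), function(a) {
      picks <- vapply(seq_along(cand),
                      function(i) cand[[i]][[choice_grid[a, i]]], character(1))
      links <- unique(data.frame(host = infections$host, parasite = picks,
                                 stringsAsFactors = FALSE))
      rownames(links) <- NULL
      links
    })
    n_amb <- n_ambiguous(infections)
  } else {
    links <- as.data.frame(infections)
    if (!all(c("host", "parasite") %in% names(links)))
      stop_format("link data frame needs columns `host` and `parasite`")
    links <- unique(data.frame(host = as.character(links$host),
                               parasite = as.character(links$parasite),
                               stringsAsFactors = FALSE))
    alternatives <- list(links)
    n_amb <- 0L
  }
  for (alt in alternatives)
    if (nrow(alt) < 3L)
      stop_format("an alternative has only %d link(s); at least 3 are required",
                  nrow(alt))
  structure(list(
    hosts = sort(unique(unlist(lapply(alternatives, `[[`, "host")))),
    parasites = sort(unique(unlist(lapply(alternatives, `[[`, "parasite")))),
    alternatives = alternatives,
    n_ambiguous = n_amb
  ), class = "association_data")
}

#' Expand PCoA coordinates over association links
#'
#' Builds the paired configuration matrices of the Procrustean co-phylogeny
#' test: row \eqn{\ell} of `X` holds the PCoA coordinates of the host of
#' link \eqn{\ell}, row \eqn{\ell} of `Y` those of its parasite, so a host
#' (or parasite) participating in several links contributes one duplicated
#' row per link. The narrower matrix is zero-padded to the common number of
#' axes and both matrices are then column-centered.
#'
#' @param x,y `pcoa_result` objects for hosts and parasites.
#' @param links Data frame with columns `host`, `parasite` whose labels all
#'   occur in `x` and `y` respectively.
#' @return List with centered matrices `X` and `Y` (both L x k).
#' @export
link_expand <- function(x, y, links) {
  stopifnot(inherits(x, "pcoa_result"), inherits(y, "pcoa_result"))
  hi <- match(links$host, x$labels)
  pi_ <- match(links$parasite, y$labels)
  if (anyNA(hi))
    stop_format("host label(s) not in the host ordination: %s",
                paste(unique(links$host[is.na(hi)]), collapse = ", "))
  if (anyNA(pi_))
    stop_format("parasite label(s) not in the parasite ordination: %s",
                paste(unique(links$parasite[is.na(pi_)]), collapse = ", "))
  X <- x$coordinates[hi, , drop = FALSE]
  Y <- y$coordinates[pi_, , drop = FALSE]
  k <- max(ncol(X), ncol(Y))
  pad <- function(m) {
    if (ncol(m) < k) cbind(m, matrix(0, nrow(m), k - ncol(m))) else m
  }
  X <- scale(pad(X), center = TRUE, scale = FALSE)
  Y <- scale(pad(Y), center = TRUE, scale = FALSE)
  attr(X, "scaled:center") <- NULL
  attr(Y, "scaled:center") <- NULL
  rownames(X) <- rownames(Y) <- paste(links$host, links$parasite, sep = "--")
  list(X = X, Y = Y)
}

#' Procrustes superimposition residuals
#'
#' Least-squares fit of the parasite configuration `Y` onto the host
#' configuration `X` allowing rotation/reflection and uniform scaling: with
#' the SVD \eqn{Y^\top X = U \Sigma V^\top}, the rotation is
#' \eqn{R = U V^\top} and the scale \eqn{c = \mathrm{tr}(\Sigma) /
#' \mathrm{tr}(Y^\top Y)}. The global statistic is the residual sum of
#' squares \eqn{m^2_{XY} = \mathrm{tr}(X^\top X) - \mathrm{tr}(\Sigma)^2 /
#' \mathrm{tr}(Y^\top Y)}, which equals the sum of the per-link squared
#' residuals \eqn{\lVert X_\ell - c Y_\ell R\rVert^2}. Smaller values mean
#' greater host-parasite congruence.
#'
#' @param X,Y Column-centered numeric matrices of equal dimension (links x
#'   axes), as returned by [link_expand()].
#' @return List with `m2`, `residuals` (per-link squared residuals, summing
#'   to `m2`), `rotation` and `scale`.
#' @export
procrustes_m2 <- function(X, Y) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (!all(dim(X) == dim(Y)))
    stop_format("X (%dx%d) and Y (%dx%d) must have equal shape",
                nrow(X), ncol(X), nrow(Y), ncol(Y))
  traceY <- sum(Y^2)
  if (traceY == 0) stop_format("Y is all zeros; Procrustes scale is undefined")
  sv <- svd(crossprod(Y, X))
  R <- sv$u %*% t(sv$v)
  cs <- sum(sv$d) / traceY
  fitted <- cs * Y %*% R
  res <- rowSums((X - fitted)^2)
  m2 <- sum(X^2) - sum(sv$d)^2 / traceY
  # the trace identity and the residual sum are the same quantity; keep the
  # residual-sum value so the per-link decomposition is exact
  stopifnot(abs(m2 - sum(res)) <= 1e-9 * max(1, sum(res)))
  list(m2 = sum(res), residuals = res, rotation = R, scale = cs)
}

# fast m2 for the permutation loop: Y fixed and centered, X built by row
# selection from the host coordinate matrix then centered
m2_for_hosts <- function(H, hidx, Yc, traceY) {
  Xs <- H[hidx, , drop = FALSE]
  Xs <- Xs - rep(colMeans(Xs), each = nrow(Xs))
  sv <- svd(crossprod(Yc, Xs), nu = 0, nv = 0)$d
  sum(Xs^2) - sum(sv)^2 / traceY
}

#' Procrustean co-phylogeny test (global fit and permutation significance)
#'
#' Tests whether host-parasite association links are more congruent than
#' expected at random. Both distance matrices are ordinated once by
#' [pcoa()]; coordinates are expanded over the links ([link_expand()]); the
#' observed goodness-of-fit \eqn{m^2_{XY}} comes from [procrustes_m2()].
#' The null distribution reassigns hosts randomly to parasites: each
#' permutation applies a uniform random permutation to the host components
#' of the link list (parasite components fixed, so the per-parasite link
#' multiset is preserved), rebuilds the host configuration and recomputes
#' \eqn{m^2}. The P value is \eqn{(1 + \#\{m^2_{perm} \le m^2_{obs}\}) /
#' (n_{perm} + 1)}; ties count toward the numerator, so P is never 0.
#'
#' @param dh,dp [dist_matrix] of hosts and of parasites (complete).
#' @param links Data frame with columns `host`, `parasite` (L >= 3 links),
#'   or an [association_data] with a single alternative.
#' @param n_perm Number of permutations (>= 99 unless `force = TRUE`).
#' @param seed Integer seed for the permutation stream (reproducibility).
#' @param jackknife If `TRUE` (default), per-link jackknife estimates and
#'   upper 95% confidence bounds are included (see [jackknife_links()]).
#' @param tolerance,correction Passed to [pcoa()].
#' @param force Allow `n_perm < 99`.
#' @return A `paco_result`: list with `m2`, `p_value`, `n_perm`, `seed` and
#'   `link_residuals` (data frame: host, parasite, observed squared
#'   residual, jackknife estimate, upper 95% CI).
#' @export
paco_test <- function(dh, dp, links, n_perm = 999L, seed = NULL,
                      jackknife = TRUE, tolerance = 1e-8,
                      correction = "none", force = FALSE) {
  links <- normalize_links(links)
  L <- nrow(links)
  if (L < 3L) stop_format("need at least 3 links, got %d", L)
  n_perm <- as.integer(n_perm)
  if (n_perm < 99L && !force)
    stop_format("n_perm = %d gives too little resolution (minimum 99); use force = TRUE to override",
                n_perm)
  px <- pcoa(dh, tolerance = tolerance, correction = correction)
  py <- pcoa(dp, tolerance = tolerance, correction = correction)
  xy <- link_expand(px, py, links)
  obs <- procrustes_m2(xy$X, xy$Y)

  # pre-padded host coordinate matrix so the loop only selects rows
  k <- ncol(xy$X)
  H <- px$coordinates
  if (ncol(H) < k) H <- cbind(H, matrix(0, nrow(H), k - ncol(H)))
  hidx <- match(links$host, px$labels)
  traceY <- sum(xy$Y^2)
  tie_eps <- 1e-12 * max(1, obs$m2)

  n_le <- with_seed(seed, {
    count <- 0L
    for (b in seq_len(n_perm)) {
      m2b <- m2_for_hosts(H, hidx[sample.int(L)], xy$Y, traceY)
      if (m2b <= obs$m2 + tie_eps) count <- count + 1L
    }
    count
  })
  p <- (1 + n_le) / (n_perm + 1)

  lr <- data.frame(host = links$host, parasite = links$parasite,
                   residual_sq = unname(obs$residuals),
                   stringsAsFactors = FALSE)
  if (jackknife && L >= 4L) {
    jk <- jackknife_core(xy$X, xy$Y, obs$residuals)
    lr$jackknife_est <- jk$estimate
    lr$jackknife_upper <- jk$upper
  } else if (jackknife) {
    warning("jackknife needs at least 4 links; reporting observed residuals only",
            call. = FALSE)
  }
  structure(list(m2 = obs$m2, p_value = p, n_perm = n_perm,
                 seed = seed, link_residuals = lr,
                 permutation_scheme = "host components permuted across links"),
            class = "paco_result")
}

normalize_links <- function(links) {
  if (inherits(links, "association_data")) {
    if (length(links$alternatives) != 1L)
      stop_format("association data has %d alternatives; use conservative_paco()",
                  length(links$alternatives))
    links <- links$alternatives[[1L]]
  }
  links <- as.data.frame(links)
  if (!all(c("host", "parasite") %in% names(links)))
    stop_format("links need columns `host` and `parasite`")
  links
}

#' @export
print.paco_result <- function(x, ...) {
  cat(sprintf("Procrustean co-phylogeny test: m2 = %.6g, P = %.3g (%d permutations)\n",
              x$m2, x$p_value, x$n_perm))
  invisible(x)
}

# leave-one-link-out jackknife on expanded configurations
jackknife_core <- function(X, Y, res_full) {
  L <- nrow(X)
  if (L < 4L) stop_format("jackknife needs at least 4 links, got %d", L)
  # pseudovalue matrix: nu[i, j] for deletion j, link i (i != j)
  nu <- matrix(NA_real_, L, L)
  for (j in seq_len(L)) {
    Xj <- X[-j, , drop = FALSE]; Yj <- Y[-j, , drop = FALSE]
    Xj <- Xj - rep(colMeans(Xj), each = L - 1L)
    Yj <- Yj - rep(colMeans(Yj), each = L - 1L)
    fit <- procrustes_m2(Xj, Yj)
    nu[seq_len(L)[-j], j] <- L * res_full[-j] - (L - 1L) * fit$residuals
  }
  est_raw <- rowMeans(nu, na.rm = TRUE)
  se <- apply(nu, 1L, stats::sd, na.rm = TRUE) / sqrt(L - 1L)
  est <- pmax(est_raw, 0)
  tcrit <- stats::qt(0.95, df = L - 2L)
  list(estimate = est, upper = est + tcrit * se)
}

#' Jackknife estimates of per-link squared residuals
#'
#' Assesses the contribution of each host-parasite link to the global fit by
#' a leave-one-link-out jackknife: for each deleted link, the configurations
#' are rebuilt (the ordination is not recomputed — permissible because links,
#' not distances, are resampled) and the Procrustes fit repeated. Each
#' remaining link's pseudovalue is \eqn{\nu_{ij} = L r^2_i - (L-1)
#' r^2_{i(-j)}}; a link's estimate is the mean of its pseudovalues over all
#' deletions (truncated below at 0, squared residuals being non-negative),
#' with a one-sided upper 95% bound `estimate + t(0.95, L-2) * SE`. Links
#' with small estimates support the co-phylogenetic signal; links created by
#' host shifts stand out with large ones.
#'
#' @inheritParams paco_test
#' @param tolerance,correction Passed to [pcoa()].
#' @return Data frame: `host`, `parasite`, `residual_sq` (observed),
#'   `jackknife_est`, `jackknife_upper`.
#' @export
jackknife_links <- function(dh, dp, links, tolerance = 1e-8,
                            correction = "none") {
  links <- normalize_links(links)
  if (nrow(links) < 4L)
    stop_format("jackknife needs at least 4 links, got %d", nrow(links))
  px <- pcoa(dh, tolerance = tolerance, correction = correction)
  py <- pcoa(dp, tolerance = tolerance, correction = correction)
  xy <- link_expand(px, py, links)
  obs <- procrustes_m2(xy$X, xy$Y)
  jk <- jackknife_core(xy$X, xy$Y, obs$residuals)
  data.frame(host = links$host, parasite = links$parasite,
             residual_sq = unname(obs$residuals),
             jackknife_est = jk$estimate, jackknife_upper = jk$upper,
             stringsAsFactors = FALSE)
}

#' Conservative co-phylogeny test over ambiguity alternatives
#'
#' Runs [paco_test()] once per alternative association matrix (one per
#' combination of candidate haplogroups of the ambiguous observations) and
#' reports the alternative with the largest P value — the most conservative
#' reading of an ambiguous dataset. Each alternative uses a seed offset
#' deterministically from `seed` by its index, so the whole analysis is
#' reproducible from one integer.
#'
#' @param dh,dp [dist_matrix] of hosts and parasites.
#' @param assoc An [association_data] (possibly with several alternatives).
#' @param n_perm,seed,jackknife,tolerance,correction,force As in
#'   [paco_test()].
#' @return List with `selected` (the max-P `paco_result`), `selected_index`,
#'   and `alternatives` (all `paco_result`s, in enumeration order).
#' @export
conservative_paco <- function(dh, dp, assoc, n_perm = 999L, seed = NULL,
                              jackknife = TRUE, tolerance = 1e-8,
                              correction = "none", force = FALSE) {
  stopifnot(inherits(assoc, "association_data"))
  results <- lapply(seq_along(assoc$alternatives), function(i) {
    paco_test(dh, dp, assoc$alternatives[[i]], n_perm = n_perm,
              seed = if (is.null(seed)) NULL else seed + (i - 1L),
              jackknife = jackknife, tolerance = tolerance,
              correction = correction, force = force)
  })
  ps <- vapply(results, `[[`, numeric(1), "p_value")
  sel <- which.max(ps)
  list(selected = results[[sel]], selected_index = sel,
       alternatives = results)
}
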