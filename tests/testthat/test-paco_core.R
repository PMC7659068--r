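test_that("principal coordinates recover Euclidean configurations", {
  # 4 points on a line
  D <- as.matrix(dist(matrix(0:3, 4, 1)))
  dimnames(D) <- list(letters[1:4], letters[1:4])
  p <- pcoa(dist_matrix(D))
  expect_equal(ncol(p$coordinates), 1)
  gaps <- abs(diff(sort(p$coordinates[, 1])))
  expect_equal(unname(gaps), rep(1, 3), tolerance = 1e-10)

  set.seed(2)
  for (k in 2:3) {
    d <- random_euclid_dm(12, k)
    p <- pcoa(d)
    expect_lt(max(abs(as.matrix(dist(p$coordinates)) - unclass(d))), 1e-8)
  }
})

test_that("degenerate and incomplete distance matrices are refused", {
  z <- dist_matrix(matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3])))
  expect_error(pcoa(z), "degenerate")
  d <- random_euclid_dm(5, 2)
  d[1, 2] <- d[2, 1] <- NA
  expect_error(pcoa(d), "missing")
})

test_that("Cailliez correction makes a non-Euclidean matrix embeddable", {
  # violates the four-point condition (a near-tree metric with distortion)
  m <- matrix(c(0, 2, 2, 3.9,
                2, 0, 3.9, 2,
                2, 3.9, 0, 2,
                3.9, 2, 2, 0), 4, 4,
              dimnames = list(letters[1:4], letters[1:4]))
  d <- dist_matrix(m)
  ev <- eigen(procophy:::gower_center(unclass(d)^2), symmetric = TRUE)$values
  expect_lt(min(ev), -1e-8)  # construction must actually be non-Euclidean
  p <- pcoa(d, correction = "cailliez")
  cc <- procophy:::cailliez_constant(unclass(d))
  target <- unclass(d) + cc; diag(target) <- 0
  expect_lt(max(abs(as.matrix(dist(p$coordinates)) - target)), 1e-6)
})

test_that("link expansion duplicates rows, pads axes and centers columns", {
  px <- structure(list(labels = c("h1", "h2"),
                       coordinates = matrix(c(1, 2, 3, 4, 5, 6), 2, 3)),
                  class = "pcoa_result")
  py <- structure(list(labels = c("p1", "p2", "p3"),
                       coordinates = matrix(c(1, 2, 3, 4, 5, 6), 3, 2)),
                  class = "pcoa_result")
  links <- data.frame(host = c("h1", "h1", "h2"),
                      parasite = c("p1", "p2", "p3"))
  xy <- link_expand(px, py, links)
  expect_equal(dim(xy$X), c(3, 3))
  expect_equal(dim(xy$Y), c(3, 3))          # padded from 2 to 3 axes
  expect_equal(xy$X[1, ], xy$X[2, ])        # h1 duplicated
  expect_lt(max(abs(colMeans(xy$X))), 1e-12)
  expect_lt(max(abs(colMeans(xy$Y))), 1e-12)
  # padding column is constant zero after centering
  expect_true(all(xy$Y[, 3] == 0))

  bad <- data.frame(host = "h9", parasite = c("p1", "p2", "p3"))
  expect_error(link_expand(px, py, bad), "h9")
})

test_that("Procrustes m2 vanishes under rotation and scaling", {
  set.seed(4)
  X <- scale(matrix(rnorm(12), 6, 2), scale = FALSE)
  expect_lt(procrustes_m2(X, X)$m2, 1e-12)
  for (theta in c(0.3, 2.2, 4.8)) {
    Y <- 0.37 * X %*% rot2(theta)
    expect_lt(procrustes_m2(X, Y)$m2, 1e-9)
  }
  expect_error(procrustes_m2(X, X * 0), "all zeros")
  expect_error(procrustes_m2(X, X[1:3, ]), "equal shape")
})

test_that("Procrustes m2 matches brute-force minimisation and vegan", {
  set.seed(9)
  for (rep in 1:10) {
    X <- scale(matrix(rnorm(12), 6, 2), scale = FALSE)
    Y <- scale(matrix(rnorm(12), 6, 2), scale = FALSE)
    fit <- procrustes_m2(X, Y)
    expect_lt(abs(fit$m2 - oracle_procrustes_m2(X, Y)), 1e-6)
    expect_equal(fit$m2, sum(fit$residuals), tolerance = 1e-9)
    if (requireNamespace("vegan", quietly = TRUE)) {
      v <- vegan::procrustes(X, Y, scale = TRUE, symmetric = FALSE)
      expect_equal(fit$m2, v$ss, tolerance = 1e-10)
    }
  }
})

test_that("congruent histories give small P and the null keeps P honest", {
  set.seed(6)
  d <- random_euclid_dm(16, 3)
  links <- data.frame(host = rownames(d), parasite = rownames(d))
  r <- paco_test(d, d, links, n_perm = 999, seed = 1, jackknife = FALSE)
  expect_lte(r$p_value, 0.01)
  expect_gte(r$p_value, 1 / 1000)
  expect_equal(r$m2, sum(r$link_residuals$residual_sq), tolerance = 1e-9)
})

test_that("the permutation test is deterministic under a seed", {
  sc <- simulate_scenario(n_tips = 8, n_shifts = 1, seed = 33)
  dh <- tn93_matrix(sc$host_aln); dp <- tn93_matrix(sc$parasite_aln)
  r1 <- paco_test(dh, dp, sc$true_links, n_perm = 199, seed = 5)
  r2 <- paco_test(dh, dp, sc$true_links, n_perm = 199, seed = 5)
  expect_identical(r1$p_value, r2$p_value)
  expect_identical(r1$m2, r2$m2)
  expect_identical(r1$link_residuals, r2$link_residuals)
  expect_error(paco_test(dh, dp, sc$true_links, n_perm = 50), "resolution")
  r3 <- paco_test(dh, dp, sc$true_links, n_perm = 50, seed = 1, force = TRUE,
                  jackknife = FALSE)
  expect_gte(r3$p_value, 1 / 51)
})

test_that("m2 is invariant to host/parasite relabeling", {
  sc <- simulate_scenario(n_tips = 8, n_shifts = 2, seed = 17)
  dh <- tn93_matrix(sc$host_aln); dp <- tn93_matrix(sc$parasite_aln)
  r <- paco_test(dh, dp, sc$true_links, n_perm = 99, seed = 1, jackknife = FALSE)
  perm <- sample(8)
  dh2 <- dist_matrix(unclass(dh)[perm, perm])
  links2 <- sc$true_links[rev(seq_len(8)), ]
  r2 <- paco_test(dh2, dp, links2, n_perm = 99, seed = 1, jackknife = FALSE)
  expect_equal(r2$m2, r$m2, tolerance = 1e-9)
})

test_that("P values from different permutation counts agree within MC error", {
  sc <- simulate_scenario(n_tips = 10, n_shifts = 3, seed = 23)
  dh <- tn93_matrix(sc$host_aln); dp <- tn93_matrix(sc$parasite_aln)
  p1 <- paco_test(dh, dp, sc$true_links, n_perm = 199, seed = 2,
                  jackknife = FALSE)$p_value
  p2 <- paco_test(dh, dp, sc$true_links, n_perm = 1999, seed = 3,
                  jackknife = FALSE)$p_value
  se <- sqrt(p2 * (1 - p2) / 199)
  expect_lt(abs(p1 - p2), 3 * se + 1e-12)
})

test_that("jackknife residuals are near zero for congruent data and flag a planted shift", {
  set.seed(8)
  d <- random_euclid_dm(10, 2)
  links <- data.frame(host = rownames(d), parasite = rownames(d))
  jk <- jackknife_links(d, d, links)
  expect_lt(max(jk$jackknife_est), 1e-10)
  expect_error(jackknife_links(d, d, links[1:3, ]), "at least 4")

  sc <- simulate_scenario(n_tips = 12, n_shifts = 1, seed = 51)
  dh <- tn93_matrix(sc$host_aln); dp <- tn93_matrix(sc$parasite_aln)
  jk <- jackknife_links(dh, dp, sc$true_links)
  expect_equal(jk$parasite[which.max(jk$jackknife_est)], sc$shifted)
  expect_true(all(jk$jackknife_upper >= jk$jackknife_est))
})

test_that("jackknife estimates rank consistently with observed residuals", {
  rhos <- vapply(1:5, function(s) {
    sc <- simulate_scenario(n_tips = 12, n_shifts = 4, seed = 60 + s)
    dh <- tn93_matrix(sc$host_aln); dp <- tn93_matrix(sc$parasite_aln)
    jk <- jackknife_links(dh, dp, sc$true_links)
    cor(jk$residual_sq, jk$jackknife_est, method = "spearman")
  }, numeric(1))
  expect_true(all(rhos > 0.8))
})

test_that("ambiguity alternatives are enumerated and the max-P one selected", {
  tab <- infection_table(data.frame(
    observation = c("o1", "o2", "o3", "o4", "o5"),
    host = c("h1", "h2", "h3", "h4", "h4"),
    candidates = c("pa|pb", "pb|pc", "pa", "pc", "pd")))
  assoc <- association_data(tab)
  expect_length(assoc$alternatives, 4)
  expect_equal(assoc$n_ambiguous, 2L)
  expect_error(association_data(tab, max_alternatives = 3), "cap")

  sc <- simulate_scenario(n_tips = 8, seed = 3)
  dh <- tn93_matrix(sc$host_aln); dp <- tn93_matrix(sc$parasite_aln)
  # unambiguous table: conservative run equals the single run
  assoc1 <- association_data(sc$true_links)
  cons <- conservative_paco(dh, dp, assoc1, n_perm = 199, seed = 4)
  single <- paco_test(dh, dp, sc$true_links, n_perm = 199, seed = 4)
  expect_identical(cons$selected$p_value, single$p_value)
  expect_length(cons$alternatives, 1)

  # ambiguous: selected P is the maximum over alternatives
  tab2 <- infection_table(data.frame(
    observation = sprintf("o%d", 1:8),
    host = sc$true_links$host,
    candidates = c(paste(sc$true_links$parasite[1], sc$true_links$parasite[2],
                         sep = "|"),
                   sc$true_links$parasite[2:8])))
  assoc2 <- association_data(tab2)
  expect_length(assoc2$alternatives, 2)
  cons2 <- conservative_paco(dh, dp, assoc2, n_perm = 199, seed = 9,
                             jackknife = FALSE)
  ps <- vapply(cons2$alternatives, `[[`, numeric(1), "p_value")
  expect_equal(cons2$selected$p_value, max(ps))
  expect_equal(cons2$selected_index, which.max(ps))
})

test_that("links must cover at least three associations", {
  expect_error(association_data(data.frame(host = c("a", "b"),
                                           parasite = c("x", "y"))),
               "at least 3")
})
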