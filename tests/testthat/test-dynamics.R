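days6 <- c(165L, 181L, 193L, 208L, 243L, 271L)

test_that("peak profiles use a strict above-mean rule", {
  p <- peak_profile(c(0, 0, 0, 0, 10, 0), days6)
  expect_equal(which(p$above_mean), 5L)
  expect_false(any(peak_profile(rep(4, 6), days6)$above_mean))
  p2 <- peak_profile(c(5, 5, 5, 5, 5, 6), days6)
  expect_equal(which(p2$above_mean), 6L)
  expect_error(peak_profile(c(NA, NA, NA, NA, NA, 3), days6), "two")
})

test_that("typology examples classify as expected", {
  lab <- function(pattern) classify_peak(list(days = days6,
                                              above_mean = pattern))
  expect_equal(lab(days6 == 243), "single3")
  expect_equal(lab(days6 %in% c(165, 271)), "single4")
  expect_equal(lab(days6 %in% c(165, 181)), "wide1")
  expect_equal(lab(days6 %in% c(165, 208, 271)), "several")
  expect_equal(lab(rep(FALSE, 6)), "flat")
  expect_equal(lab(days6 %in% c(181, 193, 208)), "wide1")
  expect_equal(lab(days6 %in% c(208, 243, 271)), "wide2")
  expect_equal(lab(days6 != 165), "several") # run of 5
})

test_that("all 64 above-mean patterns match the decision-table oracle", {
  for (code in 0:63) {
    pattern <- as.logical(bitwAnd(code, 2^(0:5)) > 0)
    got <- classify_peak(list(days = days6, above_mean = pattern))
    expect_equal(got, peak_label_oracle(pattern),
                 label = paste("pattern", paste(as.integer(pattern),
                                                collapse = "")))
  }
})

test_that("class composition percentages sum to 100 per station", {
  cl <- data.frame(votu_id = paste0("v", 1:10),
                   station = "ZQ",
                   label = c(rep("single3", 4), rep("wide1", 3),
                             rep("several", 2), "flat"))
  comp <- class_composition(cl)
  expect_equal(sum(comp$percent), 100)
  expect_equal(comp$percent[comp$label == "single3"], 40)
  expect_error(class_composition(cl[0, ]), "no classified")
})

test_that("PCA matches a dense eigen-decomposition oracle", {
  set.seed(14)
  ab <- matrix(rexp(50 * 10), 50, 10,
               dimnames = list(paste0("v", 1:50), paste0("s", 1:10)))
  p <- pca_ordination(ab)
  X <- vegan::decostand(t(ab), "hellinger")
  Xc <- scale(X, scale = FALSE)
  ev <- eigen(crossprod(Xc) / (nrow(X) - 1), symmetric = TRUE)$values
  expect_lt(max(abs(p$eig - ev[seq_along(p$eig)])), 1e-8)
  # duplicated samples get identical scores
  ab2 <- cbind(ab, ab)
  colnames(ab2) <- paste0("s", 1:20)
  p2 <- pca_ordination(ab2)
  expect_equal(unname(p2$scores[1, ]), unname(p2$scores[11, ]),
               tolerance = 1e-10)
  # a rank-one community loads entirely on axis 1
  r1 <- outer(runif(20), c(1, 2, 4, 8))
  dimnames(r1) <- list(paste0("v", 1:20), paste0("s", 1:4))
  expect_equal(pca_ordination(r1, transform = "none")$proportion[1], 1,
               tolerance = 1e-12)
  expect_error(pca_ordination(ab[, 1:2]), "3 samples")
})

test_that("CCA matches a from-scratch generalized eigenproblem oracle", {
  set.seed(15)
  Y <- matrix(rpois(12 * 6, 15), 12, 6,
              dimnames = list(paste0("v", 1:12), paste0("s", 1:6)))
  env <- data.frame(a = rnorm(6), b = rnorm(6))
  r <- cca_ordination(Y, env)
  Yt <- t(Y)
  P <- Yt / sum(Yt)
  rw <- rowSums(P)
  cw <- colSums(P)
  Q <- (P - outer(rw, cw)) / sqrt(outer(rw, cw))
  X <- as.matrix(env)
  Xc <- sweep(X, 2, colSums(X * rw) / sum(rw))
  Xs <- Xc * sqrt(rw)
  H <- Xs %*% solve(crossprod(Xs)) %*% t(Xs)
  ev <- svd(H %*% Q)$d^2
  expect_lt(max(abs(r$eig - ev[seq_along(r$eig)])), 1e-8)
  expect_equal(r$total_inertia, sum(Q^2), tolerance = 1e-10)
  expect_true(all(diff(r$eig) <= 1e-12))
  expect_lte(sum(r$proportion), 1 + 1e-12)
  expect_error(cca_ordination(Y, data.frame(a = rep(1, 6))), "constant")
})

test_that("CCA separates a planted gradient from an orthogonal covariate", {
  g <- 1:6
  Y <- rbind(s1 = 2 * g + 1, s2 = 14 - 2 * g, s3 = g + 3, s4 = 10 - g)
  colnames(Y) <- paste0("s", 1:6)
  drives <- cca_ordination(Y, data.frame(x = g))
  expect_gt(drives$proportion[1], 0.9)
  # a covariate orthogonal (under the row weights) to the gradient
  # explains essentially nothing
  ortho <- cca_ordination(Y, data.frame(x = (g - 3.5)^2))
  expect_lt(sum(ortho$proportion), 1e-6)
})

test_that("sample permutation leaves CCA eigenvalues unchanged", {
  set.seed(16)
  Y <- matrix(rpois(15 * 6, 20), 15, 6,
              dimnames = list(paste0("v", 1:15), paste0("s", 1:6)))
  env <- data.frame(a = rnorm(6), b = runif(6))
  perm <- sample(6)
  r1 <- cca_ordination(Y, env)
  r2 <- cca_ordination(Y[, perm], env[perm, ])
  expect_equal(r1$eig, r2$eig, tolerance = 1e-10)
})
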