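test_that("alpha diversity matches closed forms", {
  t <- count_table(matrix(c(10, 10, 10, 10,
                            40, 0, 0, 0,
                            30, 70, 0, 0), nrow = 4,
                          dimnames = list(paste0("F", 1:4),
                                          c("uniform", "single", "two"))))
  a <- suppressWarnings(alpha_diversity(t))
  expect_equal(a["uniform", "richness"], 4L)
  expect_equal(a["uniform", "shannon"], log(4))
  expect_equal(a["uniform", "evenness"], 1)
  expect_equal(a["single", "richness"], 1L)
  expect_equal(a["single", "shannon"], 0)
  expect_equal(a["single", "evenness"], 0)      # undefined at richness 1, flagged 0
  expect_equal(a["two", "shannon"], -0.3 * log(0.3) - 0.7 * log(0.7),
               tolerance = 1e-12)
  expect_warning(alpha_diversity(t), "rarefy")
})

test_that("Shannon is maximal iff uniform and invariant to count rescaling", {
  withr::with_seed(7, {
    for (r in 1:20) {
      n <- sample(3:8, 1)
      x <- as.numeric(rmultinom(1, 500, rep(1 / n, n)))
      x[x == 0] <- 1
      m <- cbind(uneven = x, even = rep(round(mean(x)), n), scaled = 10 * x)
      rownames(m) <- paste0("F", seq_len(n))
      a <- suppressWarnings(alpha_diversity(count_table(m)))
      expect_lte(a["uneven", "shannon"], log(n) + 1e-12)
      expect_equal(a["even", "shannon"], log(n))
      expect_equal(a["scaled", "shannon"], a["uneven", "shannon"])
      expect_equal(a["scaled", "richness"], a["uneven", "richness"])
    }
  })
})

test_that("Bray-Curtis follows the direct formula and stays in [0, 1]", {
  m <- matrix(c(1, 1,
                0, 2,
                3, 0), nrow = 2,
              dimnames = list(c("F1", "F2"), c("x", "y", "z")))
  d <- as.matrix(bray_curtis(count_table(m)))
  expect_equal(d["x", "y"], (1 + 1) / (1 + 3))   # = 0.5
  expect_equal(d["y", "z"], 1)                   # disjoint supports
  expect_equal(unname(diag(d)), rep(0, 3))
  t2 <- toy_table()
  dup <- count_table(cbind(t2$counts, sC = t2$counts[, "sA"]))
  dd <- as.matrix(bray_curtis(dup))
  expect_equal(dd["sA", "sC"], 0)
  expect_true(all(dd >= 0 & dd <= 1))
})

test_that("Bray-Curtis on proportions is invariant to per-sample depth rescaling", {
  withr::with_seed(13, {
    m <- matrix(rpois(30, 20) + 1, nrow = 5,
                dimnames = list(paste0("F", 1:5), paste0("s", 1:6)))
    scaled <- sweep(m, 2, sample(1:5, 6, replace = TRUE), "*")
    d1 <- bray_curtis(count_table(m), use = "proportions")
    d2 <- bray_curtis(count_table(scaled), use = "proportions")
    expect_equal(as.vector(d1), as.vector(d2), tolerance = 1e-12)
  })
})

test_that("classical scaling reproduces Euclidean distances exactly", {
  withr::with_seed(5, {
    pts <- matrix(rnorm(24), ncol = 3)
    rownames(pts) <- paste0("s", 1:8)
    d <- dist(pts)
    ord <- pcoa(d, k = 3)
    expect_equal(as.vector(dist(ord$points)), as.vector(d), tolerance = 1e-8)
    expect_equal(unname(colMeans(ord$points)), rep(0, 3), tolerance = 1e-10)
    expect_true(all(diff(ord$eig) <= 1e-10))     # descending eigenvalues
  })
})

test_that("pcoa recovers collinear geometry and handles duplicates", {
  # 3 points on a line at 0, 1, 2: pairwise distances 1, 1, 2
  m <- matrix(c(0, 1, 1, 0, 2, 1), 3, 2, byrow = TRUE,
              dimnames = list(c("p", "q", "r"), NULL))
  d <- dist(m[, 1])
  ord <- suppressWarnings(pcoa(d, k = 1))
  got <- as.matrix(dist(ord$points[, 1]))
  expect_equal(got["q", "p"], 1, tolerance = 1e-10)
  expect_equal(got["r", "q"], 1, tolerance = 1e-10)
  expect_equal(got["r", "p"], 2, tolerance = 1e-10)
  # duplicated samples land on identical coordinates
  pts <- rbind(a = c(0, 0), b = c(0, 0), c = c(3, 4), d = c(6, 0))
  ord2 <- suppressWarnings(pcoa(dist(pts), k = 2))
  expect_equal(ord2$points["a", ], ord2$points["b", ], tolerance = 1e-10)
  expect_error(pcoa(dist(pts), k = 5), "k must be")
})

test_that("PERMANOVA pseudo-F matches the hand-computed decomposition", {
  # 4 samples, labels AABB: oracle from within/between sums of squared
  # distances (computed from the distance matrix, not from vegan)
  withr::with_seed(3, {
    pts <- matrix(rnorm(8), 4, 2)
    rownames(pts) <- paste0("s", 1:4)
    d <- dist(pts)
    labels <- c("A", "A", "B", "B")
    m2 <- as.matrix(d)^2
    n <- 4; a <- 2
    ss_total <- sum(m2[upper.tri(m2)]) / n
    ss_within <- sum(m2[1, 2] / 2 + m2[3, 4] / 2)
    f_oracle <- ((ss_total - ss_within) / (a - 1)) / (ss_within / (n - a))
    pm <- permanova(d, labels, n_perm = 99, seed = 1)
    expect_equal(pm$pseudo_F, f_oracle, tolerance = 1e-10)
  })
})

test_that("PERMANOVA achieves the minimal p-value under perfect separation", {
  m <- matrix(1, 20, 20); diag(m) <- 0
  m[1:8, 1:8] <- 0; m[9:20, 9:20] <- 0
  rownames(m) <- colnames(m) <- paste0("s", 1:20)
  pm <- permanova(m, rep(c("A", "B"), c(8, 12)), n_perm = 999, seed = 1)
  expect_equal(pm$p_value, 1 / 1000)
  expect_gte(pm$p_value, 1 / (pm$n_permutations + 1))   # attainable floor
  expect_error(permanova(m, rep("A", 20)), "2 groups")
})

test_that("vector fitting recovers exact linear structure", {
  withr::with_seed(9, {
    pts <- matrix(rnorm(40), 20, 2)
    rownames(pts) <- paste0("s", 1:20)
    ord <- suppressWarnings(pcoa(dist(pts), k = 2))
    v <- cbind(ax1 = ord$points[, 1],
               both = ord$points[, 1] + ord$points[, 2],
               flat = rep(1, 20),
               noise = rnorm(20))
    fit <- fit_vectors(ord, v, n_perm = 199, seed = 2)
    r1 <- fit[fit$variable == "ax1", ]
    expect_equal(r1$r_squared, 1, tolerance = 1e-8)
    expect_equal(abs(r1$axis1), 1, tolerance = 1e-6)
    rb <- fit[fit$variable == "both", ]
    expect_equal(rb$r_squared, 1, tolerance = 1e-8)
    expect_equal(unname(rb$axis1^2 + rb$axis2^2), 1, tolerance = 1e-6)
    rf <- fit[fit$variable == "flat", ]
    expect_true(rf$constant)
    expect_equal(rf$r_squared, 0)
    expect_equal(fit$variable[1:2] %in% c("ax1", "both"), c(TRUE, TRUE))
  })
})
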