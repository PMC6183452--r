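test_that("diversity summaries match hand-computed genotype configurations", {
  G <- cbind(hwe = c(0L, 1L, 1L, 2L))
  rownames(G) <- paste0("i", 1:4)
  d <- diversity(G)
  expect_equal(d$loci$p, 0.5)
  expect_equal(d$loci$He, 0.5)
  expect_equal(d$loci$Ho, 0.5)
  expect_equal(d$loci$Fis, 0)
  all_het <- cbind(l1 = rep(1L, 6)); rownames(all_het) <- paste0("i", 1:6)
  expect_equal(diversity(all_het)$loci$Fis, -1)
  inbred <- cbind(l1 = c(0L, 0L, 2L, 2L)); rownames(inbred) <- paste0("i", 1:4)
  d3 <- diversity(inbred)
  expect_equal(d3$loci$Ho, 0)
  expect_equal(d3$loci$Fis, 1)
})

test_that("diversity is invariant to allele relabeling and flags monomorphs", {
  set.seed(21)
  G <- matrix(rbinom(300, 2, 0.3), 15, 20)
  G[, 1] <- 0L  # monomorphic
  rownames(G) <- paste0("i", 1:15)
  expect_message(d1 <- diversity(G), "monomorphic")
  d2 <- suppressMessages(diversity(2L - G))
  expect_equal(d1$summary$He_mean, d2$summary$He_mean)
  expect_equal(d1$summary$Ho_mean, d2$summary$Ho_mean)
  expect_equal(d1$summary$Fis_ratio, d2$summary$Fis_ratio)
  expect_equal(d1$summary$n_monomorphic, 1L)
})

test_that("both inbreeding summaries are reported", {
  set.seed(22)
  G <- matrix(rbinom(4000, 2, 0.2), 20, 200)
  rownames(G) <- paste0("i", 1:20)
  d <- suppressMessages(diversity(G))
  expect_equal(d$summary$Fis_ratio,
               1 - d$summary$Ho_mean / d$summary$He_mean)
  expect_true(is.finite(d$summary$Fis_mean))
})

test_that("LD pruning removes duplicates and spares independent loci", {
  set.seed(31)
  G <- matrix(rbinom(200 * 500, 2, 0.4), 200, 500)
  colnames(G) <- paste0("L", 1:500)
  rownames(G) <- paste0("i", 1:200)
  # duplicated column: exactly one of the two survives
  Gdup <- cbind(G[, 1:50], dup = G[, 7])
  pruned <- ld_prune(Gdup, r2_max = 0.9)
  expect_equal(sum(colnames(pruned) %in% c("L7", "dup")), 1)
  # independent loci: nearly all survive
  expect_gte(ncol(ld_prune(G, r2_max = 0.9)), 475)
  # r2_max = 1 removes only exact linear duplicates
  expect_equal(ncol(ld_prune(G, r2_max = 1)), 500)
  expect_equal(ncol(ld_prune(Gdup, r2_max = 1)), 50)
})

test_that("relatedness recovers parent-offspring and unrelated pairs", {
  set.seed(41)
  L <- 1000
  p <- rep(0.5, L)
  parent <- rbinom(L, 2, p)
  child <- rbinom(L, 1, parent / 2) + rbinom(L, 1, p)
  stranger <- rbinom(L, 2, p)
  G <- rbind(parent = parent, child = child, stranger = stranger)
  G2 <- rbind(G, other = rbinom(L, 2, p))
  rel <- relatedness_ml(G2, freqs = p)
  po <- rel$pairs[rel$pairs$id1 == "parent" & rel$pairs$id2 == "child", ]
  expect_lt(abs(po$r - 0.5), 0.05)
  expect_gt(po$k1, 0.9)
  un <- rel$pairs[rel$pairs$id1 == "parent" & rel$pairs$id2 == "stranger", ]
  expect_lt(un$r, 0.05)
})

test_that("relatedness maximization matches a simplex grid search", {
  set.seed(43)
  n <- 10; L <- 200
  G <- matrix(rbinom(n * L, 2, runif(L, 0.1, 0.9)), n, L, byrow = FALSE)
  rownames(G) <- paste0("i", 1:n)
  rel <- relatedness_ml(G)
  p <- allele_freqs(G)
  picks <- sample(nrow(rel$pairs), 10)
  for (k in picks) {
    i <- match(rel$pairs$id1[k], rownames(G))
    j <- match(rel$pairs$id2[k], rownames(G))
    oracle <- relatedness_grid_oracle(G[i, ], G[j, ], p)
    est <- unlist(rel$pairs[k, c("k0", "k1", "k2")])
    expect_lt(max(abs(oracle - est)), 0.01 + 0.02)  # grid resolution 0.02
  }
})

test_that("a duplicated sample is fully related to itself", {
  set.seed(47)
  G <- matrix(rbinom(10 * 600, 2, runif(600, 0.2, 0.8)), 10, 600)
  rownames(G) <- paste0("i", 1:10)
  G2 <- rbind(G, dup1 = G[1, ])
  rel <- relatedness_ml(G2)
  self <- rel$pairs[rel$pairs$id1 == "i1" & rel$pairs$id2 == "dup1", ]
  expect_gte(self$r, 0.95)
})

test_that("kin filtering keeps the first member and collapses chains", {
  fake <- function(pairs_df) {
    structure(list(pairs = pairs_df, r = NULL), class = "relatedness_matrix")
  }
  empty <- fake(tibble::tibble(id1 = character(0), id2 = character(0),
                               r = numeric(0)))
  kf0 <- kin_filter(empty)
  expect_equal(length(kf0$flagged), 0)
  expect_equal(length(kf0$removed), 0)
  disjoint <- fake(tibble::tibble(
    id1 = c("a", "c", "e", "g"), id2 = c("b", "d", "f", "h"),
    r = rep(0.3, 4)
  ))
  kf1 <- kin_filter(disjoint)
  expect_equal(length(kf1$flagged), 8)
  expect_identical(kf1$removed, c("b", "d", "f", "h"))
  chain <- fake(tibble::tibble(id1 = c("A", "B"), id2 = c("B", "C"),
                               r = c(0.3, 0.3)))
  kf2 <- kin_filter(chain)
  expect_identical(kf2$removed, "B")  # covers both pairs
  # below-threshold pairs are ignored
  weak <- fake(tibble::tibble(id1 = "a", id2 = "b", r = 0.05))
  expect_equal(length(kin_filter(weak)$flagged), 0)
})

test_that("genotypic distance is the squared allele-count difference", {
  G <- rbind(a = rep(0L, 10), b = rep(2L, 10), c = rep(0L, 10))
  D <- genotypic_distance(G)
  expect_equal(D["a", "b"], 40)        # 10 loci x 4
  expect_equal(D["a", "c"], 0)
  G2 <- rbind(a = c(0L, rep(1L, 5)), b = c(1L, rep(1L, 5)))
  expect_equal(genotypic_distance(G2)["a", "b"], 1)
  set.seed(51)
  Gr <- matrix(rbinom(80, 2, 0.5), 8, 10)
  rownames(Gr) <- paste0("i", 1:8)
  Dr <- genotypic_distance(Gr)
  expect_equal(Dr, t(Dr))
  expect_true(all(diag(Dr) == 0))
  per_locus <- outer(Gr[, 1], Gr[, 1], function(a, b) (a - b)^2)
  expect_true(all(per_locus %in% c(0, 1, 4)))
  Gna <- Gr; Gna[1, 1] <- NA
  expect_error(genotypic_distance(Gna), "missing")
})

test_that("PCA separates divergent clusters and not homogeneous samples", {
  set.seed(61)
  L <- 400
  p1 <- runif(L, 0.1, 0.9)
  p2 <- pmin(pmax(p1 + runif(L, -0.4, 0.4), 0.02), 0.98)
  G <- rbind(
    matrix(rbinom(25 * L, 2, rep(p1, each = 25)), 25, L),
    matrix(rbinom(25 * L, 2, rep(p2, each = 25)), 25, L)
  )
  rownames(G) <- paste0("i", 1:50)
  pc <- gen_pca(G)
  grp <- rep(1:2, each = 25)
  sil <- cluster::silhouette(grp, dist(pc$scores$PC1))
  expect_gt(mean(sil[, 3]), 0.8)
  # homogeneous samples: any even split shows no cluster structure
  G0 <- matrix(rbinom(50 * L, 2, rep(p1, each = 50)), 50, L)
  rownames(G0) <- paste0("i", 1:50)
  pc0 <- gen_pca(G0)
  sil0 <- cluster::silhouette(grp, dist(pc0$scores$PC1))
  expect_lt(mean(sil0[, 3]), 0.3)
  expect_gt(pc$var_explained[1] / pc0$var_explained[1], 2)
})

test_that("duplicated samples land on coincident PCA coordinates", {
  set.seed(65)
  G <- matrix(rbinom(12 * 300, 2, 0.4), 12, 300)
  rownames(G) <- paste0("i", 1:12)
  G2 <- rbind(G, dup = G[3, ])
  pc <- gen_pca(G2, scale = FALSE)
  a <- unlist(pc$scores[pc$scores$id == "i3", -1])
  b <- unlist(pc$scores[pc$scores$id == "dup", -1])
  expect_equal(a, b, tolerance = 1e-8)
})

test_that("kin can be excluded from the PCA by id", {
  set.seed(66)
  G <- matrix(rbinom(10 * 200, 2, 0.5), 10, 200)
  rownames(G) <- paste0("i", 1:10)
  pc <- gen_pca(G, drop = c("i1", "i2"))
  expect_equal(nrow(pc$scores), 8)
  expect_false(any(c("i1", "i2") %in% pc$scores$id))
})
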