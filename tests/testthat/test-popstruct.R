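mkrows <- function(p, n = 3000L, kind = "transition") {
  x <- rep(c("A", "C", "G", "T"), length.out = n)
  y <- x
  k <- round(p * n)
  if (k > 0) {
    idx <- seq_len(k)
    y[idx] <- c(A = "G", C = "T", G = "A", T = "C")[x[idx]]
    if (kind == "transversion")
      y[idx] <- c(A = "T", C = "G", G = "C", T = "A")[x[idx]]
  }
  c(paste(x, collapse = ""), paste(y, collapse = ""))
}

test_that("identical rows give zero distance under every model", {
  r <- mkrows(0)
  for (m in c("p", "JC", "K80")) {
    for (a in c(1, 5, Inf)) {
      expect_equal(pairwiseDistance(r[1], r[2],
                                    distanceParams(m, gamma_shape = a)), 0)
    }
  }
})

test_that("JC with alpha = 1 equals p / (1 - 4p/3) to 1e-12", {
  for (p in seq(0, 0.49, by = 0.01)) {
    r <- mkrows(p, n = 10000L)
    pobs <- mean(strsplit(r[1], "")[[1]] != strsplit(r[2], "")[[1]])
    got <- pairwiseDistance(r[1], r[2], distanceParams("JC",
                                                       gamma_shape = 1))
    expect_equal(got, pobs / (1 - 4 * pobs / 3), tolerance = 1e-12)
  }
})

test_that("the gamma correction converges to plain JC as alpha grows", {
  for (p in seq(0.02, 0.2, by = 0.03)) {
    r <- mkrows(p, n = 5000L)
    plain <- pairwiseDistance(r[1], r[2],
                              distanceParams("JC", gamma_shape = Inf))
    hi <- pairwiseDistance(r[1], r[2],
                           distanceParams("JC", gamma_shape = 1e8))
    expect_lt(abs(hi - plain), 1e-9)
    # convergence is O(1/alpha): at alpha = 1e6 the gap is ~1e-8-scale
    mid <- pairwiseDistance(r[1], r[2],
                            distanceParams("JC", gamma_shape = 1e6))
    expect_lt(abs(mid - plain), 1e-7)
    expect_gt(mid, plain)  # monotone decreasing towards the limit
  }
})

test_that("JC-gamma is monotone in p and in 1/alpha; saturation errors", {
  ds <- sapply(seq(0.01, 0.5, by = 0.02), function(p)
    pairwiseDistance(mkrows(p)[1], mkrows(p)[2],
                     distanceParams("JC", gamma_shape = 1)))
  expect_true(all(diff(ds) > 0))
  r <- mkrows(0.1)
  da <- sapply(c(0.5, 1, 2, 10, 100), function(a)
    pairwiseDistance(r[1], r[2], distanceParams("JC", gamma_shape = a)))
  expect_true(all(diff(da) < 0))
  rs <- mkrows(0.8)
  expect_error(pairwiseDistance(rs[1], rs[2], distanceParams("JC")),
               class = "mitotrio_domain_error")
})

test_that("distances agree with the ape reference implementation", {
  set.seed(3)
  n <- 2000L
  x <- sample(c("A", "C", "G", "T"), n, TRUE)
  y <- x; z <- x
  idx <- sample(n, 60L)
  for (i in idx) y[i] <- sample(setdiff(c("A", "C", "G", "T"), y[i]), 1L)
  idx2 <- sample(n, 90L)
  for (i in idx2) z[i] <- sample(setdiff(c("A", "C", "G", "T"), z[i]), 1L)
  rows <- c(a = paste(x, collapse = ""), b = paste(y, collapse = ""),
            c = paste(z, collapse = ""))
  bin <- ape::as.DNAbin(t(sapply(rows, function(s)
    tolower(strsplit(s, "")[[1]]))))
  for (model in c("JC", "K80")) {
    ape_model <- c(JC = "JC69", K80 = "K80")[[model]]
    Da <- as.matrix(ape::dist.dna(bin, model = ape_model,
                                  pairwise.deletion = TRUE))
    D <- distanceMatrix(rows, distanceParams(model, gamma_shape = Inf))
    expect_equal(unname(D), unname(Da), tolerance = 1e-9)
    # and with gamma rate variation
    Dag <- as.matrix(ape::dist.dna(bin, model = ape_model, gamma = 1,
                                   pairwise.deletion = TRUE))
    Dg <- distanceMatrix(rows, distanceParams(model, gamma_shape = 1))
    expect_equal(unname(Dg), unname(Dag), tolerance = 1e-9)
  }
})

test_that("pairwise deletion drops columns gapped in either row only", {
  a <- "AC-TA"
  b <- "ACGT-"
  # usable columns: 1,2,4 -> no differences
  expect_equal(pairwiseDistance(a, b, distanceParams("p")), 0)
  c2 <- "TC-TA"
  expect_equal(pairwiseDistance(a, c2, distanceParams("p")), 1 / 4)
  expect_error(pairwiseDistance("---", "AAA", distanceParams("p")),
               class = "mitotrio_domain_error")
})

test_that("distance is symmetric and column-permutation invariant", {
  set.seed(9)
  r <- mkrows(0.05, n = 600L)
  d1 <- pairwiseDistance(r[1], r[2], distanceParams("K80", 1))
  d2 <- pairwiseDistance(r[2], r[1], distanceParams("K80", 1))
  expect_equal(d1, d2)
  perm <- sample(600L)
  pr <- vapply(r, function(s)
    paste(strsplit(s, "")[[1]][perm], collapse = ""), "")
  expect_equal(pairwiseDistance(pr[1], pr[2], distanceParams("K80", 1)), d1)
})

test_that("distance matrix round-trips through the PHYLIP writer", {
  res <- fix_pipeline(1)
  D <- res$distances
  expect_true(isSymmetric(D))
  expect_true(all(diag(D) == 0))
  path <- withr::local_tempfile(fileext = ".tsv")
  writeDistanceMatrix(D, path)
  D2 <- readDistanceMatrix(path)
  expect_lt(max(abs(D2 - D)), 1e-9)
  expect_identical(dimnames(D2), dimnames(D))
})

two_cluster_matrix <- function(k1 = 6L, k2 = 6L, seed = 1L) {
  set.seed(seed)
  k <- k1 + k2
  labs <- paste0("s", seq_len(k))
  grp <- rep(1:2, c(k1, k2))
  D <- matrix(0, k, k, dimnames = list(labs, labs))
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    d <- if (grp[i] == grp[j]) runif(1, 0, 0.001) else runif(1, 0.02, 0.03)
    D[i, j] <- D[j, i] <- d
  }
  list(D = D, grp = setNames(grp, labs))
}

test_that("ABGD separates constructed clusters and not uniform matrices", {
  tc <- two_cluster_matrix()
  r <- abgdPartition(tc$D)
  expect_equal(r$n_groups, 2L)
  # groups coincide with the construction
  expect_equal(length(unique(r$groups[tc$grp == 1])), 1L)
  expect_equal(length(unique(r$groups[tc$grp == 2])), 1L)

  labs <- paste0("u", 1:10)
  Du <- matrix(0.01, 10, 10, dimnames = list(labs, labs))
  diag(Du) <- 0
  expect_equal(abgdPartition(Du)$n_groups, 1L)
})

test_that("ABGD is label-order invariant and coarsens as the prior grows", {
  tc <- two_cluster_matrix(seed = 4L)
  r <- abgdPartition(tc$D)
  set.seed(8)
  perm <- sample(nrow(tc$D))
  rp <- abgdPartition(tc$D[perm, perm])
  relabel <- function(g) as.integer(factor(g[sort(names(g))],
                                           levels = unique(g[sort(names(g))])))
  expect_equal(relabel(rp$groups), relabel(r$groups))
  # growing the prior can only coarsen or preserve the partition
  n_prev <- Inf
  for (P in c(1e-4, 1e-3, 5e-3, 2e-2, 1e-1)) {
    ng <- abgdPartition(tc$D, abgdParams(prior = P))$n_groups
    expect_lte(ng, n_prev)
    n_prev <- ng
  }
})
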