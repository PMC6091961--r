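test_that("pairwise distances are Euclidean with zero diagonal", {
  m <- montage(c("a", "b"), rbind(c(0, 0, 0), c(3, 4, 0)))
  d <- montage_distances(m)
  expect_equal(d[1, 2], 5)
  expect_equal(d[2, 1], 5)
  expect_equal(diag(d), c(a = 0, b = 0))

  set.seed(11)
  co <- matrix(rnorm(30), 10, 3)
  m10 <- montage(letters[1:10], co)
  d10 <- montage_distances(m10)
  # brute-force double loop oracle
  for (i in 1:10) for (j in 1:10) {
    expect_equal(unname(d10[i, j]), sqrt(sum((co[i, ] - co[j, ])^2)))
  }
})

test_that("montage validation catches bad input", {
  expect_error(montage("a", matrix(0, 1, 3)), "at least 2")
  expect_error(montage(c("a", "a"), matrix(rnorm(6), 2)), "unique")
  expect_error(montage(c("a", "b"), rbind(c(0, 0, Inf), c(1, 1, 1))), "finite")
  expect_warning(montage(c("a", "b", "c"), rbind(c(0, 0, 0), c(0, 0, 0), c(1, 0, 0))),
                 "identical coordinates")
  # 2-D coordinates are zero-padded
  m2 <- montage(c("a", "b"), rbind(c(0, 0), c(1, 0)))
  expect_equal(ncol(m2$coords), 3L)
  expect_equal(unname(m2$coords[, 3]), c(0, 0))
})

test_that("neighbor_indices picks the L nearest with self first and index tie-break", {
  m <- montage(c("p0", "p1", "p2", "p10"), cbind(c(0, 1, 2, 10), 0, 0))
  d <- montage_distances(m)
  expect_equal(neighbor_indices(d, 1, 2), c(1L, 2L))
  expect_equal(neighbor_indices(d, 1, 3), c(1L, 2L, 3L))
  # L = M gives a permutation of all electrodes
  expect_setequal(neighbor_indices(d, 3, 4), 1:4)
  # distance tie at the middle electrode resolved towards the lower index
  mt <- montage(c("lo", "mid", "hi"), cbind(c(-1, 0, 1), 0, 0))
  dt <- montage_distances(mt)
  expect_equal(neighbor_indices(dt, 2, 2), c(2L, 1L))
  expect_error(neighbor_indices(d, 1, 5), "between 1 and")
})

test_that("neighbor lists are invariant under rigid rotation and translation", {
  set.seed(21)
  co <- subica:::fibonacci_hemisphere(15)
  theta <- 0.7
  R <- rbind(c(cos(theta), -sin(theta), 0), c(sin(theta), cos(theta), 0), c(0, 0, 1))
  shift <- c(2, -1, 0.5)
  m1 <- montage(letters[1:15], co)
  m2 <- montage(letters[1:15], co %*% t(R) + rep(shift, each = 15))
  d1 <- montage_distances(m1); d2 <- montage_distances(m2)
  for (k in c(1, 7, 15)) {
    expect_equal(neighbor_indices(d1, k, 6), neighbor_indices(d2, k, 6))
  }
})

test_that("projection matrices are one-hot row selectors", {
  P <- projection_matrix(c(2, 3), 4)
  expect_equal(P, rbind(c(0, 1, 0, 0), c(0, 0, 1, 0)))
  expect_equal(rowSums(P), c(1, 1))
  set.seed(3)
  x <- matrix(rnorm(4 * 20), 4)
  idx <- c(4L, 1L, 3L)
  expect_equal(projection_matrix(idx, 4) %*% x, x[idx, ])
  expect_error(projection_matrix(c(1, 1), 4), "distinct")
  expect_error(projection_matrix(c(0, 2), 4), "out of range")
})

test_that("subspace plans satisfy the pseudoinverse identity and column counts", {
  for (spec in list(list(n = 21, L = 12), list(n = 16, L = 12), list(n = 10, L = 4))) {
    m <- hemi_montage(spec$n)
    plan <- quiet(build_subspace_plan(m, spec$L))
    M <- spec$n
    expect_equal(dim(plan$stacked), c(M * spec$L, M))
    expect_lt(max(abs(plan$pinv %*% plan$stacked - diag(M))), 1e-10)
    # P^T P diagonal with entries = neighborhood membership counts
    PtP <- crossprod(plan$stacked)
    counts <- tabulate(unlist(plan$neighbor_lists), M)
    expect_equal(unname(diag(PtP)), as.numeric(counts))
    expect_lt(max(abs(PtP - diag(counts))), 1e-12)
    expect_true(all(counts >= 1))
    expect_equal(qr(plan$stacked)$rank, M)
    # every subspace contains its own electrode
    expect_true(all(vapply(seq_len(M), function(k) k %in% plan$neighbor_lists[[k]],
                           logical(1))))
  }
})

test_that("closed-form pseudoinverse matches the generic least-squares oracle", {
  skip_if_not_installed("MASS")
  m <- hemi_montage(12)
  plan <- quiet(build_subspace_plan(m, 5))
  expect_lt(max(abs(plan$pinv - MASS::ginv(plan$stacked))), 1e-8)
})

test_that("L = M plans reduce reconstruction to exact averaging", {
  m <- hemi_montage(6)
  plan <- quiet(build_subspace_plan(m, 6))
  for (P in plan$projections) {
    expect_equal(sort(colSums(P)), rep(1, 6))  # permutation matrices
  }
  set.seed(5)
  x <- matrix(rnorm(6 * 40), 6)
  stacked_copies <- plan$stacked %*% x
  expect_equal(plan$pinv %*% stacked_copies, x)
})

test_that("montage files round-trip and report malformed lines", {
  m <- hemi_montage(7)
  path <- tempfile(fileext = ".txt")
  write_montage(m, path)
  m2 <- load_montage(path)
  expect_equal(m2$labels, m$labels)
  expect_equal(unname(m2$coords), unname(round(m$coords, 6)), tolerance = 1e-6)
  writeLines(c("a 0 0 0", "b 1 bad 0"), path)
  expect_error(load_montage(path), "line 2")
  writeLines(c("a 0 0 0", "b"), path)
  expect_error(load_montage(path), "line 2")
})

test_that("packaged montage layouts load with the documented sizes", {
  f1020 <- system.file("extdata", "montage_10-20.txt", package = "subica")
  m1020 <- load_montage(f1020)
  expect_length(m1020$labels, 21)
  expect_true(all(c("Cz", "Fpz", "Oz", "T7", "T8") %in% m1020$labels))
  expect_length(load_montage(system.file("extdata", "montage_10-10.txt",
                                         package = "subica"))$labels, 61)
  expect_length(load_montage(system.file("extdata", "montage_hd111.txt",
                                         package = "subica"))$labels, 111)
  expect_equal(standard_montage("1020")$labels, m1020$labels)
})
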