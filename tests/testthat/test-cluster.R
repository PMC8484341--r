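# small helper: well-separated Gaussian blobs as a fake feature set
make_blobs <- function(k = 4, n_per = 40, d = 10, sep = 50, seed = 1) {
  set.seed(seed)
  centers <- matrix(rnorm(k * d), k, d) * sep
  x <- do.call(rbind, lapply(seq_len(k), function(j)
    sweep(matrix(rnorm(n_per * d, sd = 0.5), n_per, d), 2, centers[j, ], "+")))
  list(features = list(x = x, channel = "FSCL", level = 4L,
                       event_id = seq_len(k * n_per)),
       truth = rep(seq_len(k), each = n_per))
}

test_that("well-separated blobs are recovered exactly and match stats::kmeans", {
  b <- make_blobs()
  mod <- fit_channel_clusters(b$features, k = 4, seed = 2)
  expect_equal(oracle_ari(mod$labels, b$truth), 1)

  # independent route: stats::kmeans finds the same canonical centroid set
  km <- stats::kmeans(b$features$x, centers = 4, nstart = 10,
                      algorithm = "Lloyd")
  ord <- order(-sqrt(rowSums(km$centers^2)))
  expect_equal(unname(mod$centroids), unname(km$centers[ord, ]),
               tolerance = 1e-8)
  expect_equal(mod$inertia, km$tot.withinss, tolerance = 1e-6)
})

test_that("fits are deterministic in the seed and canonically ordered", {
  b <- make_blobs(k = 3, seed = 5)
  m1 <- fit_channel_clusters(b$features, k = 3, seed = 7)
  m2 <- fit_channel_clusters(b$features, k = 3, seed = 7)
  expect_identical(m1$centroids, m2$centroids)
  expect_identical(m1$labels, m2$labels)

  # initialization-permutation invariance: different seeds, same canonical
  # centroids on well-separated data
  m3 <- fit_channel_clusters(b$features, k = 3, seed = 99)
  expect_equal(m1$centroids, m3$centroids, tolerance = 1e-8)

  norms <- sqrt(rowSums(m1$centroids^2))
  expect_true(all(diff(norms) <= 1e-12))
})

test_that("degenerate identical events are handled without crashing", {
  feats <- list(x = matrix(5, 30, 10), channel = "FSCL", level = 4L)
  expect_silent(mod <- fit_channel_clusters(feats, k = 8, seed = 1))
  expect_equal(mod$inertia, 0)
  expect_identical(nrow(mod$centroids), 8L)

  expect_error(fit_channel_clusters(list(x = matrix(1, 3, 4)), k = 8),
               "at least k")
})

test_that("assignment matches an exhaustive-distance oracle and is idempotent", {
  b <- make_blobs(k = 5, seed = 8)
  mod <- fit_channel_clusters(b$features, k = 5, seed = 3)
  # idempotence on the training set
  expect_identical(assign_clusters(b$features, mod), mod$labels)

  # events exactly at a centroid
  at_centroids <- list(x = mod$centroids, channel = "FSCL", level = 4L)
  expect_identical(assign_clusters(at_centroids, mod), seq_len(5L))

  # random probes vs brute force
  set.seed(17)
  probe <- list(x = matrix(rnorm(200 * 10, sd = 30), 200, 10),
                channel = "FSCL", level = 4L)
  got <- assign_clusters(probe, mod)
  brute <- apply(probe$x, 1, function(v)
    which.min(colSums((t(mod$centroids) - v)^2)))
  expect_identical(got, as.integer(brute))

  expect_error(assign_clusters(list(x = matrix(0, 2, 7)), mod), "dimension")
})

test_that("Lloyd inertia is non-increasing across iterations", {
  # .lloyd asserts monotonicity internally every iteration; drive it hard
  set.seed(23)
  x <- matrix(rnorm(500 * 8), 500, 8)       # unstructured: many iterations
  feats <- list(x = x, channel = "FSCL", level = 4L)
  expect_silent(fit_channel_clusters(feats, k = 8, seed = 4, n_init = 3))
})

test_that("combined clusters index an 8x8 contingency with exact marginals", {
  set.seed(6)
  la <- sample(1:8, 500, TRUE)
  lb <- sample(1:8, 500, TRUE)
  cmb <- combine_clusters(la, lb, 8, 8)
  expect_identical(sort(unique(cmb$combined_id)) %in% 0:63,
                   rep(TRUE, length(unique(cmb$combined_id))))
  expect_identical(sum(cmb$contingency), 500L)
  expect_identical(as.integer(rowSums(cmb$contingency)),
                   as.integer(table(factor(la, 1:8))))
  expect_identical(as.integer(colSums(cmb$contingency)),
                   as.integer(table(factor(lb, 1:8))))
  # id arithmetic
  expect_identical(cmb$combined_id, (la - 1L) * 8L + (lb - 1L))

  one <- combine_clusters(rep(1L, 9), rep(1L, 9), 8, 8)
  expect_identical(one$contingency[1, 1], 9L)
  expect_identical(sum(one$contingency != 0), 1L)

  expect_error(combine_clusters(1:3, 1:4, 8, 8), "length")
})

test_that("cluster models survive text serialization with fingerprint checks", {
  b <- make_blobs(k = 3, seed = 12)
  mod <- fit_channel_clusters(b$features, k = 3, seed = 1)
  f <- withr::local_tempfile(fileext = ".json")
  write_cluster_model(mod, f)
  back <- read_cluster_model(f)
  expect_equal(back$centroids, mod$centroids)
  expect_identical(back$fingerprint, mod$fingerprint)
  expect_identical(assign_clusters(b$features, back), mod$labels)

  # tampering is detected
  txt <- sub('"k3d10', '"k3d11', readLines(f), fixed = TRUE)
  writeLines(txt, f)
  expect_error(read_cluster_model(f), "fingerprint|version")
})

test_that("transfer assignment reproduces full-fit label distributions", {
  # well-separated classes: a model fit on half the cohort must label the
  # other half like a model fit on everything
  b <- make_blobs(k = 4, n_per = 150, sep = 60, seed = 19)
  set.seed(20)
  half <- sample(600, 300)                   # random split across classes
  fa <- list(x = b$features$x[half, ], channel = "FSCL", level = 4L)
  fb <- list(x = b$features$x[-half, ], channel = "FSCL", level = 4L)
  mod_half <- fit_channel_clusters(fa, k = 4, seed = 2)
  mod_full <- fit_channel_clusters(b$features, k = 4, seed = 2)
  lab_b_half <- assign_clusters(fb, mod_half)
  lab_b_full <- mod_full$labels[-half]
  expect_equal(oracle_ari(lab_b_half, lab_b_full), 1)
  # and the label distribution matches within multinomial error
  ta <- table(factor(lab_b_half, 1:4)); tb <- table(factor(lab_b_full, 1:4))
  expect_gt(suppressWarnings(chisq.test(cbind(ta, tb))$p.value), 0.001)
})
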