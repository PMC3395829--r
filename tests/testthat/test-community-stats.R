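test_that("rarefaction endpoints, monotonicity and closed form are exact", {
  labels <- rep(c("V1", "V2", "V3"), c(6, 3, 1))
  cur <- rarefaction(labels, n_iter = 300, seed = 1)
  N <- length(labels)
  # full depth: observed richness with a degenerate interval
  full <- cur[cur$depth == N, ]
  expect_equal(full$mean_richness, 3)
  expect_equal(full$ci_low, 3)
  expect_equal(full$ci_high, 3)
  expect_equal(full$expected, 3)
  # depth 1: exactly one VT
  expect_equal(cur$mean_richness[cur$depth == 1], 1)
  expect_true(all(diff(cur$mean_richness) >= 0))
  # closed form equals the standard rarefaction estimator
  comm <- as.integer(table(labels))
  veg <- vapply(cur$depth, function(n)
    as.numeric(vegan::rarefy(t(comm), sample = n)), numeric(1))
  expect_equal(cur$expected, veg, tolerance = 1e-10)
  expect_error(rarefaction(labels, depths = N + 1), "1..N")
})

test_that("randomized rarefaction agrees with the hypergeometric expectation", {
  for (f in 1:2) {
    set.seed(700 + f)
    counts <- stats::rgeom(25, 1 / 3) + 1
    labels <- rep(paste0("V", seq_along(counts)), counts)
    cur <- rarefaction(labels, n_iter = 1000, seed = 70 + f)
    dev <- abs(cur$mean_richness - cur$expected)
    expect_true(all(dev <= 3 * cur$se_mean + 1e-9))
  }
})

test_that("specificity counts exclusive rows overall and per column", {
  m <- rbind(V1 = c(a = 1, b = 0, c = 0),
             V2 = c(a = 2, b = 0, c = 0),
             V3 = c(a = 0, b = 3, c = 0),
             V4 = c(a = 1, b = 0, c = 2))
  s <- specificity(m)
  expect_equal(s$overall, 0.75)
  expect_equal(s$per_column[["a"]], 2 / 3)
  expect_equal(s$per_column[["b"]], 1)
  expect_equal(s$per_column[["c"]], 0)
  # a column with 10 VTs of which 5 exclusive
  m2 <- cbind(x = rep(1, 10), y = c(rep(0, 5), rep(1, 5)))
  rownames(m2) <- paste0("V", 1:10)
  expect_equal(specificity(m2)$per_column[["x"]], 0.5)
  # everything in one column
  m3 <- cbind(only = c(1, 2, 3))
  rownames(m3) <- paste0("V", 1:3)
  expect_equal(specificity(m3)$overall, 1)
  # internal consistency: overall equals the mean row indicator
  set.seed(8)
  m4 <- matrix(rbinom(60, 2, 0.4), 12, 5,
               dimnames = list(paste0("V", 1:12), paste0("c", 1:5)))
  m4[1, ] <- c(1, 0, 0, 0, 0)
  expect_equal(specificity(m4)$overall, mean(rowSums(m4 > 0) == 1))
  expect_error(specificity(matrix(0, 0, 3)), "empty")
})

test_that("host range vs geographic range regression matches closed-form OLS", {
  # construct VTs with (host, location) counts (1,1), (2,3), (3,5)
  rows <- list()
  specs <- list(c(1, 1), c(2, 3), c(3, 5))
  orders <- c("Asterales", "Fabales", "Lamiales")
  for (v in seq_along(specs)) {
    h <- specs[[v]][1]; l <- specs[[v]][2]
    k <- max(h, l)
    for (i in seq_len(k))
      rows[[length(rows) + 1]] <- meta_row(
        sprintf("v%ds%d", v, i),
        host_order = orders[((i - 1) %% h) + 1],
        location_id = sprintf("L%d_%d", v, ((i - 1) %% l) + 1))
  }
  meta <- do.call(rbind, rows)
  truth <- lapply(seq_along(specs), function(v) {
    ids <- meta$seq_id[grepl(sprintf("^v%ds", v), meta$seq_id)]
    list(taxon_id = paste0("VT", v), member_ids = ids, ancestor = "")
  })
  res <- host_range_vs_geo(truth_assignment(truth), meta)
  expect_equal(res$slope, 2)
  expect_equal(res$intercept, -1)
  expect_equal(res$r_squared, 1)
  expect_error(host_range_vs_geo(truth_assignment(truth[1:2]), meta),
               "at least 3")
})

test_that("a planted host-range/geography association is detected", {
  set.seed(55)
  rows <- list(); truth <- list()
  orders <- c("Asterales", "Fabales", "Lamiales", "Poales", "Rosales",
              "Solanales")
  for (v in 1:50) {
    h <- sample(1:6, 1)
    l <- max(1, h + sample(-1:1, 1))        # locations track host range
    k <- max(h, l)
    ids <- sprintf("w%ds%d", v, seq_len(k))
    for (i in seq_len(k))
      rows[[length(rows) + 1]] <- meta_row(
        ids[i], host_order = orders[((i - 1) %% h) + 1],
        location_id = sprintf("M%d_%d", v, ((i - 1) %% l) + 1))
    truth[[v]] <- list(taxon_id = sprintf("VT%02d", v), member_ids = ids,
                       ancestor = "")
  }
  res <- host_range_vs_geo(truth_assignment(truth), do.call(rbind, rows))
  expect_gt(res$slope, 0)
  expect_lt(res$p_value, 0.05)
  expect_equal(res$n, 50)
})

test_that("Bray-Curtis follows the formula, bounds and conventions", {
  m <- rbind(x = c(1, 2), y = c(2, 1))
  expect_equal(bray_curtis(m)["x", "y"], 1 / 3)
  ident <- rbind(a = c(3, 1, 4), b = c(3, 1, 4))
  expect_equal(bray_curtis(ident)["a", "b"], 0)
  disj <- rbind(a = c(5, 0), b = c(0, 7))
  expect_equal(bray_curtis(disj)["a", "b"], 1)
  expect_error(bray_curtis(rbind(a = c(-1, 2), b = c(1, 1))), "negative")
  # zero-vector convention
  z <- rbind(a = c(0, 0), b = c(0, 0), c = c(1, 2))
  expect_message(dz <- bray_curtis(z), "convention")
  expect_equal(dz["a", "b"], 0)
  # columns mode + agreement with vegan on random data
  set.seed(6)
  mm <- matrix(rpois(40, 3), 8, 5,
               dimnames = list(paste0("r", 1:8), paste0("c", 1:5)))
  expect_equal(unname(bray_curtis(mm, by = "columns")),
               unname(as.matrix(vegan::vegdist(t(mm), "bray"))))
  d <- bray_curtis(mm)
  expect_true(all(d >= 0 & d <= 1))
  expect_true(isSymmetric(unname(d)))
})

test_that("Mantel statistic and p behave as specified", {
  set.seed(21)
  d1 <- random_symmetric_dm(10)
  res <- mantel(d1, d1, n_perm = 99, seed = 4)
  expect_equal(res$r, 1)
  expect_equal(res$p, 1 / 100)
  # affine transformation leaves Pearson r at 1
  d2 <- 2 * d1 + 0.1; diag(d2) <- 0
  expect_equal(mantel(d1, d2, n_perm = 99, seed = 4)$r, 1)
  # determinism under a seed
  d3 <- random_symmetric_dm(10)
  r1 <- mantel(d1, d3, n_perm = 99, seed = 9)
  r2 <- mantel(d1, d3, n_perm = 99, seed = 9)
  expect_equal(r1$p, r2$p)
  expect_equal(r1$r, r2$r)
  bad <- d1; rownames(bad)[1] <- colnames(bad)[1] <- "zz"
  expect_error(mantel(d1, bad), "labels")
})

test_that("composition similarity regression recovers identity and coupling", {
  set.seed(31)
  vt <- matrix(rpois(24, 4), 6, 4,
               dimnames = list(paste0("V", 1:6), paste0("cat", 1:4)))
  res <- composition_similarity_regression(vt, vt)
  expect_equal(res$slope, 1, tolerance = 1e-9)
  expect_equal(res$r_squared, 1, tolerance = 1e-9)
  expect_equal(nrow(res$data), choose(4, 2))
  expect_error(composition_similarity_regression(vt[, 1:2], vt[, 1:2]),
               "at least 3")
  # noisy coupling: categories have distinct composition profiles and the
  # VT table is a lightly perturbed copy of the plant table
  plant <- matrix(rpois(40, rep(c(12, 4, 1, 7), each = 10)), 10, 4,
                  dimnames = list(paste0("P", 1:10), paste0("cat", 1:4)))
  noisy <- pmax(plant + matrix(sample(-1:1, 40, TRUE), 10, 4), 0)
  rownames(noisy) <- paste0("V", 1:10)
  res2 <- composition_similarity_regression(noisy, plant)
  expect_gt(res2$slope, 0)
  expect_gt(res2$r_squared, 0.5)
})
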