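# Data model, preprocessing and serialization of spot-level slices.

test_that("center_crop follows the index arithmetic and padding contract", {
  img <- array(seq_len(100 * 100 * 3), c(100, 100, 3))
  cr <- center_crop(img, c(50, 50), 40)
  expect_equal(cr, img[31:70, 31:70, ])          # rows/cols 30..69, 0-based
  expect_equal(center_crop(img, c(50, 50), 100), img)  # full-size identity
  # border crop: zero-padded, non-pad region matches a pad-then-slice oracle
  pad <- array(0, c(140, 140, 3))
  pad[21:120, 21:120, ] <- img
  expect_equal(center_crop(img, c(5, 5), 40),
               pad[(5 - 20 + 20 + 1):(5 + 19 + 20 + 1),
                   (5 - 20 + 20 + 1):(5 + 19 + 20 + 1), ])
  # output center pixel equals input center pixel
  expect_equal(center_crop(img, c(17, 63), 9)[5, 5, ], img[64, 18, ])
  expect_error(center_crop(img, c(150, 50), 40), "outside image")
})

test_that("normalize_expression implements log1p CPM exactly", {
  counts <- rbind(c(1, 1, 2), c(0, 5, 0))
  norm <- normalize_expression(counts)
  expect_equal(norm[1, ], log(1 + c(250000, 250000, 500000)))
  expect_equal(norm[2, 1], 0)                        # zero maps to zero
  expect_equal(norm[2, 2], log(1 + 1e6))             # single expressed gene
  expect_error(normalize_expression(rbind(c(1, 1), c(0, 0))), "spot.*2")
})

test_that("normalization invariants hold on random counts", {
  set.seed(21)
  counts <- matrix(rpois(30 * 40, 5), 30, 40)
  counts[rowSums(counts) == 0, 1] <- 1
  norm <- normalize_expression(counts)
  expect_lt(max(abs(rowSums(exp(norm) - 1) - 1e6)) / 1e6, 1e-6)
  for (i in c(1, 17)) {
    expect_identical(order(norm[i, ], seq_len(40)),
                     order(counts[i, ], seq_len(40)))
  }
})

test_that("HVG selection ranks by dispersion with deterministic ties", {
  norm <- cbind(a = c(0, 8, 0, 8), b = c(4, 4, 4, 4),
                cc = c(2, 6, 2, 6), d = c(3, 5, 3, 5), e = c(0, 1, 0, 1))
  p <- select_hvg(norm, colnames(norm), k = 4)
  expect_false("b" %in% p$names)          # zero-variance gene excluded
  expect_s3_class(p, "gene_panel")
  expect_equal(p$size, 4)
  full <- select_hvg(norm, colnames(norm), k = 5)
  expect_equal(sort(full$names), sort(colnames(norm)))
  expect_error(select_hvg(norm, colnames(norm), k = 6), "exceeds")
  # planted high-dispersion genes are recovered
  set.seed(22)
  quiet <- matrix(rpois(50 * 20, 20), 50, 20)
  loud <- sapply(1:5, function(j) rpois(50, 20) * rbinom(50, 1, 0.3))
  counts <- cbind(quiet, loud)
  colnames(counts) <- c(sprintf("q%02d", 1:20), sprintf("loud%d", 1:5))
  nm <- normalize_expression(counts)
  sel <- select_hvg(nm, colnames(counts), k = 5)
  expect_setequal(sel$names, sprintf("loud%d", 1:5))
})

test_that("target panel ranks by mean expression, ties lexicographic", {
  norm <- cbind(zz = c(1, 1), aa = c(1, 1), mid = c(0.5, 0.5),
                lo = c(0, 0.1))
  p <- select_target_genes(norm, colnames(norm), k = 1)
  expect_equal(p$names, "aa")             # tie broken by smaller name
  p3 <- select_target_genes(norm, colnames(norm), k = 3)
  expect_equal(p3$names, c("aa", "zz", "mid"))
  # ranking equals a brute-force sort of column means
  set.seed(23)
  m <- matrix(runif(200), 10, 20,
              dimnames = list(NULL, sprintf("g%02d", 1:20)))
  p10 <- select_target_genes(m, colnames(m), k = 10)
  expect_equal(p10$names,
               names(sort(colMeans(m), decreasing = TRUE))[1:10])
})

test_that("panel selection is invariant to gene column permutation", {
  set.seed(24)
  m <- matrix(rpois(200, 3), 10, 20)
  m[rowSums(m) == 0, 1] <- 1
  nm <- normalize_expression(m)
  colnames(nm) <- sprintf("g%02d", 1:20)
  perm <- sample(20)
  for (f in list(select_hvg, select_target_genes)) {
    p1 <- f(nm, colnames(nm), k = 7)
    p2 <- f(nm[, perm], colnames(nm)[perm], k = 7)
    expect_setequal(p1$names, p2$names)
  }
})

test_that("augmentation is seed-deterministic with an identity setting", {
  set.seed(25)
  patch <- array(runif(40 * 40 * 3, 60, 200), c(40, 40, 3))
  a1 <- augment_patch(patch, 99L)
  a2 <- augment_patch(patch, 99L)
  expect_identical(a1, a2)
  expect_false(identical(a1, augment_patch(patch, 100L)))
  ident <- augment_patch(patch, 5L, scale_range = c(1, 1), flip_prob = 0,
                         brightness = 0, contrast = 0)
  expect_equal(ident, patch)
  # mean pixel shift bounded by the brightness bound (contrast disabled)
  shifts <- vapply(1:100, function(s) {
    ag <- augment_patch(patch, s, scale_range = c(1, 1), flip_prob = 0,
                        brightness = 0.1, contrast = 0)
    abs(mean(ag) - mean(patch))
  }, numeric(1))
  expect_true(all(shifts <= 0.1 * 255 + 1e-9))
})

test_that("slices round-trip through the directory layout", {
  sl <- tiny_slice(rng_seed = 31L, grid = c(2L, 2L), n_genes = 15L)
  dir <- withr::local_tempdir()
  write_slice(sl, dir)
  expect_true(file.exists(file.path(dir, "manifest.json")))
  back <- read_slice_dir(dir)
  expect_equal(back$counts, sl$counts, ignore_attr = TRUE)
  expect_equal(back$coords, sl$coords, ignore_attr = TRUE)
  expect_equal(back$gene_names, sl$gene_names)
  expect_equal(back$n, sl$n)
  for (i in seq_len(sl$n)) {
    expect_lt(max(abs(back$patches[[i]] - round(sl$patches[[i]]))), 0.51)
  }
})

test_that("load_slice crops from a whole image and validates inputs", {
  dir <- withr::local_tempdir()
  set.seed(32)
  img <- array(runif(200 * 200 * 3, 0, 255), c(200, 200, 3))
  write_image(img, file.path(dir, "he.png"))
  counts <- matrix(rpois(9, 5) + 1, 3, 3)
  Matrix::writeMM(Matrix::Matrix(t(counts), sparse = TRUE),
                  file.path(dir, "counts.mtx"))
  writeLines(c("g1", "g2", "g3"), file.path(dir, "genes.tsv"))
  write.table(data.frame(barcode = c("b1", "b2", "b3"),
                         x = c(50, 120, 180), y = c(60, 100, 20)),
              file.path(dir, "coords.tsv"), sep = "\t", row.names = FALSE,
              quote = FALSE)
  sl <- load_slice(file.path(dir, "counts.mtx"), file.path(dir, "genes.tsv"),
                   file.path(dir, "coords.tsv"), file.path(dir, "he.png"),
                   patch_size = 40)
  expect_equal(sl$n, 3)
  expect_equal(dim(sl$patches[[1]]), c(40, 40, 3))
  # mismatched barcode rows name the offending file
  write.table(data.frame(barcode = c("b1", "b2"), x = c(1, 2), y = c(1, 2)),
              file.path(dir, "coords2.tsv"), sep = "\t", row.names = FALSE,
              quote = FALSE)
  expect_error(load_slice(file.path(dir, "counts.mtx"),
                          file.path(dir, "genes.tsv"),
                          file.path(dir, "coords2.tsv"),
                          file.path(dir, "he.png")),
               "coords2")
  # out-of-bounds coordinates list the spot indices
  write.table(data.frame(barcode = c("b1", "b2", "b3"),
                         x = c(50, 300, 180), y = c(60, 100, 20)),
              file.path(dir, "coords3.tsv"), sep = "\t", row.names = FALSE,
              quote = FALSE)
  expect_error(load_slice(file.path(dir, "counts.mtx"),
                          file.path(dir, "genes.tsv"),
                          file.path(dir, "coords3.tsv"),
                          file.path(dir, "he.png")),
               "spot\\(s\\): 2")
})

test_that("spot_slice enforces its invariants", {
  patches <- replicate(3, array(0, c(8, 8, 3)), simplify = FALSE)
  counts <- matrix(1L, 3, 4)
  coords <- matrix(0, 3, 2)
  expect_error(spot_slice("s", patches[1:2], counts, letters[1:4], coords),
               "patches")
  expect_error(spot_slice("s", patches, counts, letters[1:4], coords[1:2, ]),
               "coords")
  expect_error(spot_slice("s", patches, counts - 2L, letters[1:4], coords),
               "non-negative")
  expect_error(spot_slice("s", patches, counts, c("a", "a", "b", "c"),
                          coords), "unique")
})
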