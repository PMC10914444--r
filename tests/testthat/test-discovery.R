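test_that("putative barcode counts are exact on clean reads", {
  set.seed(51)
  bcs <- c(randSeq(16), randSeq(16), randSeq(16))
  reps <- c(50L, 30L, 20L)
  seqs <- unlist(mapply(function(bc, n) {
    vapply(seq_len(n),
           function(i) makeTenXRead(bc, randSeq(12), randSeq(20)), "")
  }, bcs, reps, SIMPLIFY = FALSE))
  # one read without any flank contributes nothing
  reads <- ReadSet(sprintf("r%03d", seq_len(101)), c(seqs, randSeq(80)))
  df <- discoverBarcodes(reads, tenXv3Structure(), quiet = TRUE)
  expect_identical(nrow(df), 3L)
  expect_identical(df$count[match(bcs, df$barcode)], reps)
  expect_identical(attr(df, "totalReads"), 101L)
  expect_identical(attr(df, "extractions"), 100L)
  expect_identical(sum(df$count), 100L)
})

test_that("count totals are conserved under sequencing errors", {
  sim <- simulateReads(simConfig(nReads = 150, nBarcodes = 10, seed = 52))
  df <- discoverBarcodes(sim$reads, tenXv3Structure(), quiet = TRUE)
  expect_identical(sum(df$count), attr(df, "extractions"))
  expect_lte(sum(df$count), attr(df, "totalReads") +
               sum(sim$truth$chimeric) / 2)
  # counts are sorted descending with lexicographic ties
  expect_false(is.unsorted(rev(df$count)))
})

test_that("rollingDerivative implements the log-log slope formula", {
  expect_identical(rollingDerivative(c(10, 10, 10, 10), window = 1),
                   c(0, 0, 0))
  # two plateaus: most negative slope exactly at the boundary rank
  counts <- c(rep(100, 50), rep(1, 50))
  sl <- rollingDerivative(counts, window = 1)
  expect_identical(which.min(sl), 50L)
  expect_equal(sl[50], (log10(1) - log10(100)) / (log10(51) - log10(50)))
  # geometric decay in rank is not constant; decay as a power of rank is
  ranks <- 1:100
  power <- 1000 * ranks^-1.5
  expect_equal(rollingDerivative(power, window = 5),
               rep(-1.5, 95), tolerance = 1e-12)
  expect_error(rollingDerivative(c(3, 2), window = 2), "entries")
  expect_error(rollingDerivative(c(1, 2, 3), window = 1), "decreasing")
})

test_that("findInflection takes the most negative slope with earliest-rank ties", {
  expect_identical(findInflection(c(-0.1, -5, -0.1)), 2L)
  expect_identical(findInflection(c(-3, -1, -2), searchRange = c(2, 3)), 3L)
  expect_identical(findInflection(c(-1, -7, -4, -7)), 2L)
  expect_error(findInflection(c(-1, -2), searchRange = c(3, 4)),
               "search range")
})

test_that("widening the search range never shrinks the candidate space", {
  set.seed(53)
  slopes <- -runif(200)
  r1 <- findInflection(slopes, c(10, 100))
  r2 <- findInflection(slopes, c(10, 200))
  expect_lte(slopes[r2], slopes[r1])
})

test_that("kneeFilter separates a clean two-plateau table", {
  counts <- data.frame(barcode = vapply(1:120, function(i) randSeq(16), ""),
                       count = c(rep(500L, 60), rep(4L, 60)))
  kr <- kneeFilter(counts, window = 5)
  expect_s4_class(kr, "KneeResult")
  expect_identical(inflectionRank(kr), 60L)
  expect_setequal(keptBarcodes(kr), counts$barcode[counts$count == 500L])
  expect_false(kr@lowConfidence)
  expect_output(show(kr), "KneeResult")
})

test_that("kneeFilter recovers the cell population from the synthetic mixture", {
  mix <- makeKneeMixture(nCells = 200L, nAmbient = 2000L, seed = 54)
  kr <- kneeFilter(mix$counts, window = 20)
  kept <- keptBarcodes(kr)
  recall <- mean(mix$cells %in% kept)
  precision <- mean(kept %in% mix$cells)
  expect_gte(recall, 0.98)
  expect_gte(precision, 0.98)
})

test_that("whitelist restriction precedes the knee and bounds the kept set", {
  mix <- makeKneeMixture(nCells = 100L, nAmbient = 1000L, seed = 55)
  wl <- c(mix$cells, mix$ambient[1:50])
  kr <- kneeFilter(mix$counts, window = 10, whitelist = wl)
  expect_true(all(keptBarcodes(kr) %in% wl))
  expect_error(kneeFilter(mix$counts, window = 10,
                          whitelist = mix$cells[1:5]), "window")
})

test_that("a smooth single-plateau curve is flagged low-confidence", {
  set.seed(56)
  # smooth power-law decay: no knee, near-constant log-log slope
  counts <- data.frame(barcode = vapply(1:200, function(i) randSeq(16), ""),
                       count = as.integer(round(1e4 * (1:200)^-0.5)))
  kr <- kneeFilter(counts, window = 10)
  expect_true(kr@lowConfidence)
  # the clean two-plateau table from above is confidently knee'd instead
})

test_that("discovered and knee-filtered barcodes drive accurate demultiplexing", {
  # end-to-end: discover -> knee filter -> demux with the kept list
  nCell <- 12L
  sim <- simulateReads(simConfig(nReads = 400, nBarcodes = nCell, seed = 57,
                                 subRate = 0.02, insRate = 0.01,
                                 delRate = 0.01))
  rs <- tenXv3Structure()
  counts <- discoverBarcodes(sim$reads, rs, quiet = TRUE)
  kr <- kneeFilter(counts, window = 3, searchRange = c(2, 30))
  kept <- keptBarcodes(kr)
  expect_gte(mean(sim$whitelist %in% kept), 0.9)
  a <- demultiplex(sim$reads, rs, whitelist = kept, quiet = TRUE)
  asn <- a[a$status == "ASSIGNED", ]
  tr <- sim$truth
  key <- paste(asn$readId, asn$strand)
  m <- match(key, paste(tr$readId, tr$strand))
  ok <- asn$barcode == tr$barcode[m]
  expect_gte(mean(ok, na.rm = TRUE), 0.95)
})
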