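test_that("assignBarcode reports the unique lowest-distance barcode", {
  bc <- "ACGTACGTACGTACGT"
  win <- paste0("GATCT", bc, "TTGGCCAATTGGTTTTT")
  a <- assignBarcode(win, c(bc, "GGGGCCCCAAAATTTT"), maxDist = 2)
  expect_identical(a$status, "ASSIGNED")
  expect_identical(a$barcode, bc)
  expect_identical(a$distance, 0L)
  expect_identical(substr(win, a$start, a$end), bc)
})

test_that("equal lowest distance to two barcodes is ambiguous", {
  a <- assignBarcode("TTAAAACCCCTT", c("AAAACCCA", "AAAACCCT"), maxDist = 2)
  expect_identical(a$status, "AMBIGUOUS")
  expect_true(is.na(a$barcode))
  expect_identical(a$distance, 1L)
})

test_that("assignment exceeds maxDist -> NO_BARCODE; empty whitelist errors", {
  a <- assignBarcode("TTTTTTTTTTTT", c("AAAAAAAA", "CCCCCCCC"), maxDist = 2)
  expect_identical(a$status, "NO_BARCODE")
  expect_error(assignBarcode("ACGT", character(0)), "empty")
})

test_that("assignment is invariant to whitelist order", {
  set.seed(41)
  wl <- generateWhitelist(30, 16, 5, seed = 5)
  for (i in 1:20) {
    bc <- sample(wl, 1)
    win <- paste0(randSeq(5), .injectEditsForTest(bc, sample(0:2, 1)),
                  randSeq(12))
    a1 <- assignBarcode(win, wl, 2)
    a2 <- assignBarcode(win, sample(wl), 2)
    expect_identical(a1[c("status", "barcode", "distance")],
                     a2[c("status", "barcode", "distance")])
  }
})

test_that("k edits in the barcode are corrected when spacing >= 2k+1", {
  wl <- generateWhitelist(25, 16, 5, seed = 6)
  set.seed(42)
  for (i in 1:40) {
    bc <- sample(wl, 1)
    k <- sample(1:2, 1)
    mut <- .injectEditsForTest(bc, k)
    win <- paste0(randSeq(5), mut, randSeq(12))
    a <- assignBarcode(win, wl, 2)
    # brute-force verification: the true barcode is the unique nearest
    d <- levenshteinDist(mut, wl)
    expect_identical(wl[which.min(d)], bc)
    expect_identical(a$status, "ASSIGNED")
    expect_identical(a$barcode, bc)
  }
})

test_that("a clean singleton read yields one record with exact barcode and UMI", {
  rs <- tenXv3Structure()
  set.seed(43)
  bc <- randSeq(16); umi <- randSeq(12); insert <- randSeq(40)
  read <- makeTenXRead(bc, umi, insert, junk5 = randSeq(7))
  wl <- c(bc, generateWhitelist(5, 16, 5, seed = 7))
  df <- demultiplexRead(read, rs, whitelist = wl)
  expect_identical(nrow(df), 1L)
  expect_identical(df$status, "ASSIGNED")
  expect_identical(df$barcode, bc)
  expect_identical(df$umi, umi)
  expect_identical(df$barcodeDist, 0L)
  expect_identical(df$strand, "+")
  expect_identical(df$trimmedSeq, insert)
})

test_that("a two-part chimera is split into both true records with tiled inserts", {
  rs <- tenXv3Structure()
  set.seed(44)
  wl <- generateWhitelist(6, 16, 5, seed = 8)
  bc1 <- wl[1]; bc2 <- wl[2]
  umi1 <- randSeq(12); umi2 <- randSeq(12)
  ins1 <- randSeq(35); ins2 <- randSeq(50)
  read <- paste0(makeTenXRead(bc1, umi1, ins1), makeTenXRead(bc2, umi2, ins2))
  df <- demultiplexRead(read, rs, whitelist = wl)
  expect_identical(nrow(df), 2L)
  expect_identical(df$barcode, c(bc1, bc2))
  expect_identical(df$umi, c(umi1, umi2))
  expect_identical(df$trimmedSeq, c(ins1, ins2))
  expect_identical(df$subReadIndex, 0:1)
  # with splitting disabled at most one record survives
  df1 <- demultiplexRead(read, rs, whitelist = wl, splitChimeras = FALSE)
  expect_identical(nrow(df1), 1L)
  expect_identical(df1$barcode, bc1)
})

test_that("a reverse-complemented read gives the same call with flipped strand", {
  rs <- tenXv3Structure()
  set.seed(45)
  for (i in 1:10) {
    bc <- randSeq(16); umi <- randSeq(12)
    read <- makeTenXRead(bc, umi, randSeq(30), junk5 = randSeq(5),
                         junk3 = randSeq(5))
    wl <- c(bc, generateWhitelist(4, 16, 5, seed = i))
    fw <- demultiplexRead(read, rs, whitelist = wl)
    rv <- demultiplexRead(reverseComplement(read), rs, whitelist = wl)
    expect_identical(rv$barcode, fw$barcode)
    expect_identical(rv$umi, fw$umi)
    expect_identical(rv$trimmedSeq, fw$trimmedSeq)
    expect_identical(fw$strand, "+")
    expect_identical(rv$strand, "-")
  }
})

test_that("reads without the flank produce a single NO_FLANK pass-through record", {
  rs <- tenXv3Structure()
  set.seed(46)
  read <- randSeq(120)
  df <- demultiplexRead(read, rs, whitelist = c("ACGTACGTACGTACGT"))
  expect_identical(nrow(df), 1L)
  expect_identical(df$status, "NO_FLANK")
  expect_identical(df$trimmedSeq, read)
  expect_true(is.na(df$barcode))
})

test_that("a truncated tail yields a flagged short UMI", {
  rs <- readStructure(flankSegment(TENX_PRIMER, "primer"), barcodeSegment(16),
                      umiSegment(12))
  set.seed(47)
  bc <- randSeq(16)
  read <- paste0(TENX_PRIMER, bc, "AAAAA")   # only 5 bases after the barcode
  df <- demultiplexRead(read, rs, whitelist = c(bc, "GGGGCCCCAAAATTTT"))
  expect_identical(df$status, "ASSIGNED")
  expect_identical(nchar(df$umi), 5L)
  expect_true(df$umiTruncated)
})

test_that("demultiplex output is independent of chunk size and whitelist order", {
  sim <- simulateReads(simConfig(nReads = 150, nBarcodes = 12, seed = 9))
  rs <- tenXv3Structure()
  a1 <- demultiplex(sim$reads, rs, whitelist = sim$whitelist,
                    chunkSize = 7, quiet = TRUE)
  a2 <- demultiplex(sim$reads, rs, whitelist = sim$whitelist,
                    chunkSize = 1000, quiet = TRUE)
  set.seed(48)
  a3 <- demultiplex(sim$reads, rs, whitelist = sample(sim$whitelist),
                    chunkSize = 64, quiet = TRUE)
  attr(a1, "summary") <- attr(a2, "summary") <- attr(a3, "summary") <- NULL
  expect_identical(a1, a2)
  expect_identical(a1, a3)
})

test_that("splitting never yields more records than embedded structure copies", {
  sim <- simulateReads(simConfig(nReads = 120, nBarcodes = 10, seed = 10,
                                 chimeraRate = 0.5))
  rs <- tenXv3Structure()
  a <- demultiplex(sim$reads, rs, whitelist = sim$whitelist, quiet = TRUE)
  nRec <- table(factor(a$readId[a$status == "ASSIGNED"],
                       levels = unique(sim$truth$readId)))
  nTrue <- table(factor(sim$truth$readId, levels = unique(sim$truth$readId)))
  expect_true(all(nRec <= nTrue))
})

test_that("search-only structures report matching reads unmodified", {
  rs <- readStructure(flankSegment("ACGTACGTGGCCAATT", "target"),
                      flankMaxDist = 2)
  set.seed(49)
  yes <- paste0(randSeq(20), "ACGTACGTGGCCAATT", randSeq(20))
  near <- paste0(randSeq(20), "ACGTACGAGGCCAATT", randSeq(20))  # 1 mismatch
  no <- randSeq(56)
  reads <- ReadSet(c("a", "b", "c"), c(yes, near, no))
  df <- demultiplex(reads, rs, quiet = TRUE)
  expect_identical(df$status[df$readId == "a"], "MATCHED")
  expect_identical(df$status[df$readId == "b"], "MATCHED")
  expect_identical(df$status[df$readId == "c"], "NO_FLANK")
  expect_identical(df$flankDist[df$readId == "b"], 1L)
})
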