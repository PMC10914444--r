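test_that("FASTQ records parse with ids, descriptions and qualities", {
  fq <- tempfile(fileext = ".fastq")
  writeLines(c("@r1 first read", "ACGTACGT", "+", "IIIIFFFF",
               "@r2", "GGTT", "+", "!!!!"), fq)
  r <- readReads(fq)
  expect_identical(length(r), 2L)
  expect_identical(readIds(r), c("r1", "r2"))
  expect_identical(r@description, c("first read", ""))
  expect_identical(sequences(r), c("ACGTACGT", "GGTT"))
  expect_identical(qualities(r), c("IIIIFFFF", "!!!!"))
})

test_that("gzip input is transparent", {
  fq <- tempfile(fileext = ".fastq")
  writeLines(c("@r1", "ACGTACGT", "+", "IIIIIIII"), fq)
  gz <- tempfile(fileext = ".fastq.gz")
  con <- gzfile(gz, "wt")
  writeLines(readLines(fq), con)
  close(con)
  expect_identical(as.data.frame(readReads(gz)),
                   as.data.frame(readReads(fq)))
})

test_that("wrapped multi-line FASTA is concatenated", {
  fa <- tempfile(fileext = ".fasta")
  set.seed(61)
  s <- randSeq(150)
  writeLines(c(">long read",
               substr(s, 1, 60), substr(s, 61, 120), substr(s, 121, 150),
               ">short", "ACGT"), fa)
  r <- readReads(fa)
  expect_identical(sequences(r), c(s, "ACGT"))
  expect_true(all(is.na(qualities(r))))
})

test_that("round trips are byte-exact for unwrapped output", {
  set.seed(62)
  n <- 100L
  seqs <- vapply(1:n, function(i) randSeq(sample(10:80, 1)), "")
  quals <- vapply(nchar(seqs), function(l)
    paste(sample(strsplit(rawToChar(as.raw(33:73)), "")[[1]], l,
                 replace = TRUE), collapse = ""), "")
  r <- ReadSet(sprintf("read%03d", 1:n), seqs, quality = quals,
               description = ifelse(1:n %% 3 == 0, "desc text", ""))
  fq <- tempfile(fileext = ".fastq")
  writeReads(r, fq, format = "fastq")
  r2 <- readReads(fq)
  fq2 <- tempfile(fileext = ".fastq")
  writeReads(r2, fq2, format = "fastq")
  expect_identical(readLines(fq), readLines(fq2))
  expect_identical(as.data.frame(r), as.data.frame(r2))
  # FASTA round trip and quality dropping
  fa <- tempfile(fileext = ".fasta")
  writeReads(r, fa, format = "fasta")
  r3 <- readReads(fa)
  expect_identical(sequences(r3), sequences(r))
  expect_true(all(is.na(qualities(r3))))
  # gz round trip
  gz <- tempfile(fileext = ".fastq.gz")
  writeReads(r, gz, format = "fastq")
  expect_identical(as.data.frame(readReads(gz)), as.data.frame(r2))
})

test_that("FASTQ output without qualities fabricates flagged constant scores", {
  r <- ReadSet("r1", "ACGT")
  fq <- tempfile(fileext = ".fastq")
  expect_message(writeReads(r, fq, format = "fastq"), "fabricating")
  expect_identical(readLines(fq), c("@r1", "ACGT", "+", "IIII"))
})

test_that("malformed input fails with the offending record index", {
  bad <- tempfile()
  writeLines(c("@r1", "ACGT", "+", "IIII", "@r2", "ACGT", "+", "III"), bad)
  expect_error(readReads(bad), "mismatch at record index 2")
  trunc <- tempfile()
  writeLines(c("@r1", "ACGT", "+", "IIII", "@r2", "ACGT"), trunc)
  expect_error(readReads(trunc), "truncated FASTQ record at record index 2")
  junk <- tempfile()
  writeLines(c("not a fasta", "ACGT"), junk)
  expect_error(readReads(junk), "cannot detect")
  emptyRec <- tempfile()
  writeLines(c(">r1", ">r2", "ACGT"), emptyRec)
  expect_error(readReads(emptyRec), "empty sequence .* record index 1")
})

test_that("empty input is an empty stream, not an error", {
  empty <- tempfile()
  file.create(empty)
  r <- readReads(empty)
  expect_identical(length(r), 0L)
})

test_that("chunked streaming preserves record order and content", {
  set.seed(63)
  n <- 2000L
  r <- ReadSet(sprintf("read%05d", 1:n),
               vapply(1:n, function(i) randSeq(sample(20:60, 1)), ""))
  fa <- tempfile(fileext = ".fasta")
  writeReads(r, fa)
  st <- openReads(fa)
  got <- list()
  repeat {
    ch <- st$nextChunk(37)
    if (is.null(ch)) break
    expect_lte(length(ch), 37L)
    got[[length(got) + 1L]] <- ch
  }
  st$close()
  all <- do.call(c, lapply(got, readIds))
  expect_identical(all, readIds(r))
})

test_that("the reader agrees with Biostrings on the same files", {
  skip_if_not_installed("Biostrings")
  set.seed(64)
  n <- 50L
  r <- ReadSet(sprintf("r%02d", 1:n),
               vapply(1:n, function(i) randSeq(sample(30:90, 1)), ""))
  fa <- tempfile(fileext = ".fasta")
  writeReads(r, fa)
  bs <- Biostrings::readDNAStringSet(fa)
  expect_identical(unname(as.character(bs)), sequences(readReads(fa)))
  expect_identical(names(bs), readIds(r))
  fq <- tempfile(fileext = ".fastq")
  writeReads(ReadSet(r@id, r@sequence,
                     quality = strrep("F", nchar(r@sequence))), fq,
             format = "fastq")
  bq <- Biostrings::readDNAStringSet(fq, format = "fastq")
  expect_identical(unname(as.character(bq)), sequences(r))
})

test_that("assignment and count tables round-trip through their TSV forms", {
  sim <- simulateReads(simConfig(nReads = 30, nBarcodes = 4, seed = 65))
  a <- demultiplex(sim$reads, tenXv3Structure(), whitelist = sim$whitelist,
                   quiet = TRUE)
  tsv <- tempfile(fileext = ".tsv")
  writeAssignments(a, tsv)
  lines <- readLines(tsv)
  expect_true(startsWith(lines[1], "#read_id\t"))
  expect_identical(length(lines), nrow(a) + 1L)
  counts <- data.frame(barcode = c("AAAA", "CCCC", "GGGG"),
                       count = c(5L, 10L, 2L))
  ct <- tempfile(fileext = ".tsv")
  writeBarcodeCounts(counts, ct)
  back <- readBarcodeCounts(ct)
  expect_identical(back$barcode, c("CCCC", "AAAA", "GGGG"))
  expect_identical(back$count, c(10L, 5L, 2L))
})
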