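test_that("adapter trimming removes a full internal adapter occurrence", {
  read <- paste0("TTTGGATTGAAGGGAGCTCTA", ADAPTER)
  tr <- trim_adapter(substr(read, 1, 36), ADAPTER)
  expect_equal(tr$seq, "TTTGGATTGAAGGGAGCTCTA")
  expect_false(tr$no_adapter)
})

test_that("trimming falls back to the longest suffix-prefix overlap", {
  insert <- "ACGTACGTACGTACGTACGTACGTACGT"  # 28 nt: only 8 adapter nt fit
  read <- substr(paste0(insert, ADAPTER), 1, 36)
  tr <- trim_adapter(read, ADAPTER)
  expect_equal(tr$seq, insert)
  expect_false(tr$no_adapter)
})

test_that("reads without adapter evidence are flagged, not modified", {
  read <- strrep("G", 30)  # no adapter content at all
  tr <- trim_adapter(read, ADAPTER)
  expect_true(tr$no_adapter)
  expect_equal(tr$seq, read)
  # overlap below min_overlap is not trimmed
  short_ov <- paste0(strrep("G", 25), substr(ADAPTER, 1, 5))
  tr2 <- trim_adapter(short_ov, ADAPTER, min_overlap = 6)
  expect_true(tr2$no_adapter)
})

test_that("trimming recovers every planted insert exactly (manifest oracle)", {
  cfg <- sim_config(seed = 31)
  ref <- generate_reference(cfg)
  reads <- vapply(ref$manifest$mature_seq, function(m)
    substr(paste0(m, ADAPTER, strrep("A", 36)), 1, 36), character(1),
    USE.NAMES = FALSE)
  tr <- trim_adapter(reads, ADAPTER)
  expect_false(any(tr$no_adapter))
  expect_equal(tr$seq, ref$manifest$mature_seq)
})

test_that("classification assigns the documented categories", {
  set.seed(71)
  good <- substr(paste0(rand_dna(21), ADAPTER), 1, 36)
  too_long <- substr(paste0(rand_dna(26), ADAPTER), 1, 36)  # 26 nt insert
  too_short <- substr(paste0(rand_dna(16), ADAPTER, strrep("A", 20)), 1, 36)
  polya <- substr(paste0(strrep("A", 22), ADAPTER), 1, 36)
  with_n <- substr(paste0(paste0(rand_dna(10), "N", rand_dna(9)), ADAPTER),
                   1, 36)
  crs <- classify_and_filter(c(good, too_long, too_short, polya, with_n),
                             adapter = ADAPTER)
  acct <- crs$accounting
  get <- function(cat) acct$total_a[acct$category == cat]
  expect_equal(get("Raw reads"), 5)
  expect_equal(get("3ADT&length filter"), 2)
  expect_equal(get("Junk reads"), 2)
  expect_equal(get("Clean reads"), 1)
  expect_equal(crs$reads$seq, trim_adapter(good, ADAPTER)$seq)
})

test_that("accounting is a strict partition of the raw reads", {
  cfg <- sim_config(seed = 32, depth_per_library = 3000)
  libs <- generate_libraries(generate_reference(cfg))
  crs <- classify_and_filter(libs$reads_a, libs$reads_b, adapter = ADAPTER)
  acct <- crs$accounting
  raw <- acct[acct$category == "Raw reads", ]
  parts <- acct[acct$category != "Raw reads", ]
  expect_equal(sum(parts$total_a), raw$total_a)
  expect_equal(sum(parts$total_b), raw$total_b)
  expect_equal(raw$total_a, length(libs$reads_a))
  expect_equal(raw$total_b, length(libs$reads_b))
  # collapsed counts conserve the clean totals
  expect_equal(sum(crs$reads$count_a),
               acct$total_a[acct$category == "Clean reads"])
  expect_equal(sum(crs$reads$count_b),
               acct$total_b[acct$category == "Clean reads"])
})

test_that("collapsing counts each unique sequence once with true multiplicity", {
  set.seed(72)
  ins <- replicate(5, rand_dna(21))
  mult_a <- c(7, 3, 0, 2, 1)
  mult_b <- c(0, 4, 5, 2, 1)
  mk <- function(m) substr(paste0(m, ADAPTER), 1, 36)
  ra <- rep(vapply(ins, mk, character(1)), mult_a)
  rb <- rep(vapply(ins, mk, character(1)), mult_b)
  crs <- classify_and_filter(sample(ra), sample(rb), adapter = ADAPTER)
  expect_equal(nrow(crs$reads), sum(mult_a + mult_b > 0))
  for (i in seq_along(ins)) {
    if (mult_a[i] + mult_b[i] == 0) next
    row <- crs$reads[crs$reads$seq == ins[i], ]
    expect_equal(row$count_a, mult_a[i])
    expect_equal(row$count_b, mult_b[i])
  }
  # sorted by decreasing total count, ties by sequence
  tot <- crs$reads$count_a + crs$reads$count_b
  expect_true(all(diff(tot) <= 0))
})

test_that("cleaning already-clean inserts is idempotent", {
  set.seed(73)
  ins <- replicate(10, rand_dna(sample(18:25, 1)))
  reads <- vapply(ins, function(m) substr(paste0(m, ADAPTER), 1, 36),
                  character(1))
  crs1 <- classify_and_filter(reads, adapter = ADAPTER)
  # feed the clean sequences back through (they carry no adapter and are
  # within the raw window, so they survive unchanged)
  crs2 <- classify_and_filter(rep(crs1$reads$seq, crs1$reads$count_a),
                              adapter = ADAPTER)
  expect_equal(crs2$reads$seq, crs1$reads$seq)
  expect_equal(crs2$reads$count_a, crs1$reads$count_a)
})

test_that("clean reads round-trip through FASTA and TSV writers", {
  set.seed(74)
  reads <- vapply(replicate(4, rand_dna(20)), function(m)
    substr(paste0(m, ADAPTER), 1, 36), character(1))
  crs <- classify_and_filter(reads, reads[1:2], adapter = ADAPTER)
  fa <- withr::local_tempfile(fileext = ".fasta")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_clean_reads(crs, fa, tsv)
  back <- Biostrings::readDNAStringSet(fa)
  expect_equal(as.character(back), crs$reads$seq, ignore_attr = TRUE)
  expect_match(names(back)[1], "^uid1_count_A=\\d+;count_B=\\d+$")
  tab <- read.delim(tsv, stringsAsFactors = FALSE)
  expect_equal(tab$seq, crs$reads$seq)
  acc <- withr::local_tempfile(fileext = ".tsv")
  got <- write_accounting(crs, acc)
  expect_equal(got$pct_a[got$category == "Raw reads"], 100)
})

test_that("fastq reading returns plain sequences", {
  fq <- withr::local_tempfile(fileext = ".fastq")
  writeLines(c("@r1", "ACGTACGT", "+", "IIIIIIII",
               "@r2", "GGGTTTAA", "+", "IIIIIIII"), fq)
  expect_equal(read_fastq_seqs(fq), c(r1 = "ACGTACGT", r2 = "GGGTTTAA"),
               ignore_attr = TRUE)
})
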