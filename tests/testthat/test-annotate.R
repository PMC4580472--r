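test_that("contaminant classes follow the fixed precedence order", {
  seed_frag <- "GATTACAGATTACAGATTAC"
  cat <- reference_catalog(
    contaminants = list(
      rRNA = c(r = paste0("CCC", seed_frag, "CCC")),
      tRNA = c(t = paste0("GGG", seed_frag, "GGG"))),
    mirnas = NULL)
  reads <- data.frame(seq = seed_frag, count_a = 3, count_b = 1,
                      stringsAsFactors = FALSE)
  out <- classify_contaminants(reads, cat)
  expect_equal(out$class, "rRNA")  # in both, rRNA wins
})

test_that("contaminant matching also checks the reverse complement strand", {
  frag <- "GATTACAGATTACAGATTAC"
  cat <- reference_catalog(
    contaminants = list(tRNA = c(t = paste0("AA", rc(frag), "AA"))))
  out <- classify_contaminants(
    data.frame(seq = frag, count_a = 1, count_b = 0,
               stringsAsFactors = FALSE), cat)
  expect_equal(out$class, "tRNA")
  out2 <- classify_contaminants(
    data.frame(seq = "TTTTTTTTTTTTTTTTGGGG", count_a = 1, count_b = 0,
               stringsAsFactors = FALSE), cat)
  expect_equal(out2$class, "none")
})

test_that("an exact catalog match carries the empty suffix", {
  cat <- toy_catalog()
  reads <- data.frame(seq = "TTTGGATTGAAGGGAGCTCTA", count_a = 5, count_b = 2,
                      stringsAsFactors = FALSE)
  hits <- match_known(reads, cat)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$name, "tae-miR159a")
  expect_equal(hits$suffix, "")
  expect_equal(hits$full_name, "tae-miR159a")
  expect_equal(hits$family, "miR159")
  expect_equal(hits$count_a, 5)
})

test_that("end-shift and substitution variants get the documented suffixes", {
  cat <- toy_catalog()
  ref <- "TTTGGATTGAAGGGAGCTCTA"  # tae-miR159a
  # one extra base on the right end
  r_plus1 <- paste0(ref, "T")
  # one base missing on the left, plus a substitution at detected position 11
  l_minus1 <- substr(ref, 2, nchar(ref))
  sub_read <- l_minus1
  substr(sub_read, 11, 11) <- "C"   # reference base at that spot is G
  stopifnot(substr(l_minus1, 11, 11) == "G")
  hits <- match_known(
    data.frame(seq = c(r_plus1, sub_read), count_a = c(1, 1),
               count_b = c(0, 0), stringsAsFactors = FALSE), cat)
  expect_equal(hits$suffix[hits$seq == r_plus1], "_R+1")
  expect_equal(hits$suffix[hits$seq == sub_read], "_L-1_1ss11GC")
  expect_equal(hits$full_name[hits$seq == sub_read],
               "tae-miR159a_L-1_1ss11GC")
})

test_that("reads beyond the shift or mismatch budget are not matched", {
  cat <- toy_catalog()
  ref <- "TTTGGATTGAAGGGAGCTCTA"
  three_left <- substr(ref, 4, nchar(ref))          # left shift -3
  two_subs <- ref
  substr(two_subs, 5, 5) <- "C"; substr(two_subs, 9, 9) <- "T"
  stopifnot(two_subs != ref)
  hits <- match_known(
    data.frame(seq = c(three_left, two_subs), count_a = 1, count_b = 1,
               stringsAsFactors = FALSE), cat)
  expect_false(three_left %in% hits$seq)
  expect_false(two_subs %in% hits$seq)
})

test_that("best-hit selection matches an exhaustive oracle on random variants", {
  cat <- toy_catalog()
  set.seed(81)
  for (i in 1:50) {
    ref <- sample(cat$mirnas$mature, 1)
    s <- ref
    # random end shifts within budget
    ls <- sample(-2:2, 1); rs <- sample(-2:2, 1)
    if (ls > 0) s <- paste0(rand_dna(ls), s)
    if (ls < 0) s <- substr(s, 1 - ls, nchar(s))
    if (rs > 0) s <- paste0(s, rand_dna(rs))
    if (rs < 0) s <- substr(s, 1, nchar(s) + rs)
    if (runif(1) < 0.5) {  # one substitution inside the overlap
      p <- sample(seq_len(nchar(s)), 1)
      substr(s, p, p) <- sample(c("A", "C", "G", "T"), 1)
    }
    hits <- match_known(data.frame(seq = s, count_a = 1, count_b = 0,
                                   stringsAsFactors = FALSE), cat)
    oracle <- bf_best_hit(s, cat)
    if (is.null(oracle)) {
      expect_equal(nrow(hits), 0, info = s)
    } else {
      expect_equal(nrow(hits), 1, info = s)
      expect_equal(hits$name, oracle$name, info = s)
      expect_equal(hits$n_sub, oracle$n_sub, info = s)
    }
  }
})

test_that("species priority breaks ties between identical matures", {
  matures <- data.frame(
    name = c("osa-miR399a", "cre-miR399a"),
    species = c("osa", "cre"),
    mature = "TGCCAAAGGAGAGTTGCCCTG",
    stringsAsFactors = FALSE)
  cat_cre <- reference_catalog(mirnas = matures,
                               species_priority = c("cre", "osa"))
  cat_osa <- reference_catalog(mirnas = matures,
                               species_priority = c("osa", "cre"))
  reads <- data.frame(seq = "TGCCAAAGGAGAGTTGCCCTG", count_a = 1, count_b = 0,
                      stringsAsFactors = FALSE)
  expect_equal(match_known(reads, cat_cre)$name, "cre-miR399a")
  expect_equal(match_known(reads, cat_osa)$name, "osa-miR399a")
})

test_that("family assignment strips species, letters and arm designations", {
  expect_equal(assign_family(c("tae-miR159a", "osa-miR168a-5p", "xxx-foo")),
               c("miR159", "miR168", "unknown"))
})

test_that("annotation partitions the unique reads exactly", {
  cfg <- sim_config(seed = 33, depth_per_library = 4000)
  libs <- generate_libraries(generate_reference(cfg))
  crs <- classify_and_filter(libs$reads_a, libs$reads_b, adapter = ADAPTER)
  ann <- annotate_reads(crs, libs$reference$catalog)
  n_cont <- nrow(ann$contaminants)
  n_hits <- nrow(ann$hits)
  n_rem <- nrow(ann$remainder)
  expect_equal(n_cont + n_hits + n_rem, nrow(crs$reads))
  expect_length(intersect(ann$hits$seq, ann$remainder$seq), 0)
  expect_length(intersect(ann$hits$seq, ann$contaminants$seq), 0)
  # every known planted mature is recovered as an exact hit
  man <- libs$reference$manifest
  known_present <- man$known & (man$expected_a + man$expected_b > 0)
  expect_true(all(man$mature_seq[known_present] %in% ann$hits$seq))
  # the contaminant report percentages are anchored to the raw totals
  rep <- contaminant_report(ann$assigned,
                            raw_total_a = length(libs$reads_a),
                            raw_total_b = length(libs$reads_b))
  expect_true(all(rep$pct_total_a >= 0 & rep$pct_total_a <= 100))
  expect_equal(rep$pct_total_a,
               pct(rep$total_a, length(libs$reads_a)))
})

test_that("an empty catalog warns and yields no hits", {
  cat <- reference_catalog()
  reads <- data.frame(seq = "TTTGGATTGAAGGGAGCTCTA", count_a = 1, count_b = 0,
                      stringsAsFactors = FALSE)
  expect_warning(hits <- match_known(reads, cat), "empty")
  expect_equal(nrow(hits), 0)
})
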