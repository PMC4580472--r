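test_that("window extraction does the stated flank arithmetic", {
  contig <- strrep("A", 200)
  w <- extract_windows(contig, 100, 121, flank = 60)
  expect_equal(w$start, c(40, 100, 40))
  expect_equal(w$end, c(121, 181, 181))
  expect_equal(w$mature_start, c(61, 1, 61))
  expect_equal(w$mature_end, c(82, 22, 82))
})

test_that("windows truncate at contig bounds", {
  contig <- strrep("A", 100)
  w <- extract_windows(contig, 5, 26, flank = 60)
  expect_equal(w$start[w$window == "upstream"], 1)
  expect_equal(w$end[w$window == "downstream"], 86)
  expect_equal(w$mature_start[w$window == "upstream"], 5)
})

test_that("a perfect designed hairpin passes all eleven criteria", {
  set.seed(61)
  d <- make_designed_hairpin(n_bp = 24, k = 12, loop_len = 8, energy = -40)
  # mature = 20 nt fully inside the 5' arm pairs
  rep <- evaluate_hairpin(d$structure, 1, 20)
  expect_true(attr(rep, "overall"))
  expect_equal(rep$value[rep$criterion == "stem_bp"], 24)
  expect_equal(rep$value[rep$criterion == "mature_bp"], 20)
  expect_equal(rep$value[rep$criterion == "pct_mature_in_stem"], 100)
})

test_that("a 13 nt stem bulge fails the bulge criterion only", {
  set.seed(62)
  d <- make_designed_hairpin(n_bp = 24, k = 12, loop_len = 8, bulge5 = 13,
                             energy = -40)
  rep <- evaluate_hairpin(d$structure, 1, 12)  # mature on clean P1 pairs
  expect_false(attr(rep, "overall"))
  expect_equal(rep$value[rep$criterion == "max_stem_bulge_nt"], 13)
  expect_false(rep$pass[rep$criterion == "max_stem_bulge_nt"])
  expect_true(all(rep$pass[rep$criterion != "max_stem_bulge_nt"]))
})

test_that("an energy above -15 kcal/mol fails the energy criterion", {
  set.seed(63)
  d <- make_designed_hairpin(n_bp = 24, k = 12, loop_len = 8, energy = -14)
  rep <- evaluate_hairpin(d$structure, 1, 20)
  expect_false(rep$pass[rep$criterion == "free_energy"])
  expect_false(attr(rep, "overall"))
})

test_that("criteria flags on 30 random designed hairpins equal the
           construction-time ground truth", {
  set.seed(64)
  for (i in 1:30) {
    n_bp <- sample(14:30, 1)
    k <- sample(seq(4, n_bp - 4), 1)
    loop_len <- sample(c(3:8, 150, 201, 230), 1)
    bulge5 <- sample(c(0, 0, 2, 5, 13, 15), 1)
    energy <- sample(c(-40, -20, -14, -10), 1)
    d <- make_designed_hairpin(n_bp, k, loop_len, bulge5 = bulge5,
                               energy = energy)
    m_len <- min(12, k)
    rep <- evaluate_hairpin(d$structure, 1, m_len)
    expected <- c(
      max_stem_bulge_nt = bulge5 <= 12,
      stem_bp = n_bp >= 16,
      free_energy = energy <= -15,
      hairpin_len = d$len >= 50,
      loop_len = loop_len <= 200,
      mature_bp = m_len >= 12)
    got <- setNames(rep$pass, rep$criterion)[names(expected)]
    expect_equal(unname(got), unname(expected),
                 info = sprintf("case %d: n_bp=%d k=%d loop=%d bulge=%d e=%g",
                                i, n_bp, k, loop_len, bulge5, energy))
    # mature on clean pairs: mature-region criteria must pass
    expect_true(all(rep$pass[rep$criterion %in%
                               c("max_mature_bulge_nt",
                                 "mature_biased_errors",
                                 "mature_biased_bulges", "mature_errors")]))
  }
})

test_that("mature-region bulge and bias metrics see a planted one-arm bulge", {
  set.seed(65)
  d <- make_designed_hairpin(n_bp = 24, k = 12, loop_len = 8, bulge5 = 3,
                             energy = -40)
  # mature spans P1 tail + the 3 nt gap + P2 head: positions 8..27
  rep <- evaluate_hairpin(d$structure, 8, 27)
  expect_equal(rep$value[rep$criterion == "max_mature_bulge_nt"], 3)
  expect_equal(rep$value[rep$criterion == "mature_biased_errors"], 3)
  expect_equal(rep$value[rep$criterion == "mature_biased_bulges"], 1)
  expect_equal(rep$value[rep$criterion == "mature_errors"], 0)
  expect_equal(rep$value[rep$criterion == "mature_bp"], 20 - 3)
})

test_that("a structure with no hairpin loop fails with undefined stem metrics", {
  st <- fold_rna(strrep("A", 60))
  rep <- evaluate_hairpin(st, 1, 20)
  expect_false(attr(rep, "overall"))
  expect_true(all(is.na(rep$value[rep$criterion == "stem_bp"])))
})

test_that("evaluate is pure: identical inputs give identical reports", {
  set.seed(66)
  d <- make_designed_hairpin(n_bp = 20, k = 10, loop_len = 6)
  r1 <- evaluate_hairpin(d$structure, 1, 15)
  r2 <- evaluate_hairpin(d$structure, 1, 15)
  expect_identical(r1, r2)
})

test_that("precursor stats count length and GC directly", {
  expect_equal(precursor_stats("GGCC")$gc_pct, 100)
  expect_equal(precursor_stats("CAAAATGGGCGGCAAGAAAGGCT")$length, 23)
  set.seed(67)
  s <- rand_dna(100)
  b <- strsplit(s, "")[[1]]
  expect_equal(precursor_stats(s)$gc_pct,
               round(100 * sum(b %in% c("G", "C")) / 100, 2))
})

test_that("mapping finds exact loci and reports non-mapping reads", {
  tx <- c(c1 = paste0(strrep("A", 50), "GATTACAGATTACAGATCGCG",
                      strrep("T", 50)))
  hit <- map_to_transcriptome("GATTACAGATTACAGATCGCG", tx)
  expect_equal(nrow(hit), 1)
  expect_equal(hit$start, 51)
  expect_equal(hit$end, 71)
  expect_equal(nrow(map_to_transcriptome("CCCCCCCCCCCCCCCCC", tx)), 0)
})

test_that("discovery accepts a planted precursor and emits GFF", {
  cfg <- sim_config(seed = 5, fold_change_spec = list(1, 1, 1),
                    known_fraction = 0)
  ref <- generate_reference(cfg)
  reads <- data.frame(seq = ref$manifest$mature_seq,
                      count_a = 1, count_b = 1, stringsAsFactors = FALSE)
  cand <- discover_hairpins(reads, ref$transcriptome)
  expect_setequal(cand$mature_seq, ref$manifest$mature_seq)
  # the kept window contains the planted mature locus
  for (i in seq_len(nrow(cand))) {
    man <- ref$manifest[ref$manifest$mature_seq == cand$mature_seq[i], ]
    expect_equal(cand$contig[i], man$contig)
    expect_lte(cand$precursor_start[i], man$mature_start)
    expect_gte(cand$precursor_end[i], man$mature_end)
  }
  gff <- withr::local_tempfile(fileext = ".gff3")
  write_hairpin_gff(cand, gff)
  expect_true(any(grepl("miRNA_primary_transcript", readLines(gff))))
})
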