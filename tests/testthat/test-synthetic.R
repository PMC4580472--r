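test_that("generation is deterministic under a fixed seed", {
  cfg <- sim_config(seed = 41, depth_per_library = 2000)
  r1 <- generate_reference(cfg)
  r2 <- generate_reference(cfg)
  expect_identical(r1$transcriptome, r2$transcriptome)
  expect_identical(r1$manifest, r2$manifest)
  l1 <- generate_libraries(r1)
  l2 <- generate_libraries(r2)
  expect_identical(l1$reads_a, l2$reads_a)
  expect_identical(l1$reads_b, l2$reads_b)
  # a different seed changes the transcriptome
  r3 <- generate_reference(sim_config(seed = 42, depth_per_library = 2000))
  expect_false(identical(r1$transcriptome, r3$transcriptome))
})

test_that("written simulations are byte-identical across runs", {
  cfg <- sim_config(seed = 43, depth_per_library = 500)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_simulation(generate_libraries(generate_reference(cfg)), d1)
  write_simulation(generate_libraries(generate_reference(cfg)), d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), info = f)
  }
})

test_that("zero planted miRNAs yields a consistent empty manifest", {
  cfg <- sim_config(seed = 44, n_planted_mirnas = 0,
                    fold_change_spec = list())
  ref <- generate_reference(cfg)
  expect_equal(nrow(ref$manifest), 0)
  expect_equal(nrow(ref$catalog$mirnas), 0)
  libs <- generate_libraries(ref, depth_per_library = 1000)
  # only contaminant/junk/out-of-window reads remain
  expect_true(all(libs$truth$class %in%
                    c(names(ref$contaminants), "junk_polyA", "junk_N",
                      "oob_long", "oob_short", "oob_noadapter")))
})

test_that("zero depth warns and emits empty libraries", {
  cfg <- sim_config(seed = 45, depth_per_library = 0)
  ref <- generate_reference(cfg)
  expect_warning(libs <- generate_libraries(ref), "depth 0")
  expect_length(libs$reads_a, 0)
  expect_length(libs$reads_b, 0)
})

test_that("planted matures are unique and map to a single locus", {
  cfg <- sim_config(seed = 46)
  ref <- generate_reference(cfg)
  man <- ref$manifest
  expect_false(any(duplicated(man$mature_seq)))
  for (i in seq_len(nrow(man))) {
    hit <- map_to_transcriptome(man$mature_seq[i], ref$transcriptome)
    expect_equal(nrow(hit), 1)
    expect_equal(hit$contig, man$contig[i])
    expect_equal(hit$start, man$mature_start[i])
    expect_equal(hit$end, man$mature_end[i])
  }
})

test_that("every planted precursor passes the full hairpin criteria", {
  cfg <- sim_config(seed = 47)
  ref <- generate_reference(cfg)
  man <- ref$manifest
  for (i in seq_len(nrow(man))) {
    prec <- substr(ref$transcriptome[[man$contig[i]]],
                   man$precursor_start[i], man$precursor_end[i])
    st <- fold_rna(prec)
    rep <- evaluate_hairpin(st,
                            man$mature_start[i] - man$precursor_start[i] + 1L,
                            man$mature_end[i] - man$precursor_start[i] + 1L)
    expect_true(attr(rep, "overall"), info = man$id[i])
    expect_lte(st$energy, -15)
  }
})

test_that("deterministic mode reproduces the manifest's expected counts", {
  cfg <- sim_config(seed = 48, depth_per_library = 5000)
  ref <- generate_reference(cfg)
  libs <- generate_libraries(ref, mode = "deterministic")
  expect_equal(libs$counts$count_a, ref$manifest$expected_a)
  expect_equal(libs$counts$count_b, ref$manifest$expected_b)
  # and the emitted reads really carry those multiplicities
  for (i in seq_len(nrow(ref$manifest))) {
    rd <- substr(paste0(ref$manifest$mature_seq[i], cfg$adapter_seq,
                        strrep("A", 36)), 1, 36)
    expect_equal(sum(libs$reads_a == rd), ref$manifest$expected_a[i],
                 info = ref$manifest$id[i])
    expect_equal(sum(libs$reads_b == rd), ref$manifest$expected_b[i],
                 info = ref$manifest$id[i])
  }
})

test_that("present-in-one-library sentinels are exactly absent from the other", {
  cfg <- sim_config(seed = 49)
  ref <- generate_reference(cfg)
  man <- ref$manifest
  only_a <- man[man$ratio == "only-A", ]
  only_b <- man[man$ratio == "only-B", ]
  expect_gte(nrow(only_a), 1)
  expect_gte(nrow(only_b), 1)
  expect_true(all(only_a$expected_b == 0))
  expect_true(all(only_a$expected_a > 0))
  expect_true(all(only_b$expected_a == 0))
})

test_that("multinomial counts recover the planted ratio at high depth", {
  cfg <- sim_config(seed = 50, fold_change_spec = list(4, 1),
                    depth_per_library = 20000)
  ref <- generate_reference(cfg)
  libs <- generate_libraries(ref, mode = "multinomial",
                             depth_per_library = 1e5)
  cnt <- libs$counts
  man <- ref$manifest
  for (i in 1:2) {
    ea <- man$expected_a[i] * 5  # depth scaled x5
    # binomial SE of a multinomial cell around its expectation
    n_tot <- sum(man$expected_a) * 5
    p <- ea / n_tot
    se <- sqrt(n_tot * p * (1 - p))
    expect_lt(abs(cnt$count_a[i] - ea), 3 * se + 1)
  }
})

test_that("configuration validation rejects impossible geometries", {
  expect_error(sim_config(contig_len = 100), "too short")
  expect_error(sim_config(n_contigs = 2, fold_change_spec = as.list(rep(1, 6))),
               "slots")
  expect_error(sim_config(fold_change_spec = list(-2)), "positive")
  expect_error(sim_config(mature_len_range = c(10, 24)))
})
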