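# Seeded synthetic-data generator: a toy transcriptome with planted miRNA
# hairpin precursors, contaminant ncRNA references, a known-miRNA catalog,
# and two small RNA libraries with known per-miRNA abundance ratios plus a
# truth manifest.
#
# Precursor design. Each planted precursor is a perfect stem-loop
#   [flankL][mature]  [loop]  [revcomp(mature)][revcomp(flankL)]
# with |flankL| = 48 - |mature| and a 12 nt loop, i.e. 48 nt arms and a fixed
# 108 nt precursor. The loop is drawn from {A,C} (which cannot base-pair with
# itself) and the 3' tail revcomp(flankL) from an alphabet chosen so that it
# can pair neither with itself nor with the first mature base; under the
# package's maximum-base-pairing folder the designed stem is then provably
# the optimal structure of the right-hand extraction window
# [mature_start, mature_end + 60], which equals mature+loop+3'arm exactly.
# That makes planted-precursor recall deterministic, not statistical.

.SIM_LOOP_LEN <- 12L
.SIM_ARM_LEN <- 48L

# alphabet for the 3' tail given the first mature base: no self-pairing and
# no pairing with that base (A:T, C:G, G:{C,T}, T:{A,G} under wobble rules)
.tail_alphabet <- function(first_base) {
  switch(first_base,
         A = c("A", "C"), C = c("A", "C"),
         G = c("A", "G"), T = c("C", "T"),
         c("A", "C"))
}

#' Default fold-change specification of the simulator
#'
#' Twelve between-library abundance ratios mirroring the magnitudes of the
#' motivating study's differentially expressed miRNAs: log2 ratios
#' -2.06, -2.05, -1.11, 1.12, 1.21, 1.23, 1.23, 1.23, 1.38, 1.79 plus one
#' present-in-A-only and one present-in-B-only miRNA.
#'
#' @return character/numeric list of ratios: numeric A/B ratios, or the
#'   sentinels `"only-A"` / `"only-B"`.
#' @export
default_fold_changes <- function() {
  lfc <- c(-2.06, -2.05, -1.11, 1.12, 1.21, 1.23, 1.23, 1.23, 1.38, 1.79)
  c(as.list(2^lfc), list("only-A", "only-B"))
}

#' Simulation configuration
#'
#' @param seed integer RNG seed; a fixed seed makes all outputs
#'   byte-identical across runs.
#' @param n_contigs,contig_len toy transcriptome dimensions (defaults 8 x
#'   600 nt).
#' @param n_planted_mirnas number of planted miRNAs (default: length of
#'   `fold_change_spec`).
#' @param mature_len_range inclusive mature length range, within 18-25
#'   (default 20-24).
#' @param flank_design fraction of designed stem positions kept complementary
#'   in the 3' arm (default 1 = perfect stem; lower values plant mismatches).
#' @param n_contaminants named vector of reference-sequence counts per class
#'   (default 2 rRNA, 2 tRNA, 1 snoRNA, 1 snRNA, 1 repeats).
#' @param adapter_seq 3' adapter (default the Illumina small RNA adapter
#'   TGGAATTCTCGGGTGCCAAGG).
#' @param read_len platform read length in nt (default 36).
#' @param depth_per_library reads per library (default 20000).
#' @param fold_change_spec list of per-miRNA A/B ratios (> 0) or the
#'   sentinels `"only-A"`/`"only-B"`; recycled to `n_planted_mirnas`.
#'   Default [default_fold_changes()].
#' @param junk_fraction fraction of reads that are junk (poly(A) or
#'   N-containing; default 0.05).
#' @param oob_fraction fraction of reads planted outside the analysis window
#'   or without adapter, to exercise the length/adapter filter (default
#'   0.05).
#' @param contaminant_fraction fraction of reads drawn from contaminant
#'   references (default 0.15).
#' @param known_fraction fraction of planted miRNAs copied into the known
#'   catalog; the rest are novel by construction (default 0.75).
#' @return object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_contigs = 8L, contig_len = 600L,
                       n_planted_mirnas = NULL,
                       mature_len_range = c(20L, 24L), flank_design = 1,
                       n_contaminants = c(rRNA = 2L, tRNA = 2L, snoRNA = 1L,
                                          snRNA = 1L, repeats = 1L),
                       adapter_seq = "TGGAATTCTCGGGTGCCAAGG",
                       read_len = 36L, depth_per_library = 20000L,
                       fold_change_spec = default_fold_changes(),
                       junk_fraction = 0.05, oob_fraction = 0.05,
                       contaminant_fraction = 0.15,
                       known_fraction = 0.75) {
  if (is.null(n_planted_mirnas)) n_planted_mirnas <- length(fold_change_spec)
  stopifnot(mature_len_range[1] >= 18L, mature_len_range[2] <= 25L,
            mature_len_range[1] <= mature_len_range[2],
            flank_design >= 0, flank_design <= 1,
            junk_fraction >= 0, junk_fraction <= 1,
            oob_fraction >= 0, contaminant_fraction >= 0,
            junk_fraction + oob_fraction + contaminant_fraction < 1,
            depth_per_library >= 0, n_planted_mirnas >= 0)
  if (n_planted_mirnas > 0) {
    fold_change_spec <- rep(fold_change_spec,
                            length.out = n_planted_mirnas)
    ok <- vapply(fold_change_spec, function(r) {
      (is.numeric(r) && r > 0) || identical(r, "only-A") ||
        identical(r, "only-B")
    }, logical(1))
    if (!all(ok)) stop("ratios must be strictly positive or 'only-A'/'only-B'")
  } else {
    fold_change_spec <- list()
  }
  # a precursor needs its full 108 nt inside a contig, plus the 60 nt
  # right-hand window; 2 slots per contig are used
  prec_len <- 2L * .SIM_ARM_LEN + .SIM_LOOP_LEN
  if (contig_len < prec_len + 20L) {
    stop("contig_len ", contig_len, " too short to host a ", prec_len,
         " nt precursor; need >= ", prec_len + 20L)
  }
  if (n_planted_mirnas > 2L * n_contigs) {
    stop("not enough contig slots: ", n_planted_mirnas,
         " miRNAs need > ", 2L * n_contigs, " slots; raise n_contigs")
  }
  out <- list(seed = as.integer(seed), n_contigs = as.integer(n_contigs),
              contig_len = as.integer(contig_len),
              n_planted_mirnas = as.integer(n_planted_mirnas),
              mature_len_range = as.integer(mature_len_range),
              flank_design = flank_design,
              n_contaminants = n_contaminants,
              adapter_seq = norm_seq(adapter_seq),
              read_len = as.integer(read_len),
              depth_per_library = as.integer(depth_per_library),
              fold_change_spec = fold_change_spec,
              junk_fraction = junk_fraction, oob_fraction = oob_fraction,
              contaminant_fraction = contaminant_fraction,
              known_fraction = known_fraction,
              prec_len = prec_len)
  class(out) <- "sim_config"
  out
}

# design one precursor around a mature sequence; returns list(precursor,
# mature_offset) with the mature interval at [mature_offset,
# mature_offset + |mature| - 1] (1-based within the precursor)
.design_precursor <- function(mature, flank_design = 1) {
  m <- nchar(mature)
  tail_alpha <- .tail_alphabet(substr(mature, 1, 1))
  rc_flank <- random_seq(.SIM_ARM_LEN - m, alphabet = tail_alpha)
  flank_l <- revcomp(rc_flank)
  arm5 <- paste0(flank_l, mature)
  loop <- random_seq(.SIM_LOOP_LEN, alphabet = c("A", "C"))
  arm3 <- revcomp(arm5)
  if (flank_design < 1) {
    ch <- seq_chars(arm3)
    n_mm <- round((1 - flank_design) * length(ch))
    if (n_mm > 0) {
      pos <- sample(seq_along(ch), n_mm)
      ch[pos] <- vapply(ch[pos], function(b)
        sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
      arm3 <- paste(ch, collapse = "")
    }
  }
  list(precursor = paste0(arm5, loop, arm3),
       mature_offset = nchar(flank_l) + 1L)
}

#' Generate the synthetic reference set
#'
#' Builds, under the configured seed: a toy transcriptome with
#' `n_planted_mirnas` designed hairpin precursors planted on the plus strand;
#' per-class contaminant reference sequences; a known-miRNA catalog
#' containing `known_fraction` of the planted matures (miRBase-style names,
#' species prefix `aca`, with the first entries duplicated under a second
#' species prefix for occurrence counting); and the truth manifest. Planted
#' mature sequences are unique across the transcriptome and catalog; matures
#' whose read would not trim back exactly to themselves under the configured
#' adapter are re-drawn (up to a retry cap).
#'
#' @param config a `sim_config`.
#' @return object of class `sim_reference`: list with `transcriptome` (named
#'   character), `contaminants` (list of class -> named character), `catalog`
#'   (data.frame `name`, `species`, `mature`), `manifest` (data.frame of
#'   planted miRNAs: id, contig, precursor/mature intervals, sequence, known
#'   flag, catalog name, family, ratio, expected counts) and `config`.
#' @export
generate_reference <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  contigs <- setNames(
    vapply(seq_len(config$n_contigs), function(i)
      random_seq(config$contig_len), character(1)),
    sprintf("contig%02d", seq_len(config$n_contigs)))

  n <- config$n_planted_mirnas
  fams <- c(159L, 166L, 169L, 396L)
  manifest <- NULL
  if (n > 0) {
    # two fixed slots per contig, filled column-first
    slot_contig <- rep(seq_len(config$n_contigs), times = 2)[seq_len(n)]
    slot_idx <- rep(1:2, each = config$n_contigs)[seq_len(n)]
    slot_start <- ifelse(slot_idx == 1L, 15L,
                         config$contig_len - config$prec_len - 14L)
    if (config$contig_len < 2L * config$prec_len + 40L &&
        any(slot_idx == 2L)) {
      stop("contig_len too short for two precursor slots; raise contig_len ",
           "or n_contigs")
    }
    matures <- character(0)
    rows <- vector("list", n)
    for (i in seq_len(n)) {
      ok <- FALSE
      for (try in 1:200) {
        m_len <- sample(config$mature_len_range[1]:config$mature_len_range[2],
                        1)
        mature <- random_seq(m_len)
        des <- .design_precursor(mature, config$flank_design)
        read <- substr(paste0(mature, config$adapter_seq), 1, config$read_len)
        tr <- trim_adapter(read, config$adapter_seq)
        if (mature %in% matures) next
        if (tr$no_adapter || tr$seq != mature) next
        cn <- names(contigs)[slot_contig[i]]
        s0 <- slot_start[i]
        cand <- paste0(substr(contigs[[cn]], 1, s0 - 1L), des$precursor,
                       substr(contigs[[cn]], s0 + config$prec_len,
                              config$contig_len))
        probe <- contigs
        probe[[cn]] <- cand
        hits <- map_to_transcriptome(mature, probe)
        if (nrow(hits) != 1L) next
        contigs[[cn]] <- cand
        matures <- c(matures, mature)
        rows[[i]] <- data.frame(
          id = sprintf("pl-mir-%02d", i), contig = cn,
          precursor_start = s0,
          precursor_end = s0 + config$prec_len - 1L,
          mature_start = s0 + des$mature_offset - 1L,
          mature_end = s0 + des$mature_offset + m_len - 2L,
          mature_seq = mature, stringsAsFactors = FALSE)
        ok <- TRUE
        break
      }
      if (!ok) stop("could not design a unique plantable mature after 200 ",
                    "retries (miRNA ", i, ")")
    }
    manifest <- do.call(rbind, rows)
    n_known <- round(config$known_fraction * n)
    manifest$known <- seq_len(n) <= n_known
    fam_id <- fams[(seq_len(n) - 1L) %% length(fams) + 1L]
    manifest$family <- paste0("miR", fam_id)
    manifest$catalog_name <- ifelse(
      manifest$known,
      sprintf("aca-miR%d%s", fam_id, letters[seq_len(n)]),
      NA_character_)
    ratio_chr <- vapply(config$fold_change_spec, function(r)
      if (is.numeric(r)) formatC(r, format = "g") else r, character(1))
    manifest$ratio <- ratio_chr
  } else {
    manifest <- data.frame(id = character(0), contig = character(0),
                           precursor_start = integer(0),
                           precursor_end = integer(0),
                           mature_start = integer(0), mature_end = integer(0),
                           mature_seq = character(0), known = logical(0),
                           family = character(0), catalog_name = character(0),
                           ratio = character(0), stringsAsFactors = FALSE)
  }

  contaminants <- list()
  for (cl in names(config$n_contaminants)) {
    k <- config$n_contaminants[[cl]]
    if (k > 0) {
      contaminants[[cl]] <- setNames(
        vapply(seq_len(k), function(i) random_seq(sample(80:120, 1)),
               character(1)),
        sprintf("%s_%02d", cl, seq_len(k)))
    }
  }

  known <- manifest[manifest$known, , drop = FALSE]
  catalog_df <- data.frame(name = known$catalog_name,
                           species = rep("aca", nrow(known)),
                           mature = known$mature_seq,
                           stringsAsFactors = FALSE)
  # duplicate the first (up to) two known entries under a second species so
  # priority and occurrence counting are exercised
  if (nrow(catalog_df) >= 2) {
    dup <- catalog_df[1:2, , drop = FALSE]
    dup$species <- "osa"
    dup$name <- sub("^aca-", "osa-", dup$name)
    catalog_df <- rbind(catalog_df, dup)
  }
  catalog <- reference_catalog(
    contaminants = contaminants, mirnas = catalog_df,
    species_priority = if (nrow(catalog_df)) unique(c("aca",
                                                      catalog_df$species))
                       else character(0))

  # expected counts per library (deterministic-mode counts)
  mir_share <- 1 - config$junk_fraction - config$oob_fraction -
    config$contaminant_fraction
  if (n > 0) {
    base <- floor(mir_share * config$depth_per_library / n)
    exp_a <- numeric(n); exp_b <- numeric(n)
    for (i in seq_len(n)) {
      r <- config$fold_change_spec[[i]]
      if (identical(r, "only-A")) { exp_a[i] <- base; exp_b[i] <- 0 }
      else if (identical(r, "only-B")) { exp_a[i] <- 0; exp_b[i] <- base }
      else { exp_a[i] <- round(r * base); exp_b[i] <- base }
    }
    manifest$expected_a <- exp_a
    manifest$expected_b <- exp_b
  } else {
    manifest$expected_a <- numeric(0)
    manifest$expected_b <- numeric(0)
  }

  out <- list(transcriptome = contigs, contaminants = contaminants,
              catalog = catalog, manifest = manifest, config = config)
  class(out) <- "sim_reference"
  out
}

# build the platform read for an insert: insert + adapter, truncated/padded
# to read_len (padding with A, emulating run-off)
.platform_read <- function(insert, adapter, read_len) {
  full <- paste0(insert, adapter, strrep("A", read_len))
  substr(full, 1, read_len)
}

#' Generate the two synthetic FASTQ libraries
#'
#' Emits reads for both libraries from the reference: per planted miRNA, the
#' expected counts (deterministic mode) or a multinomial sample at the
#' configured depth with probabilities proportional to the expected counts
#' (multinomial mode); contaminant fragments (18-25 nt substrings of the
#' class references); junk reads (poly(A) and N-containing); and
#' out-of-window/adapterless reads exercising the length filter. Reads are
#' insert + 3' adapter truncated to the platform read length; qualities are
#' the constant `I`.
#'
#' @param reference a `sim_reference`.
#' @param mode `"deterministic"` (counts exactly equal the manifest's
#'   expectations) or `"multinomial"`.
#' @param depth_per_library overrides the configured depth (e.g. for power
#'   checks); in deterministic mode expected counts are rescaled accordingly.
#' @return object of class `sim_libraries`: list with `reads_a`, `reads_b`
#'   (character vectors of read sequences), `truth` (data.frame: read class
#'   per emitted read id), `counts` (per-miRNA realized counts) and
#'   `reference`.
#' @export
generate_libraries <- function(reference,
                               mode = c("deterministic", "multinomial"),
                               depth_per_library = NULL) {
  stopifnot(inherits(reference, "sim_reference"))
  mode <- match.arg(mode)
  config <- reference$config
  set.seed(config$seed + 1L)
  depth <- if (is.null(depth_per_library)) config$depth_per_library
           else as.integer(depth_per_library)
  if (depth == 0) {
    warning("depth 0: emitting empty libraries")
    out <- list(reads_a = character(0), reads_b = character(0),
                truth = data.frame(class = character(0), library = character(0),
                                   stringsAsFactors = FALSE),
                counts = reference$manifest[, c("id", "expected_a",
                                                "expected_b"), drop = FALSE],
                reference = reference)
    class(out) <- "sim_libraries"
    return(out)
  }
  scale <- depth / max(config$depth_per_library, 1L)
  man <- reference$manifest
  n <- nrow(man)

  mir_counts <- function(expected) {
    expected <- expected * scale
    if (mode == "deterministic") round(expected)
    else if (sum(expected) == 0) rep(0L, length(expected))
    else as.integer(stats::rmultinom(1, size = round(sum(expected)),
                                     prob = expected / sum(expected)))
  }
  cnt_a <- if (n) mir_counts(man$expected_a) else integer(0)
  cnt_b <- if (n) mir_counts(man$expected_b) else integer(0)

  # per-class contaminant fragments: a fixed fragment per reference sequence
  frag_of <- function(ref_seq) {
    L <- sample(18:25, 1)
    s <- sample(seq_len(nchar(ref_seq) - L + 1L), 1)
    substr(ref_seq, s, s + L - 1L)
  }
  cont_classes <- names(reference$contaminants)
  cont_total <- round(config$contaminant_fraction * depth)
  cont_frags <- list()
  if (length(cont_classes) && cont_total > 0) {
    per_class <- floor(cont_total / length(cont_classes))
    for (cl in cont_classes) {
      refs <- reference$contaminants[[cl]]
      frs <- vapply(refs, frag_of, character(1))
      per_frag <- floor(per_class / length(frs))
      cont_frags[[cl]] <- list(frags = frs, count = per_frag)
    }
  }

  junk_total <- round(config$junk_fraction * depth)
  oob_total <- round(config$oob_fraction * depth)

  build_library <- function(counts) {
    reads <- character(0); cls <- character(0)
    if (n) {
      for (i in seq_len(n)) {
        if (counts[i] > 0) {
          rd <- .platform_read(man$mature_seq[i], config$adapter_seq,
                               config$read_len)
          reads <- c(reads, rep(rd, counts[i]))
          cls <- c(cls, rep(man$id[i], counts[i]))
        }
      }
    }
    for (cl in names(cont_frags)) {
      for (fr in cont_frags[[cl]]$frags) {
        k <- cont_frags[[cl]]$count
        if (k > 0) {
          rd <- .platform_read(fr, config$adapter_seq, config$read_len)
          reads <- c(reads, rep(rd, k))
          cls <- c(cls, rep(cl, k))
        }
      }
    }
    if (junk_total > 0) {
      k1 <- ceiling(junk_total / 2); k2 <- junk_total - k1
      pa <- .platform_read(strrep("A", 22), config$adapter_seq,
                           config$read_len)
      reads <- c(reads, rep(pa, k1)); cls <- c(cls, rep("junk_polyA", k1))
      if (k2 > 0) {
        nj <- paste0(random_seq(9), "N", random_seq(10))
        rd <- .platform_read(nj, config$adapter_seq, config$read_len)
        reads <- c(reads, rep(rd, k2)); cls <- c(cls, rep("junk_N", k2))
      }
    }
    if (oob_total > 0) {
      k1 <- ceiling(oob_total / 3); k2 <- k1
      k3 <- oob_total - k1 - k2
      long_ins <- random_seq(30)
      short_ins <- random_seq(16)
      noad <- random_seq(config$read_len)
      rd1 <- .platform_read(long_ins, config$adapter_seq, config$read_len)
      rd2 <- .platform_read(short_ins, config$adapter_seq, config$read_len)
      reads <- c(reads, rep(rd1, k1), rep(rd2, k2), rep(noad, max(k3, 0)))
      cls <- c(cls, rep("oob_long", k1), rep("oob_short", k2),
               rep("oob_noadapter", max(k3, 0)))
    }
    list(reads = reads, cls = cls)
  }

  la <- build_library(cnt_a)
  lb <- build_library(cnt_b)
  truth <- rbind(
    data.frame(class = la$cls, library = "A", stringsAsFactors = FALSE),
    data.frame(class = lb$cls, library = "B", stringsAsFactors = FALSE))
  counts <- if (n) data.frame(id = man$id, count_a = cnt_a, count_b = cnt_b,
                              stringsAsFactors = FALSE)
            else data.frame(id = character(0), count_a = integer(0),
                            count_b = integer(0), stringsAsFactors = FALSE)
  out <- list(reads_a = la$reads, reads_b = lb$reads, truth = truth,
              counts = counts, reference = reference)
  class(out) <- "sim_libraries"
  out
}

#' Write a simulation to disk
#'
#' Writes the transcriptome and per-class contaminant FASTA files, the
#' known-miRNA catalog FASTA, the two FASTQ libraries (Phred+33, constant
#' quality `I`), and the truth manifest as both TSV and JSON.
#'
#' @param libs a `sim_libraries`.
#' @param outdir output directory (created if needed).
#' @return invisibly, the vector of written paths.
#' @export
write_simulation <- function(libs, outdir) {
  stopifnot(inherits(libs, "sim_libraries"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  ref <- libs$reference
  paths <- character(0)
  p <- file.path(outdir, "transcriptome.fasta")
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(ref$transcriptome), p)
  paths <- c(paths, p)
  for (cl in names(ref$contaminants)) {
    p <- file.path(outdir, paste0("contaminant_", cl, ".fasta"))
    Biostrings::writeXStringSet(
      Biostrings::DNAStringSet(ref$contaminants[[cl]]), p)
    paths <- c(paths, p)
  }
  cat_df <- ref$catalog$mirnas
  if (nrow(cat_df)) {
    p <- file.path(outdir, "known_mirnas.fasta")
    x <- Biostrings::DNAStringSet(cat_df$mature)
    names(x) <- cat_df$name
    Biostrings::writeXStringSet(x, p)
    paths <- c(paths, p)
  }
  write_fq <- function(reads, p) {
    ids <- sprintf("@read%07d", seq_along(reads))
    qual <- strrep("I", nchar(reads))
    writeLines(rbind(ids, reads, "+", qual), p)
    p
  }
  if (length(libs$reads_a) || length(libs$reads_b)) {
    paths <- c(paths, write_fq(libs$reads_a,
                               file.path(outdir, "library_A.fastq")),
               write_fq(libs$reads_b, file.path(outdir, "library_B.fastq")))
  }
  p <- file.path(outdir, "manifest.tsv")
  utils::write.table(ref$manifest, p, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths <- c(paths, p)
  p <- file.path(outdir, "manifest.json")
  jsonlite::write_json(list(config = unclass(ref$config)[
    setdiff(names(ref$config), "fold_change_spec")],
    mirnas = ref$manifest), p, auto_unbox = TRUE, digits = NA)
  paths <- c(paths, p)
  invisible(paths)
}
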