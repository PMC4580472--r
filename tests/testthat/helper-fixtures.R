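# Fixture builders: designed hairpins with construction-time ground truth,
# and small catalogs. All randomness is drawn from the caller's RNG stream.

ADAPTER <- "TGGAATTCTCGGGTGCCAAGG"

rand_dna <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

rc <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

# A designed hairpin built directly as sequence + dot-bracket (fed through
# the external-structure path, so the construction IS the structure):
#   [P1: k pairs][bulge5][P2: n_bp-k pairs][loop][P2'][bulge3][P1']
# Returns the structure pieces plus the design parameters.
make_designed_hairpin <- function(n_bp = 20L, k = 10L, loop_len = 6L,
                                  bulge5 = 0L, bulge3 = 0L, energy = -30) {
  stopifnot(k >= 1L, n_bp - k >= 1L)
  p1 <- rand_dna(k)
  p2 <- rand_dna(n_bp - k)
  g5 <- if (bulge5 > 0) rand_dna(bulge5, c("A", "C")) else ""
  g3 <- if (bulge3 > 0) rand_dna(bulge3, c("A", "C")) else ""
  loop <- rand_dna(loop_len, c("A", "C"))
  seqs <- paste0(p1, g5, p2, loop, rc(p2), g3, rc(p1))
  db <- paste0(strrep("(", k), strrep(".", bulge5), strrep("(", n_bp - k),
               strrep(".", loop_len), strrep(")", n_bp - k),
               strrep(".", bulge3), strrep(")", k))
  st <- fold_rna(seqs, structure = db, energy = energy)
  list(structure = st, n_bp = n_bp, k = k, loop_len = loop_len,
       bulge5 = bulge5, bulge3 = bulge3, energy = energy,
       len = nchar(seqs),
       # handy intervals (1-based)
       p1 = c(1L, k),
       gap5 = if (bulge5 > 0) c(k + 1L, k + bulge5) else NULL,
       p2 = c(k + bulge5 + 1L, k + bulge5 + n_bp - k))
}

# small known-miRNA catalog for matcher tests
toy_catalog <- function() {
  reference_catalog(
    contaminants = list(
      rRNA = c(r1 = paste0("GGGAAACCC", rand_dna(60), "TTTGGGAAA")),
      repeats = c(rep1 = rand_dna(80))),
    mirnas = data.frame(
      name = c("tae-miR159a", "osa-miR168a-5p", "zma-miR169f-5p",
               "cre-miR910"),
      species = c("tae", "osa", "zma", "cre"),
      mature = c("TTTGGATTGAAGGGAGCTCTA",
                 "TCGCTTGGTGCAGGTCGGGAA",
                 "TAGCCAAGGATGACTTGCCTG",
                 "TTCAGTTTCTTCTCGGAAGCTCA"),
      stringsAsFactors = FALSE),
    species_priority = c("cre", "tae", "osa", "zma"))
}

# exhaustive best-hit search over all shifts/substitutions, independent of
# match_known's bookkeeping
bf_best_hit <- function(read, catalog, max_mismatch = 1L, max_shift = 2L) {
  cat_df <- catalog$mirnas
  prio <- match(cat_df$species, catalog$species_priority)
  best <- NULL
  for (mi in seq_len(nrow(cat_df))) {
    ref <- cat_df$mature[mi]
    ld <- nchar(read); lr <- nchar(ref)
    for (ls in -max_shift:max_shift) for (rs in -max_shift:max_shift) {
      if (ld != lr + ls + rs) next
      d_from <- 1 + max(ls, 0); d_to <- ld - max(rs, 0)
      if (d_to < d_from) next
      ov_d <- substr(read, d_from, d_to)
      ov_r <- substr(ref, d_from - ls, d_to - ls)
      nm <- sum(strsplit(ov_d, "")[[1]] != strsplit(ov_r, "")[[1]])
      if (nm > max_mismatch) next
      cand <- list(name = cat_df$name[mi], n_sub = nm,
                   shift = abs(ls) + abs(rs), prio = prio[mi])
      if (is.null(best) ||
          cand$n_sub < best$n_sub ||
          (cand$n_sub == best$n_sub && cand$shift < best$shift) ||
          (cand$n_sub == best$n_sub && cand$shift == best$shift &&
           cand$prio < best$prio) ||
          (cand$n_sub == best$n_sub && cand$shift == best$shift &&
           cand$prio == best$prio && cand$name < best$name)) {
        best <- cand
      }
    }
  }
  best
}
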