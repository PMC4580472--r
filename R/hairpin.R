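# Hairpin precursor extraction and the eleven-criterion acceptance test.
#
# Coordinates are 1-based inclusive everywhere, both on contigs and inside
# precursor windows.

#' Default thresholds of the eleven precursor acceptance criteria
#'
#' The criteria, applied to a folded candidate precursor with a designated
#' mature interval:
#' \enumerate{
#'   \item largest single bulge in the stem <= 12 nt;
#'   \item stem contains >= 16 base pairs;
#'   \item free energy <= -15 kcal/mol;
#'   \item hairpin length (both stem arms + terminal loop) >= 50 nt;
#'   \item terminal loop <= 200 nt;
#'   \item largest bulge within the mature region <= 4 nt;
#'   \item biased (one-arm) error nucleotides in the mature region <= 4;
#'   \item biased bulges touching the mature region <= 2;
#'   \item error (symmetric mismatch) nucleotides in the mature region <= 2;
#'   \item mature region contains >= 12 paired bases;
#'   \item >= 80\% of the mature sequence lies in the stem.
#' }
#'
#' "Errors" are symmetric internal-loop positions (both arms unpaired between
#' consecutive stem pairs); "biased" nucleotides are the one-arm excess of an
#' asymmetric interruption. This asymmetric reading is a documented
#' convention; `bias_mode = "any"` instead counts every unpaired stem
#' nucleotide as biased.
#'
#' @return named list of thresholds, suitable for the `criteria` argument of
#'   [evaluate_hairpin()].
#' @export
hairpin_criteria <- function() {
  list(max_stem_bulge_nt       = 12,
       min_stem_bp             = 16,
       max_free_energy         = -15,
       min_hairpin_len         = 50,
       max_loop_len            = 200,
       max_mature_bulge_nt     = 4,
       max_mature_biased_errors = 4,
       max_mature_biased_bulges = 2,
       max_mature_errors       = 2,
       min_mature_bp           = 12,
       min_pct_mature_in_stem  = 80)
}

#' Extract candidate precursor windows around a mapped mature locus
#'
#' For a mature small RNA mapped at `[start, end]` on a contig, emits up to
#' three candidate windows using `flank` nt of context: upstream-only
#' `[start - flank, end]`, downstream-only `[start, end + flank]`, and
#' combined `[start - flank, end + flank]`, each truncated at the contig
#' bounds. Duplicate windows after truncation are dropped.
#'
#' @param contig_seq contig nucleotide string.
#' @param start,end 1-based inclusive mature coordinates on the contig.
#' @param flank context length in nt (default 60).
#' @return data.frame with columns `window` (label), `start`, `end`, `seq`,
#'   `mature_start`, `mature_end` (mature coordinates local to the window).
#' @export
extract_windows <- function(contig_seq, start, end, flank = 60L) {
  n <- nchar(contig_seq)
  stopifnot(start >= 1L, end <= n, start <= end)
  defs <- list(upstream   = c(start - flank, end),
               downstream = c(start, end + flank),
               both       = c(start - flank, end + flank))
  rows <- lapply(names(defs), function(lbl) {
    s <- max(1L, defs[[lbl]][1]); e <- min(n, defs[[lbl]][2])
    data.frame(window = lbl, start = s, end = e,
               seq = substr(contig_seq, s, e),
               mature_start = start - s + 1L,
               mature_end = end - s + 1L,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[!duplicated(out[, c("start", "end")]), , drop = FALSE]
}

# Decompose a pair table into hairpin loops and their stems.
# Returns, per hairpin loop: the closing pair, the stem chain (outer-to-inner
# list of pairs along enclosing pairs that enclose only this hairpin).
.stem_chains <- function(pairs) {
  n <- length(pairs)
  opens <- which(pairs > seq_len(n))
  if (!length(opens)) return(list())
  # parent / children relations among pairs (identified by their open index)
  parent <- setNames(rep(NA_integer_, length(opens)), opens)
  nchild <- setNames(rep(0L, length(opens)), opens)
  stk <- integer(0)
  for (i in seq_len(n)) {
    if (pairs[i] > i) {
      if (length(stk)) {
        parent[as.character(i)] <- stk[length(stk)]
        key <- as.character(stk[length(stk)])
        nchild[key] <- nchild[key] + 1L
      }
      stk <- c(stk, i)
    } else if (pairs[i] != 0 && pairs[i] < i) {
      stk <- stk[-length(stk)]
    }
  }
  hairpins <- opens[vapply(opens, function(i) {
    j <- pairs[i]
    j - i > 1L && !any(pairs[(i + 1L):(j - 1L)] > 0)
  }, logical(1))]
  lapply(hairpins, function(h) {
    chain <- h
    cur <- h
    repeat {
      p <- parent[as.character(cur)]
      if (is.na(p) || nchild[as.character(p)] != 1L) break
      chain <- c(p, chain)
      cur <- p
    }
    list(closing = c(h, pairs[h]),
         chain_open = chain,                       # outer-to-inner 5' indices
         chain = cbind(i = chain, j = pairs[chain]))
  })
}

#' Apply the eleven-criterion precursor acceptance test
#'
#' Decomposes the structure into a stem and terminal loop (the hairpin loop
#' whose stem overlaps the mature interval best; leftmost on ties), measures
#' all eleven criteria (see [hairpin_criteria()]) and reports measured values
#' with pass flags. A structure with no hairpin loop fails all
#' structure-dependent criteria with `NA` measurements.
#'
#' @param structure a `secondary_structure` (from [fold_rna()]).
#' @param mature_start,mature_end 1-based inclusive mature interval within the
#'   folded sequence.
#' @param criteria threshold list, see [hairpin_criteria()].
#' @param bias_mode `"asymmetric"` (default) or `"any"`; see
#'   [hairpin_criteria()].
#' @return an object of class `criteria_report`: a data.frame with columns
#'   `criterion`, `value`, `threshold`, `direction`, `pass`, plus attribute
#'   `overall` (logical: all eleven pass).
#' @export
evaluate_hairpin <- function(structure, mature_start, mature_end,
                             criteria = hairpin_criteria(),
                             bias_mode = c("asymmetric", "any")) {
  bias_mode <- match.arg(bias_mode)
  pairs <- structure$pairs
  n <- length(pairs)
  stopifnot(mature_start >= 1L, mature_end <= n, mature_start <= mature_end)
  mpos <- mature_start:mature_end

  crit_names <- c("max_stem_bulge_nt", "stem_bp", "free_energy",
                  "hairpin_len", "loop_len", "max_mature_bulge_nt",
                  "mature_biased_errors", "mature_biased_bulges",
                  "mature_errors", "mature_bp", "pct_mature_in_stem")
  thr <- unlist(criteria)[c("max_stem_bulge_nt", "min_stem_bp",
                            "max_free_energy", "min_hairpin_len",
                            "max_loop_len", "max_mature_bulge_nt",
                            "max_mature_biased_errors",
                            "max_mature_biased_bulges", "max_mature_errors",
                            "min_mature_bp", "min_pct_mature_in_stem")]
  dir <- c("<=", ">=", "<=", ">=", "<=", "<=", "<=", "<=", "<=", ">=", ">=")

  chains <- .stem_chains(pairs)
  if (!length(chains)) {
    vals <- rep(NA_real_, 11)
    vals[3] <- structure$energy
    pass <- rep(FALSE, 11)
    pass[3] <- !is.na(structure$energy) && structure$energy <= thr[3]
    rep_df <- data.frame(criterion = crit_names, value = vals,
                         threshold = unname(thr), direction = dir,
                         pass = pass, stringsAsFactors = FALSE)
    attr(rep_df, "overall") <- FALSE
    class(rep_df) <- c("criteria_report", "data.frame")
    return(rep_df)
  }

  # choose the hairpin whose stem arms cover the mature interval best
  cover <- vapply(chains, function(ch) {
    I <- ch$chain[1, "i"]; J <- ch$chain[1, "j"]
    i0 <- ch$closing[1]; j0 <- ch$closing[2]
    arms <- c(I:i0, j0:J)
    sum(mpos %in% arms)
  }, numeric(1))
  ch <- chains[[which.max(cover)]]
  chain <- ch$chain
  i0 <- ch$closing[1]; j0 <- ch$closing[2]
  I <- chain[1, "i"]; J <- chain[1, "j"]
  arms <- c(I:i0, j0:J)

  # interface analysis between consecutive stem pairs
  label <- rep(NA_character_, n)
  label[arms[pairs[arms] > 0]] <- "paired"
  iface <- list()
  if (nrow(chain) > 1L) {
    for (t in seq_len(nrow(chain) - 1L)) {
      a <- chain[t, "i"]; b <- chain[t, "j"]
      a2 <- chain[t + 1L, "i"]; b2 <- chain[t + 1L, "j"]
      g5 <- a2 - a - 1L; g3 <- b - b2 - 1L
      if (g5 + g3 == 0L) next
      e <- min(g5, g3)
      pos5 <- if (g5 > 0L) (a + 1L):(a2 - 1L) else integer(0)
      pos3 <- if (g3 > 0L) (b - 1L):(b2 + 1L) else integer(0)  # outer-first
      if (bias_mode == "any") {
        err5 <- integer(0); err3 <- integer(0)
        bia5 <- pos5; bia3 <- pos3
      } else {
        err5 <- utils::head(pos5, e); bia5 <- utils::tail(pos5, g5 - e)
        err3 <- utils::head(pos3, e); bia3 <- utils::tail(pos3, g3 - e)
      }
      label[err5] <- "error"; label[err3] <- "error"
      label[bia5] <- "biased"; label[bia3] <- "biased"
      iface[[length(iface) + 1L]] <-
        list(g5 = g5, g3 = g3, biased_pos = c(bia5, bia3))
    }
  }

  max_gap <- if (length(iface)) {
    max(vapply(iface, function(x) max(x$g5, x$g3), numeric(1)))
  } else 0
  unpaired_m <- pairs[mpos] == 0
  runs <- rle(unpaired_m)
  max_m_bulge <- if (any(runs$values)) max(runs$lengths[runs$values]) else 0
  biased_in_m <- sum(label[mpos] %in% "biased", na.rm = TRUE)
  biased_bulges_m <- if (length(iface)) {
    sum(vapply(iface, function(x) length(x$biased_pos) > 0 &&
                 any(x$biased_pos %in% mpos), logical(1)))
  } else 0
  errors_in_m <- sum(label[mpos] %in% "error", na.rm = TRUE)

  vals <- c(max_gap,
            nrow(chain),
            structure$energy,
            J - I + 1L,
            j0 - i0 - 1L,
            max_m_bulge,
            biased_in_m,
            biased_bulges_m,
            errors_in_m,
            sum(pairs[mpos] > 0),
            round(100 * sum(mpos %in% arms) / length(mpos), 2))
  pass <- ifelse(dir == "<=", vals <= thr, vals >= thr)
  pass[is.na(pass)] <- FALSE
  rep_df <- data.frame(criterion = crit_names, value = unname(vals),
                       threshold = unname(thr), direction = dir,
                       pass = pass, stringsAsFactors = FALSE)
  attr(rep_df, "overall") <- all(pass)
  attr(rep_df, "stem_interval") <- c(I, J)
  attr(rep_df, "loop_interval") <- c(i0 + 1L, j0 - 1L)
  class(rep_df) <- c("criteria_report", "data.frame")
  rep_df
}

#' @export
print.criteria_report <- function(x, ...) {
  cat("Hairpin criteria report — overall ",
      if (isTRUE(attr(x, "overall"))) "PASS" else "FAIL", "\n", sep = "")
  print.data.frame(x)
  invisible(x)
}

#' Precursor summary statistics
#'
#' @param sequence precursor nucleotide string.
#' @param structure its `secondary_structure` (for the energy), or `NULL`.
#' @return list with `length` (nt), `gc_pct` (percent, 2 dp) and `dg`
#'   (kcal/mol, `NA` if no structure given).
#' @export
precursor_stats <- function(sequence, structure = NULL) {
  s <- norm_seq(sequence)
  b <- seq_chars(s)
  list(length = nchar(s),
       gc_pct = round(100 * sum(b %in% c("G", "C")) / length(b), 2),
       dg = if (is.null(structure)) NA_real_ else structure$energy)
}

#' Locate a small RNA on transcriptome contigs (plus strand, exact match)
#'
#' @param mature_seq small RNA sequence.
#' @param transcriptome named character vector of contig sequences.
#' @return data.frame with columns `contig`, `start`, `end`; zero rows if the
#'   sequence does not map.
#' @export
map_to_transcriptome <- function(mature_seq, transcriptome) {
  pat <- norm_seq(mature_seq)
  hits <- lapply(names(transcriptome), function(cn) {
    m <- gregexpr(pat, transcriptome[[cn]], fixed = TRUE)[[1]]
    if (m[1] == -1) return(NULL)
    data.frame(contig = cn, start = as.integer(m),
               end = as.integer(m) + nchar(pat) - 1L,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, hits)
  if (is.null(out)) {
    out <- data.frame(contig = character(0), start = integer(0),
                      end = integer(0), stringsAsFactors = FALSE)
  }
  out
}

#' Discover novel miRNA hairpin precursors for unannotated reads
#'
#' For each unannotated unique read: maps it to the transcriptome (exact,
#' plus strand), extracts the three flank windows around every locus, folds
#' each window and applies the eleven-criterion test. Among passing windows of
#' one locus the lowest-energy (tie: shortest) candidate is kept. A read
#' mapping to several loci yields one candidate per locus, suffixed `-1`,
#' `-2`, ...
#'
#' @param reads data.frame with columns `seq`, `count_a`, `count_b`
#'   (unannotated unique reads).
#' @param transcriptome named character vector of contigs.
#' @param flank window context in nt (default 60).
#' @param criteria threshold list, see [hairpin_criteria()].
#' @param structures optional named list of externally folded
#'   `secondary_structure` objects keyed by window sequence; used instead of
#'   the internal folder where present.
#' @return data.frame of accepted candidates: `id`, `mature_seq`, `contig`,
#'   `precursor_start`, `precursor_end`, `mature_start`, `mature_end`,
#'   `mature_len`, `precursor_len`, `gc_pct`, `dg`, `dot_bracket`,
#'   `count_a`, `count_b`.
#' @export
discover_hairpins <- function(reads, transcriptome, flank = 60L,
                              criteria = hairpin_criteria(),
                              structures = NULL) {
  stopifnot(is.data.frame(reads), all(c("seq") %in% names(reads)))
  if (!"count_a" %in% names(reads)) reads$count_a <- 0
  if (!"count_b" %in% names(reads)) reads$count_b <- 0
  out <- list()
  for (r in seq_len(nrow(reads))) {
    seqr <- norm_seq(reads$seq[r])
    loci <- map_to_transcriptome(seqr, transcriptome)
    if (!nrow(loci)) next
    for (l in seq_len(nrow(loci))) {
      wins <- extract_windows(transcriptome[[loci$contig[l]]],
                              loci$start[l], loci$end[l], flank = flank)
      passing <- list()
      for (w in seq_len(nrow(wins))) {
        wseq <- wins$seq[w]
        st <- if (!is.null(structures) && !is.null(structures[[wseq]])) {
          structures[[wseq]]
        } else {
          tryCatch(fold_rna(wseq), error = function(e) NULL)
        }
        if (is.null(st)) next
        rep_w <- evaluate_hairpin(st, wins$mature_start[w], wins$mature_end[w],
                                  criteria = criteria)
        if (isTRUE(attr(rep_w, "overall"))) {
          passing[[length(passing) + 1L]] <- list(win = wins[w, ], st = st)
        }
      }
      if (!length(passing)) next
      en <- vapply(passing, function(p) p$st$energy, numeric(1))
      ln <- vapply(passing, function(p) nchar(p$win$seq), numeric(1))
      best <- order(en, ln)[1]
      pw <- passing[[best]]
      stats <- precursor_stats(pw$win$seq, pw$st)
      id <- if (nrow(loci) > 1L) paste0("cand-", r, "-", l) else paste0("cand-", r)
      out[[length(out) + 1L]] <- data.frame(
        id = id, mature_seq = seqr,
        contig = loci$contig[l],
        precursor_start = pw$win$start, precursor_end = pw$win$end,
        mature_start = loci$start[l], mature_end = loci$end[l],
        mature_len = nchar(seqr),
        precursor_len = stats$length, gc_pct = stats$gc_pct, dg = stats$dg,
        dot_bracket = pw$st$dot_bracket,
        count_a = reads$count_a[r], count_b = reads$count_b[r],
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(id = character(0), mature_seq = character(0),
                      contig = character(0), precursor_start = integer(0),
                      precursor_end = integer(0), mature_start = integer(0),
                      mature_end = integer(0), mature_len = integer(0),
                      precursor_len = integer(0), gc_pct = numeric(0),
                      dg = numeric(0), dot_bracket = character(0),
                      count_a = numeric(0), count_b = numeric(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Export discovered precursor and mature loci as GFF3
#'
#' @param candidates data.frame from [discover_hairpins()].
#' @param path output file path.
#' @export
write_hairpin_gff <- function(candidates, path) {
  if (!nrow(candidates)) {
    rtracklayer::export(GenomicRanges::GRanges(), path, format = "gff3")
    return(invisible(path))
  }
  gr <- GenomicRanges::GRanges(
    seqnames = rep(candidates$contig, 2),
    ranges = IRanges::IRanges(
      start = c(candidates$precursor_start, candidates$mature_start),
      end = c(candidates$precursor_end, candidates$mature_end)),
    strand = "+",
    type = rep(c("miRNA_primary_transcript", "miRNA"),
               each = nrow(candidates)),
    ID = c(candidates$id, paste0(candidates$id, "_mature")))
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}
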