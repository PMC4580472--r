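# Read cleaning: 3' adapter removal, length window, junk filtering, and
# collapsing to unique sequences with per-library counts.
#
# Accounting is a strict partition: every raw read lands in exactly one of
# "3ADT&length filter", "Junk reads" or "Clean reads", in that precedence
# order, so category totals always sum to the raw total.

#' Trim a 3' adapter from reads
#'
#' Removes the leftmost full occurrence of the adapter; if the adapter does
#' not occur in full (typically because the platform read ends inside it),
#' removes the longest read suffix of length >= `min_overlap` that equals an
#' adapter prefix. Reads without either are flagged `no_adapter`.
#'
#' @param reads character vector of read sequences.
#' @param adapter 3' adapter sequence (non-empty).
#' @param min_overlap minimum suffix-prefix overlap in nt (default 6; must be
#'   <= adapter length).
#' @return data.frame with columns `seq` (trimmed sequence, or the input when
#'   no adapter was found) and `no_adapter` (logical).
#' @export
#' @examples
#' trim_adapter(c("ACGTACGTTGGAATTC"), adapter = "TGGAATTCTCGGGTGCCAAGG")
trim_adapter <- function(reads, adapter, min_overlap = 6L) {
  if (!is.character(adapter) || length(adapter) != 1L || !nzchar(adapter)) {
    stop("adapter must be a non-empty nucleotide string")
  }
  adapter <- norm_seq(adapter)
  if (min_overlap < 1L || min_overlap > nchar(adapter)) {
    stop("min_overlap must satisfy 1 <= min_overlap <= nchar(adapter)")
  }
  reads <- norm_seq(reads)
  n <- length(reads)
  out_seq <- reads
  no_adapter <- rep(TRUE, n)
  pos <- regexpr(adapter, reads, fixed = TRUE)
  full <- pos > 0
  out_seq[full] <- substr(reads[full], 1L, pos[full] - 1L)
  no_adapter[full] <- FALSE
  # suffix-prefix overlap for the rest
  rest <- which(!full)
  for (i in rest) {
    len <- nchar(reads[i])
    kmax <- min(len, nchar(adapter) - 1L)
    if (kmax < min_overlap) next
    for (k in kmax:min_overlap) {
      if (substr(reads[i], len - k + 1L, len) == substr(adapter, 1L, k)) {
        out_seq[i] <- substr(reads[i], 1L, len - k)
        no_adapter[i] <- FALSE
        break
      }
    }
  }
  data.frame(seq = out_seq, no_adapter = no_adapter, stringsAsFactors = FALSE)
}

#' Rules for read classification
#'
#' @param min_len,max_len analysis length window in nt (defaults 18 and 25).
#' @param raw_min,raw_max raw-length window within which an adapterless read
#'   may still be kept (defaults 15 and 40, the library insert-size
#'   selection).
#' @param polya_frac a read whose longest run of A covers at least this
#'   fraction of its length is junk (default 0.8).
#' @return named list of rules for [classify_and_filter()].
#' @export
filter_rules <- function(min_len = 18L, max_len = 25L,
                         raw_min = 15L, raw_max = 40L, polya_frac = 0.8) {
  list(min_len = min_len, max_len = max_len,
       raw_min = raw_min, raw_max = raw_max, polya_frac = polya_frac)
}

.is_junk <- function(seqs, polya_frac) {
  has_n <- grepl("N", seqs, fixed = TRUE)
  max_a <- vapply(seqs, function(s) {
    r <- rle(seq_chars(s) == "A")
    if (any(r$values)) max(r$lengths[r$values]) else 0L
  }, integer(1), USE.NAMES = FALSE)
  has_n | (max_a >= polya_frac * nchar(seqs))
}

#' Classify raw reads and collapse to a clean unique-read set
#'
#' Applies, per library and in fixed precedence order: (1) adapter trimming
#' and the length window — reads whose trimmed length falls outside
#' `[min_len, max_len]`, and adapterless reads outside the raw windows, go to
#' "3ADT&length filter"; (2) junk — any remaining read containing N or with a
#' poly(A) run covering >= `polya_frac` of its length goes to "Junk reads";
#' (3) the remainder are "Clean reads" and are collapsed to unique sequences
#' with per-library counts.
#'
#' @param reads_a,reads_b character vectors of raw read sequences for the two
#'   libraries (library A = first condition, e.g. lag phase; library B =
#'   second, e.g. logarithmic phase). `reads_b` may be omitted.
#' @param adapter 3' adapter sequence.
#' @param rules classification rules, see [filter_rules()].
#' @param min_overlap adapter overlap, see [trim_adapter()].
#' @return an object of class `clean_read_set`: list with `reads` (data.frame
#'   `seq`, `count_a`, `count_b`, sorted by decreasing total count then
#'   sequence), `accounting` (data.frame with rows Raw reads, 3ADT&length
#'   filter, Junk reads, Clean reads x columns `total_a`, `unique_a`,
#'   `total_b`, `unique_b`) and `rules`.
#' @export
classify_and_filter <- function(reads_a, reads_b = character(0),
                                adapter, rules = filter_rules(),
                                min_overlap = 6L) {
  per_lib <- function(reads) {
    reads <- norm_seq(reads)
    nraw <- length(reads)
    if (!nraw) {
      return(list(clean = character(0),
                  acct = c(raw_t = 0, raw_u = 0, adt_t = 0, adt_u = 0,
                           junk_t = 0, junk_u = 0, clean_t = 0, clean_u = 0)))
    }
    tr <- trim_adapter(reads, adapter, min_overlap = min_overlap)
    lens <- nchar(tr$seq)
    rawlens <- nchar(reads)
    in_window <- lens >= rules$min_len & lens <= rules$max_len
    keep_noad <- !tr$no_adapter |
      (rawlens >= rules$raw_min & rawlens <= rules$raw_max)
    cat_adt <- !in_window | !keep_noad
    junk <- rep(FALSE, nraw)
    cand <- which(!cat_adt)
    if (length(cand)) junk[cand] <- .is_junk(tr$seq[cand], rules$polya_frac)
    clean <- !cat_adt & !junk
    list(clean = tr$seq[clean],
         acct = c(raw_t = nraw, raw_u = length(unique(reads)),
                  adt_t = sum(cat_adt), adt_u = length(unique(reads[cat_adt])),
                  junk_t = sum(junk), junk_u = length(unique(tr$seq[junk])),
                  clean_t = sum(clean),
                  clean_u = length(unique(tr$seq[clean]))))
  }
  la <- per_lib(reads_a)
  lb <- per_lib(reads_b)
  ta <- table(la$clean)
  tb <- table(lb$clean)
  seqs <- as.character(sort(union(names(ta), names(tb))))
  reads <- data.frame(seq = seqs,
                      count_a = as.numeric(ifelse(seqs %in% names(ta),
                                                  ta[seqs], 0)),
                      count_b = as.numeric(ifelse(seqs %in% names(tb),
                                                  tb[seqs], 0)),
                      stringsAsFactors = FALSE)
  reads <- reads[order(-(reads$count_a + reads$count_b), reads$seq), ,
                 drop = FALSE]
  rownames(reads) <- NULL
  acct <- data.frame(
    category = c("Raw reads", "3ADT&length filter", "Junk reads",
                 "Clean reads"),
    total_a = c(la$acct["raw_t"], la$acct["adt_t"], la$acct["junk_t"],
                la$acct["clean_t"]),
    unique_a = c(la$acct["raw_u"], la$acct["adt_u"], la$acct["junk_u"],
                 la$acct["clean_u"]),
    total_b = c(lb$acct["raw_t"], lb$acct["adt_t"], lb$acct["junk_t"],
                lb$acct["clean_t"]),
    unique_b = c(lb$acct["raw_u"], lb$acct["adt_u"], lb$acct["junk_u"],
                 lb$acct["clean_u"]),
    stringsAsFactors = FALSE)
  rownames(acct) <- NULL
  out <- list(reads = reads, accounting = acct, rules = rules)
  class(out) <- "clean_read_set"
  out
}

#' @export
print.clean_read_set <- function(x, ...) {
  cat("Clean read set: ", nrow(x$reads), " unique sequences (",
      sum(x$reads$count_a), " + ", sum(x$reads$count_b),
      " reads in libraries A/B)\n", sep = "")
  print.data.frame(x$accounting)
  invisible(x)
}

#' Read a FASTQ file into a character vector of read sequences
#'
#' @param path FASTQ file (Phred+33; qualities are carried by the format but
#'   unused downstream).
#' @return character vector of sequences.
#' @export
read_fastq_seqs <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  as.character(x)
}

#' Write collapsed unique reads as FASTA and TSV
#'
#' FASTA headers follow `>uid<i>_count_A=<n>;count_B=<m>`.
#'
#' @param crs a `clean_read_set`.
#' @param fasta_path,tsv_path output paths (either may be `NULL` to skip).
#' @export
write_clean_reads <- function(crs, fasta_path = NULL, tsv_path = NULL) {
  stopifnot(inherits(crs, "clean_read_set"))
  if (!is.null(fasta_path)) {
    x <- Biostrings::DNAStringSet(crs$reads$seq)
    names(x) <- sprintf("uid%d_count_A=%d;count_B=%d",
                        seq_len(nrow(crs$reads)),
                        as.integer(crs$reads$count_a),
                        as.integer(crs$reads$count_b))
    Biostrings::writeXStringSet(x, fasta_path)
  }
  if (!is.null(tsv_path)) {
    utils::write.table(crs$reads, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(crs)
}

#' Write the read-accounting report
#'
#' One row per category with totals, unique counts, and percentages of the
#' library's raw total.
#'
#' @param crs a `clean_read_set`.
#' @param path output TSV path.
#' @export
write_accounting <- function(crs, path) {
  acct <- crs$accounting
  raw_a <- acct$total_a[acct$category == "Raw reads"]
  raw_b <- acct$total_b[acct$category == "Raw reads"]
  acct$pct_a <- if (raw_a > 0) pct(acct$total_a, raw_a) else NA_real_
  acct$pct_b <- if (raw_b > 0) pct(acct$total_b, raw_b) else NA_real_
  utils::write.table(acct, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(acct)
}
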