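# Annotation of unique clean reads: contaminant ncRNA classes (discard
# filter), known-miRNA matching with end-shift/substitution variant notation,
# and family assignment.

.CONTAMINANT_ORDER <- c("rRNA", "tRNA", "snoRNA", "snRNA", "otherRfam",
                        "repeats")

#' Build a reference catalog for annotation
#'
#' @param contaminants named list of character vectors of reference sequences,
#'   using any of the class names `rRNA`, `tRNA`, `snoRNA`, `snRNA`,
#'   `otherRfam`, `repeats`; missing classes are treated as empty.
#' @param mirnas data.frame of known mature miRNAs with columns `name` (e.g.
#'   `"tae-miR159a"`), `mature` (sequence) and optionally `species` (derived
#'   from the name prefix when absent) and `precursor`.
#' @param species_priority character vector of species prefixes in decreasing
#'   priority; defaults to the order of first appearance in `mirnas`.
#' @return object of class `reference_catalog`.
#' @export
reference_catalog <- function(contaminants = list(), mirnas = NULL,
                              species_priority = NULL) {
  contaminants <- lapply(contaminants, norm_seq)
  unknown <- setdiff(names(contaminants), .CONTAMINANT_ORDER)
  if (length(unknown)) stop("unknown contaminant classes: ",
                            paste(unknown, collapse = ", "))
  if (is.null(mirnas)) {
    mirnas <- data.frame(name = character(0), mature = character(0),
                         species = character(0), stringsAsFactors = FALSE)
  }
  stopifnot(all(c("name", "mature") %in% names(mirnas)))
  mirnas$mature <- norm_seq(mirnas$mature)
  if (!"species" %in% names(mirnas)) {
    mirnas$species <- sub("-.*$", "", mirnas$name)
  }
  if (is.null(species_priority)) species_priority <- unique(mirnas$species)
  if (!all(mirnas$species %in% species_priority)) {
    stop("species_priority must cover every species prefix in the catalog")
  }
  out <- list(contaminants = contaminants, mirnas = mirnas,
              species_priority = species_priority)
  class(out) <- "reference_catalog"
  out
}

#' Partition unique reads into contaminant ncRNA classes
#'
#' A read is assigned to the first class, in the fixed order rRNA, tRNA,
#' snoRNA, snRNA, otherRfam, repeats, in which it occurs as an exact substring
#' of a reference sequence on either strand. Unassigned reads are class
#' `"none"`.
#'
#' @param crs a `clean_read_set` (or a data.frame `seq`/`count_a`/`count_b`).
#' @param catalog a `reference_catalog`.
#' @return data.frame with the read columns plus `class`.
#' @export
classify_contaminants <- function(crs, catalog) {
  reads <- if (inherits(crs, "clean_read_set")) crs$reads else crs
  stopifnot(inherits(catalog, "reference_catalog"))
  cls <- rep("none", nrow(reads))
  if (nrow(reads)) {
    for (cl in .CONTAMINANT_ORDER) {
      refs <- catalog$contaminants[[cl]]
      if (is.null(refs) || !length(refs)) next
      todo <- which(cls == "none")
      if (!length(todo)) break
      for (i in todo) {
        s <- reads$seq[i]
        rc <- revcomp(s)
        if (any(grepl(s, refs, fixed = TRUE)) ||
            any(grepl(rc, refs, fixed = TRUE))) {
          cls[i] <- cl
        }
      }
    }
  }
  cbind(reads, class = cls, stringsAsFactors = FALSE)
}

#' Per-class contaminant report with percentages of the raw totals
#'
#' @param assigned output of [classify_contaminants()].
#' @param raw_total_a,raw_total_b raw read totals per library (denominators
#'   for the percentage columns).
#' @param raw_unique_a,raw_unique_b raw unique totals (reported alongside).
#' @return data.frame: one row per class with total/unique counts per library
#'   and percentages of the raw totals.
#' @export
contaminant_report <- function(assigned, raw_total_a, raw_total_b,
                               raw_unique_a = NA, raw_unique_b = NA) {
  rows <- lapply(.CONTAMINANT_ORDER, function(cl) {
    sel <- assigned$class == cl
    data.frame(class = cl,
               total_a = sum(assigned$count_a[sel]),
               unique_a = sum(sel & assigned$count_a > 0),
               total_b = sum(assigned$count_b[sel]),
               unique_b = sum(sel & assigned$count_b > 0),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$pct_total_a <- pct(out$total_a, raw_total_a)
  out$pct_unique_a <- pct(out$unique_a, raw_total_a)
  out$pct_total_b <- pct(out$total_b, raw_total_b)
  out$pct_unique_b <- pct(out$unique_b, raw_total_b)
  out
}

.hamming <- function(a, b) sum(seq_chars(a) != seq_chars(b))

# All admissible alignments of a detected read against one reference mature:
# end shifts left/right in [-max_shift, max_shift], Hamming distance over the
# overlap <= max_mismatch. Returns NULL or a list describing the best
# alignment for this reference.
.align_variant <- function(read, ref, max_mismatch = 1L, max_shift = 2L) {
  ld <- nchar(read); lr <- nchar(ref)
  best <- NULL
  for (ls in -max_shift:max_shift) {
    rs <- ld - lr - ls            # right shift forced by the lengths
    if (abs(rs) > max_shift) next
    # overlap in detected coordinates
    d_from <- 1L + max(ls, 0L)
    d_to <- ld - max(rs, 0L)
    if (d_to < d_from) next
    r_from <- d_from - ls
    r_to <- d_to - ls
    ov_d <- substr(read, d_from, d_to)
    ov_r <- substr(ref, r_from, r_to)
    dch <- seq_chars(ov_d); rch <- seq_chars(ov_r)
    mism <- which(dch != rch)
    if (length(mism) > max_mismatch) next
    cand <- list(n_sub = length(mism),
                 left_shift = ls, right_shift = rs,
                 sub_pos = if (length(mism)) d_from + mism[1] - 1L else NA_integer_,
                 sub_ref = if (length(mism)) rch[mism[1]] else NA_character_,
                 sub_read = if (length(mism)) dch[mism[1]] else NA_character_)
    if (is.null(best) ||
        cand$n_sub < best$n_sub ||
        (cand$n_sub == best$n_sub &&
         abs(cand$left_shift) + abs(cand$right_shift) <
         abs(best$left_shift) + abs(best$right_shift))) {
      best <- cand
    }
  }
  best
}

#' Compose the variant suffix for a known-miRNA hit
#'
#' Grammar: `_L[+-]n` when the detected read has n bases more (`+`) or fewer
#' (`-`) than the reference on the left end, `_R[+-]n` likewise on the right,
#' and `_1ss<pos><refBase><readBase>` for one substitution at `pos` (1-based
#' on the detected read). An exact full-length match has the empty suffix.
#'
#' @param left_shift,right_shift signed end shifts (detected minus reference).
#' @param sub_pos,sub_ref,sub_read substitution descriptor (NA if none).
#' @return suffix string, e.g. `"_L-1_1ss11GC"`.
#' @export
variant_suffix <- function(left_shift, right_shift,
                           sub_pos = NA, sub_ref = NA, sub_read = NA) {
  parts <- character(0)
  if (left_shift != 0) {
    parts <- c(parts, sprintf("L%+d", left_shift))
  }
  if (right_shift != 0) {
    parts <- c(parts, sprintf("R%+d", right_shift))
  }
  if (!is.na(sub_pos)) {
    parts <- c(parts, sprintf("1ss%d%s%s", sub_pos, sub_ref, sub_read))
  }
  if (!length(parts)) "" else paste0("_", paste(parts, collapse = "_"))
}

#' Match unique reads against the known-miRNA catalog
#'
#' For each read, every catalog mature is considered under end shifts of up
#' to `max_shift` nt on each side; an alignment is accepted when the Hamming
#' distance over the overlap is <= `max_mismatch`. Among accepted alignments
#' the best is chosen by (fewest substitutions, smallest total absolute
#' shift, highest species priority, lexicographic name). Matched reads get
#' the reference name plus a variant suffix ([variant_suffix()]).
#'
#' @param reads data.frame `seq`/`count_a`/`count_b` (uncontaminated unique
#'   reads).
#' @param catalog a `reference_catalog`.
#' @param max_mismatch maximum substitutions over the overlap (default 1).
#' @param max_shift maximum end shift per side in nt (default 2).
#' @return data.frame of hits: `seq`, `name`, `suffix`, `full_name`,
#'   `n_sub`, `left_shift`, `right_shift`, `family`, `count_a`, `count_b`.
#'   Reads without a hit are absent.
#' @export
match_known <- function(reads, catalog, max_mismatch = 1L, max_shift = 2L) {
  stopifnot(inherits(catalog, "reference_catalog"))
  cat_df <- catalog$mirnas
  if (!nrow(cat_df)) {
    warning("empty known-miRNA catalog; no hits possible")
    return(data.frame(seq = character(0), name = character(0),
                      suffix = character(0), full_name = character(0),
                      n_sub = integer(0), left_shift = integer(0),
                      right_shift = integer(0), family = character(0),
                      count_a = numeric(0), count_b = numeric(0),
                      stringsAsFactors = FALSE))
  }
  prio <- match(cat_df$species, catalog$species_priority)
  hits <- list()
  for (r in seq_len(nrow(reads))) {
    s <- norm_seq(reads$seq[r])
    best <- NULL
    for (m in seq_len(nrow(cat_df))) {
      al <- .align_variant(s, cat_df$mature[m], max_mismatch, max_shift)
      if (is.null(al)) next
      key <- c(al$n_sub, abs(al$left_shift) + abs(al$right_shift),
               prio[m])
      better <- is.null(best) ||
        key[1] < best$key[1] ||
        (key[1] == best$key[1] && key[2] < best$key[2]) ||
        (key[1] == best$key[1] && key[2] == best$key[2] &&
         key[3] < best$key[3]) ||
        (all(key == best$key) && cat_df$name[m] < best$name)
      if (better) best <- c(al, list(key = key, name = cat_df$name[m]))
    }
    if (is.null(best)) next
    suf <- variant_suffix(best$left_shift, best$right_shift,
                          best$sub_pos, best$sub_ref, best$sub_read)
    hits[[length(hits) + 1L]] <- data.frame(
      seq = s, name = best$name, suffix = suf,
      full_name = paste0(best$name, suf),
      n_sub = best$n_sub, left_shift = best$left_shift,
      right_shift = best$right_shift,
      family = assign_family(best$name),
      count_a = reads$count_a[r], count_b = reads$count_b[r],
      stringsAsFactors = FALSE)
  }
  if (!length(hits)) {
    return(data.frame(seq = character(0), name = character(0),
                      suffix = character(0), full_name = character(0),
                      n_sub = integer(0), left_shift = integer(0),
                      right_shift = integer(0), family = character(0),
                      count_a = numeric(0), count_b = numeric(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, hits)
}

#' Derive the miRNA family from a catalog name
#'
#' The family is `"miR"` plus the leading integer of the numeric core, i.e.
#' species prefix, letter suffixes and arm designations are stripped:
#' `"zma-miR169f-5p"` -> `"miR169"`. Unparseable names give `"unknown"`.
#'
#' @param name character vector of catalog names.
#' @return character vector of family names.
#' @export
#' @examples
#' assign_family(c("tae-miR159a", "osa-miR168a-5p", "xxx-foo"))
assign_family <- function(name) {
  m <- regmatches(name, regexpr("miR[0-9]+", name))
  out <- rep("unknown", length(name))
  ok <- regexpr("miR[0-9]+", name) > 0
  out[ok] <- m
  out
}

#' Annotate a clean read set end to end
#'
#' Runs [classify_contaminants()] then [match_known()] on the remainder, and
#' returns the partition: every unique clean read is exactly one of
#' contaminant, known hit, or unannotated remainder.
#'
#' @inheritParams classify_contaminants
#' @inheritParams match_known
#' @return list with `contaminants` (reads with class != "none"), `hits`
#'   (known-miRNA hits), `remainder` (unannotated reads, input to novel
#'   discovery) and `assigned` (the full class column).
#' @export
annotate_reads <- function(crs, catalog, max_mismatch = 1L, max_shift = 2L) {
  assigned <- classify_contaminants(crs, catalog)
  non_cont <- assigned[assigned$class == "none",
                       c("seq", "count_a", "count_b")]
  hits <- match_known(non_cont, catalog, max_mismatch, max_shift)
  remainder <- non_cont[!(non_cont$seq %in% hits$seq), , drop = FALSE]
  rownames(remainder) <- NULL
  list(contaminants = assigned[assigned$class != "none", , drop = FALSE],
       hits = hits, remainder = remainder, assigned = assigned)
}
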