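# Descriptive profiles of a small RNA dataset: length distribution, 5' first
# nucleotide bias, family membership and abundance, co-expression sets, and
# cross-species occurrence over the supplied catalog.

#' Per-length read proportions
#'
#' Proportion of clean reads of each length in the analysis window, per
#' library, weighted by read counts.
#'
#' @param crs a `clean_read_set` (or data.frame `seq`/`count_a`/`count_b`).
#' @param lengths lengths to report (default 18:25).
#' @return data.frame `length`, `prop_a`, `prop_b`; proportions sum to 1 per
#'   non-empty library.
#' @export
length_distribution <- function(crs, lengths = 18:25) {
  reads <- if (inherits(crs, "clean_read_set")) crs$reads else crs
  if (!nrow(reads) || (sum(reads$count_a) + sum(reads$count_b)) == 0) {
    stop("empty read set")
  }
  len <- nchar(reads$seq)
  tot_a <- sum(reads$count_a); tot_b <- sum(reads$count_b)
  data.frame(length = lengths,
             prop_a = vapply(lengths, function(L)
               if (tot_a > 0) sum(reads$count_a[len == L]) / tot_a else NA_real_,
               numeric(1)),
             prop_b = vapply(lengths, function(L)
               if (tot_b > 0) sum(reads$count_b[len == L]) / tot_b else NA_real_,
               numeric(1)))
}

#' First-nucleotide bias of identified miRNAs, by length
#'
#' For each read length, the fraction of distinct miRNAs whose first (5')
#' base is A, C, G or U.
#'
#' @param hits known-hit data.frame (from [match_known()]); distinctness is
#'   by `full_name` when present, else by sequence.
#' @param lengths lengths to report (default 18:25).
#' @return data.frame `length`, `n`, `A`, `C`, `G`, `U`; fractions sum to 1
#'   for lengths with any miRNA.
#' @export
first_nt_bias <- function(hits, lengths = 18:25) {
  if (!nrow(hits)) stop("no hits to profile")
  key <- if ("full_name" %in% names(hits)) hits$full_name else hits$seq
  uni <- hits[!duplicated(key), , drop = FALSE]
  len <- nchar(uni$seq)
  first <- substr(uni$seq, 1, 1)
  first <- chartr("T", "U", first)
  rows <- lapply(lengths, function(L) {
    sel <- len == L
    n <- sum(sel)
    fr <- if (n) {
      tab <- table(factor(first[sel], levels = c("A", "C", "G", "U")))
      as.numeric(tab) / n
    } else rep(NA_real_, 4)
    data.frame(length = L, n = n, A = fr[1], C = fr[2], G = fr[3], U = fr[4])
  })
  do.call(rbind, rows)
}

#' Family membership and abundance summary
#'
#' A family member is a distinct catalog mature name (letter and arm variants
#' collapse only by exact name). Abundance is the per-library sum of
#' per-million normalized counts over the family's hits.
#'
#' @param hits known-hit data.frame with `name`, `family`, `count_a`,
#'   `count_b`.
#' @param La,Lb library sizes for normalization.
#' @return data.frame `family`, `members`, `abundance_a`, `abundance_b`,
#'   sorted by decreasing member count.
#' @export
family_summary <- function(hits, La, Lb) {
  if (!nrow(hits)) {
    return(data.frame(family = character(0), members = integer(0),
                      abundance_a = numeric(0), abundance_b = numeric(0),
                      stringsAsFactors = FALSE))
  }
  fam <- split(hits, hits$family)
  out <- do.call(rbind, lapply(names(fam), function(f) {
    h <- fam[[f]]
    data.frame(family = f, members = length(unique(h$name)),
               abundance_a = sum(normalize_cpm(h$count_a, La)),
               abundance_b = sum(normalize_cpm(h$count_b, Lb)),
               stringsAsFactors = FALSE)
  }))
  out <- out[order(-out$members, out$family), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Co-expression (Venn) sets of identified miRNAs
#'
#' Splits distinct miRNAs into expressed-in-A-only, expressed-in-B-only and
#' co-expressed, keyed on count > 0 per library.
#'
#' @param hits known-hit data.frame; distinctness by `full_name` when
#'   present, else by sequence.
#' @return list with character vectors `a_only`, `b_only`, `both` and the
#'   `sizes` vector (the three sizes always sum to the number of distinct
#'   miRNAs).
#' @export
co_expression <- function(hits) {
  key <- if ("full_name" %in% names(hits)) hits$full_name else hits$seq
  agg_a <- tapply(hits$count_a, key, sum)
  agg_b <- tapply(hits$count_b, key, sum)
  ids <- names(agg_a)
  in_a <- agg_a > 0
  in_b <- agg_b[ids] > 0
  out <- list(a_only = ids[in_a & !in_b],
              b_only = ids[!in_a & in_b],
              both = ids[in_a & in_b])
  out$sizes <- c(a_only = length(out$a_only), b_only = length(out$b_only),
                 both = length(out$both))
  out
}

#' Cross-species occurrence counts over the catalog
#'
#' For each detected mature sequence, counts each catalog species owning an
#' identical mature entry; reports, per species, how many detected miRNAs
#' occur in it. This is occurrence counting over the supplied catalog only.
#'
#' @param hits known-hit data.frame with `seq`.
#' @param catalog a `reference_catalog`.
#' @return data.frame `species`, `occurrences`, sorted decreasing.
#' @export
species_occurrence <- function(hits, catalog) {
  stopifnot(inherits(catalog, "reference_catalog"))
  seqs <- unique(hits$seq)
  cat_df <- catalog$mirnas
  counts <- vapply(unique(cat_df$species), function(sp) {
    sum(seqs %in% cat_df$mature[cat_df$species == sp])
  }, numeric(1))
  out <- data.frame(species = names(counts), occurrences = as.numeric(counts),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$occurrences, out$species), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Full descriptive profile
#'
#' @param crs a `clean_read_set`.
#' @param hits known-hit data.frame.
#' @param catalog a `reference_catalog`.
#' @return list with `length_dist`, `first_nt`, `families`, `venn`,
#'   `occurrence`.
#' @export
profile_report <- function(crs, hits, catalog) {
  La <- sum(crs$reads$count_a)
  Lb <- sum(crs$reads$count_b)
  list(length_dist = length_distribution(crs),
       first_nt = if (nrow(hits)) first_nt_bias(hits) else NULL,
       families = family_summary(hits, max(La, 1), max(Lb, 1)),
       venn = if (nrow(hits)) co_expression(hits) else
         list(a_only = character(0), b_only = character(0),
              both = character(0),
              sizes = c(a_only = 0, b_only = 0, both = 0)),
       occurrence = if (nrow(hits)) species_occurrence(hits, catalog) else
         NULL)
}
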