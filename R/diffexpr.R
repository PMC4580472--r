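# Two-library differential expression on miRNA counts: per-million
# normalization, log2 fold change with presence/absence sentinels, 2x2 Fisher
# exact and chi-square tests, Bonferroni adjustment, and the threshold
# classification into up / down / ns.
#
# Direction convention: fold change = log2(library A / library B) on
# normalized counts, with A the first condition (lag phase in the motivating
# study); positive fold changes are called "up".

#' Per-million normalization
#'
#' @param count raw count(s), >= 0.
#' @param library_size clean-read total of the library, > 0.
#' @return `1e6 * count / library_size`.
#' @export
normalize_cpm <- function(count, library_size) {
  if (!is.numeric(library_size) || any(library_size <= 0)) {
    stop("library_size must be > 0")
  }
  if (any(count < 0)) stop("counts must be >= 0")
  1e6 * count / library_size
}

#' Log2 fold change with infinity sentinels
#'
#' `log2(na / nb)`; when only `na` is zero the result is `-Inf`, when only
#' `nb` is zero it is `+Inf`. Both zero is undefined (`NA` with a warning):
#' such records are dropped by [de_table()].
#'
#' @param na,nb normalized abundances in libraries A and B.
#' @return numeric vector (possibly `Inf`/`-Inf`/`NA`).
#' @export
fold_change <- function(na, nb) {
  out <- ifelse(na == 0 & nb == 0, NA_real_,
                ifelse(na == 0, -Inf, ifelse(nb == 0, Inf, log2(na / nb))))
  if (any(is.na(out) & !is.na(na) & !is.na(nb))) {
    warning("fold change undefined for records with zero counts in both ",
            "libraries; returned NA")
  }
  out
}

#' 2x2 count significance tests
#'
#' Tests the table `[[a, La - a], [b, Lb - b]]` with the two-sided Fisher
#' exact test (hypergeometric enumeration of tables at most as probable as
#' the observed one) and the 1-df chi-square test without continuity
#' correction. A degenerate table with `a = b = 0` gives p = 1 for both.
#'
#' @param a,b raw counts in libraries A and B.
#' @param La,Lb library sizes (clean totals), > counts.
#' @return named numeric vector `c(p_fisher, p_chisq)`.
#' @export
test_counts <- function(a, b, La, Lb) {
  stopifnot(a >= 0, b >= 0, La > a, Lb > b)
  if (a == 0 && b == 0) {
    return(c(p_fisher = 1, p_chisq = 1))
  }
  tab <- matrix(c(a, La - a, b, Lb - b), nrow = 2, byrow = TRUE)
  pf <- stats::fisher.test(tab)$p.value
  pc <- suppressWarnings(stats::chisq.test(tab, correct = FALSE)$p.value)
  c(p_fisher = min(pf, 1), p_chisq = pc)
}

#' Classify a record as differentially expressed
#'
#' DE iff `|log2fc| > fc_thresh` (infinite fold changes count as exceeding
#' any threshold) and `p < p_thresh`; the direction is the sign of the fold
#' change (`up` for positive). `significant` additionally requires
#' `p < strict_thresh`.
#'
#' @param log2fc log2 fold change(s), infinities allowed.
#' @param p gating p value(s).
#' @param fc_thresh fold-change threshold (default 1).
#' @param p_thresh DE p threshold (default 0.05).
#' @param strict_thresh stricter significance tier (default 0.01).
#' @return data.frame with `call` (`"up"`/`"down"`/`"ns"`) and
#'   `significant_01` (logical).
#' @export
classify_de <- function(log2fc, p, fc_thresh = 1, p_thresh = 0.05,
                        strict_thresh = 0.01) {
  de <- abs(log2fc) > fc_thresh & p < p_thresh
  call <- ifelse(!de | is.na(de), "ns", ifelse(log2fc > 0, "up", "down"))
  data.frame(call = call,
             significant_01 = de & p < strict_thresh,
             stringsAsFactors = FALSE)
}

#' Build the full differential-expression table
#'
#' Per miRNA: normalized counts, fold change, Fisher and chi-square p values,
#' Bonferroni-adjusted gate p, and the DE call. The gating p value is the
#' chi-square p when all four expected cells are >= 5, otherwise the Fisher
#' exact p; classification uses the raw gate p unless `use_adjusted = TRUE`.
#' Records with zero counts in both libraries are dropped with a warning.
#'
#' @param ids miRNA identifiers.
#' @param a,b raw counts per library.
#' @param La,Lb library sizes (clean totals).
#' @param fc_thresh,p_thresh,strict_thresh see [classify_de()].
#' @param use_adjusted gate on the Bonferroni-adjusted p instead of the raw p
#'   (default FALSE, matching the motivating study's printed table).
#' @return data.frame of class `de_table`: `id`, `count_a`, `count_b`, `na`,
#'   `nb`, `log2fc`, `p_fisher`, `p_chisq`, `p_gate`, `p_adj`, `call`,
#'   `significant_01`.
#' @export
de_table <- function(ids, a, b, La, Lb, fc_thresh = 1, p_thresh = 0.05,
                     strict_thresh = 0.01, use_adjusted = FALSE) {
  stopifnot(length(ids) == length(a), length(a) == length(b))
  keep <- !(a == 0 & b == 0)
  if (any(!keep)) {
    warning(sum(!keep), " record(s) with zero counts in both libraries ",
            "dropped")
  }
  ids <- ids[keep]; a <- a[keep]; b <- b[keep]
  if (!length(ids)) {
    out <- data.frame(id = character(0), count_a = numeric(0),
                      count_b = numeric(0), na = numeric(0), nb = numeric(0),
                      log2fc = numeric(0), p_fisher = numeric(0),
                      p_chisq = numeric(0), p_gate = numeric(0),
                      p_adj = numeric(0), call = character(0),
                      significant_01 = logical(0), stringsAsFactors = FALSE)
    class(out) <- c("de_table", "data.frame")
    return(out)
  }
  na <- normalize_cpm(a, La)
  nb <- normalize_cpm(b, Lb)
  lfc <- suppressWarnings(fold_change(na, nb))
  tests <- t(mapply(test_counts, a, b, MoreArgs = list(La = La, Lb = Lb)))
  # expected cells of the 2x2 under independence
  exp_ok <- mapply(function(ai, bi) {
    tot <- La + Lb
    e <- outer(c(ai + bi, tot - ai - bi), c(La, Lb)) / tot
    all(e >= 5)
  }, a, b)
  p_gate <- ifelse(exp_ok, tests[, "p_chisq"], tests[, "p_fisher"])
  m <- length(ids)
  p_adj <- pmin(1, p_gate * m)
  cls <- classify_de(lfc, if (use_adjusted) p_adj else p_gate,
                     fc_thresh, p_thresh, strict_thresh)
  out <- data.frame(id = ids, count_a = a, count_b = b, na = na, nb = nb,
                    log2fc = lfc, p_fisher = tests[, "p_fisher"],
                    p_chisq = tests[, "p_chisq"], p_gate = p_gate,
                    p_adj = p_adj, call = cls$call,
                    significant_01 = cls$significant_01,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("de_table", "data.frame")
  out
}

#' Write a DE table as TSV
#'
#' Infinite fold changes are serialized as `+inf` / `-inf`.
#'
#' @param de a `de_table`.
#' @param path output path.
#' @export
write_de_table <- function(de, path) {
  out <- as.data.frame(de)
  out$log2fc <- ifelse(is.infinite(out$log2fc),
                       ifelse(out$log2fc > 0, "+inf", "-inf"),
                       formatC(out$log2fc, format = "f", digits = 4))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
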