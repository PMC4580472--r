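# Term enrichment over predicted target-gene lists: the upper-tail
# hypergeometric statistic evaluated from its explicit finite sum, and the
# one-sided Fisher exact alternative. Target-site prediction itself is out of
# scope; the module ingests a precomputed miRNA -> target-gene table.

.check_enrichment_input <- function(N, n, M, m) {
  if (any(c(N, n, M, m) < 0) || n > N || M > N || m > min(n, M) ||
      n - m > N - M) {
    stop("invalid enrichment input: need max(0, n - (N - M)) <= m <= ",
         "min(n, M), n <= N, M <= N")
  }
  invisible(TRUE)
}

#' Upper-tail hypergeometric enrichment p value
#'
#' Evaluates `P = 1 - sum_{i=0}^{m-1} C(M,i) C(N-M,n-i) / C(N,n)`, the
#' probability of drawing at least `m` term-annotated genes when `n` genes
#' are drawn from a background of `N` of which `M` carry the term. The sum is
#' evaluated term by term through log-binomials, which is exact to double
#' precision for any desk-scale `N`.
#'
#' @param N background size (genes with annotation).
#' @param n number of differentially-targeted genes within the background.
#' @param M genes annotated to the term.
#' @param m target genes annotated to the term.
#' @return p value between 0 and 1; `m = 0` gives exactly 1 (empty sum).
#' @export
#' @examples
#' hypergeom_p(N = 10, n = 3, M = 4, m = 2)  # 1/3
hypergeom_p <- function(N, n, M, m) {
  .check_enrichment_input(N, n, M, m)
  if (m == 0) return(1)
  i <- 0:(m - 1)
  terms <- exp(lchoose(M, i) + lchoose(N - M, n - i) - lchoose(N, n))
  p <- 1 - sum(terms)
  min(max(p, 0), 1)
}

#' One-sided (enrichment-tail) Fisher exact p value
#'
#' Fisher exact test on the table `[[m, n-m], [M-m, N-M-(n-m)]]` with the
#' `greater` alternative; by construction this equals the hypergeometric
#' upper tail of [hypergeom_p()].
#'
#' @inheritParams hypergeom_p
#' @return p value between 0 and 1.
#' @export
fisher_p <- function(N, n, M, m) {
  .check_enrichment_input(N, n, M, m)
  tab <- matrix(c(m, n - m, M - m, N - M - (n - m)), nrow = 2, byrow = TRUE)
  stats::fisher.test(tab, alternative = "greater")$p.value
}

#' Term enrichment of a target-gene set
#'
#' Computes per-term counts from the annotation map and background, evaluates
#' both [hypergeom_p()] and [fisher_p()], and flags terms with p below the
#' threshold. Target genes absent from the background are excluded from `n`
#' (with a message). Results are ordered by p value, then term id.
#'
#' @param targets character vector of target gene ids.
#' @param annotation data.frame with columns `gene`, `term` and optionally
#'   `label`.
#' @param background character vector of background gene ids; defaults to all
#'   annotated genes.
#' @param p_thresh enrichment threshold (default 0.05).
#' @param adjust apply Benjamini-Hochberg across terms and flag on the
#'   adjusted p (default FALSE: the bare threshold).
#' @return data.frame of class `enrichment_result`: `term`, `label`, `N`,
#'   `n`, `M`, `m`, `p_hypergeom`, `p_fisher`, (`p_adj` when `adjust`),
#'   `enriched`.
#' @export
enrich <- function(targets, annotation, background = NULL, p_thresh = 0.05,
                   adjust = FALSE) {
  stopifnot(all(c("gene", "term") %in% names(annotation)))
  if (!nrow(annotation)) stop("annotation map is empty")
  annotated <- unique(annotation$gene)
  if (is.null(background)) background <- annotated
  bg <- intersect(annotated, unique(background))
  N <- length(bg)
  tg <- unique(targets)
  dropped <- setdiff(tg, bg)
  if (length(dropped)) {
    message(length(dropped), " target gene(s) absent from the annotated ",
            "background excluded")
  }
  tg <- intersect(tg, bg)
  n <- length(tg)
  ann <- annotation[annotation$gene %in% bg, , drop = FALSE]
  terms <- sort(unique(ann$term))
  rows <- lapply(terms, function(tm) {
    genes_tm <- unique(ann$gene[ann$term == tm])
    M <- length(genes_tm)
    m <- length(intersect(genes_tm, tg))
    lab <- if ("label" %in% names(ann)) ann$label[ann$term == tm][1] else tm
    data.frame(term = tm, label = lab, N = N, n = n, M = M, m = m,
               p_hypergeom = hypergeom_p(N, n, M, m),
               p_fisher = fisher_p(N, n, M, m),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  p <- out$p_hypergeom
  if (adjust) {
    out$p_adj <- stats::p.adjust(p, method = "BH")
    out$enriched <- out$p_adj < p_thresh
  } else {
    out$enriched <- p < p_thresh
  }
  out <- out[order(out$p_hypergeom, out$term), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("enrichment_result", "data.frame")
  out
}

#' Read a two-column gene-to-term annotation map
#'
#' @param path TSV with columns gene, term (and optional third label column);
#'   no header by default.
#' @param header logical.
#' @return annotation data.frame for [enrich()].
#' @export
read_annotation_map <- function(path, header = FALSE) {
  x <- utils::read.table(path, sep = "\t", header = header,
                         stringsAsFactors = FALSE, quote = "")
  names(x)[1:2] <- c("gene", "term")
  if (ncol(x) >= 3) names(x)[3] <- "label"
  x
}
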