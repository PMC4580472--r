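# Comparative-threshold (2^-ddCt) quantification of qPCR Ct tables, with a
# reference gene (e.g. the 5.8S rRNA) and a calibrator sample.

#' Relative expression by the comparative-threshold method
#'
#' For each sample: `dCt = mean Ct(target) - mean Ct(reference)`;
#' `ddCt = dCt(sample) - dCt(calibrator)`; relative expression `2^-ddCt`.
#' The standard error is propagated from the replicate Ct standard
#' deviations (`var(dCt) = var_t/n_t + var_r/n_r`, summed over sample and
#' calibrator, then the delta method on `2^-x`). A two-sided paired t test on
#' the per-replicate dCt values (sample vs calibrator, paired by replicate
#' id) gives the significance tiers `*` (p < 0.05) and `**` (p < 0.01).
#'
#' @param ct data.frame with columns `sample`, `gene`, `replicate`, `ct`
#'   (threshold cycles, > 0).
#' @param target target gene name.
#' @param reference reference (normalizer) gene name.
#' @param calibrator calibrator sample name.
#' @return data.frame, one row per sample: `sample`, `dct`, `ddct`,
#'   `rel_expr`, `se`, `p_value`, `signif`.
#' @export
ddct <- function(ct, target, reference, calibrator) {
  stopifnot(all(c("sample", "gene", "replicate", "ct") %in% names(ct)))
  if (any(ct$ct <= 0)) stop("Ct values must be > 0")
  samples <- unique(ct$sample)
  if (!calibrator %in% samples) stop("calibrator sample '", calibrator,
                                     "' not in table")
  grab <- function(s, g) {
    x <- ct[ct$sample == s & ct$gene == g, , drop = FALSE]
    if (!nrow(x)) stop("no '", g, "' rows for sample '", s, "'")
    x
  }
  dct_stats <- function(s) {
    t_rows <- grab(s, target)
    r_rows <- grab(s, reference)
    list(dct = mean(t_rows$ct) - mean(r_rows$ct),
         var = stats::var(t_rows$ct) / nrow(t_rows) +
           stats::var(r_rows$ct) / nrow(r_rows),
         per_rep = {
           tt <- tapply(t_rows$ct, t_rows$replicate, mean)
           rr <- tapply(r_rows$ct, r_rows$replicate, mean)
           reps <- intersect(names(tt), names(rr))
           setNames(tt[reps] - rr[reps], reps)
         })
  }
  cal <- dct_stats(calibrator)
  rows <- lapply(samples, function(s) {
    st <- dct_stats(s)
    dd <- st$dct - cal$dct
    rel <- 2^(-dd)
    se_dd <- sqrt((if (is.na(st$var)) 0 else st$var) +
                  (if (s == calibrator) 0
                   else if (is.na(cal$var)) 0 else cal$var))
    se <- log(2) * rel * se_dd
    p <- NA_real_
    if (s != calibrator) {
      reps <- intersect(names(st$per_rep), names(cal$per_rep))
      if (length(reps) >= 2) {
        p <- tryCatch(stats::t.test(st$per_rep[reps], cal$per_rep[reps],
                                    paired = TRUE)$p.value,
                      error = function(e) NA_real_)
      }
    }
    data.frame(sample = s, dct = st$dct, ddct = dd, rel_expr = rel, se = se,
               p_value = p,
               signif = if (is.na(p)) "" else if (p < 0.01) "**"
                        else if (p < 0.05) "*" else "",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Read a Ct table from CSV
#'
#' @param path CSV with header columns sample, gene, replicate, ct.
#' @return data.frame for [ddct()].
#' @export
read_ct_table <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
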