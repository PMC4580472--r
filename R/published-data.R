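# Bundled summary tables from the Alexandrium catenella two-growth-phase
# small RNA dataset (lag phase = library A, logarithmic phase = library B).
# These are inputs for worked examples and internal consistency checks of the
# report arithmetic; they are read-only reference data, not recomputed.

.extdata <- function(name) {
  path <- system.file("extdata", name, package = "dinomir")
  if (!nzchar(path)) stop("bundled table not found: ", name)
  path
}

#' Bundled A. catenella summary tables
#'
#' `acatenella_de_table()`: the twelve differentially expressed miRNAs with
#' their reported log2 fold changes (lag/log; `+inf`/`-inf` parsed to
#' infinities), chi-square 2x2 p values and direction calls.
#' `acatenella_novel_table()`: the fifteen novel miRNA candidates with mature
#' sequence and length, precursor length, GC\% and folding energy.
#' `acatenella_read_stats()`: the per-library read accounting (raw,
#' filter/junk categories, clean), total and unique.
#' `acatenella_class_stats()`: per-library counts for the contaminant ncRNA
#' classes.
#'
#' @return a data.frame.
#' @export
acatenella_de_table <- function() {
  x <- utils::read.table(.extdata("acatenella_de_mirnas.tsv"), sep = "\t",
                         header = TRUE, stringsAsFactors = FALSE,
                         colClasses = c("character", "character", "numeric",
                                        "character"))
  x$log2fc <- vapply(x$log2fc, function(v) {
    if (v == "+inf") Inf else if (v == "-inf") -Inf else as.numeric(v)
  }, numeric(1), USE.NAMES = FALSE)
  x
}

#' @rdname acatenella_de_table
#' @export
acatenella_novel_table <- function() {
  utils::read.table(.extdata("acatenella_novel_mirnas.tsv"), sep = "\t",
                    header = TRUE, stringsAsFactors = FALSE)
}

#' @rdname acatenella_de_table
#' @export
acatenella_read_stats <- function() {
  utils::read.table(.extdata("acatenella_read_stats.tsv"), sep = "\t",
                    header = TRUE, stringsAsFactors = FALSE, quote = "")
}

#' @rdname acatenella_de_table
#' @export
acatenella_class_stats <- function() {
  utils::read.table(.extdata("acatenella_rna_classes.tsv"), sep = "\t",
                    header = TRUE, stringsAsFactors = FALSE)
}
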