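# Independent oracles used across the suite. Deliberately naive: plain
# enumeration / recursion, no shared code with the package internals.

# maximum number of non-crossing complementary pairs (plain Nussinov, no
# stacking, unit scores) by memoized recursion
bf_max_pairs <- function(seq, min_loop = 3L) {
  b <- strsplit(toupper(chartr("u", "T", seq)), "")[[1]]
  can <- function(x, y) {
    p <- paste0(x, y)
    p %in% c("AT", "TA", "GC", "CG", "GT", "TG")
  }
  n <- length(b)
  memo <- new.env(hash = TRUE)
  f <- function(i, j) {
    if (j - i < min_loop + 1L) return(0L)
    key <- paste(i, j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    best <- f(i, j - 1L)
    for (k in i:(j - min_loop - 1L)) {
      if (can(b[k], b[j])) {
        cand <- 1L + (if (k > i) f(i, k - 1L) else 0L) + f(k + 1L, j - 1L)
        if (cand > best) best <- cand
      }
    }
    memo[[key]] <- best
    best
  }
  if (n < min_loop + 2L) 0L else f(1L, n)
}

# exhaustive hypergeometric upper tail: enumerate all C(N, n) draws from an
# urn with M specials, count draws with >= m specials
enum_hypergeom_tail <- function(N, n, M, m) {
  draws <- utils::combn(N, n)
  special <- seq_len(M)
  hits <- apply(draws, 2, function(d) sum(d %in% special))
  mean(hits >= m)
}

# brute-force two-sided Fisher p for table [[a, La-a], [b, Lb-b]]: sum the
# probabilities (via choose()) of all tables with the same margins that are
# at most as probable as the observed one
bf_fisher_two_sided <- function(a, b, La, Lb) {
  r1 <- La; r2 <- Lb; c1 <- a + b
  lo <- max(0, c1 - r2); hi <- min(c1, r1)
  pr <- function(x) {
    exp(lchoose(r1, x) + lchoose(r2, c1 - x) - lchoose(r1 + r2, c1))
  }
  pobs <- pr(a)
  xs <- lo:hi
  sum(vapply(xs, pr, numeric(1))[vapply(xs, pr, numeric(1)) <=
                                   pobs * (1 + 1e-7)])
}

# spreadsheet-style ddCt recomputation
oracle_ddct <- function(ct, target, reference, sample, calibrator) {
  dct <- function(s) {
    mean(ct$ct[ct$sample == s & ct$gene == target]) -
      mean(ct$ct[ct$sample == s & ct$gene == reference])
  }
  2^(-(dct(sample) - dct(calibrator)))
}
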