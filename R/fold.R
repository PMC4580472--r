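# Secondary-structure prediction for candidate precursor windows.
#
# The internal folder is a maximum base-pairing dynamic program (Nussinov-style)
# with a stacking bonus and a pseudo-energy readout; it is NOT a thermodynamic
# nearest-neighbour model. Externally computed Vienna structures (e.g. from
# RNAfold) can be supplied instead and bypass the internal folder entirely.

# Pair score lookup. Canonical pairs in T-space: A:T, G:C and the G:T wobble.
.pair_score_matrix <- function(pair_scores = c(AT = 2, GC = 3, GT = 1)) {
  bases <- c("A", "C", "G", "T")
  S <- matrix(0, 4, 4, dimnames = list(bases, bases))
  S["A", "T"] <- S["T", "A"] <- pair_scores[["AT"]]
  S["G", "C"] <- S["C", "G"] <- pair_scores[["GC"]]
  S["G", "T"] <- S["T", "G"] <- pair_scores[["GT"]]
  S
}

#' Fold a sequence into a hairpin-compatible secondary structure
#'
#' Computes a pseudo-knot-free secondary structure by dynamic programming that
#' maximizes a weighted pair score (`AT`/`AU` = 2, `GC` = 3, `GT`/`GU` = 1 by
#' default) plus a bonus of `stack_bonus` for every stacked pair (a pair whose
#' immediately inner neighbour is also paired), with a minimum hairpin loop of
#' `min_loop` unpaired bases. The reported energy is a pseudo-energy,
#' `-score / 2` kcal/mol: more negative means more (and better-stacked)
#' pairing. Traceback is deterministic: on ties, pairing is preferred over not
#' pairing, stacking over branching, and the leftmost partner is chosen.
#'
#' Alternatively, an externally computed structure (Vienna dot-bracket plus
#' energy, e.g. RNAfold output) can be passed via `structure`/`energy`, in
#' which case the internal folder is bypassed and the supplied structure is
#' validated (balanced brackets, complementary pairs) and wrapped.
#'
#' @param sequence nucleotide string (RNA or DNA alphabet; U and T equivalent).
#' @param structure optional dot-bracket string of the same length; supplying
#'   it bypasses the internal folder.
#' @param energy optional energy in kcal/mol accompanying `structure`.
#' @param pair_scores named numeric vector with elements `AT`, `GC`, `GT`.
#' @param stack_bonus score bonus per stacked pair (default 1).
#' @param min_loop minimum number of unpaired bases in a hairpin loop
#'   (default 3).
#' @param min_len,max_len admissible sequence length bounds for the internal
#'   folder (defaults 50 and 400 nt); sequences outside are rejected.
#' @return an object of class `secondary_structure`: a list with elements
#'   `sequence`, `dot_bracket`, `energy` (kcal/mol), `pairs` (integer vector,
#'   `pairs[i]` = partner of i or 0) and `score`.
#' @export
#' @examples
#' hp <- paste0("GGGGGGGGGGGGGGGGGGGGGGGGG", "AACAA",
#'              "CCCCCCCCCCCCCCCCCCCCCCCCC")
#' fold_rna(hp)
fold_rna <- function(sequence, structure = NULL, energy = NULL,
                     pair_scores = c(AT = 2, GC = 3, GT = 1),
                     stack_bonus = 1, min_loop = 3L,
                     min_len = 50L, max_len = 400L) {
  seq_t <- norm_seq(sequence)
  n <- nchar(seq_t)

  if (!is.null(structure)) {
    if (nchar(structure) != n) {
      stop("dot-bracket length (", nchar(structure),
           ") does not match sequence length (", n, ")")
    }
    pairs <- parse_dot_bracket(structure)
    .check_pair_complementarity(seq_t, pairs)
    out <- list(sequence = seq_t, dot_bracket = structure,
                energy = if (is.null(energy)) NA_real_ else energy,
                pairs = pairs, score = NA_real_)
    class(out) <- "secondary_structure"
    return(out)
  }

  if (n < min_len || n > max_len) {
    stop("sequence length ", n, " outside admissible folding range [",
         min_len, ", ", max_len, "] nt")
  }

  res <- nussinov_stack(seq_t, pair_scores = pair_scores,
                        stack_bonus = stack_bonus, min_loop = min_loop)
  out <- list(sequence = seq_t,
              dot_bracket = res$dot_bracket,
              energy = -res$score * 0.5,
              pairs = res$pairs,
              score = res$score)
  class(out) <- "secondary_structure"
  out
}

#' Maximum weighted base-pairing with stacking (internal DP engine)
#'
#' Exposed mainly so the traceback and scoring can be tested directly at any
#' length; `fold_rna()` enforces the precursor length window around it.
#'
#' @inheritParams fold_rna
#' @return list with `score`, `pairs`, `dot_bracket`.
#' @export
nussinov_stack <- function(sequence,
                           pair_scores = c(AT = 2, GC = 3, GT = 1),
                           stack_bonus = 1, min_loop = 3L) {
  seq_t <- norm_seq(sequence)
  b <- seq_chars(seq_t)
  n <- length(b)
  S <- .pair_score_matrix(pair_scores)
  bases <- c("A", "C", "G", "T")
  ci <- match(b, bases)          # NA for N and friends -> cannot pair
  sc_of <- function(i, j) {
    if (is.na(ci[i]) || is.na(ci[j])) 0 else S[ci[i], ci[j]]
  }

  pairs <- integer(n)
  if (n < min_loop + 2L) {
    return(list(score = 0,
                pairs = pairs,
                dot_bracket = paste(rep(".", n), collapse = "")))
  }

  V <- matrix(-Inf, n, n)  # best score given (i,j) paired
  W <- matrix(0, n, n)     # best score on i..j

  for (span in seq(min_loop + 1L, n - 1L)) {
    for (i in seq_len(n - span)) {
      j <- i + span
      sc <- sc_of(i, j)
      if (sc > 0) {
        inner <- W[i + 1L, j - 1L]
        stk <- V[i + 1L, j - 1L] + stack_bonus
        V[i, j] <- sc + max(inner, stk)
      }
      ks <- i:(j - min_loop - 1L)
      vk <- V[ks, j]
      fin <- which(is.finite(vk))
      best <- W[i, j - 1L]
      if (length(fin)) {
        wk <- numeric(length(ks))
        if (length(ks) > 1L) wk[-1L] <- W[i, ks[-1L] - 1L]
        best <- max(best, max(wk[fin] + vk[fin]))
      }
      W[i, j] <- best
    }
  }

  # Deterministic traceback: prefer pairing, then stacking, then leftmost k.
  stack <- list(list(i = 1L, j = n, type = "W"))
  while (length(stack)) {
    fr <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    i <- fr$i; j <- fr$j
    if (fr$type == "W") {
      if (j - i < min_loop + 1L || W[i, j] <= 0) next
      target <- W[i, j]
      paired <- FALSE
      for (k in i:(j - min_loop - 1L)) {
        if (!is.finite(V[k, j])) next
        cand <- V[k, j] + if (k > i) W[i, k - 1L] else 0
        if (cand == target) {
          stack[[length(stack) + 1L]] <- list(i = k, j = j, type = "V")
          if (k > i) {
            stack[[length(stack) + 1L]] <- list(i = i, j = k - 1L, type = "W")
          }
          paired <- TRUE
          break
        }
      }
      if (!paired) {
        stack[[length(stack) + 1L]] <- list(i = i, j = j - 1L, type = "W")
      }
    } else {                      # V: (i,j) are paired
      pairs[i] <- j
      pairs[j] <- i
      sc <- sc_of(i, j)
      stk <- V[i + 1L, j - 1L] + stack_bonus
      if (is.finite(stk) && sc + stk == V[i, j]) {
        stack[[length(stack) + 1L]] <- list(i = i + 1L, j = j - 1L, type = "V")
      } else if ((j - 1L) - (i + 1L) >= min_loop + 1L) {
        stack[[length(stack) + 1L]] <- list(i = i + 1L, j = j - 1L, type = "W")
      }
    }
  }

  db <- rep(".", n)
  db[pairs > seq_len(n)] <- "("
  db[pairs != 0 & pairs < seq_len(n)] <- ")"
  list(score = W[1L, n], pairs = pairs,
       dot_bracket = paste(db, collapse = ""))
}

#' Parse a dot-bracket string into a pair table
#'
#' @param dot_bracket string over `.`, `(`, `)`.
#' @return integer vector `p` with `p[i]` the 1-based partner of position i,
#'   or 0 if unpaired.
#' @export
parse_dot_bracket <- function(dot_bracket) {
  ch <- seq_chars(dot_bracket)
  bad <- setdiff(unique(ch), c(".", "(", ")"))
  if (length(bad)) stop("invalid dot-bracket characters: ",
                        paste(bad, collapse = " "))
  n <- length(ch)
  pairs <- integer(n)
  open <- integer(0)
  for (i in seq_len(n)) {
    if (ch[i] == "(") {
      open <- c(open, i)
    } else if (ch[i] == ")") {
      if (!length(open)) stop("unbalanced dot-bracket: unmatched ')' at ", i)
      j <- open[length(open)]
      open <- open[-length(open)]
      pairs[i] <- j
      pairs[j] <- i
    }
  }
  if (length(open)) stop("unbalanced dot-bracket: unmatched '(' at ",
                         paste(open, collapse = ","))
  pairs
}

.check_pair_complementarity <- function(seq_t, pairs) {
  S <- .pair_score_matrix()
  b <- seq_chars(seq_t)
  idx <- which(pairs > seq_along(pairs))
  for (i in idx) {
    j <- pairs[i]
    if (!(b[i] %in% rownames(S)) || !(b[j] %in% rownames(S)) ||
        S[b[i], b[j]] == 0) {
      stop("non-complementary pair ", b[i], "-", b[j],
           " at positions ", i, ",", j)
    }
  }
  invisible(TRUE)
}

#' @export
print.secondary_structure <- function(x, ...) {
  cat("Secondary structure (", nchar(x$sequence), " nt, ",
      sum(x$pairs > 0) / 2, " pairs, energy ",
      formatC(x$energy, format = "f", digits = 1), " kcal/mol)\n", sep = "")
  cat(to_rna(x$sequence), "\n", x$dot_bracket, "\n", sep = "")
  invisible(x)
}

#' Read and write Vienna-format structure files
#'
#' Vienna format, as produced by RNAfold: a FASTA-like header line, the
#' sequence line, then the dot-bracket line with the energy in parentheses,
#' e.g. `"((((...)))) (-12.30)"`.
#'
#' @param path file path.
#' @return `read_vienna()`: a named list of `secondary_structure` objects.
#' @export
read_vienna <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- list()
  i <- 1L
  while (i + 2L <= length(lines)) {
    if (!startsWith(lines[i], ">")) stop("expected '>' header at line ", i)
    name <- sub("^>", "", lines[i])
    seqline <- lines[i + 1L]
    stline <- lines[i + 2L]
    m <- regmatches(stline, regexec("^([.()]+)\\s*\\(\\s*(-?[0-9.]+)\\s*\\)\\s*$",
                                    stline))[[1]]
    if (length(m) == 3L) {
      db <- m[2]; en <- as.numeric(m[3])
    } else {
      db <- gsub("\\s.*$", "", stline); en <- NA_real_
    }
    out[[name]] <- fold_rna(seqline, structure = db, energy = en)
    i <- i + 3L
  }
  out
}

#' @param structures named list of `secondary_structure` objects.
#' @rdname read_vienna
#' @export
write_vienna <- function(structures, path) {
  lines <- unlist(lapply(names(structures), function(nm) {
    s <- structures[[nm]]
    c(paste0(">", nm),
      to_rna(s$sequence),
      paste0(s$dot_bracket, " (",
             formatC(ifelse(is.na(s$energy), 0, s$energy),
                     format = "f", digits = 2), ")"))
  }))
  writeLines(lines, path)
  invisible(path)
}
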