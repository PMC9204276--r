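# Independent oracles, deliberately written without any of the package's
# internal machinery: plain substring enumeration and non-log arithmetic.

DNA4 <- c("A", "C", "G", "T")
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

oracle_windows <- function(s, k, chars) {
  n <- nchar(s)
  if (n < k) return(character(0))
  w <- substring(s, 1:(n - k + 1), k:n)
  w[vapply(strsplit(w, ""), function(x) all(x %in% chars), logical(1))]
}

# class-conditional smoothed word probability from raw training counts
oracle_prob <- function(word, train_seqs, k, alpha, chars) {
  wins <- unlist(lapply(train_seqs, oracle_windows, k = k, chars = chars))
  (sum(wins == word) + alpha) / (length(wins) + alpha * length(chars)^nchar(word))
}

# Direct evaluation of the two-class k-mer naive Bayes score in non-log
# arithmetic: prior times the product of k-mer probabilities over all
# offsets, divided by the product of (k-1)-mer probabilities over interior
# offsets 2..n-k+1 ("printed") or 2..n-k+2 ("textbook"). Ambiguous windows
# contribute nothing to either product.
oracle_nbk_score <- function(query, train, k, alpha = 1, chars = DNA4,
                             boundary = "printed") {
  classes <- c("c0", "c1")
  n <- nchar(query)
  sapply(classes, function(cl) {
    seqs_cl <- train$seq[train$class == cl]
    prior <- length(seqs_cl) / nrow(train)
    num <- 1
    for (i in seq_len(max(n - k + 1, 0))) {
      w <- substr(query, i, i + k - 1)
      if (all(strsplit(w, "")[[1]] %in% chars)) {
        num <- num * oracle_prob(w, seqs_cl, k, alpha, chars)
      }
    }
    den <- 1
    if (k >= 2) {
      last <- if (boundary == "printed") n - k + 1 else n - k + 2
      # training table for the denominator uses the same interior offsets
      tr_wins <- unlist(lapply(seqs_cl, function(s) {
        m <- nchar(s)
        lw <- if (boundary == "printed") m - k + 1 else m - k + 2
        if (lw < 2) return(character(0))
        w <- substring(s, 2:lw, (2:lw) + k - 2)
        w[vapply(strsplit(w, ""), function(x) all(x %in% chars), logical(1))]
      }))
      W <- length(tr_wins)
      for (i in seq_len(max(last - 1, 0)) + 1) {
        if (i > n - k + 2) next
        w <- substr(query, i, i + k - 2)
        if (all(strsplit(w, "")[[1]] %in% chars)) {
          den <- den * (sum(tr_wins == w) + alpha) /
            (W + alpha * length(chars)^(k - 1))
        }
      }
    }
    prior * num / den
  })
}

# Eq.-style single-letter classifier: prior times the product of smoothed
# per-letter probabilities (the k = 1 special case, no denominator).
oracle_nb1_class <- function(query, train, alpha = 1, chars = DNA4) {
  s <- oracle_nbk_score(query, train, k = 1, alpha = alpha, chars = chars)
  if (s[["c1"]] > s[["c0"]]) "c1" else "c0"
}

# nearest-rank percentile by brute force: count how many values pass
oracle_top_cutoff <- function(values, percent) {
  r <- ceiling(percent / 100 * length(values))
  sort(values, decreasing = TRUE)[r]
}

random_dna <- function(n, with_ambiguity = FALSE) {
  chars <- if (with_ambiguity) c(DNA4, "N") else DNA4
  paste(sample(chars, n, replace = TRUE,
               prob = if (with_ambiguity) c(rep(0.23, 4), 0.08) else NULL),
        collapse = "")
}

random_protein <- function(n) paste(sample(AA20, n, replace = TRUE), collapse = "")

# small wide expression table written to a temp file
write_expr_file <- function(df) {
  path <- tempfile(fileext = ".tsv")
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
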