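# ---- k-mer machinery -------------------------------------------------------
#
# k-mers are handled as integer codes in [1, |A|^k] (first letter most
# significant). Windows containing any symbol outside the canonical alphabet
# encode as NA and are skipped — symmetrically in numerator and denominator
# sums, so the Markov telescoping stays consistent. Counts are kept sparsely
# (named by code) because the protein space 20^k is not materialisable for
# large k; additive smoothing covers every unseen k-mer through a single
# shared probability.

encode_residues <- function(s, alphabet) {
  match(strsplit(toupper(s), "", fixed = TRUE)[[1]], alphabet_chars(alphabet))
}

# codes of all length-k windows at offsets 1..n-k+1 (NA where the window
# contains a non-canonical symbol); numeric to stay exact up to 20^7 < 2^53
window_codes <- function(v, k, A) {
  n <- length(v)
  m <- n - k + 1L
  if (m < 1L) return(numeric(0))
  idx <- numeric(m)
  for (j in 0:(k - 1L)) idx <- idx * A + (v[(1L + j):(m + j)] - 1)
  idx + 1
}

count_codes <- function(codes) {
  codes <- codes[!is.na(codes)]
  if (length(codes) == 0) return(setNames(numeric(0), character(0)))
  tab <- sort(codes, method = "radix")
  r <- rle(tab)
  setNames(as.numeric(r$lengths), format(r$values, scientific = FALSE, trim = TRUE))
}

decode_kmer <- function(code, k, alphabet) {
  chars <- alphabet_chars(alphabet)
  A <- length(chars)
  code <- as.numeric(code) - 1
  out <- matrix("", length(code), k)
  for (j in k:1) {
    out[, j] <- chars[code %% A + 1]
    code <- code %/% A
  }
  apply(out, 1, paste, collapse = "")
}

encode_kmer <- function(kmer, alphabet) {
  A <- length(alphabet_chars(alphabet))
  vapply(kmer, function(s) {
    v <- encode_residues(s, alphabet)
    sum((v - 1) * A^(rev(seq_along(v)) - 1)) + 1
  }, numeric(1), USE.NAMES = FALSE)
}

#' Count overlapping k-mers in sequences
#'
#' Slides a length-`k` window over every offset of each sequence and counts
#' occurrences. Windows containing any symbol outside the canonical alphabet
#' (e.g. N in DNA, X in protein) are skipped; the number of skipped windows is
#' reported in the `n_skipped` attribute. Sequences shorter than `k` yield no
#' counts.
#'
#' @param x a single sequence string, or a sequence tibble (see [seq_tbl()]).
#' @param k word length, an integer in 1..7.
#' @param alphabet `"DNA"` or `"PROTEIN"`; defaults to the tibble's alphabet
#'   attribute when `x` is a sequence tibble.
#' @return For a single string, a tibble `kmer`, `count`; for a sequence
#'   tibble, a tibble `id`, `kmer`, `count`. Attribute `n_skipped` holds the
#'   skipped-window count (per id in the tibble case).
#' @export
count_kmers <- function(x, k, alphabet = NULL) {
  k <- as.integer(k)
  if (is.na(k) || k < 1L || k > 7L) abort("`k` must be an integer in 1..7")
  if (is.character(x) && length(x) == 1L) {
    alphabet <- match_alphabet(alphabet %||% "DNA")
    v <- encode_residues(x, alphabet)
    codes <- window_codes(v, k, length(alphabet_chars(alphabet)))
    cc <- count_codes(codes)
    out <- tibble(kmer = decode_kmer(as.numeric(names(cc)), k, alphabet),
                  count = as.integer(cc))
    out <- out[order(out$kmer), , drop = FALSE]
    attr(out, "n_skipped") <- sum(is.na(codes))
    return(out)
  }
  if (!is.data.frame(x)) abort("`x` must be a string or a sequence tibble")
  alphabet <- match_alphabet(alphabet %||% seq_alphabet(x))
  per <- purrr::map(x$seq, function(s) count_kmers(s, k, alphabet))
  out <- dplyr::bind_rows(setNames(per, x$id), .id = "id")
  attr(out, "n_skipped") <- tibble(
    id = x$id, n_skipped = vapply(per, attr, integer(1), "n_skipped")
  )
  out
}

#' Precompute the k-mer profile of a sequence corpus
#'
#' The NB(k) score of a sequence needs its k-mer counts over all offsets
#' (numerator) and its (k-1)-mer counts over the interior offsets matching
#' the model's denominator index range (offsets 2..n-k+1 of the printed
#' form, or 2..n-k+2 of the textbook telescoping variant). Training and
#' scoring both consume this profile; computing it once per corpus and
#' reusing it across cross-validation folds avoids recounting.
#'
#' @param seqs sequence tibble.
#' @inheritParams count_kmers
#' @param boundary `"printed"` (default) or `"textbook"`; see [nbk_train()].
#' @return An object of class `nbk_profile`.
#' @export
nbk_profile <- function(seqs, k, alphabet = NULL,
                        boundary = c("printed", "textbook")) {
  boundary <- match.arg(boundary)
  k <- as.integer(k)
  if (is.na(k) || k < 1L || k > 7L) abort("`k` must be an integer in 1..7")
  alphabet <- match_alphabet(alphabet %||% seq_alphabet(seqs))
  A <- length(alphabet_chars(alphabet))
  ids <- seqs$id
  num_list <- vector("list", length(ids))
  den_list <- vector("list", length(ids))
  n_num <- n_den <- setNames(numeric(length(ids)), ids)
  for (i in seq_along(ids)) {
    v <- encode_residues(seqs$seq[i], alphabet)
    codes <- window_codes(v, k, A)
    codes <- codes[!is.na(codes)]
    n_num[i] <- length(codes)
    cc <- count_codes(codes)
    num_list[[i]] <- if (length(cc))
      data.frame(id = ids[i], code = names(cc), count = as.numeric(cc))
    if (k >= 2L) {
      sub <- window_codes(v, k - 1L, A)   # offsets 1..n-k+2
      L <- length(sub)
      last <- if (boundary == "printed") L - 1L else L
      sub <- if (last >= 2L) sub[2:last] else numeric(0)
      sub <- sub[!is.na(sub)]
      n_den[i] <- length(sub)
      cd <- count_codes(sub)
      den_list[[i]] <- if (length(cd))
        data.frame(id = ids[i], code = names(cd), count = as.numeric(cd))
    }
  }
  empty <- data.frame(id = character(0), code = character(0), count = numeric(0))
  bind_counts <- function(lst) {
    out <- dplyr::bind_rows(lst)
    if (nrow(out) == 0) empty else out
  }
  structure(list(
    num = bind_counts(num_list),
    den = if (k >= 2L) bind_counts(den_list),
    n_num = n_num, n_den = n_den,
    k = k, alphabet = alphabet, boundary = boundary, ids = ids
  ), class = "nbk_profile")
}

smoothed_log_table <- function(counts, total, alpha, space) {
  # log[(count + alpha) / (total + alpha * |A|^k)]; `unseen` covers every
  # k-mer not in `counts`
  denom <- log(total + alpha * space)
  list(lp = setNames(log(as.numeric(counts) + alpha) - denom, names(counts)),
       unseen = log(alpha) - denom)
}

lookup_lp <- function(tab, code) {
  v <- tab$lp[match(code, names(tab$lp))]
  v[is.na(v)] <- tab$unseen
  v
}

class_counts <- function(df, ids_by_class) {
  lapply(ids_by_class, function(ids) {
    sub <- df[df$id %in% ids, , drop = FALSE]
    if (nrow(sub) == 0) return(setNames(numeric(0), character(0)))
    agg <- rowsum(sub$count, sub$code)
    setNames(as.numeric(agg), rownames(agg))
  })
}

#' Train a k-mer naive Bayes (order k-1 Markov) classifier
#'
#' Fits the NB(k) model: per class, additively smoothed probabilities of all
#' k-mers and of the interior (k-1)-mers, plus class priors taken as the
#' class frequencies of the training set (0.5/0.5 after balancing). The
#' smoothed probability of word w is `(count(w) + alpha) / (windows + alpha *
#' |A|^k)`, so both tables sum to one over the full k-mer space including
#' unseen words.
#'
#' The classifier scores a sequence S of length n as
#' `log P(c) + sum_{i=1..n-k+1} log P(kmer_i | c) - sum_{i=2..n-k+1} log
#' P((k-1)mer_i | c)` — the k-mer product corrected for the (k-1)-letter
#' overlap of consecutive windows, i.e. an order-(k-1) Markov chain
#' likelihood up to boundary terms. With `boundary = "printed"` the
#' denominator sum stops at offset n-k+1, leaving one boundary (k-1)-mer
#' uncancelled; `"textbook"` extends it to n-k+2, the exact Markov chain
#' factorisation. At `k = 1` the denominator is empty and the model is the
#' plain single-letter naive Bayes classifier.
#'
#' @param seqs sequence tibble of the training corpus.
#' @param labels data frame with columns `gene` (or `id`) and `class`
#'   (`"c0"`/`"c1"`); only listed sequences are used.
#' @param k word length (1..7).
#' @param alpha additive smoothing pseudocount, > 0 (default 1).
#' @param boundary denominator index-range variant; see Details.
#' @param profile optional precomputed [nbk_profile()] of `seqs` (must match
#'   `k` and `boundary`).
#' @return An object of class `nbk_model`.
#' @export
nbk_train <- function(seqs, labels, k, alpha = 1,
                      boundary = c("printed", "textbook"), profile = NULL) {
  boundary <- match.arg(boundary)
  if (!is.numeric(alpha) || alpha <= 0) abort("`alpha` must be > 0")
  id_col <- if ("gene" %in% names(labels)) "gene" else "id"
  labels <- labels[labels[[id_col]] %in% seqs$id, , drop = FALSE]
  cls <- setNames(as.character(labels$class), labels[[id_col]])
  if (!all(cls %in% c("c0", "c1"))) abort("classes must be 'c0' or 'c1'")
  ids_by_class <- split(names(cls), factor(cls, levels = c("c0", "c1")))
  if (any(lengths(ids_by_class) == 0)) abort("both classes must be represented")

  use <- seqs[seqs$id %in% names(cls), , drop = FALSE]
  if (is.null(profile)) {
    profile <- nbk_profile(use, k, boundary = boundary)
  } else {
    if (!inherits(profile, "nbk_profile") || profile$k != k ||
        profile$boundary != boundary) {
      abort("`profile` does not match k/boundary")
    }
  }
  alphabet <- profile$alphabet
  A <- length(alphabet_chars(alphabet))

  num_counts <- class_counts(profile$num[profile$num$id %in% names(cls), ], ids_by_class)
  num_tot <- vapply(ids_by_class, function(i) sum(profile$n_num[i], na.rm = TRUE), numeric(1))
  if (any(num_tot == 0)) abort("a class has zero valid k-mer windows")
  den_counts <- den_tot <- NULL
  if (k >= 2L) {
    den_counts <- class_counts(profile$den[profile$den$id %in% names(cls), ], ids_by_class)
    den_tot <- vapply(ids_by_class, function(i) sum(profile$n_den[i], na.rm = TRUE), numeric(1))
  }

  n_train <- lengths(ids_by_class)
  priors <- n_train / sum(n_train)
  model <- list(
    k = as.integer(k), alphabet = alphabet, alpha = alpha, boundary = boundary,
    priors = priors, n_train = n_train,
    counts = list(num = num_counts, den = den_counts),
    totals = list(num = num_tot, den = den_tot),
    tables = list(
      num = lapply(c(c0 = "c0", c1 = "c1"), function(cl)
        smoothed_log_table(num_counts[[cl]], num_tot[[cl]], alpha, A^k)),
      den = if (k >= 2L) lapply(c(c0 = "c0", c1 = "c1"), function(cl)
        smoothed_log_table(den_counts[[cl]], den_tot[[cl]], alpha, A^(k - 1)))
    )
  )
  class(model) <- "nbk_model"
  model
}

#' Score sequences under an NB(k) model
#'
#' Computes the per-class log-scores (log prior plus smoothed k-mer
#' log-probabilities minus interior (k-1)-mer log-probabilities). Sequences
#' with zero valid k-mer windows are unscorable: their scores are `NA` and
#' flagged.
#'
#' @param model an [nbk_train()] fit.
#' @param seqs sequence tibble to score.
#' @param profile optional precomputed [nbk_profile()] of `seqs`.
#' @return Tibble `id`, `score_c0`, `score_c1`, `n_windows`, `unscorable`.
#' @export
nbk_score <- function(model, seqs, profile = NULL) {
  if (is.null(profile)) {
    profile <- nbk_profile(seqs, model$k, model$alphabet, model$boundary)
  } else if (profile$k != model$k || profile$boundary != model$boundary ||
             profile$alphabet != model$alphabet) {
    abort("`profile` does not match the model")
  }
  ids <- if (is.null(seqs)) profile$ids else seqs$id
  sums_for <- function(df, tab) {
    if (is.null(df) || nrow(df) == 0) return(setNames(numeric(length(ids)), ids))
    contrib <- rowsum(df$count * lookup_lp(tab, df$code), df$id)
    out <- setNames(numeric(length(ids)), ids)
    out[rownames(contrib)] <- contrib[, 1]
    out
  }
  num <- profile$num[profile$num$id %in% ids, , drop = FALSE]
  den <- if (!is.null(profile$den) && nrow(profile$den)) {
    profile$den[profile$den$id %in% ids, , drop = FALSE]
  }
  score <- function(cl) {
    s <- log(model$priors[[cl]]) + sums_for(num, model$tables$num[[cl]])
    if (model$k >= 2L) s <- s - sums_for(den, model$tables$den[[cl]])
    s
  }
  n_windows <- profile$n_num[ids]
  out <- tibble(id = ids, score_c0 = unname(score("c0")),
                score_c1 = unname(score("c1")),
                n_windows = unname(n_windows),
                unscorable = unname(n_windows == 0))
  out$score_c0[out$unscorable] <- NA_real_
  out$score_c1[out$unscorable] <- NA_real_
  out
}

#' Classify sequences with an NB(k) model
#'
#' Takes the argmax of the class log-scores. Exact ties and unscorable
#' sequences (no valid window) fall back to `c0`, the unexpressed class;
#' unscorable cases are flagged.
#'
#' @inheritParams nbk_score
#' @return Tibble `id`, `class`, `score_c0`, `score_c1`, `unscorable`.
#' @export
nbk_classify <- function(model, seqs, profile = NULL) {
  s <- nbk_score(model, seqs, profile)
  cls <- ifelse(!s$unscorable & s$score_c1 > s$score_c0, "c1", "c0")
  tibble(id = s$id, class = cls, score_c0 = s$score_c0,
         score_c1 = s$score_c1, unscorable = s$unscorable)
}

# Leave-one-out classification of a model's own training genes: each gene is
# scored with its own windows removed from its class's count tables (and the
# priors adjusted), which is exact for count-based NB(k). Genes outside the
# training set get ordinary scores. Used to featurize Phase II training
# vectors without letting a gene's own Phase I label leak into its slots.
nbk_classify_loo <- function(model, profile, labels, ids) {
  id_col <- if ("gene" %in% names(labels)) "gene" else "id"
  cls <- setNames(as.character(labels$class), labels[[id_col]])
  A <- length(alphabet_chars(model$alphabet))
  n_tot <- sum(model$n_train)

  part_sum <- function(df, tab) {
    if (is.null(df) || nrow(df) == 0) return(setNames(numeric(length(ids)), ids))
    agg <- rowsum(df$count * lookup_lp(tab, df$code), df$id)
    out <- setNames(numeric(length(ids)), ids)
    out[rownames(agg)] <- agg[, 1]
    out
  }
  # adjusted own-class sum: log(count - c_g + alpha) summed with the gene's
  # own query counts, minus n_g * log(total - n_g + alpha * space)
  loo_sum <- function(df, counts, totals, n_self, space) {
    out <- setNames(numeric(length(ids)), ids)
    if (is.null(df) || nrow(df) == 0) return(out)
    pool <- counts[match(df$code, names(counts))]
    pool[is.na(pool)] <- 0
    agg <- rowsum(df$count * log(pmax(pool - df$count, 0) + model$alpha), df$id)
    out[rownames(agg)] <- agg[, 1]
    out - n_self[ids] * log(totals - n_self[ids] + model$alpha * space)
  }

  num <- profile$num[profile$num$id %in% ids, , drop = FALSE]
  den <- if (!is.null(profile$den) && nrow(profile$den)) {
    profile$den[profile$den$id %in% ids, , drop = FALSE]
  }
  in_train <- ids %in% names(cls)
  scores <- matrix(NA_real_, length(ids), 2, dimnames = list(ids, c("c0", "c1")))
  for (cl in c("c0", "c1")) {
    plain <- part_sum(num, model$tables$num[[cl]])
    if (model$k >= 2L) plain <- plain - part_sum(den, model$tables$den[[cl]])
    plain <- log(model$priors[[cl]]) + plain
    # self-exclusion applies only where the gene belongs to class cl
    self <- in_train & cls[ids] == cl
    if (any(self) && model$n_train[[cl]] > 1) {
      sid <- ids[self]
      adj <- loo_sum(num[num$id %in% sid, , drop = FALSE],
                     model$counts$num[[cl]], model$totals$num[[cl]],
                     profile$n_num, A^model$k)
      if (model$k >= 2L) {
        adj <- adj - loo_sum(den[den$id %in% sid, , drop = FALSE],
                             model$counts$den[[cl]], model$totals$den[[cl]],
                             profile$n_den, A^(model$k - 1))
      }
      prior_adj <- log((model$n_train[[cl]] - 1) / (n_tot - 1))
      plain[sid] <- prior_adj + adj[sid]
    }
    # the other class's prior also shifts for training genes
    other <- in_train & cls[ids] != cl
    if (any(other)) {
      plain[ids[other]] <- plain[ids[other]] - log(model$priors[[cl]]) +
        log(model$n_train[[cl]] / (n_tot - 1))
    }
    scores[, cl] <- plain
  }
  n_win <- profile$n_num[ids]
  cls_out <- ifelse(n_win > 0 & scores[, "c1"] > scores[, "c0"], "c1", "c0")
  tibble(id = ids, class = unname(cls_out),
         unscorable = unname(n_win == 0))
}

#' Conditional next-residue probabilities implied by an NB(k) model
#'
#' For `k >= 2`, the smoothed k-mer counts induce the order-(k-1) Markov
#' transition estimates `P(a | context) = (count(context a) + alpha) /
#' (sum_b count(context b) + alpha |A|)`. Useful for checking parameter
#' recovery against a generating chain.
#'
#' @param model an [nbk_train()] fit with `k >= 2`.
#' @return Tibble `class`, `context`, `letter`, `prob`; probabilities sum to
#'   one within each (class, context).
#' @export
nbk_conditionals <- function(model) {
  if (model$k < 2L) abort("conditionals require k >= 2")
  chars <- alphabet_chars(model$alphabet)
  A <- length(chars)
  k <- model$k
  n_ctx <- A^(k - 1)
  purrr::map_dfr(c("c0", "c1"), function(cl) {
    cnt <- model$counts$num[[cl]]
    full <- setNames(numeric(A^k), format(seq_len(A^k), scientific = FALSE, trim = TRUE))
    full[names(cnt)] <- cnt
    m <- matrix(full, nrow = n_ctx, ncol = A, byrow = TRUE)
    sm <- m + model$alpha
    p <- sm / rowSums(sm)
    tibble(class = cl,
           context = rep(decode_kmer(seq_len(n_ctx), k - 1L, model$alphabet), A),
           letter = rep(chars, each = n_ctx),
           prob = as.vector(p))
  })
}

# ---- serialization ---------------------------------------------------------

#' Serialize / restore an NB(k) model as JSON
#'
#' The model is written as a versioned JSON document holding alphabet, k,
#' alpha, boundary variant, priors and the raw per-class count tables (keyed
#' by k-mer string), from which the smoothed tables are rebuilt on read.
#'
#' @param model an `nbk_model`.
#' @param path file path.
#' @return `path` invisibly; `nbk_read()` returns the restored `nbk_model`.
#' @export
nbk_write <- function(model, path) {
  named_counts <- function(cnt, k) {
    if (length(cnt) == 0) return(stats::setNames(list(), character(0)))
    as.list(setNames(as.numeric(cnt), decode_kmer(as.numeric(names(cnt)), k, model$alphabet)))
  }
  doc <- list(
    format = "tnbk/nbk_model", version = 1L,
    alphabet = model$alphabet, k = model$k, alpha = model$alpha,
    boundary = model$boundary,
    priors = as.list(model$priors), n_train = as.list(model$n_train),
    totals = list(num = as.list(model$totals$num),
                  den = if (model$k >= 2L) as.list(model$totals$den)),
    counts = list(
      num = lapply(model$counts$num, named_counts, k = model$k),
      den = if (model$k >= 2L) lapply(model$counts$den, named_counts, k = model$k - 1L)
    )
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname nbk_write
#' @export
nbk_read <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$format, "tnbk/nbk_model")) abort("not an nbk_model document")
  k <- as.integer(doc$k)
  alphabet <- doc$alphabet
  A <- length(alphabet_chars(alphabet))
  recode <- function(x) {
    if (length(x) == 0) return(setNames(numeric(0), character(0)))
    cnt <- unlist(x)
    setNames(as.numeric(cnt),
             format(encode_kmer(names(cnt), alphabet), scientific = FALSE, trim = TRUE))
  }
  num_counts <- lapply(doc$counts$num, recode)
  den_counts <- if (k >= 2L) lapply(doc$counts$den, recode)
  num_tot <- unlist(doc$totals$num)
  den_tot <- if (k >= 2L) unlist(doc$totals$den)
  model <- list(
    k = k, alphabet = alphabet, alpha = doc$alpha, boundary = doc$boundary,
    priors = unlist(doc$priors), n_train = unlist(doc$n_train),
    counts = list(num = num_counts, den = den_counts),
    totals = list(num = num_tot, den = den_tot),
    tables = list(
      num = lapply(c(c0 = "c0", c1 = "c1"), function(cl)
        smoothed_log_table(num_counts[[cl]], num_tot[[cl]], doc$alpha, A^k)),
      den = if (k >= 2L) lapply(c(c0 = "c0", c1 = "c1"), function(cl)
        smoothed_log_table(den_counts[[cl]], den_tot[[cl]], doc$alpha, A^(k - 1)))
    )
  )
  class(model) <- "nbk_model"
  model
}

# ---- broom-style methods ---------------------------------------------------

#' @export
generics::tidy

#' @export
generics::glance

#' Tidy an NB(k) model
#'
#' @param x an `nbk_model`.
#' @param ... unused.
#' @return Tibble `order` (k or k-1 table), `class`, `kmer`, `count`,
#'   `log_prob` for every observed word.
#' @method tidy nbk_model
#' @export
tidy.nbk_model <- function(x, ...) {
  one <- function(part, ord) purrr::map_dfr(c("c0", "c1"), function(cl) {
    cnt <- x$counts[[part]][[cl]]
    if (length(cnt) == 0) return(tibble())
    tibble(order = ord, class = cl,
           kmer = decode_kmer(as.numeric(names(cnt)), ord, x$alphabet),
           count = as.numeric(cnt),
           log_prob = unname(lookup_lp(x$tables[[part]][[cl]], names(cnt))))
  })
  out <- one("num", x$k)
  if (x$k >= 2L) out <- dplyr::bind_rows(out, one("den", x$k - 1L))
  dplyr::arrange(out, .data$order, .data$class, .data$kmer)
}

#' @rdname tidy.nbk_model
#' @method glance nbk_model
#' @export
glance.nbk_model <- function(x, ...) {
  tibble(k = x$k, alphabet = x$alphabet, alpha = x$alpha,
         boundary = x$boundary,
         n_c0 = as.integer(x$n_train[["c0"]]), n_c1 = as.integer(x$n_train[["c1"]]),
         prior_c1 = unname(x$priors[["c1"]]),
         kmers_observed = length(x$counts$num$c0) + length(x$counts$num$c1))
}

#' @export
print.nbk_model <- function(x, ...) {
  cat(sprintf("NB(%d) %s classifier (alpha = %g, %s boundary)\n",
              x$k, x$alphabet, x$alpha, x$boundary))
  cat(sprintf("  trained on %d c0 / %d c1 sequences; prior(c1) = %.3f\n",
              x$n_train[["c0"]], x$n_train[["c1"]], x$priors[["c1"]]))
  invisible(x)
}
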