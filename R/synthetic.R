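# ---- synthetic study designs ----------------------------------------------
#
# The generator emulates the statistical structure the two-phase method
# assumes: per-class planted order-(k-1) Markov chains generating sequences,
# and a gene x tissue abundance matrix whose binary tissue labels are
# correlated across tissues through a Gaussian copula (one shared latent
# factor per gene), with class-dependent log-normal abundance and per-tissue
# missingness.

#' Planted Markov chains for the two classes
#'
#' Draws a pair of order-(k-1) Markov chains over the alphabet: the c0 chain
#' has Dirichlet-distributed transition rows; the c1 chain is an
#' exponentially tilted perturbation of it whose strength is set by
#' `separation` (0 = identical chains). Initial context distributions are
#' uniform.
#'
#' @param k word length whose order-(k-1) chain is planted (k >= 1; k = 1
#'   plants i.i.d. letter distributions).
#' @param alphabet `"DNA"` or `"PROTEIN"`.
#' @param separation tilt strength >= 0 controlling how far apart the two
#'   chains are (roughly, per-step KL grows with its square).
#' @param seed integer seed.
#' @param concentration Dirichlet concentration of the base rows (default 5,
#'   mildly non-uniform rows).
#' @return List of class `planted_chains`: `trans` (list `c0`, `c1` of
#'   `|A|^(k-1) x |A|` row-stochastic matrices), `init` (context
#'   distribution), `k`, `alphabet`.
#' @export
planted_chains <- function(k, alphabet = "DNA", separation = 0.5, seed = 1L,
                           concentration = 5) {
  alphabet <- match_alphabet(alphabet)
  A <- length(alphabet_chars(alphabet))
  m <- k - 1L
  n_ctx <- A^m
  withr::with_seed(seed, {
    g <- matrix(stats::rgamma(n_ctx * A, shape = concentration), n_ctx, A)
    p0 <- g / rowSums(g)
    tilt <- matrix(rnorm(n_ctx * A), n_ctx, A)
    p1 <- p0 * exp(separation * tilt)
    p1 <- p1 / rowSums(p1)
  })
  if (any(rowSums(p0) == 0) || any(rowSums(p1) == 0)) abort("degenerate chain row")
  structure(list(trans = list(c0 = p0, c1 = p1),
                 init = rep(1 / n_ctx, n_ctx),
                 k = as.integer(k), alphabet = alphabet),
            class = "planted_chains")
}

#' Per-step KL divergence between the planted chains
#'
#' Mean Kullback-Leibler divergence `KL(c1 row || c0 row)` over contexts,
#' weighted by the stationary context distribution of the c1 chain — the
#' expected per-step log-likelihood-ratio drift that drives classification
#' accuracy on c1 sequences.
#'
#' @param chains a [planted_chains()] object.
#' @return A single non-negative number (nats per step).
#' @export
chain_kl <- function(chains) {
  p0 <- chains$trans$c0
  p1 <- chains$trans$c1
  A <- length(alphabet_chars(chains$alphabet))
  n_ctx <- nrow(p1)
  if (n_ctx == 1) {
    return(sum(p1[1, ] * (log(p1[1, ]) - log(p0[1, ]))))
  }
  # stationary distribution of the context process under c1 by power iteration
  pi1 <- rep(1 / n_ctx, n_ctx)
  base <- ((seq_len(n_ctx) - 1) %% (n_ctx / A)) * A
  for (it in 1:200) {
    nxt <- numeric(n_ctx)
    for (a in seq_len(A)) {
      agg <- rowsum(pi1 * p1[, a], base + a)
      nxt[as.integer(rownames(agg))] <- nxt[as.integer(rownames(agg))] + agg[, 1]
    }
    if (max(abs(nxt - pi1)) < 1e-12) { pi1 <- nxt; break }
    pi1 <- nxt
  }
  sum(pi1 * rowSums(p1 * (log(p1) - log(p0))))
}

#' Sample sequences from planted class chains
#'
#' Each gene's sequence is generated from the Markov chain of its class,
#' with length drawn uniformly from `length_range`. Fully vectorised across
#' genes; deterministic given `seed`.
#'
#' @param chains a [planted_chains()] object.
#' @param classes tibble `gene`, `class` (`"c0"`/`"c1"`) — one sequence per row.
#' @param length_range integer two-vector of sequence lengths (default
#'   `c(300, 5000)`, the promoter-like regime; use shorter for protein).
#' @param seed integer seed.
#' @return Sequence tibble (columns `id`, `seq`).
#' @export
sample_sequences <- function(chains, classes, length_range = c(300, 5000),
                             seed = 1L) {
  alphabet <- chains$alphabet
  chars <- alphabet_chars(alphabet)
  A <- length(chars)
  m <- chains$k - 1L
  n_ctx <- A^m
  for (tr in chains$trans) {
    if (any(tr < 0) || any(abs(rowSums(tr) - 1) > 1e-8)) {
      abort("degenerate chain: transition rows must be non-negative and sum to 1")
    }
  }
  n <- nrow(classes)
  is1 <- classes$class == "c1"
  cum <- lapply(chains$trans, function(p) t(apply(p, 1, cumsum)))
  withr::with_seed(seed, {
    lens <- length_range[1] +
      sample.int(length_range[2] - length_range[1] + 1L, n, replace = TRUE) - 1L
    maxlen <- max(lens)
    letters_mat <- matrix(0L, n, maxlen)
    # initial m-letter context
    ctx <- sample.int(n_ctx, n, replace = TRUE, prob = chains$init)
    if (m > 0) {
      dec <- ctx - 1L
      for (j in m:1) {
        letters_mat[, j] <- dec %% A + 1L
        dec <- dec %/% A
      }
    }
    start <- m + 1L
    if (maxlen >= start) {
      for (pos in start:maxlen) {
        u <- runif(n)
        r0 <- cum$c0[ctx, , drop = FALSE]
        r1 <- cum$c1[ctx, , drop = FALSE]
        r <- r0
        r[is1, ] <- r1[is1, ]
        letter <- 1L + as.integer(rowSums(u > r[, -A, drop = FALSE]))
        letters_mat[, pos] <- letter
        ctx <- if (m > 0) ((ctx - 1L) %% (n_ctx %/% A)) * A + letter else ctx
        if (m == 1L) ctx <- letter
      }
    }
  })
  charmat <- matrix(chars[letters_mat], n, maxlen)
  # column-wise paste in chunks to keep argument lists bounded
  seqs <- rep("", n)
  for (lo in seq(1L, maxlen, by = 1000L)) {
    hi <- min(lo + 999L, maxlen)
    seqs <- paste0(seqs, do.call(paste0, as.data.frame(charmat[, lo:hi, drop = FALSE],
                                                       stringsAsFactors = FALSE)))
  }
  seqs <- substr(seqs, 1L, lens)
  seq_tbl(classes$gene, seqs, alphabet)
}

#' Sample a correlated gene-by-tissue expression matrix
#'
#' Latent per-gene, per-tissue binary labels are generated by thresholding a
#' Gaussian copula: `x_gt = sqrt(rho) u_g + sqrt(1 - rho) e_gt` with a shared
#' standard-normal factor `u_g` per gene, so any two tissues' latent scores
#' correlate at `rho`. A gene is latently "expressed" in a tissue when
#' `x_gt` exceeds the `1 - pos_rate` normal quantile; the gene-level class
#' (`u_g` over the same quantile) is returned as ground truth. Abundance is
#' log-normal with class-dependent log-mean, and a per-tissue Bernoulli
#' missingness mask is applied (re-opening one tissue for any gene that would
#' be entirely missing, preserving the matrix invariant).
#'
#' @param n_genes number of genes.
#' @param tissues tissue names or a count (default 23).
#' @param rho cross-tissue latent correlation in `[0, 1]`.
#' @param pos_rate marginal latent positive rate per tissue (default 0.3).
#' @param meanlog_lo,meanlog_hi log-mean abundance of the unexpressed /
#'   expressed classes (defaults `log(5)`, `log(50)`: a 10x separation).
#' @param sdlog log-scale abundance noise (default 0.4).
#' @param missingness per-tissue missing probability (default 0.1).
#' @param seed integer seed.
#' @return List: `expression` (long tibble `gene`, `tissue`, `value` with
#'   `NA` for missing), `truth` (tibble `gene`, `tissue`, `label` of latent
#'   tissue labels), `gene_class` (tibble `gene`, `class` of the gene-level
#'   ground truth, for recovery tests).
#' @export
sample_expression <- function(n_genes, tissues = 23, rho = 0.8, pos_rate = 0.3,
                              meanlog_lo = log(5), meanlog_hi = log(50),
                              sdlog = 0.4, missingness = 0.1, seed = 1L) {
  if (rho < 0 || rho > 1) abort("`rho` must be in [0, 1]")
  if (missingness < 0 || missingness >= 1) abort("`missingness` must be in [0, 1)")
  if (length(tissues) == 1 && is.numeric(tissues)) {
    tissues <- sprintf("tissue%02d", seq_len(tissues))
  }
  tiss <- as.character(tissues)
  Tn <- length(tiss)
  genes <- sprintf("g%05d", seq_len(n_genes))
  thr <- qnorm(1 - pos_rate)
  withr::with_seed(seed, {
    u <- rnorm(n_genes)
    e <- matrix(rnorm(n_genes * Tn), n_genes, Tn)
    x <- sqrt(rho) * u + sqrt(1 - rho) * e
    y <- x > thr
    value <- matrix(exp(rnorm(n_genes * Tn,
                              mean = ifelse(y, meanlog_hi, meanlog_lo),
                              sd = sdlog)), n_genes, Tn)
    miss <- matrix(runif(n_genes * Tn) < missingness, n_genes, Tn)
    all_missing <- which(rowSums(!miss) == 0)
    if (length(all_missing)) {
      keep <- sample.int(Tn, length(all_missing), replace = TRUE)
      miss[cbind(all_missing, keep)] <- FALSE
    }
  })
  value[miss] <- NA_real_
  expr <- tibble(gene = rep(genes, each = Tn), tissue = rep(tiss, n_genes),
                 value = as.vector(t(value)))
  truth <- tibble(gene = rep(genes, each = Tn), tissue = rep(tiss, n_genes),
                  label = ifelse(as.vector(t(y)), "c1", "c0"))
  gene_class <- tibble(gene = genes, class = ifelse(u > thr, "c1", "c0"))
  list(expression = expr, truth = truth, gene_class = gene_class)
}

#' Generate a complete synthetic study
#'
#' Bundles [planted_chains()], [sample_expression()] and
#' [sample_sequences()] into one seeded draw: a pair of class chains, a
#' correlated gene-by-tissue abundance matrix, and one promoter-like
#' sequence per gene sampled from the chain of the gene-level latent class.
#' The defaults describe the regime the two-phase method targets: a weak
#' sequence signal (`separation = 0.1`), short informative proximal-promoter
#' segments (300-600 bp), rare positives (`pos_rate = 0.05`, the top-5%
#' labeling regime), strong cross-tissue co-expression (`rho = 0.8`) and
#' 10% missing measurements per tissue.
#'
#' @param n_genes number of genes.
#' @param tissues tissue names or count (default 23).
#' @param k word length of the planted chains.
#' @param separation chain separation (see [planted_chains()]).
#' @param length_range sequence length range in bases.
#' @param rho,pos_rate,missingness,meanlog_lo,meanlog_hi,sdlog see
#'   [sample_expression()].
#' @param alphabet `"DNA"` or `"PROTEIN"`.
#' @param seed integer seed.
#' @return List: `seqs`, `expression`, `truth`, `gene_class`, `chains`.
#' @export
synthetic_study <- function(n_genes = 2000, tissues = 23, k = 3,
                            separation = 0.1, length_range = c(300, 600),
                            rho = 0.8, pos_rate = 0.05, missingness = 0.1,
                            meanlog_lo = log(5), meanlog_hi = log(50),
                            sdlog = 0.4, alphabet = "DNA", seed = 1L) {
  seed <- as.integer(seed)
  chains <- planted_chains(k, alphabet, separation, seed = seed + 100L)
  ex <- sample_expression(n_genes, tissues, rho, pos_rate, meanlog_lo,
                          meanlog_hi, sdlog, missingness, seed = seed + 1L)
  seqs <- sample_sequences(chains, ex$gene_class, length_range, seed = seed + 2L)
  c(list(seqs = seqs), ex, list(chains = chains))
}
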