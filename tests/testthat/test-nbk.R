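test_that("k-mer counting slides over all offsets and skips ambiguous windows", {
  c1 <- count_kmers("ACGT", 3)
  expect_equal(c1$kmer, c("ACG", "CGT"))
  expect_equal(c1$count, c(1L, 1L))
  expect_equal(attr(c1, "n_skipped"), 0L)

  c2 <- count_kmers("AAAA", 2)
  expect_equal(c2$kmer, "AA")
  expect_equal(c2$count, 3L)

  c3 <- count_kmers("ACNGT", 2)
  expect_equal(c3$kmer, c("AC", "GT"))
  expect_equal(attr(c3, "n_skipped"), 2L)

  # shorter than k
  expect_equal(nrow(count_kmers("AC", 3)), 0)

  # protein counting over the 20-letter alphabet
  cp <- count_kmers("MKVM", 2, "PROTEIN")
  expect_setequal(cp$kmer, c("MK", "KV", "VM"))

  # tibble input: one row per (id, kmer)
  seqs <- seq_tbl(c("a", "b"), c("ACGT", "AAAA"), "DNA")
  ct <- count_kmers(seqs, 2)
  expect_equal(sum(ct$count[ct$id == "b"]), 3)
})

test_that("training applies additive smoothing, class priors and totals", {
  seqs <- seq_tbl(c("a", "b"), c("AAAA", "ACGT"), "DNA")
  lab <- data.frame(gene = c("a", "b"), class = c("c1", "c0"))
  m <- nbk_train(seqs, lab, k = 2, alpha = 1)
  td <- tidy(m)
  # (3 + 1) / (3 + 16) for AA in c1
  expect_equal(exp(td$log_prob[td$order == 2 & td$class == "c1" & td$kmer == "AA"]),
               4 / 19)
  expect_equal(unname(m$priors), c(0.5, 0.5))
  expect_equal(glance(m)$prior_c1, 0.5)

  # alpha -> 0 limit reproduces maximum-likelihood frequencies
  m0 <- nbk_train(seqs, lab, k = 2, alpha = 1e-10)
  td0 <- tidy(m0)
  expect_equal(exp(td0$log_prob[td0$order == 2 & td0$class == "c1" & td0$kmer == "AA"]),
               1, tolerance = 1e-8)

  # unbalanced training: priors follow class frequencies
  seqs3 <- seq_tbl(c("a", "b", "c"), c("AAAA", "ACGT", "GGCC"), "DNA")
  lab3 <- data.frame(gene = c("a", "b", "c"), class = c("c1", "c0", "c0"))
  expect_equal(unname(nbk_train(seqs3, lab3, 2)$priors), c(2 / 3, 1 / 3))

  expect_error(nbk_train(seqs, data.frame(gene = "a", class = "c1"), 2),
               "both classes")
})

test_that("smoothed k-mer and (k-1)-mer tables sum to one per class", {
  withr::with_seed(31, {
    seqs <- seq_tbl(paste0("g", 1:6),
                    replicate(6, random_dna(60, with_ambiguity = TRUE)), "DNA")
  })
  lab <- data.frame(gene = seqs$id, class = rep(c("c0", "c1"), 3))
  for (k in 2:3) {
    m <- nbk_train(seqs, lab, k, alpha = 0.7)
    for (cl in c("c0", "c1")) {
      for (part in c("num", "den")) {
        space <- 4^(if (part == "num") k else k - 1)
        tab <- m$tables[[part]][[cl]]
        total <- sum(exp(tab$lp)) + (space - length(tab$lp)) * exp(tab$unseen)
        expect_equal(total, 1, tolerance = 1e-9)
      }
    }
  }
})

test_that("scores match the direct product-form oracle on the tiny fixture", {
  seqs <- seq_tbl(c("a", "b"), c("AAAA", "ACGT"), "DNA")
  lab <- data.frame(gene = c("a", "b"), class = c("c1", "c0"))
  train <- data.frame(seq = seqs$seq, class = lab$class)
  q <- seq_tbl("q", "AAAC", "DNA")

  m <- nbk_train(seqs, lab, k = 2, alpha = 1)
  s <- nbk_score(m, q)
  o <- oracle_nbk_score("AAAC", train, k = 2)
  expect_equal(s$score_c0, log(o[["c0"]]), tolerance = 1e-12)
  expect_equal(s$score_c1, log(o[["c1"]]), tolerance = 1e-12)
  # frozen oracle values: 0.5 * (16/6859)/(1/4) and 0.5 * (2/6859)/(1/36)
  expect_equal(s$score_c1, log(32 / 6859), tolerance = 1e-12)
  expect_equal(s$score_c0, log(36 / 6859), tolerance = 1e-12)
  # the oracle decides the class: c0 wins on this fixture
  expect_equal(nbk_classify(m, q)$class, "c0")

  # textbook boundary variant agrees with its oracle too
  mt <- nbk_train(seqs, lab, k = 2, alpha = 1, boundary = "textbook")
  st <- nbk_score(mt, q)
  ot <- oracle_nbk_score("AAAC", train, k = 2, boundary = "textbook")
  expect_equal(st$score_c1, log(ot[["c1"]]), tolerance = 1e-12)
  expect_equal(st$score_c0, log(ot[["c0"]]), tolerance = 1e-12)
})

test_that("log-domain scoring equals the term-by-term oracle on random instances", {
  withr::with_seed(99, {
    for (i in 1:40) {
      k <- sample(2:4, 1)
      boundary <- sample(c("printed", "textbook"), 1)
      n_tr <- sample(2:3, 1)
      train <- data.frame(
        seq = replicate(2 * n_tr, random_dna(sample(k:30, 1), with_ambiguity = TRUE)),
        class = rep(c("c0", "c1"), each = n_tr)
      )
      seqs <- seq_tbl(paste0("t", seq_len(nrow(train))), train$seq, "DNA")
      lab <- data.frame(gene = seqs$id, class = train$class)
      alpha <- sample(c(0.5, 1, 2), 1)
      m <- tryCatch(nbk_train(seqs, lab, k, alpha, boundary),
                    error = function(e) NULL)
      if (is.null(m)) next  # a class had no valid window at this k
      q <- random_dna(sample(k:30, 1), with_ambiguity = TRUE)
      s <- nbk_score(m, seq_tbl("q", q, "DNA"))
      if (s$unscorable) next
      o <- oracle_nbk_score(q, train, k, alpha, DNA4, boundary)
      expect_equal(s$score_c0, log(o[["c0"]]), tolerance = 1e-9)
      expect_equal(s$score_c1, log(o[["c1"]]), tolerance = 1e-9)
    }
    # protein instances
    for (i in 1:10) {
      k <- sample(2:3, 1)
      train <- data.frame(seq = replicate(4, random_protein(sample(k:25, 1))),
                          class = rep(c("c0", "c1"), each = 2))
      seqs <- seq_tbl(paste0("t", 1:4), train$seq, "PROTEIN")
      lab <- data.frame(gene = seqs$id, class = train$class)
      m <- nbk_train(seqs, lab, k)
      q <- random_protein(sample(k:25, 1))
      s <- nbk_score(m, seq_tbl("q", q, "PROTEIN"))
      o <- oracle_nbk_score(q, train, k, 1, AA20)
      expect_equal(s$score_c0, log(o[["c0"]]), tolerance = 1e-9)
      expect_equal(s$score_c1, log(o[["c1"]]), tolerance = 1e-9)
    }
  })
})

test_that("NB(1) reduces exactly to the single-letter classifier", {
  withr::with_seed(7, {
    train <- data.frame(seq = replicate(8, random_dna(40)),
                        class = rep(c("c0", "c1"), 4))
    seqs <- seq_tbl(paste0("t", 1:8), train$seq, "DNA")
    lab <- data.frame(gene = seqs$id, class = train$class)
    m1 <- nbk_train(seqs, lab, k = 1)
    queries <- replicate(30, random_dna(sample(5:60, 1), with_ambiguity = TRUE))
  })
  qt <- seq_tbl(paste0("q", seq_along(queries)), queries, "DNA")
  got <- nbk_classify(m1, qt)$class
  want <- vapply(queries, oracle_nb1_class, character(1), train = train)
  expect_equal(got, unname(want))
})

test_that("symmetric training data gives equal class scores; ties fall to c0", {
  seqs <- seq_tbl(c("a", "b"), c("ACGTAC", "ACGTAC"), "DNA")
  lab <- data.frame(gene = c("a", "b"), class = c("c0", "c1"))
  m <- nbk_train(seqs, lab, 2)
  s <- nbk_score(m, seq_tbl("q", "ACGT", "DNA"))
  expect_equal(s$score_c0, s$score_c1)
  expect_equal(nbk_classify(m, seq_tbl("q", "ACGT", "DNA"))$class, "c0")
})

test_that("sequences with no valid window are unscorable and default to c0", {
  seqs <- seq_tbl(c("a", "b"), c("AAAA", "ACGT"), "DNA")
  m <- nbk_train(seqs, data.frame(gene = c("a", "b"), class = c("c1", "c0")), 2)
  out <- nbk_classify(m, seq_tbl("q", "NNNN", "DNA"))
  expect_true(out$unscorable)
  expect_equal(out$class, "c0")
  expect_true(is.na(out$score_c1))
})

test_that("planted order-2 chain conditionals are recovered within 0.02", {
  chains <- planted_chains(3, "DNA", separation = 0.65, seed = 4)
  cls <- tibble::tibble(gene = sprintf("g%04d", 1:1000),
                        class = rep(c("c0", "c1"), 500))
  seqs <- sample_sequences(chains, cls, length_range = c(300, 300), seed = 5)
  m <- nbk_train(seqs, dplyr::rename(cls, gene = gene), 3)
  cond <- nbk_conditionals(m)
  for (cl in c("c0", "c1")) {
    est <- cond[cond$class == cl, ]
    est <- matrix(est$prob[order(est$letter, est$context)], nrow = 16,
                  dimnames = list(sort(unique(est$context)), sort(unique(est$letter))))
    expect_lt(max(abs(est - chains$trans[[cl]])), 0.02)
  }
  # conditionals are row-stochastic
  sums <- tapply(cond$prob, paste(cond$class, cond$context), sum)
  expect_equal(as.vector(sums), rep(1, length(sums)), tolerance = 1e-12)
})

test_that("well-separated chains are classified with high accuracy", {
  chains <- planted_chains(3, "DNA", separation = 0.65, seed = 4)
  expect_gte(chain_kl(chains), 0.1)
  train_cls <- tibble::tibble(gene = sprintf("tr%04d", 1:500),
                              class = rep(c("c0", "c1"), 250))
  test_cls <- tibble::tibble(gene = sprintf("te%04d", 1:300),
                             class = rep(c("c0", "c1"), 150))
  tr <- sample_sequences(chains, train_cls, c(300, 300), seed = 6)
  te <- sample_sequences(chains, test_cls, c(300, 300), seed = 7)
  m <- nbk_train(tr, train_cls, 3)
  pred <- nbk_classify(m, te)
  expect_gte(mean(pred$class == test_cls$class), 0.95)
})

test_that("JSON serialization round-trips models and their scores", {
  withr::with_seed(15, {
    seqs <- seq_tbl(paste0("g", 1:6), replicate(6, random_dna(50)), "DNA")
  })
  lab <- data.frame(gene = seqs$id, class = rep(c("c0", "c1"), 3))
  m <- nbk_train(seqs, lab, 3, alpha = 0.5)
  path <- tempfile(fileext = ".json")
  nbk_write(m, path)
  m2 <- nbk_read(path)
  q <- seq_tbl("q", random_dna(40), "DNA")
  expect_equal(nbk_score(m2, q), nbk_score(m, q), tolerance = 1e-12)
  expect_equal(m2$priors, m$priors)
  expect_equal(m2$boundary, m$boundary)
})

test_that("leave-one-out scoring equals retraining without the gene", {
  chains <- planted_chains(3, "DNA", separation = 0.3, seed = 5)
  cls <- tibble::tibble(gene = sprintf("g%03d", 1:30), class = rep(c("c0", "c1"), 15))
  seqs <- sample_sequences(chains, cls, c(50, 120), seed = 6)
  prof <- nbk_profile(seqs, 3)
  m <- nbk_train(seqs, cls, 3, profile = prof)
  loo <- tnbk:::nbk_classify_loo(m, prof, cls, seqs$id)
  for (i in seq_len(30)) {
    m2 <- nbk_train(seqs, cls[-i, ], 3, profile = prof)
    expect_equal(loo$class[i],
                 nbk_classify(m2, seqs[i, , drop = FALSE], prof)$class)
  }
})
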