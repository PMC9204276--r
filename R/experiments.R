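# ---- experiment grid, cross-validation, metrics ----------------------------

#' Enumerate the full experiment grid
#'
#' Builds the Cartesian product of experiment factors: tissue, k (3..7 by
#' default), cutoff direction (top/bottom) and percent (5..30 by 5), sequence
#' input (promoter DNA / protein) and label type (mRNA abundance RA / protein
#' abundance PA); Phase II additionally crosses four backend algorithms.
#' With 23 tissues this yields 5,520 Phase I and 22,080 Phase II
#' configurations. Each row carries a deterministic seed derived by hashing
#' the configuration, so partial reruns reproduce identical folds and draws.
#'
#' @param tissues character vector of tissue names.
#' @param phase `"I"` or `"II"`.
#' @param k integer vector of word lengths (default 3:7).
#' @param percents cutoff percentiles (default `seq(5, 30, 5)`).
#' @param inputs sequence input types (default PROMOTER, PROTEIN).
#' @param label_types expression label types (default RA, PA).
#' @param algorithms Phase II backends (default BN, DT, KNN, SVM).
#' @param base_seed integer mixed into each configuration's hash seed.
#' @return Tibble, one configuration per row, in deterministic order, with a
#'   `seed` column.
#' @export
enumerate_grid <- function(tissues, phase = c("I", "II"), k = 3:7,
                           percents = seq(5, 30, 5),
                           inputs = c("PROMOTER", "PROTEIN"),
                           label_types = c("RA", "PA"),
                           algorithms = c("BN", "DT", "KNN", "SVM"),
                           base_seed = 0L) {
  phase <- match.arg(phase)
  if (length(tissues) == 0) abort("`tissues` must be non-empty")
  grid <- tidyr::expand_grid(
    phase = phase,
    input = inputs,
    label_type = label_types,
    tissue = as.character(tissues),
    k = as.integer(k),
    direction = c("top", "bottom"),
    percent = as.numeric(percents)
  )
  if (phase == "II") {
    grid <- tidyr::expand_grid(grid, algorithm = algorithms)
  } else {
    grid$algorithm <- NA_character_
  }
  key <- do.call(paste, c(grid, sep = "|"))
  grid$seed <- (hash_string(key) + as.integer(base_seed)) %% 2147483647L
  grid
}

#' Classification metrics from confusion counts
#'
#' Standard binary metrics with `c1` (expressed) as the positive class:
#' accuracy `(TP+TN)/total`, precision `TP/(TP+FP)`, recall `TP/(TP+FN)`,
#' F-measure `2PR/(P+R)`. Precision, recall and F are defined as 0 when
#' their denominator is 0.
#'
#' @param tp,fp,fn,tn non-negative confusion counts (vectors recycle).
#' @return Tibble `tp`, `fp`, `fn`, `tn`, `accuracy`, `precision`, `recall`,
#'   `f_measure`.
#' @export
eval_metrics <- function(tp, fp, fn, tn) {
  total <- tp + fp + fn + tn
  if (any(c(tp, fp, fn, tn) < 0)) abort("confusion counts must be non-negative")
  if (any(total == 0)) abort("no evaluated examples")
  precision <- ifelse(tp + fp > 0, tp / (tp + fp), 0)
  recall <- ifelse(tp + fn > 0, tp / (tp + fn), 0)
  f <- ifelse(precision + recall > 0,
              2 * precision * recall / (precision + recall), 0)
  tibble(tp = tp, fp = fp, fn = fn, tn = tn,
         accuracy = (tp + tn) / total,
         precision = precision, recall = recall, f_measure = f)
}

confusion_counts <- function(truth, pred) {
  c(tp = sum(truth == "c1" & pred == "c1"),
    fp = sum(truth == "c0" & pred == "c1"),
    fn = sum(truth == "c1" & pred == "c0"),
    tn = sum(truth == "c0" & pred == "c0"))
}

#' Stratified fold assignment
#'
#' Assigns each example to one of `folds` folds, stratified by class, with a
#' deterministic seeded shuffle. If the smaller class has fewer members than
#' `folds`, the fold count is reduced with a warning.
#'
#' @param classes character vector of `"c0"`/`"c1"` labels.
#' @param folds requested fold count (default 10).
#' @param seed integer seed.
#' @return Integer fold ids (1..folds) aligned with `classes`; the attribute
#'   `folds` records the fold count actually used.
#' @export
make_folds <- function(classes, folds = 10L, seed = 0L) {
  folds <- as.integer(folds)
  min_class <- min(table(factor(classes, levels = c("c0", "c1"))))
  if (min_class < folds) {
    folds <- max(2L, as.integer(min_class))
    warn(paste0("fewer members than folds; reduced to ", folds, " folds"))
  }
  out <- integer(length(classes))
  withr::with_seed(seed, {
    for (cl in unique(classes)) {
      i <- which(classes == cl)
      out[i] <- sample(rep_len(seq_len(folds), length(i)))
    }
  })
  attr(out, "folds") <- folds
  out
}

#' Cross-validate a Phase I NB(k) classifier
#'
#' Stratified k-fold cross-validation of [nbk_train()] on one tissue's
#' balanced labeled set: per fold, the model is trained on the in-fold genes
#' and evaluated on the held-out genes; confusion counts are pooled over
#' folds before metrics are computed (micro-average).
#'
#' @param seqs sequence tibble covering the labeled genes.
#' @param labeled balanced label tibble (`gene`, `class`), e.g. from
#'   [labeled_set()].
#' @param k word length.
#' @param alpha smoothing pseudocount.
#' @param folds fold count (default 10).
#' @param seed integer seed for fold assignment.
#' @param boundary see [nbk_train()].
#' @param profile optional shared [nbk_profile()] of `seqs`.
#' @param keep_predictions if `TRUE`, attach the per-gene held-out
#'   predictions as the `predictions` attribute (`gene`, `truth`, `pred`,
#'   `fold`).
#' @return One-row tibble: `folds`, confusion counts, and the four metrics.
#' @export
nbk_cv <- function(seqs, labeled, k, alpha = 1, folds = 10L, seed = 0L,
                   boundary = c("printed", "textbook"), profile = NULL,
                   keep_predictions = FALSE) {
  boundary <- match.arg(boundary)
  labeled <- labeled[labeled$gene %in% seqs$id, , drop = FALSE]
  if (nrow(labeled) == 0) abort("no labeled genes with sequences")
  if (is.null(profile)) {
    profile <- nbk_profile(seqs[seqs$id %in% labeled$gene, , drop = FALSE],
                           k, boundary = boundary)
  }
  fold_id <- make_folds(labeled$class, folds, seed)
  counts <- c(tp = 0, fp = 0, fn = 0, tn = 0)
  preds <- list()
  for (f in seq_len(attr(fold_id, "folds"))) {
    train_lab <- labeled[fold_id != f, , drop = FALSE]
    test_lab <- labeled[fold_id == f, , drop = FALSE]
    model <- nbk_train(seqs, train_lab, k, alpha, boundary, profile = profile)
    pred <- nbk_classify(model, seqs[match(test_lab$gene, seqs$id), , drop = FALSE],
                         profile = profile)
    counts <- counts + confusion_counts(test_lab$class, pred$class)
    if (keep_predictions) {
      preds[[f]] <- tibble(gene = test_lab$gene, truth = test_lab$class,
                           pred = pred$class, fold = f)
    }
  }
  out <- eval_metrics(counts[["tp"]], counts[["fp"]], counts[["fn"]], counts[["tn"]])
  out <- dplyr::bind_cols(tibble(folds = attr(fold_id, "folds")), out)
  if (keep_predictions) attr(out, "predictions") <- dplyr::bind_rows(preds)
  out
}

#' Cross-validate the two-phase tNB(k) classifier
#'
#' Stratified k-fold cross-validation of the full two-phase scheme for one
#' assigned tissue. Per fold: every tissue's Phase I NB(k) model is trained
#' on that tissue's balanced labeled set *excluding the held-out genes*
#' (out-of-fold featurization, so no Phase I model that contributes a test
#' gene's features ever saw that gene); feature vectors are built for in-fold
#' and held-out genes; imputation means come from the in-fold vectors only;
#' the Phase II backend is fitted on the in-fold vectors and evaluated on the
#' held-out ones. Confusion counts are pooled over folds.
#'
#' @param seqs sequence tibble covering all genes.
#' @param labeled_sets named list of balanced label tibbles, one per tissue
#'   (names = tissues); defines both the Phase I training data and the slot
#'   order.
#' @param measured long expression tibble driving slot missingness.
#' @param assigned_tissue the tissue whose labels Phase II predicts; its
#'   entry of `labeled_sets` supplies the evaluation labels.
#' @param algorithm Phase II backend (BN, DT, KNN or SVM).
#' @param k,alpha,folds,seed,boundary,profile as in [nbk_cv()].
#' @param keep_predictions as in [nbk_cv()].
#' @param ... passed to [train_phase2()].
#' @return One-row tibble: `folds`, confusion counts, metrics.
#' @export
tnbk_cv <- function(seqs, labeled_sets, measured, assigned_tissue,
                    algorithm = c("BN", "DT", "KNN", "SVM"),
                    k = 3L, alpha = 1, folds = 10L, seed = 0L,
                    boundary = c("printed", "textbook"), profile = NULL,
                    keep_predictions = FALSE, ...) {
  algorithm <- match.arg(algorithm)
  boundary <- match.arg(boundary)
  tissues <- names(labeled_sets)
  if (!assigned_tissue %in% tissues) abort("`assigned_tissue` has no labeled set")
  target <- labeled_sets[[assigned_tissue]]
  target <- target[target$gene %in% seqs$id, , drop = FALSE]
  if (is.null(profile)) profile <- nbk_profile(seqs, k, boundary = boundary)
  fold_id <- make_folds(target$class, folds, seed)
  counts <- c(tp = 0, fp = 0, fn = 0, tn = 0)
  preds <- list()
  for (f in seq_len(attr(fold_id, "folds"))) {
    train_lab <- target[fold_id != f, , drop = FALSE]
    test_lab <- target[fold_id == f, , drop = FALSE]
    held_out <- test_lab$gene
    models <- lapply(setNames(tissues, tissues), function(t) {
      lab_t <- labeled_sets[[t]]
      lab_t <- lab_t[!lab_t$gene %in% held_out & lab_t$gene %in% seqs$id, , drop = FALSE]
      nbk_train(seqs, lab_t, k, alpha, boundary, profile = profile)
    })
    featurize <- function(genes, loo = FALSE) {
      sub <- seqs[match(genes, seqs$id), , drop = FALSE]
      if (!loo) {
        return(build_feature_vectors(sub, models, measured, assigned_tissue,
                                     profile = profile))
      }
      # training genes: exact leave-one-out slots, so a gene's own Phase I
      # label never reaches its Phase II features
      pred <- matrix(NA_real_, length(genes), length(tissues),
                     dimnames = list(genes, tissues))
      meas <- measured[!is.na(measured$value), c("gene", "tissue")]
      for (t in tissues) {
        lab_t <- labeled_sets[[t]]
        lab_t <- lab_t[!lab_t$gene %in% held_out & lab_t$gene %in% seqs$id, , drop = FALSE]
        cl <- nbk_classify_loo(models[[t]], profile, lab_t, genes)
        slot <- as.numeric(cl$class == "c1")
        slot[!genes %in% meas$gene[meas$tissue == t]] <- NA_real_
        pred[, t] <- slot
      }
      base <- as_tibble(pred)
      names(base) <- paste0("slot_", tissues)
      out <- dplyr::bind_cols(tibble(gene_id = genes,
                                     assigned_tissue = assigned_tissue), base)
      attr(out, "tissues") <- tissues
      out
    }
    train_vec <- featurize(train_lab$gene, loo = TRUE)
    train_vec <- impute_features(train_vec, feature_means(train_vec))
    p2 <- train_phase2(train_vec,
                       tibble(gene_id = train_lab$gene,
                              assigned_tissue = assigned_tissue,
                              class = train_lab$class),
                       algorithm, ...)
    pred <- predict_phase2(p2, featurize(test_lab$gene))
    counts <- counts + confusion_counts(test_lab$class, pred$class)
    if (keep_predictions) {
      preds[[f]] <- tibble(gene = test_lab$gene, truth = test_lab$class,
                           pred = pred$class, fold = f)
    }
  }
  out <- eval_metrics(counts[["tp"]], counts[["fp"]], counts[["fn"]], counts[["tn"]])
  out <- dplyr::bind_cols(tibble(folds = attr(fold_id, "folds")), out)
  if (keep_predictions) attr(out, "predictions") <- dplyr::bind_rows(preds)
  out
}

#' Summary tables for a set of evaluation reports
#'
#' Reshapes a long tibble of evaluation reports (one row per configuration,
#' carrying at least `tissue`, `phase`, `input`, `label_type`, `f_measure`,
#' `accuracy`) into the wide per-tissue layout with an `FM_` and `AC_` column
#' per (phase, input, label type) combination, and returns the long
#' machine-readable companion alongside. When the same configuration appears
#' more than once the latest row wins, with a warning.
#'
#' @param reports long tibble of evaluation reports.
#' @return List with elements `wide` and `long`.
#' @export
report_tables <- function(reports) {
  if (nrow(reports) == 0) {
    return(list(wide = tibble(), long = tibble()))
  }
  keys <- c("tissue", "phase", "input", "label_type")
  id_cols <- intersect(c(keys, "k", "direction", "percent", "algorithm"),
                       names(reports))
  dup_key <- do.call(paste, c(reports[id_cols], sep = "|"))
  if (anyDuplicated(dup_key)) {
    warn("duplicate configurations; keeping the latest of each")
    reports <- reports[!duplicated(dup_key, fromLast = TRUE), , drop = FALSE]
  }
  long <- as_tibble(reports)
  wide <- long |>
    dplyr::mutate(combo = paste(.data$phase, .data$input, .data$label_type, sep = "_")) |>
    dplyr::select(dplyr::all_of(c("tissue", "combo", "f_measure", "accuracy"))) |>
    tidyr::pivot_wider(names_from = "combo",
                       values_from = c("f_measure", "accuracy"),
                       names_glue = "{ifelse(.value == 'f_measure', 'FM', 'AC')}_{combo}",
                       values_fn = function(x) x[length(x)])
  list(wide = wide, long = long)
}
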