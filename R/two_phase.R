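# ---- Phase II: cross-tissue feature vectors and the second-stage learner --

#' Build cross-tissue feature vectors from Phase I models
#'
#' For each gene and each assigned tissue, records the per-tissue NB(k)
#' predictions as a feature vector: one slot per tissue holding the model's
#' binary call (1 = expressed) on the gene's sequence, `NA` where the gene
#' has no measured value in that tissue. With T tissues the vector has T + 2
#' elements — gene id, T prediction slots, assigned tissue — 25 in the
#' 23-tissue study design. The gene id is carried as an identifier only and
#' is never used as a learned feature.
#'
#' @param seqs sequence tibble covering the genes to featurize.
#' @param models named list of [nbk_train()] fits, one per tissue; names are
#'   the tissue names and fix the slot order.
#' @param measured long expression tibble (`gene`, `tissue`, `value`) whose
#'   missingness pattern determines which slots are `NA`; genes absent from a
#'   tissue's rows count as unmeasured there.
#' @param assigned_tissue character vector of tissues whose label each gene's
#'   vector targets; one vector is emitted per (gene, assigned tissue) pair.
#' @param profile optional shared [nbk_profile()] of `seqs` for fast scoring.
#' @return Tibble with columns `gene_id`, `assigned_tissue`, and one
#'   `slot_<tissue>` column per model, in model order.
#' @export
build_feature_vectors <- function(seqs, models, measured, assigned_tissue,
                                  profile = NULL) {
  tissues <- names(models)
  if (is.null(tissues) || any(!nzchar(tissues))) abort("`models` must be a named list")
  if (!all(assigned_tissue %in% tissues)) {
    abort("every assigned tissue needs a Phase I model")
  }
  if (is.null(profile)) {
    profile <- nbk_profile(seqs, models[[1]]$k, models[[1]]$alphabet,
                           models[[1]]$boundary)
  }
  pred <- matrix(NA_real_, nrow(seqs), length(tissues),
                 dimnames = list(seqs$id, tissues))
  for (t in tissues) {
    pred[, t] <- as.numeric(nbk_classify(models[[t]], seqs, profile)$class == "c1")
  }
  # a slot is missing when the gene has no measured value in that tissue
  meas <- measured[!is.na(measured$value), c("gene", "tissue")]
  for (t in tissues) {
    unmeasured <- !seqs$id %in% meas$gene[meas$tissue == t]
    pred[unmeasured, t] <- NA_real_
  }
  base <- as_tibble(pred)
  names(base) <- paste0("slot_", tissues)
  out <- purrr::map_dfr(assigned_tissue, function(at)
    dplyr::bind_cols(tibble(gene_id = seqs$id, assigned_tissue = at), base))
  attr(out, "tissues") <- tissues
  out
}

slot_cols <- function(vectors) grep("^slot_", names(vectors), value = TRUE)

#' Per-slot training means for imputation
#'
#' @param vectors feature-vector tibble from [build_feature_vectors()]
#'   restricted to training genes (the means must never be computed on
#'   vectors whose labels are being predicted).
#' @return Named numeric vector of per-slot means in `[0, 1]`; slots with no
#'   observed value fall back to 0.5 with a warning.
#' @export
feature_means <- function(vectors) {
  cols <- slot_cols(vectors)
  m <- vapply(vectors[cols], function(v) mean(v, na.rm = TRUE), numeric(1))
  if (any(is.nan(m))) {
    warn("slot(s) with no training observations; imputing 0.5")
    m[is.nan(m)] <- 0.5
  }
  m
}

#' Mean-impute missing feature slots
#'
#' Replaces each missing slot with its per-slot training mean; present slots
#' are untouched.
#'
#' @param vectors feature-vector tibble.
#' @param means named per-slot means from [feature_means()] computed on
#'   training vectors only; defaults to means of `vectors` itself (only
#'   appropriate when `vectors` is the training set).
#' @return The completed tibble, with the means recorded in the
#'   `imputation_means` attribute.
#' @export
impute_features <- function(vectors, means = NULL) {
  if (is.null(means)) means <- feature_means(vectors)
  cols <- slot_cols(vectors)
  if (!all(cols %in% names(means))) abort("`means` do not cover all slots")
  for (cl in cols) {
    miss <- is.na(vectors[[cl]])
    if (any(miss)) vectors[[cl]][miss] <- means[[cl]]
  }
  attr(vectors, "imputation_means") <- means
  vectors
}

encode_phase2 <- function(vectors, tissue_levels, slot_names) {
  cols <- slot_cols(vectors)
  if (!identical(sort(cols), sort(slot_names))) {
    abort("feature-vector slot layout does not match the model")
  }
  X <- as.data.frame(vectors[slot_names])
  # assigned tissue one-hot; no ordinal structure imposed
  at <- factor(vectors$assigned_tissue, levels = tissue_levels)
  if (anyNA(at)) abort("assigned tissue outside the model's tissue set")
  for (t in tissue_levels) X[[paste0("tissue_", t)]] <- as.numeric(at == t)
  X
}

#' Train the Phase II (tNB(k)) classifier
#'
#' Fits the second-stage learner on the imputed cross-tissue feature vectors:
#' features are the T prediction slots plus a one-hot encoding of the
#' assigned tissue; the gene id is excluded. Backends: `"BN"` a
#' naive-structure Bayes network ([e1071::naiveBayes()] on slots discretized
#' at 0.5), `"DT"` a pruned decision tree ([rpart::rpart()]), `"KNN"`
#' k-nearest neighbour (`class::knn`, default 1 neighbour), `"SVM"` a linear
#' kernel support vector machine ([e1071::svm()]).
#'
#' @param vectors feature-vector tibble; missing slots are imputed with
#'   training means if any remain.
#' @param labels data frame `gene_id`, `assigned_tissue`, `class` giving the
#'   training label of each vector.
#' @param algorithm one of `"BN"`, `"DT"`, `"KNN"`, `"SVM"`.
#' @param knn_k neighbours for `"KNN"` (default 1).
#' @param ... passed to the backend fitting function (DT, SVM, BN).
#' @return An object of class `phase2_model`.
#' @export
train_phase2 <- function(vectors, labels, algorithm = c("BN", "DT", "KNN", "SVM"),
                         knn_k = 1L, ...) {
  algorithm <- match.arg(algorithm)
  dat <- dplyr::inner_join(vectors, as_tibble(labels),
                           by = c("gene_id", "assigned_tissue"))
  if (nrow(dat) == 0) abort("no labeled training vectors")
  y <- factor(dat$class, levels = c("c0", "c1"))
  if (length(unique(dat$class)) < 2) abort("training labels contain a single class")

  means <- attr(vectors, "imputation_means")
  if (anyNA(dat[slot_cols(dat)])) {
    if (is.null(means)) means <- feature_means(dat)
    dat <- impute_features(dat, means)
  }
  if (is.null(means)) means <- feature_means(dat)

  tissue_levels <- attr(vectors, "tissues") %||% sort(unique(vectors$assigned_tissue))
  slots <- slot_cols(vectors)
  X <- encode_phase2(dat, tissue_levels, slots)

  fit <- switch(algorithm,
    BN = {
      Xf <- as.data.frame(lapply(X, function(v)
        factor(as.integer(v >= 0.5), levels = c(0L, 1L))))
      e1071::naiveBayes(Xf, y, laplace = 1, ...)
    },
    DT = rpart::rpart(class ~ ., data = cbind(X, class = y), method = "class", ...),
    KNN = list(train = as.matrix(X), y = y, k = as.integer(knn_k)),
    SVM = e1071::svm(as.matrix(X), y, kernel = "linear", scale = FALSE, ...)
  )
  structure(list(algorithm = algorithm, fit = fit,
                 slot_names = slots, tissue_levels = tissue_levels,
                 means = means),
            class = "phase2_model")
}

#' Predict with a Phase II model
#'
#' Applies the fitted second-stage learner to new feature vectors; missing
#' slots are imputed with the means stored at training time, and the feature
#' layout must match the training layout.
#'
#' @param model a `phase2_model`.
#' @param vectors feature-vector tibble.
#' @return Tibble `gene_id`, `assigned_tissue`, `class`.
#' @export
predict_phase2 <- function(model, vectors) {
  vectors <- impute_features(vectors, model$means)
  X <- encode_phase2(vectors, model$tissue_levels, model$slot_names)
  cls <- switch(model$algorithm,
    BN = {
      Xf <- as.data.frame(lapply(X, function(v)
        factor(as.integer(v >= 0.5), levels = c(0L, 1L))))
      as.character(predict(model$fit, Xf, type = "class"))
    },
    DT = as.character(predict(model$fit, X, type = "class")),
    KNN = as.character(class::knn(model$fit$train, as.matrix(X),
                                  model$fit$y, k = model$fit$k)),
    SVM = as.character(predict(model$fit, as.matrix(X)))
  )
  tibble(gene_id = vectors$gene_id, assigned_tissue = vectors$assigned_tissue,
         class = cls)
}

#' @rdname train_phase2
#' @param x a `phase2_model`.
#' @method glance phase2_model
#' @export
glance.phase2_model <- function(x, ...) {
  tibble(algorithm = x$algorithm,
         n_slots = length(x$slot_names),
         n_tissues = length(x$tissue_levels),
         n_features = length(x$slot_names) + length(x$tissue_levels))
}

#' @export
print.phase2_model <- function(x, ...) {
  cat(sprintf("Phase II %s classifier: %d slots + %d-tissue one-hot\n",
              x$algorithm, length(x$slot_names), length(x$tissue_levels)))
  invisible(x)
}

#' Write feature vectors as tab-delimited text
#'
#' Missing slots are written as `?`.
#'
#' @param vectors feature-vector tibble.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_feature_vectors <- function(vectors, path) {
  out <- as.data.frame(vectors)
  for (cl in slot_cols(out)) {
    v <- as.character(out[[cl]])
    v[is.na(v)] <- "?"
    out[[cl]] <- v
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
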