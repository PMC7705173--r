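#' Confusion matrix of a classifier
#'
#' Counts `n_ij` of windows truly in class `i` (rows) predicted as class
#' `j` (columns). Estimated on the validation split, the confusion matrix
#' summarizes each decoder's error distribution over the classes and is
#' the sole calibration input to the belief fusion.
#'
#' @param true_labels,predicted_labels Equal-length label vectors over
#'   `classes`.
#' @param classes Class set (row/column order of the matrix).
#' @return Integer matrix of class `confusion_matrix` with `classes` as
#'   dimnames.
#' @export
estimate_confusion <- function(true_labels, predicted_labels, classes) {
  if (length(true_labels) != length(predicted_labels)) {
    stop("label sequences differ in length")
  }
  bad <- setdiff(unique(c(true_labels, predicted_labels)), classes)
  if (length(bad)) stop("unknown label(s): ", paste(bad, collapse = ", "))
  cm <- table(factor(true_labels, levels = classes),
              factor(predicted_labels, levels = classes))
  cm <- matrix(as.integer(cm), length(classes), length(classes),
               dimnames = list(true = classes, predicted = classes))
  class(cm) <- c("confusion_matrix", class(cm))
  cm
}

#' Conditional reliabilities from a confusion matrix
#'
#' Column-normalizes the confusion counts into `P(true = i | predicted =
#' j)`: column `j` becomes `(n_ij + alpha) / sum_i (n_ij + alpha)`.
#' Additive smoothing (`alpha`, default 1) keeps columns for classes the
#' classifier never predicted on the validation split well-defined — such
#' a column becomes uniform, i.e. an uninformative prediction. `alpha =
#' 0` reproduces the raw column normalization.
#'
#' @param cm A confusion matrix from [estimate_confusion()].
#' @param alpha Additive smoothing count (default 1).
#' @return Matrix of the same shape; every column sums to 1.
#' @export
conditionals_from_confusion <- function(cm, alpha = 1) {
  stopifnot(all(cm >= 0), alpha >= 0)
  sm <- unclass(cm) + alpha
  colsums <- colSums(sm)
  if (any(colsums == 0)) {
    stop("confusion matrix has an all-zero column and alpha = 0; ",
         "the conditional for that predicted class is undefined")
  }
  sweep(sm, 2, colsums, "/")
}

#' Calibrated Bayesian fusion model
#'
#' Holds the per-classifier conditional reliability tables, the class
#' priors, and the class mapping that ties the 2-class EEG decoder to the
#' 3-class fused problem: the EEG conditional for `SWING` is used for
#' both the `RIGHT` and `LEFT` fused classes (the EEG decoder detects
#' stepping regardless of the leg; only the EMG decoder arbitrates the
#' side), while `STANCE` maps to `STANCE`.
#'
#' Two weighting forms are available. The default (`form = "product"`)
#' multiplies the conditionals by a single prior factor per class. The
#' alternative (`form = "normalized"`) divides the product of
#' conditionals by `P(c_i)^(K-1)`, the form that arises when each
#' classifier's posterior is treated as an independent update of the
#' prior; with uniform priors the two differ only by a constant and give
#' identical decisions.
#'
#' @param eeg_conditionals 2x2 conditional table over `{SWING, STANCE}`
#'   (columns = predicted class, columns sum to 1).
#' @param emg_conditionals 3x3 conditional table over
#'   `{RIGHT, LEFT, STANCE}`.
#' @param priors Fused-class priors, default uniform (the walking speed,
#'   hence the phase occupancy, is unknown to the classifier).
#' @param form `"product"` or `"normalized"` (see above).
#' @param alpha Smoothing used when the tables were built (stored for
#'   provenance).
#' @return A `fusion_model` object.
#' @export
fusion_model <- function(eeg_conditionals, emg_conditionals,
                         priors = c(RIGHT = 1, LEFT = 1, STANCE = 1) / 3,
                         form = c("product", "normalized"), alpha = NA) {
  form <- match.arg(form)
  stopifnot(identical(dim(eeg_conditionals), c(2L, 2L)),
            identical(dim(emg_conditionals), c(3L, 3L)))
  if (max(abs(colSums(eeg_conditionals) - 1)) > 1e-8 ||
      max(abs(colSums(emg_conditionals) - 1)) > 1e-8) {
    stop("conditional table columns must sum to 1")
  }
  priors <- priors / sum(priors)
  dimnames(eeg_conditionals) <- list(true = EEG_CLASSES,
                                     predicted = EEG_CLASSES)
  dimnames(emg_conditionals) <- list(true = GAIT_CLASSES,
                                     predicted = GAIT_CLASSES)
  structure(list(eeg = eeg_conditionals, emg = emg_conditionals,
                 priors = stats::setNames(priors, GAIT_CLASSES),
                 form = form, alpha = alpha,
                 # fused class -> EEG class mapping (SWING repeated twice)
                 eeg_map = c(RIGHT = "SWING", LEFT = "SWING",
                             STANCE = "STANCE"),
                 tie_order = c("STANCE", "RIGHT", "LEFT")),
            class = "fusion_model")
}

#' Calibrate a fusion model from validation-set predictions
#'
#' Estimates each decoder's confusion matrix on the validation split and
#' converts it to conditional reliabilities. EEG confusion is computed
#' over `{SWING, STANCE}` (true labels are collapsed with
#' [to_eeg_classes()] if needed).
#'
#' @param eeg_true,eeg_pred Validation labels/predictions for the EEG
#'   decoder (fused-class true labels are collapsed automatically).
#' @param emg_true,emg_pred Validation labels/predictions for the EMG
#'   decoder over `{RIGHT, LEFT, STANCE}`.
#' @param alpha Additive smoothing for
#'   [conditionals_from_confusion()] (default 1).
#' @param priors,form Passed to [fusion_model()].
#' @return A calibrated `fusion_model`; the two confusion matrices are
#'   attached as attribute `"confusions"`.
#' @export
calibrate_fusion <- function(eeg_true, eeg_pred, emg_true, emg_pred,
                             alpha = 1,
                             priors = c(RIGHT = 1, LEFT = 1, STANCE = 1) / 3,
                             form = c("product", "normalized")) {
  eeg_true <- to_eeg_classes(eeg_true)
  eeg_pred <- to_eeg_classes(eeg_pred)
  cm_eeg <- estimate_confusion(eeg_true, eeg_pred, EEG_CLASSES)
  cm_emg <- estimate_confusion(emg_true, emg_pred, GAIT_CLASSES)
  fm <- fusion_model(conditionals_from_confusion(cm_eeg, alpha),
                     conditionals_from_confusion(cm_emg, alpha),
                     priors = priors, form = form, alpha = alpha)
  attr(fm, "confusions") <- list(eeg = cm_eeg, emg = cm_emg)
  fm
}

#' Fuse one pair of classifier decisions
#'
#' Computes the belief of each fused class given the two hard predictions:
#' the product over classifiers of `P(true class | predicted class)`
#' times the class prior, with the EEG conditional entering through the
#' repeated-SWING mapping. The decision is the class with the highest
#' belief; exact ties are broken by the deterministic preference
#' `STANCE > RIGHT > LEFT`, so ambiguity never commands a step.
#'
#' @param e_eeg EEG prediction, `"SWING"` or `"STANCE"`.
#' @param e_emg EMG prediction, `"RIGHT"`, `"LEFT"` or `"STANCE"`.
#' @param model A calibrated [fusion_model()].
#' @return List with `belief` (named numeric over the fused classes) and
#'   `decision` (character).
#' @export
fuse <- function(e_eeg, e_emg, model) {
  if (!inherits(model, "fusion_model")) {
    stop("fusion model is not calibrated (expected a fusion_model object)")
  }
  if (!e_eeg %in% EEG_CLASSES) stop("unknown EEG prediction: ", e_eeg)
  if (!e_emg %in% GAIT_CLASSES) stop("unknown EMG prediction: ", e_emg)
  p_eeg <- model$eeg[model$eeg_map[GAIT_CLASSES], e_eeg]
  p_emg <- model$emg[GAIT_CLASSES, e_emg]
  belief <- p_eeg * p_emg *
    switch(model$form,
           product = model$priors,
           normalized = 1 / model$priors)
  names(belief) <- GAIT_CLASSES
  list(belief = belief, decision = belief_argmax(belief, model$tie_order))
}

belief_argmax <- function(belief, tie_order) {
  top <- names(belief)[belief == max(belief)]
  tie_order[tie_order %in% top][1]
}

#' Fuse aligned prediction sequences
#'
#' Elementwise [fuse()] over index-aligned per-window predictions from
#' the two decoders, yielding the fused decision stream at the decision
#' rate. With only six possible prediction pairs the beliefs are computed
#' once per pair and looked up.
#'
#' @param eeg_predictions Character vector over `{SWING, STANCE}`.
#' @param emg_predictions Character vector over `{RIGHT, LEFT, STANCE}`,
#'   same length.
#' @param model A calibrated [fusion_model()].
#' @return List with `decision` (character vector) and `belief`
#'   (windows x 3 matrix of beliefs).
#' @export
fuse_sequence <- function(eeg_predictions, emg_predictions, model) {
  if (length(eeg_predictions) != length(emg_predictions)) {
    stop("prediction sequences differ in length")
  }
  pairs <- expand.grid(eeg = EEG_CLASSES, emg = GAIT_CLASSES,
                       stringsAsFactors = FALSE)
  lut_dec <- character(nrow(pairs))
  lut_bel <- matrix(0, nrow(pairs), 3,
                    dimnames = list(NULL, GAIT_CLASSES))
  for (r in seq_len(nrow(pairs))) {
    fz <- fuse(pairs$eeg[r], pairs$emg[r], model)
    lut_dec[r] <- fz$decision
    lut_bel[r, ] <- fz$belief
  }
  key <- match(eeg_predictions, EEG_CLASSES) +
    2L * (match(emg_predictions, GAIT_CLASSES) - 1L)
  if (anyNA(key)) stop("predictions outside the decoder class sets")
  list(decision = lut_dec[key], belief = lut_bel[key, , drop = FALSE])
}

#' Serialize a fusion model to JSON
#'
#' @param model A [fusion_model()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fusion_model <- function(model, path) {
  obj <- list(eeg_conditionals = unclass(model$eeg),
              emg_conditionals = unclass(model$emg),
              priors = as.list(model$priors), form = model$form,
              alpha = model$alpha,
              eeg_map = as.list(model$eeg_map),
              tie_order = model$tie_order)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' Read a fusion model from JSON
#'
#' @param path File written by [write_fusion_model()].
#' @return A [fusion_model()].
#' @export
read_fusion_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  fusion_model(matrix(obj$eeg_conditionals, 2, 2, byrow = FALSE),
               matrix(obj$emg_conditionals, 3, 3, byrow = FALSE),
               priors = unlist(obj$priors), form = obj$form,
               alpha = obj$alpha)
}
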