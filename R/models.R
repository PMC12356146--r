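ARCHITECTURES <- c(
  "fnn", "ae_baseline", "ae_bayes", "ae_sparse", "bilstm", "gru",
  "cnn", "resnet", "stacked_ae_fnn", "stacked_ae_bilstm"
)

#' Declarative model specification
#'
#' Describes one classifier architecture plus its hyperparameters. Only the
#' hyperparameters relevant to the architecture family are used: `neurons_1`
#' / `neurons_2` for fully connected models, `units` for recurrent models,
#' `filter_size` for convolutional models, `bottleneck` for the autoencoder
#' variants (default: a quarter of the input features, rounded up). Every
#' architecture trains with binary cross-entropy, Adam at `learning_rate`,
#' dropout at `dropout_rate`, and mini-batches of `batch_size`, with seeded
#' weight initialization and batch shuffling.
#'
#' @param architecture One of `r paste0('"', ARCHITECTURES, '"', collapse = ", ")`.
#' @param epochs Training epochs.
#' @param dropout_rate Dropout fraction in [0, 1).
#' @param batch_size Mini-batch size.
#' @param learning_rate Adam step size.
#' @param neurons_1,neurons_2 Hidden-layer widths (fully connected family).
#' @param units Hidden state size (recurrent family).
#' @param filter_size Convolution width (convolutional family).
#' @param bottleneck Autoencoder code size; `NULL` = `ceiling(d / 4)`.
#' @param sparsity_weight L1 activity penalty on the bottleneck
#'   (sparse autoencoder only).
#' @param seed Integer seed; (data, spec, seed) fully determine the fit.
#' @return A `model_spec` object.
#' @export
#' @examples
#' model_spec("fnn", epochs = 50, neurons_1 = 16, neurons_2 = 8)
model_spec <- function(architecture, epochs = 100, dropout_rate = 0.3,
                       batch_size = 32, learning_rate = 1e-3,
                       neurons_1 = 64, neurons_2 = 32, units = 32,
                       filter_size = 3, bottleneck = NULL,
                       sparsity_weight = 1e-4, seed = 1) {
  if (!is.character(architecture) || length(architecture) != 1 ||
    !architecture %in% ARCHITECTURES) {
    abort(sprintf(
      "unknown architecture '%s'; must be one of: %s",
      paste(architecture, collapse = ","), paste(ARCHITECTURES, collapse = ", ")
    ))
  }
  spec <- list(
    architecture = architecture,
    epochs = check_count(epochs, "epochs"),
    dropout_rate = check_fraction(dropout_rate, "dropout_rate", 0, 1,
      hi_open = TRUE
    ),
    batch_size = check_count(batch_size, "batch_size"),
    learning_rate = learning_rate,
    neurons_1 = check_count(neurons_1, "neurons_1"),
    neurons_2 = check_count(neurons_2, "neurons_2"),
    units = check_count(units, "units"),
    filter_size = check_count(filter_size, "filter_size"),
    bottleneck = if (!is.null(bottleneck)) check_count(bottleneck, "bottleneck"),
    sparsity_weight = sparsity_weight,
    seed = check_count(seed, "seed", min = -.Machine$integer.max)
  )
  if (!is.numeric(learning_rate) || length(learning_rate) != 1 ||
    !is.finite(learning_rate) || learning_rate <= 0) {
    abort("`learning_rate` must be a single positive number.")
  }
  structure(spec, class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf(
    "<model_spec> %s: epochs %d, dropout %.2f, batch %d, lr %g, seed %d\n",
    x$architecture, x$epochs, x$dropout_rate, x$batch_size,
    x$learning_rate, x$seed
  ))
  invisible(x)
}

uses_autoencoder <- function(arch) {
  arch %in% c(
    "ae_baseline", "ae_bayes", "ae_sparse",
    "stacked_ae_fnn", "stacked_ae_bilstm"
  )
}

# classifier arch (head) operating on the model's working representation
head_arch <- function(spec, d_in) {
  switch(spec$architecture,
    fnn = ,
    stacked_ae_fnn = build_mlp(
      d_in, c(spec$neurons_1, spec$neurons_2), spec$dropout_rate
    ),
    ae_baseline = ,
    ae_bayes = ,
    ae_sparse = build_mlp(d_in, integer(0), spec$dropout_rate),
    gru = build_gru_classifier(d_in, spec$units, spec$dropout_rate),
    bilstm = ,
    stacked_ae_bilstm = build_bilstm_classifier(
      d_in, spec$units, spec$dropout_rate
    ),
    cnn = build_cnn_classifier(d_in, spec$filter_size,
      dropout_rate = spec$dropout_rate
    ),
    resnet = build_resnet_classifier(d_in, spec$filter_size,
      dropout_rate = spec$dropout_rate
    )
  )
}

#' Pre-train an autoencoder on encoded SNP data
#'
#' Fits a single-hidden-layer (linear bottleneck) autoencoder by Adam on
#' mean squared reconstruction error. The bottleneck defaults to a quarter
#' of the input features (rounded up), a simple structural adaptation to the
#' panel size; the sparse variant adds an L1 activity penalty on the
#' bottleneck codes. The returned encoder maps feature vectors to codes and
#' is what the stacked classifiers train their heads on.
#'
#' @param data Labeled encoded tibble (numeric SNP columns).
#' @param spec A [model_spec()]; `bottleneck`, `epochs`, `batch_size`,
#'   `learning_rate`, `sparsity_weight` (for `ae_sparse`) and `seed` are
#'   used.
#' @return An `ae_encoder`: list with `params`, `history` (loss per epoch),
#'   `bottleneck`, `features`.
#' @export
pretrain_autoencoder <- function(data, spec = model_spec("ae_baseline")) {
  X <- snp_matrix(data)
  bn <- spec$bottleneck %||% ceiling(ncol(X) / 4)
  if (bn >= ncol(X)) {
    abort("`bottleneck` must be smaller than the number of features.")
  }
  l1a <- if (spec$architecture == "ae_sparse") spec$sparsity_weight else 0
  fit <- with_rng(spec$seed, train_autoencoder(
    X, bn,
    epochs = spec$epochs, batch_size = spec$batch_size,
    learning_rate = spec$learning_rate, l1_activity = l1a
  ))
  structure(
    list(
      params = fit$params, history = fit$history,
      bottleneck = bn, features = colnames(X)
    ),
    class = "ae_encoder"
  )
}

#' Encode samples with a pre-trained autoencoder
#'
#' @param encoder An `ae_encoder` from [pretrain_autoencoder()].
#' @param data Labeled encoded tibble with the encoder's feature columns.
#' @return Numeric matrix of bottleneck codes (samples x bottleneck).
#' @export
encode_samples <- function(encoder, data) {
  if (!inherits(encoder, "ae_encoder")) abort("`encoder` must be an ae_encoder.")
  X <- snp_matrix(data)
  missing <- setdiff(encoder$features, colnames(X))
  if (length(missing) > 0) {
    abort(sprintf(
      "data lacks encoder feature(s): %s",
      paste(utils::head(missing, 5), collapse = ", ")
    ))
  }
  ae_encode(encoder$params, X[, encoder$features, drop = FALSE])
}

#' Train a classifier from a model specification
#'
#' Trains the architecture named in `spec` on the encoded dataset with
#' binary cross-entropy (Case = 1). Autoencoder-based architectures first
#' pre-train their encoder on the training features, freeze it, and train
#' the classification head on the bottleneck codes; recurrent architectures
#' consume the feature vector as a sequence of scalars in panel order;
#' convolutional architectures convolve along the feature axis. The whole
#' fit is a pure function of (data, spec), seed included.
#'
#' @param data Labeled encoded tibble.
#' @param spec A [model_spec()].
#' @return A `trained_model` with the spec, fitted parameters, the frozen
#'   encoder (if any) and the per-epoch training-loss history.
#' @export
train_classifier <- function(data, spec) {
  if (!inherits(spec, "model_spec")) abort("`spec` must be a model_spec.")
  X <- snp_matrix(data)
  if (any(!is.finite(X))) abort("feature matrix contains non-finite values.")
  y <- case_indicator(data)
  encoder <- NULL
  if (uses_autoencoder(spec$architecture)) {
    encoder <- pretrain_autoencoder(data, spec)
    Xw <- encode_samples(encoder, data)
  } else {
    Xw <- X
  }
  arch <- head_arch(spec, ncol(Xw))
  fit <- with_rng(spec$seed + 1L, train_nn_classifier(
    arch, Xw, y,
    epochs = spec$epochs, batch_size = spec$batch_size,
    learning_rate = spec$learning_rate
  ))
  structure(
    list(
      spec = spec, params = fit$params, history = fit$history,
      encoder = encoder, features = colnames(X), arch = arch
    ),
    class = "trained_model"
  )
}

#' @export
print.trained_model <- function(x, ...) {
  cat(sprintf(
    "<trained_model> %s on %d features; final training loss %.4f\n",
    x$spec$architecture, length(x$features),
    x$history[length(x$history)]
  ))
  invisible(x)
}

#' Predict case probabilities with a trained model
#'
#' Prediction is pure: no dropout, no RNG. Hard labels use the fixed rule
#' probability >= 0.5 -> Case.
#'
#' @param object A `trained_model`.
#' @param new_data Labeled or unlabeled encoded tibble containing the
#'   model's feature columns.
#' @param ... Unused.
#' @return A tibble with `Sample_ID` (if present), `.prob` (case
#'   probability) and `.pred` ("Case"/"Control").
#' @export
predict.trained_model <- function(object, new_data, ...) {
  cols <- setdiff(names(new_data), ID_COLS)
  missing <- setdiff(object$features, cols)
  if (length(missing) > 0) {
    abort(sprintf(
      "new_data lacks %d model feature(s), e.g. %s",
      length(missing), paste(utils::head(missing, 3), collapse = ", ")
    ))
  }
  X <- as.matrix(new_data[, object$features, drop = FALSE])
  storage.mode(X) <- "double"
  Xw <- if (!is.null(object$encoder)) {
    ae_encode(object$encoder$params, X)
  } else {
    X
  }
  p <- sigmoid(object$arch$forward(object$params, Xw, training = FALSE)$logit)
  out <- tibble(
    .prob = as.numeric(p),
    .pred = ifelse(p >= 0.5, "Case", "Control")
  )
  if ("Sample_ID" %in% names(new_data)) {
    out <- dplyr::bind_cols(tibble(Sample_ID = new_data$Sample_ID), out)
  }
  out
}

#' @rdname tidy.cv_report
#' @method tidy trained_model
#' @export
tidy.trained_model <- function(x, ...) {
  tibble(epoch = seq_along(x$history), loss = x$history)
}

#' @rdname tidy.cv_report
#' @method glance trained_model
#' @export
glance.trained_model <- function(x, ...) {
  tibble(
    architecture = x$spec$architecture,
    epochs = x$spec$epochs,
    n_features = length(x$features),
    final_loss = x$history[length(x$history)]
  )
}
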