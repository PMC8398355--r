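# End-to-end experiment: generate -> preprocess -> represent -> extract ->
# classify -> evaluate, fully seeded, with subject-wise splits.

#' Experiment configuration
#'
#' Bundles every stage's parameters. The defaults are the package's
#' desk-scale benchmark: 6 subjects x 12 classes x 8 trials each of 1 s of
#' 4-channel sEMG at 2048 Hz, an 8 Hz frequency grid over 6--500 Hz rendered
#' at 64 x 64, a reduced extractor (stem 24 filters, blocks (3, 6), growth
#' 12) and a flatten -> 128 -> 96 -> 12 classifier, evaluated on two
#' held-out subject pairs. Pass a full-scale [acquisition_spec()] /
#' [mffn_config()] / [dbn_config()] layer plan for the complete architecture.
#'
#' @param acq [acquisition_spec()] of the synthetic corpus.
#' @param noise [noise_spec()].
#' @param filter [filter_spec()] for denoising.
#' @param f_lo,f_hi,f_step Frequency grid of the wavelet decomposition (Hz).
#' @param image_size Rendered image height = width.
#' @param norm,colormap Passed to [render_rgb()].
#' @param mffn [mffn_config()] of the feature extractor.
#' @param hidden_sizes Hidden layer sizes of the classifier stack (the input
#'   size is the extractor's flatten length).
#' @param dbn_epochs,dbn_lr Fine-tuning schedule.
#' @param pretrain_epochs Pretraining epochs for the RBM stack.
#' @param train_extractor Joint fine-tuning of the conv extractor?
#' @param compare_fc Also train the fully connected baseline head?
#' @param splits List of held-out subject-id vectors, one per split.
#' @param subject_sigma Per-subject log-normal gain jitter.
#' @param seed Master seed for every random stage.
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(acq = acquisition_spec(duration = 1,
                                                     n_subjects = 6,
                                                     trials_per_class_per_subject = 8),
                              noise = noise_spec(),
                              filter = filter_spec(),
                              f_lo = 6, f_hi = 500, f_step = 8,
                              image_size = 64, norm = "minmax",
                              colormap = "jet",
                              mffn = mffn_config(input_size = 64,
                                                 stem_filters = 24,
                                                 block_sizes = c(3, 6),
                                                 growth = 12),
                              hidden_sizes = c(128, 96),
                              dbn_epochs = 40, dbn_lr = 1e-3,
                              pretrain_epochs = 5,
                              train_extractor = FALSE,
                              compare_fc = TRUE,
                              splits = list(c(1, 2), c(3, 4)),
                              subject_sigma = 0.2,
                              seed = 1) {
  stopifnot(inherits(acq, "acquisition_spec"), inherits(mffn, "mffn_config"),
            image_size == mffn$input_size, length(splits) >= 1)
  structure(
    list(acq = acq, noise = noise, filter = filter,
         f_lo = f_lo, f_hi = f_hi, f_step = f_step,
         image_size = image_size, norm = norm, colormap = colormap,
         mffn = mffn, hidden_sizes = hidden_sizes,
         dbn_epochs = dbn_epochs, dbn_lr = dbn_lr,
         pretrain_epochs = pretrain_epochs,
         train_extractor = isTRUE(train_extractor),
         compare_fc = isTRUE(compare_fc),
         splits = splits, subject_sigma = subject_sigma,
         seed = as.integer(seed)),
    class = "experiment_config"
  )
}

# Representation stage shared by run_experiment and compare_heads:
# images, extraction-point features and channel-mean profiles per trial.
represent_dataset <- function(dataset, config, keep_images = FALSE) {
  grid <- make_grid(config$f_lo, config$f_hi, config$f_step,
                    dataset$acq$sampling_rate)
  extractor <- build_mffn(config$mffn, seed = derive_seed(config$seed, 11))
  n <- nrow(dataset$trials)
  d_flat <- utils::tail(shape_plan(config$mffn)$channels, 1)
  features <- matrix(0, n, d_flat)
  images <- array(0, c(config$image_size, config$image_size, 3, n))
  acq <- dataset$acq
  for (i in seq_len(n)) {
    trial <- structure(list(data = dataset$trials$data[[i]],
                            class_id = dataset$trials$class[i],
                            subject_id = dataset$trials$subject[i],
                            acq = acq, preprocessed = dataset$preprocessed),
                       class = "semg_trial")
    img <- trial_to_image(trial, grid, size = config$image_size,
                          norm = config$norm, colormap = config$colormap)
    images[, , , i] <- img$pixels
  }
  fms <- extract_features(extractor, images)
  profiles <- matrix(0, n, length(channel_mean_profile(fms[[1]])))
  for (i in seq_len(n)) {
    features[i, ] <- fms[[i]]$flat
    profiles[i, ] <- channel_mean_profile(fms[[i]])
  }
  list(features = features, profiles = profiles,
       images = if (keep_images) images else NULL,
       extractor = extractor, grid = grid,
       labels = dataset$trials$class, subjects = dataset$trials$subject)
}

classifier_config <- function(config, d_flat, seed) {
  dbn_config(layer_sizes = c(d_flat, config$hidden_sizes),
             n_classes = config$acq$n_classes,
             pretrain_epochs = config$pretrain_epochs,
             finetune_epochs = config$dbn_epochs,
             finetune_lr = config$dbn_lr,
             train_extractor = config$train_extractor,
             seed = seed)
}

#' Run the full end-to-end experiment
#'
#' Generates (or takes) a dataset, denoises it, builds the fused wavelet
#' images, extracts convolutional features, then for every subject-wise
#' split trains the DBN classifier (and optionally the fully connected
#' baseline) on the training subjects only — standardization constants and
#' all training see no test-subject trial — and scores the held-out
#' subjects. Feature-mutation statistics (QD/MD/STD), the 12 x 12
#' correlation matrix of per-class mean channel profiles, and per-class
#' box-plot summaries of the correlations are computed from the extracted
#' features. Fully deterministic under `config$seed`.
#'
#' @param config An [experiment_config()].
#' @param dataset Optional pre-generated `semg_dataset` (otherwise generated
#'   from `config`).
#' @return An object of class `semg_eval`; see [tidy.semg_eval()] and
#'   [glance.semg_eval()].
#' @export
run_experiment <- function(config = experiment_config(), dataset = NULL) {
  stopifnot(inherits(config, "experiment_config"))
  if (is.null(dataset)) {
    dataset <- generate_dataset(config$acq, config$noise, seed = config$seed,
                                subject_sigma = config$subject_sigma)
  }
  if (!isTRUE(dataset$preprocessed)) {
    dataset <- preprocess_dataset(dataset, config$filter)
  }
  rep <- represent_dataset(dataset, config,
                           keep_images = config$train_extractor)
  n_classes <- config$acq$n_classes
  cm <- matrix(0L, n_classes, n_classes,
               dimnames = list(true = seq_len(n_classes),
                               predicted = seq_len(n_classes)))
  split_rows <- vector("list", length(config$splits))
  for (si in seq_along(config$splits)) {
    test_subjects <- config$splits[[si]]
    in_test <- rep$subjects %in% test_subjects
    if (!any(in_test) || all(in_test)) {
      stop("split ", si, " leaves an empty partition", call. = FALSE)
    }
    cfg <- classifier_config(config, ncol(rep$features),
                             seed = derive_seed(config$seed, 300, si))
    stack <- pretrain(cfg, rep$features[!in_test, , drop = FALSE])
    dbn_fit <- finetune(stack, rep$features[!in_test, , drop = FALSE],
                        rep$labels[!in_test], cfg,
                        extractor = if (config$train_extractor) rep$extractor,
                        images = if (config$train_extractor) {
                          rep$images[, , , !in_test, drop = FALSE]
                        })
    pred <- predict(dbn_fit, rep$features[in_test, , drop = FALSE])
    acc_dbn <- accuracy(pred, rep$labels[in_test])
    cm <- cm + confusion(pred, rep$labels[in_test], n_classes)
    acc_fc <- NA_real_
    if (config$compare_fc) {
      fc_fit <- fc_baseline(rep$features[!in_test, , drop = FALSE],
                            rep$labels[!in_test], cfg)
      acc_fc <- accuracy(predict(fc_fit, rep$features[in_test, , drop = FALSE]),
                         rep$labels[in_test])
    }
    split_rows[[si]] <- tibble::tibble(
      split = si, test_subjects = paste(test_subjects, collapse = ","),
      n_train = sum(!in_test), n_test = sum(in_test),
      accuracy_dbn = acc_dbn, accuracy_fc = acc_fc
    )
  }
  split_results <- dplyr::bind_rows(split_rows)
  class_profiles <- vapply(seq_len(n_classes), function(cl) {
    colMeans(rep$profiles[rep$labels == cl, , drop = FALSE])
  }, numeric(ncol(rep$profiles)))
  class_stats <- tibble::tibble(
    class = seq_len(n_classes),
    qd = apply(class_profiles, 2, qd),
    md = apply(class_profiles, 2, md),
    stdev = apply(class_profiles, 2, stdev)
  )
  rho <- correlation_matrix(class_profiles)
  box_stats <- if (n_classes >= 6) { # box statistics need >= 5 correlations
    dplyr::bind_rows(lapply(seq_len(n_classes), function(cl) {
      f <- five_number_summary(rho[cl, -cl])
      tibble::tibble(class = cl, min = f$min, q1 = f$q1, median = f$median,
                     q3 = f$q3, max = f$max, n_outliers = length(f$outliers))
    }))
  } else {
    tibble::tibble(class = integer(), min = numeric(), q1 = numeric(),
                   median = numeric(), q3 = numeric(), max = numeric(),
                   n_outliers = integer())
  }
  structure(
    list(split_results = split_results,
         mean_accuracy = mean(split_results$accuracy_dbn),
         mean_accuracy_fc = if (config$compare_fc) {
           mean(split_results$accuracy_fc)
         } else NA_real_,
         confusion = cm, class_stats = class_stats,
         correlation = rho, box_stats = box_stats,
         features = rep$features, profiles = rep$profiles,
         labels = rep$labels, subjects = rep$subjects,
         quartile_convention = "type 7 (linear interpolation)",
         config = config),
    class = "semg_eval"
  )
}

#' Train DBN and FC heads over several seeds on fixed features
#'
#' Used for the directional head comparison: both classifiers see exactly
#' the same extracted features and split, only the head (pretrained DBN vs
#' randomly initialized fully connected stack) differs.
#'
#' @param report A [run_experiment()] result (its stored features are used).
#' @param split Which configured split to use.
#' @param seeds Integer vector of training seeds.
#' @return Tibble with one row per seed: `accuracy_dbn`, `accuracy_fc`.
#' @export
compare_heads <- function(report, split = 1, seeds = 1:5) {
  stopifnot(inherits(report, "semg_eval"))
  config <- report$config
  test_subjects <- config$splits[[split]]
  in_test <- report$subjects %in% test_subjects
  rows <- lapply(seeds, function(s) {
    cfg <- classifier_config(config, ncol(report$features),
                             seed = derive_seed(config$seed, 770, s))
    cfg$train_extractor <- FALSE
    stack <- pretrain(cfg, report$features[!in_test, , drop = FALSE])
    dbn_fit <- finetune(stack, report$features[!in_test, , drop = FALSE],
                        report$labels[!in_test], cfg)
    fc_fit <- fc_baseline(report$features[!in_test, , drop = FALSE],
                          report$labels[!in_test], cfg)
    tibble::tibble(
      seed = s,
      accuracy_dbn = accuracy(
        predict(dbn_fit, report$features[in_test, , drop = FALSE]),
        report$labels[in_test]),
      accuracy_fc = accuracy(
        predict(fc_fit, report$features[in_test, , drop = FALSE]),
        report$labels[in_test])
    )
  })
  dplyr::bind_rows(rows)
}

#' @export
print.semg_eval <- function(x, ...) {
  cat("<semg_eval> ", nrow(x$split_results), " subject-wise split(s)\n", sep = "")
  print(x$split_results)
  cat(sprintf("mean accuracy: DBN %.2f%%", x$mean_accuracy))
  if (!is.na(x$mean_accuracy_fc)) cat(sprintf(", FC %.2f%%", x$mean_accuracy_fc))
  cat("\n")
  invisible(x)
}

#' Per-split results of an evaluation report
#'
#' @param x A `semg_eval`.
#' @param ... Unused.
#' @return Tibble with one row per subject-wise split.
#' @method tidy semg_eval
#' @export
tidy.semg_eval <- function(x, ...) x$split_results

#' One-row summary of an evaluation report
#'
#' @param x A `semg_eval`.
#' @param ... Unused.
#' @return One-row tibble: split count, trial counts, mean accuracies,
#'   confusion-derived accuracy.
#' @method glance semg_eval
#' @export
glance.semg_eval <- function(x, ...) {
  tibble::tibble(
    n_splits = nrow(x$split_results),
    n_trials = length(x$labels),
    mean_accuracy = x$mean_accuracy,
    mean_accuracy_fc = x$mean_accuracy_fc,
    confusion_accuracy = 100 * sum(diag(x$confusion)) / sum(x$confusion)
  )
}

#' Confusion-matrix heat map of an evaluation report
#'
#' @param object A `semg_eval`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot semg_eval
#' @export
autoplot.semg_eval <- function(object, ...) {
  df <- as.data.frame(as.table(object$confusion))
  names(df) <- c("true", "predicted", "count")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$predicted, y = .data$true,
                                   fill = .data$count)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$count), size = 3) +
    ggplot2::scale_y_discrete(limits = rev(levels(df$true))) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::labs(x = "predicted class", y = "true class",
                  title = "Motion classification confusion matrix") +
    ggplot2::theme_minimal()
}

#' Scalogram heat map
#'
#' @param object A `scalogram` from [mdtfr()].
#' @param ... Unused.
#' @return A ggplot object (time vs frequency, |CWT| magnitude fill).
#' @method autoplot scalogram
#' @export
autoplot.scalogram <- function(object, ...) {
  m <- object$magnitude
  df <- data.frame(
    time = rep(seq_len(ncol(m)) / object$grid$fs, each = nrow(m)),
    frequency = rep(object$grid$frequencies, ncol(m)),
    magnitude = as.vector(m)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$frequency,
                                   fill = .data$magnitude)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "time (s)", y = "frequency (Hz)", fill = "|CWT|") +
    ggplot2::theme_minimal()
}

#' Per-class correlation box-plot summary
#'
#' Mirrors the box-plot view of between-class feature correlations: one box
#' per class, built from that class's correlations with every other class.
#'
#' @param report A `semg_eval`.
#' @return A ggplot object.
#' @export
plot_correlation_boxes <- function(report) {
  stopifnot(inherits(report, "semg_eval"))
  rho <- report$correlation
  k <- nrow(rho)
  df <- do.call(rbind, lapply(seq_len(k), function(cl) {
    data.frame(class = factor(cl, levels = seq_len(k)), rho = rho[cl, -cl])
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$class, y = .data$rho)) +
    ggplot2::geom_boxplot(fill = "lightsteelblue") +
    ggplot2::labs(x = "action class", y = "correlation coefficient") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
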