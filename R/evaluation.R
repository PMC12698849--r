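# Classification and attack metrics, the noise-type sweep experiment, and
# report serialization.

#' Classification report
#'
#' Confusion matrix (rows = true class), per-class precision/recall/F1 and
#' support, overall accuracy, and macro (unweighted) and weighted
#' (support-weighted) averages. A class with zero predicted (resp. true)
#' positives gets precision (resp. recall) 0.
#'
#' @param true_labels,predicted_labels integer labels in
#'   `0:(n_classes - 1)`, equal length
#' @param n_classes number of classes
#' @return an object of class `metrics_report`
#' @examples
#' r <- compute_metrics(c(0, 0, 1, 1), c(0, 0, 0, 0), 2)
#' r$accuracy       # 0.5
#' r$macro$f1       # 1/3
#' @export
compute_metrics <- function(true_labels, predicted_labels, n_classes) {
  if (length(true_labels) != length(predicted_labels))
    stop("label vectors differ in length")
  if (length(true_labels) == 0L) stop("no samples to evaluate")
  lv <- 0:(n_classes - 1L)
  if (any(!true_labels %in% lv) || any(!predicted_labels %in% lv))
    stop("labels outside 0..", n_classes - 1L)
  cm <- table(factor(true_labels, levels = lv),
              factor(predicted_labels, levels = lv))
  cm <- matrix(as.integer(cm), n_classes, n_classes,
               dimnames = list(true = lv, predicted = lv))
  support <- rowSums(cm)
  tp <- diag(cm)
  pred_pos <- colSums(cm)
  precision <- ifelse(pred_pos > 0, tp / pred_pos, 0)
  recall <- ifelse(support > 0, tp / support, 0)
  f1 <- ifelse(precision + recall > 0,
               2 * precision * recall / (precision + recall), 0)
  w <- support / sum(support)
  structure(list(
    confusion = cm,
    per_class = data.frame(class = lv, precision = precision,
                           recall = recall, f1 = f1, support = support,
                           row.names = NULL),
    accuracy = sum(tp) / sum(cm),
    macro = list(precision = mean(precision), recall = mean(recall),
                 f1 = mean(f1)),
    weighted = list(precision = sum(w * precision),
                    recall = sum(w * recall), f1 = sum(w * f1)),
    n = sum(cm)), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, digits = 3, ...) {
  cat("Classification report (", x$n, " samples)\n", sep = "")
  print(round(as.data.frame(x$per_class), digits))
  cat(sprintf("accuracy %.3f | macro P/R/F1 %.3f/%.3f/%.3f | weighted %.3f/%.3f/%.3f\n",
              x$accuracy, x$macro$precision, x$macro$recall, x$macro$f1,
              x$weighted$precision, x$weighted$recall, x$weighted$f1))
  invisible(x)
}

#' Privacy/utility sweep over noise families and scales
#'
#' For every combination of noise family, scale, and seed, measures the
#' model's test accuracy and the label inference attack accuracy under that
#' noise, plus one noise-free baseline row per seed (family `"none"`,
#' scale 0). Two regimes:
#' \describe{
#'   \item{`retrain = TRUE`}{a SplitFed model is trained from scratch per
#'     combination with the noise active during training (the full defense),
#'     and the attack observes noisy transmissions.}
#'   \item{`retrain = FALSE`}{one noise-free model is trained per seed and
#'     the noise is applied to the transmissions the adversary observes at
#'     attack time; model accuracy is then the clean accuracy. Much cheaper;
#'     isolates the defense's effect on the attack.}
#' }
#'
#' @param data,plan,test training data, partition plan, and held-out set
#' @param base_cfg a [train_config()] used for every run (its `dp` field is
#'   overridden per combination)
#' @param families character vector of noise families
#' @param scales numeric vector of noise scales
#' @param seeds integer vector of seeds
#' @param n_attack samples attacked per run
#' @param location noise location parameter (default 0)
#' @param targets injection targets for the swept noise
#' @param retrain see above
#' @param out_csv optional path; partial rows are flushed there after every
#'   run
#' @return a `sweep_result` data.frame with columns family, location, scale,
#'   seed, model_accuracy, attack_accuracy
#' @export
run_noise_sweep <- function(data, plan, test, base_cfg,
                            families = c("gaussian", "laplace", "cauchy",
                                         "exponential"),
                            scales = c(0.01, 0.1, 1, 10),
                            seeds = 1:3, n_attack = 100L, location = 0,
                            targets = c("activations", "gradients"),
                            retrain = TRUE, out_csv = NULL) {
  rows <- list()
  flush <- function() {
    out <- do.call(rbind, rows)
    if (!is.null(out_csv)) utils::write.csv(out, out_csv, row.names = FALSE)
    out
  }
  for (sd in seeds) {
    cfg0 <- base_cfg
    cfg0$seed <- as.integer(sd)
    cfg0$dp <- NULL
    base_state <- if (!retrain)
      train_splitfed(data, plan, cfg0, test = test) else NULL
    # baseline: no DP
    state <- base_state %||% train_splitfed(data, plan, cfg0, test = test)
    macc <- evaluate_model(state, test)$accuracy
    aacc <- run_attack(state, test, n_attack, seed = sd)$accuracy
    rows[[length(rows) + 1L]] <- data.frame(
      family = "none", location = 0, scale = 0, seed = sd,
      model_accuracy = macc, attack_accuracy = aacc)
    flush()
    for (fam in families) {
      for (sc in scales) {
        ns <- noise_spec(fam, location = location, scale = sc,
                         targets = targets)
        if (retrain) {
          cfg1 <- cfg0
          cfg1$dp <- ns
          state <- train_splitfed(data, plan, cfg1, test = test)
          macc <- evaluate_model(state, test)$accuracy
        } else {
          state <- base_state
          macc <- rows[[which(vapply(rows, function(r)
            r$family == "none" && r$seed == sd, logical(1)))[1]]]$model_accuracy
        }
        aacc <- run_attack(state, test, n_attack, seed = sd,
                           noise = ns)$accuracy
        rows[[length(rows) + 1L]] <- data.frame(
          family = fam, location = location, scale = sc, seed = sd,
          model_accuracy = macc, attack_accuracy = aacc)
        flush()
      }
    }
  }
  structure(flush(), class = c("sweep_result", "data.frame"))
}

#' Serialize a report to disk
#'
#' `metrics_report` and `attack_result` objects are written as JSON;
#' `sweep_result` (and any data.frame) as CSV with a header row. The
#' round-trip through [read_report()] reproduces every number exactly
#' (JSON is written at full precision).
#'
#' @param report the object to write
#' @param path output file; extension selects the format (`.json` or
#'   `.csv`)
#' @return `path`, invisibly
#' @export
write_report <- function(report, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") {
    stopifnot(is.data.frame(report))
    utils::write.csv(report, path, row.names = FALSE)
  } else if (ext == "json") {
    payload <-
      if (inherits(report, "metrics_report")) {
        list(type = "metrics_report",
             confusion = unclass(report$confusion),
             per_class = report$per_class, accuracy = report$accuracy,
             macro = report$macro, weighted = report$weighted, n = report$n)
      } else if (inherits(report, "attack_result")) {
        list(type = "attack_result", per_sample = report$per_sample,
             accuracy = report$accuracy, n = report$n,
             clone_mode = report$clone_mode)
      } else as.list(report)
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17),
                         dataframe = "columns")
  } else stop("unsupported report extension: ", ext)
  invisible(path)
}

#' Read back a serialized report
#'
#' @param path a `.json` or `.csv` file written by [write_report()]
#' @return a list (JSON) or data.frame (CSV)
#' @export
read_report <- function(path) {
  if (!file.exists(path)) stop("no such report: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") utils::read.csv(path)
  else if (ext == "json") jsonlite::read_json(path, simplifyVector = TRUE)
  else stop("unsupported report extension: ", ext)
}
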