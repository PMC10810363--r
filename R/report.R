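#' Static HTML reports
#'
#' Two self-contained report types: one for the evaluation of a learning
#' methodology (per-size summary tables over the training/test/full slices
#' and a performance-vs-size figure with per-model dots, boxplots, the mean
#' line, confidence bands and the selected best model highlighted in red)
#' and one for a single model (confusion matrix, per-class and averaged
#' metrics, ROC curve for binary problems, PCA scatter restricted to the
#' model's features, violin plots of the first principal-component score by
#' class, and an external-data section when external data are supplied).
#'
#' Reports embed their figures as base64 images (no network assets) and a
#' plot-data JSON is written alongside each report so the figures can be
#' re-rendered or made interactive downstream. The methodology report is a
#' pure function of the evaluation object: it never refits or rescores.
#'
#' @name report
NULL

html_escape <- function(x) {
  x <- gsub("&", "&amp;", as.character(x), fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

html_table <- function(df, digits = 4) {
  fmt <- function(v) {
    if (is.numeric(v)) ifelse(is.na(v), "", signif(v, digits))
    else html_escape(ifelse(is.na(v), "", as.character(v)))
  }
  cells <- vapply(df, function(col) as.character(fmt(col)), character(nrow(df)))
  if (nrow(df) == 1L) cells <- matrix(cells, nrow = 1L)
  head_row <- paste0("<tr>", paste0("<th>", html_escape(names(df)), "</th>",
                                    collapse = ""), "</tr>")
  body <- apply(cells, 1L, function(r)
    paste0("<tr>", paste0("<td>", r, "</td>", collapse = ""), "</tr>"))
  paste0("<table>", head_row, paste(body, collapse = ""), "</table>")
}

embed_plot <- function(p, width = 8, height = 5) {
  f <- tempfile(fileext = ".png")
  on.exit(unlink(f))
  grDevices::png(f, width = width * 96, height = height * 96, res = 96,
                 type = "cairo")
  print(p)
  grDevices::dev.off()
  paste0("<img src=\"data:image/png;base64,",
         jsonlite::base64_enc(readBin(f, "raw", file.size(f))),
         "\" width=\"", width * 96, "\"/>")
}

html_page <- function(title, body) {
  paste0("<!DOCTYPE html>\n<html><head><meta charset=\"utf-8\"/>",
         "<title>", html_escape(title), "</title><style>",
         "body{font-family:sans-serif;max-width:1000px;margin:2em auto;}",
         "table{border-collapse:collapse;margin:1em 0;}",
         "td,th{border:1px solid #999;padding:3px 8px;text-align:right;}",
         "th{background:#eee;}h2{border-bottom:1px solid #ccc;}",
         "</style></head><body><h1>", html_escape(title), "</h1>",
         body, "</body></html>")
}

method_plot_data <- function(ev) {
  recs <- Filter(function(r) !isTRUE(r$failed), ev$records)
  best_idx <- if (!is.null(ev$best))
    vapply(recs, function(r)
      r$size_index == ev$best$size_index &&
        r$repeat_id == ev$best$repeat_id, logical(1))
  else rep(FALSE, length(recs))
  pts <- do.call(rbind, lapply(seq_along(recs), function(i) {
    r <- recs[[i]]
    data.frame(size = r$size,
               slice = c("train", "test", "full"),
               score = c(r$train_score, r$test_score, r$full_score),
               best = best_idx[i])
  }))
  pts$slice <- factor(pts$slice, levels = c("train", "test", "full"))
  pts
}

#' Render the learning-methodology report
#'
#' @param ev A `method_evaluation` (freshly computed or read back via
#'   [read_evaluation()]).
#' @param out_path Output HTML path; a `<name>_plotdata.json` file is
#'   written next to it.
#' @return Invisibly, `out_path`.
#' @export
render_method_report <- function(ev, out_path) {
  meta <- data.frame(
    setting = c("task", "learner", "metric", "direction", "sampling scheme",
                "training-set sizes", "repeats per size", "inner tuning",
                "tuning rule", "supervised screening", "confidence level",
                "seed", "failed fits"),
    value = c(ev$task, ev$learner$family, ev$metric, ev$direction,
              ev$scheme, paste(ev$sizes, collapse = ", "), ev$n_repeats,
              paste0(ev$inner$scheme, " (k=", ev$inner$k, ")"),
              ev$tuning_rule,
              if (is.null(ev$screening$method)) "none"
              else ev$screening$method,
              ev$confidence, ev$seed, ev$n_failed))

  pts <- method_plot_data(ev)
  sm <- ev$summaries
  fig <- ggplot2::ggplot(pts, ggplot2::aes(x = factor(size), y = score)) +
    ggplot2::geom_boxplot(outlier.shape = NA, fill = NA,
                          colour = "grey60") +
    ggplot2::geom_point(data = pts[!pts$best, , drop = FALSE],
                        colour = "darkgreen", alpha = 0.6,
                        position = ggplot2::position_jitter(width = 0.1,
                                                            seed = 1)) +
    ggplot2::geom_point(data = pts[pts$best & pts$slice == "test", ,
                                   drop = FALSE],
                        colour = "red", size = 3) +
    ggplot2::geom_errorbar(
      data = sm, ggplot2::aes(x = factor(size), ymin = ci_low,
                              ymax = ci_high), inherit.aes = FALSE,
      width = 0.4, colour = "grey40", alpha = 0.7) +
    ggplot2::geom_line(data = sm,
                       ggplot2::aes(x = factor(size), y = mean, group = 1),
                       inherit.aes = FALSE, colour = "orange") +
    ggplot2::facet_wrap(~slice, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "training-set size", y = ev$metric,
                  title = paste0(ev$learner$family, ": ", ev$metric,
                                 " vs training-set size")) +
    ggplot2::theme_minimal()

  slice_tables <- vapply(c("train", "test", "full"), function(sl) {
    tb <- sm[sm$slice == sl, c("size", "mean", "sd", "sem", "ci_low",
                               "ci_high", "n", "n_missing")]
    paste0("<h3>", sl, " slice</h3>", html_table(as.data.frame(tb)))
  }, character(1))

  best_html <- if (!is.null(ev$best)) {
    paste0("<p>Best model (red): size ", ev$best$size, ", repeat ",
           ev$best$repeat_id, ", test ", ev$metric, " = ",
           signif(ev$best$test_score, 4), ", configuration ",
           html_escape(paste(names(ev$best$configuration),
                             unlist(ev$best$configuration), sep = "=",
                             collapse = "; ")), "</p>")
  } else "<p>No best model (all records failed).</p>"

  body <- paste0(
    "<h2>Methodology</h2>", html_table(meta),
    "<h2>Best model</h2>", best_html,
    "<h2>Performance across training-set sizes</h2>", embed_plot(fig, 8, 9),
    "<h2>Per-size summaries</h2>", paste(slice_tables, collapse = ""))
  writeLines(html_page("Learning-method evaluation report", body), out_path)

  pd_path <- sub("\\.html?$", "_plotdata.json", out_path)
  if (pd_path == out_path) pd_path <- paste0(out_path, "_plotdata.json")
  jsonlite::write_json(list(points = pts, summaries = sm), pd_path,
                       digits = NA, na = "null")
  invisible(out_path)
}

#' Render the single-model report
#'
#' @param model A `trained_model` (e.g. `ev$best_model`).
#' @param dataset The internal `ml_dataset` the model came from.
#' @param external Optional list with elements `X` and `y`: an external
#'   dataset for additional evaluation.
#' @param out_path Output HTML path; a `<name>_plotdata.json` is written
#'   next to it.
#' @return Invisibly, `out_path`.
#' @export
render_model_report <- function(model, dataset, external = NULL, out_path) {
  task <- model$spec$task
  pred <- stats::predict(model, dataset$X)
  plotdata <- list()
  body <- paste0("<h2>Model</h2><p>", model$spec$family, " (", task,
                 "), configuration ",
                 html_escape(paste(names(model$configuration),
                                   unlist(model$configuration), sep = "=",
                                   collapse = "; ")), "; ",
                 sum(model$presence), " of ", length(model$presence),
                 " features present.</p>")

  metric_table <- function(y, yh) {
    if (task == "classification") {
      classes <- levels(factor(y))
      mets <- c("acc", "err", "precision", "sensitivity", "f1")
      per <- do.call(rbind, lapply(classes, function(cl) {
        cm <- confusion_matrix(as.character(y), yh, cl)
        data.frame(class = cl, t(vapply(mets, function(m)
          classification_score(cm, m), numeric(1))))
      }))
      avg <- data.frame(class = "macro average",
                        t(vapply(mets, function(m)
                          score(as.character(y), yh, m), numeric(1))))
      rbind(per, avg)
    } else {
      data.frame(t(vapply(c("mse", "rmse", "mae", "mape", "r2"),
                          function(m) regression_score(y, yh, m),
                          numeric(1))))
    }
  }

  internal_tb <- metric_table(dataset$y, pred)
  if (task == "classification") {
    cm_tab <- as.data.frame.matrix(table(actual = dataset$y,
                                         predicted = factor(pred,
                                           levels = levels(dataset$y))))
    cm_tab <- cbind(actual = rownames(cm_tab), cm_tab)
    body <- paste0(body, "<h2>Confusion matrix (internal data)</h2>",
                   html_table(cm_tab, digits = 10))
  }
  body <- paste0(body, "<h2>Performance metrics (internal data)</h2>",
                 html_table(internal_tb))
  plotdata$internal_metrics <- internal_tb

  # ROC: binary classification with a continuous decision value
  if (task == "classification" && length(model$levels) == 2L) {
    sc <- stats::predict(model, dataset$X, type = "score")
    if (!is.null(sc)) {
      roc <- pROC::roc(response = dataset$y, predictor = sc,
                       levels = model$levels, direction = "<", quiet = TRUE)
      rocdf <- data.frame(fpr = 1 - roc$specificities,
                          tpr = roc$sensitivities)
      rocdf <- rocdf[order(rocdf$fpr, rocdf$tpr), ]
      figroc <- ggplot2::ggplot(rocdf, ggplot2::aes(fpr, tpr)) +
        ggplot2::geom_path(colour = "steelblue") +
        ggplot2::geom_abline(linetype = 2, colour = "grey") +
        ggplot2::labs(title = sprintf("ROC curve (AUC = %.3f)",
                                      as.numeric(pROC::auc(roc))),
                      x = "false positive rate",
                      y = "true positive rate") +
        ggplot2::theme_minimal()
      body <- paste0(body, "<h2>ROC curve</h2>", embed_plot(figroc, 5, 4.5))
      plotdata$roc <- rocdf
    } else {
      body <- paste0(body, "<h2>ROC curve</h2><p>The learner exposes no ",
                     "continuous decision value; panel omitted.</p>")
    }
  }

  # PCA restricted to the model's features
  feats <- names(model$presence)[model$presence == 1L]
  if (length(feats) >= 2L) {
    pc <- stats::prcomp(dataset$X[, feats, drop = FALSE], scale. = FALSE)
    varfrac <- pc$sdev^2 / sum(pc$sdev^2)
    pcdf <- data.frame(PC1 = pc$x[, 1L], PC2 = pc$x[, 2L])
    if (task == "classification") pcdf$class <- dataset$y
    figpca <- ggplot2::ggplot(pcdf, ggplot2::aes(PC1, PC2)) +
      (if (task == "classification")
        ggplot2::geom_point(ggplot2::aes(colour = class), alpha = 0.7)
       else ggplot2::geom_point(alpha = 0.7, colour = "steelblue")) +
      ggplot2::labs(
        title = "PCA of the model's features",
        x = sprintf("PC1 (%.1f%%)", 100 * varfrac[1L]),
        y = sprintf("PC2 (%.1f%%)", 100 * varfrac[2L])) +
      ggplot2::theme_minimal()
    body <- paste0(body, "<h2>PCA of model features</h2>",
                   embed_plot(figpca, 6, 5))
    plotdata$pca <- pcdf
    # violin of the summarised features (first PC score) per class
    if (task == "classification") {
      vdf <- data.frame(class = dataset$y, PC1 = pc$x[, 1L])
      figv <- ggplot2::ggplot(vdf, ggplot2::aes(class, PC1, fill = class)) +
        ggplot2::geom_violin(alpha = 0.6) +
        ggplot2::labs(title = "First principal-component score by class",
                      y = "PC1 score (model features)") +
        ggplot2::theme_minimal() + ggplot2::theme(legend.position = "none")
      body <- paste0(body,
                     "<h2>Summarised features by class</h2>",
                     embed_plot(figv, 6, 4))
    }
  }

  if (!is.null(external)) {
    pred_ext <- stats::predict(model, external$X)
    ext_tb <- metric_table(external$y, pred_ext)
    body <- paste0(body, "<h2>Performance metrics (external data)</h2>",
                   html_table(ext_tb))
    plotdata$external_metrics <- ext_tb
  }

  writeLines(html_page("Model evaluation report", body), out_path)
  pd_path <- sub("\\.html?$", "_plotdata.json", out_path)
  if (pd_path == out_path) pd_path <- paste0(out_path, "_plotdata.json")
  jsonlite::write_json(plotdata, pd_path, digits = NA, na = "null")
  invisible(out_path)
}
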