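# The end-to-end pipeline: simulate (or load) inputs, build the training
# set, encode features, rank + select, train, and evaluate the meta-model
# next to every upstream tool's raw calls.

#' Pipeline configuration
#'
#' @param seed Integer seed; mandatory, drives every stochastic step.
#' @param mode Training-set design (`"trA"`, `"trB"`, `"trC"`, `"trR"`).
#' @param pn_ratio Positive/negative ratio enforced on the training set
#'   (1 = balanced, the recommended default).
#' @param k Cross-validation folds.
#' @param bins MI discretization bins.
#' @param svm SVM settings, see [svm_config()].
#' @param policy Missing-prediction policy for tool evaluation, see
#'   [evaluate_tool_panel()].
#' @param generator Synthetic study config ([generator_config()]); ignored
#'   when `paths` supplies real inputs.
#' @param paths Optional named list with `tool_table`, `interactions` and
#'   optionally `fasta` — file paths to real inputs replacing the
#'   generator.
#' @param trr_size trR sample size (trR mode only).
#' @param ifs Run mRMR + incremental feature selection (default TRUE).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(seed, mode = "trA", pn_ratio = 1, k = 10,
                            bins = 10, svm = svm_config(),
                            policy = "missing_as_negative",
                            generator = NULL, paths = NULL,
                            trr_size = NULL, ifs = TRUE) {
  if (missing(seed) || is.null(seed)) stop("config must specify a seed")
  if (is.null(generator) && is.null(paths))
    generator <- generator_config(seed = seed)
  structure(list(seed = as.integer(seed), mode = mode, pn_ratio = pn_ratio,
                 k = k, bins = bins, svm = svm, policy = policy,
                 generator = generator, paths = paths, trr_size = trr_size,
                 ifs = ifs),
            class = "pipeline_config")
}

.config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(config, auto_unbox = TRUE, force = TRUE,
                              digits = NA), tmp)
  unname(tools::md5sum(tmp))
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full meta-prediction pipeline
#'
#' Executes simulate/load, training-set construction, feature encoding,
#' mRMR + IFS feature selection, SVM training with cross-validation, and
#' side-by-side evaluation of every upstream tool's raw calls. Writes the
#' metric report, feature ranking, IFS curve, fold plan, training set and
#' the fitted model into `outdir`. Every TSV carries a comment header with
#' the config hash and seed; reruns with the same config are reproducible.
#'
#' @param config A [pipeline_config()].
#' @param outdir Output directory (created if needed).
#' @return Invisibly, a list with the training set, feature matrix,
#'   ranking, IFS result, CV result, per-method panels and the paths of
#'   all artifacts.
#' @export
run_pipeline <- function(config, outdir = tempfile("mirmeta_run_")) {
  if (!inherits(config, "pipeline_config"))
    stop("config must be built with pipeline_config()")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  hash <- .config_hash(config)
  hdr <- paste0("config=", hash, " seed=", config$seed)

  inputs <- .stage("inputs", {
    if (!is.null(config$paths)) {
      tool_table <- read_tool_table(config$paths$tool_table)
      interactions <- read_interactions(config$paths$interactions)
      seqs <- if (!is.null(config$paths$fasta))
        read_fasta(config$paths$fasta) else NULL
      list(interactions = interactions, tool_table = tool_table,
           sequences = list(targets = seqs))
    } else {
      simulate_study(config$generator)
    }
  })

  tset <- .stage("build_training_set", {
    ts <- build_training_set(inputs$interactions, mode = config$mode,
                             seed = config$seed, size = config$trr_size)
    pos <- ts$records[ts$records$label == "positive", , drop = FALSE]
    neg <- ts$records[ts$records$label == "negative", , drop = FALSE]
    bal <- enforce_pn_ratio(pos, neg, ratio = config$pn_ratio,
                            seed = config$seed)
    ts$records <- rbind(bal$pos, bal$neg)
    rownames(ts$records) <- NULL
    ts
  })

  registry <- default_registry()
  x <- .stage("encode", assemble_feature_matrix(
    inputs$tool_table, tset$records, inputs$sequences$targets, registry,
    aggregate = "most_stable"))
  y <- tset$records$label

  ranking <- .stage("rank_features",
                    mrmr_miq_rank(x, y, bins = config$bins))
  sel <- if (isTRUE(config$ifs)) {
    .stage("ifs", ifs_select(x, y, ranking, k = config$k,
                             seed = config$seed, config = config$svm))
  } else {
    list(curve = NULL, selected = ranking$feature,
         best_chl = NA_real_)
  }

  xsel <- x[, sel$selected, drop = FALSE]
  cv <- .stage("cross_validate",
               cross_validate(xsel, y, k = config$k, seed = config$seed,
                              config = config$svm))
  model <- .stage("train", train_meta_model(xsel, y, config = config$svm,
                                            seed = config$seed))

  panels <- .stage("evaluate_tools", {
    truth <- tset$records[, c("mirna_id", "target_id", "label")]
    p <- list(meta_svm = cv$panel)
    for (tool in supported_tools()) {
      calls <- tool_calls_from_table(inputs$tool_table, tool)
      calls <- calls[paste(calls$mirna_id, calls$target_id, sep = "|") %in%
                       paste(truth$mirna_id, truth$target_id, sep = "|"), ,
                     drop = FALSE]
      p[[tool]] <- evaluate_tool_panel(calls, truth, policy = config$policy)
    }
    p
  })

  paths <- .stage("write_artifacts", {
    rp <- file.path(outdir, "metric_report.tsv")
    write_metric_report(panels, rp, header = hdr)
    rk <- file.path(outdir, "feature_ranking.tsv")
    .write_tsv(ranking, rk, hdr)
    ts_path <- file.path(outdir, "training_set.tsv")
    write_interactions(tset$records, ts_path, header = hdr)
    fold_path <- file.path(outdir, "folds.tsv")
    .write_tsv(data.frame(record = rownames(xsel), fold = cv$folds),
               fold_path, hdr)
    ifs_path <- NULL
    if (!is.null(sel$curve)) {
      ifs_path <- file.path(outdir, "ifs_curve.tsv")
      .write_tsv(sel$curve, ifs_path, hdr)
    }
    model_path <- file.path(outdir, "model.rds")
    saveRDS(list(model = model, selected = sel$selected, config = config,
                 hash = hash), model_path)
    list(report = rp, ranking = rk, training_set = ts_path,
         folds = fold_path, ifs_curve = ifs_path, model = model_path)
  })

  invisible(list(training_set = tset, features = x, ranking = ranking,
                 ifs = sel, cv = cv, model = model, panels = panels,
                 paths = paths, hash = hash, outdir = outdir))
}

.write_tsv <- function(df, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
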