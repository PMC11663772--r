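# Plain-text I/O (CSV feature tables, CSV clinical table, YAML/JSON config)
# and the end-to-end experiment driver reproducing the study workflow on
# synthetic or user-supplied tables.

#' Write / read a feature set as CSV
#'
#' Subjects as rows; first column `subject_id`, remaining columns the
#' element labels.
#'
#' @param fs a `feature_set` (or matrix with rownames and colnames).
#' @param path CSV file path.
#' @return `read_feature_set` returns a `feature_set`.
#' @export
write_feature_set <- function(fs, path) {
  df <- data.frame(subject_id = rownames(fs), as.data.frame(unclass(fs)),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_set
#' @param name feature-set name; default: file name without extension.
#' @export
read_feature_set <- function(path, name = NULL) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"subject_id" %in% names(df))
    stop("schema error: missing column 'subject_id' in ", path)
  m <- as.matrix(df[, setdiff(names(df), "subject_id"), drop = FALSE])
  if (!is.numeric(m)) stop("schema error: non-numeric feature values in ", path)
  rownames(m) <- df$subject_id
  feature_set(m, name %||% sub("\\.[^.]+$", "", basename(path)))
}

#' Read and validate a clinical table
#'
#' Required columns: `subject_id`, `group`, `hdrs_baseline`,
#' `hdrs_followup`. A missing column raises a schema error naming it.
#'
#' @param path CSV path.
#' @return Data frame.
#' @export
read_clinical <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("subject_id", "group", "hdrs_baseline", "hdrs_followup")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("schema error: missing clinical column(s): ",
         paste(missing, collapse = ", "))
  check_hdrs(df$hdrs_baseline); check_hdrs(df$hdrs_followup)
  if (anyDuplicated(df$subject_id)) stop("schema error: duplicate subject ids")
  df
}

#' Run the full classification experiment
#'
#' Executes the study workflow on a directory of feature-set CSVs plus a
#' clinical table (or on in-memory objects): per-set uni-modal nested-LOOCV
#' classification, the three fusion strategies (concatenation, forced
#' fusion, majority-vote ensembles), optional permutation test and
#' bootstrap CI on the best models, the FDR group screen, and the feature
#' contribution analysis. Reports are written as JSON/CSV under `out_dir`
#' with the configuration and seed echoed.
#'
#' @param sets named list of feature matrices, or a directory of CSVs.
#' @param clinical clinical data frame or CSV path.
#' @param task `"diagnosis"` (group labels) or `"outcome"` (PO/NO from
#'   HDRS; subjects without follow-up are dropped).
#' @param method ranking method, `"mrmr"` or `"cvsvm"`.
#' @param k_initial,k_final double-ranking sizes (reference operating
#'   point: 10 and 5).
#' @param n_set_grid ensemble sizes to evaluate.
#' @param n_perm permutations for the best uni-modal model (0 = skip).
#' @param n_boot bootstrap resamples for the best uni-modal model (0 =
#'   skip).
#' @param seed master seed, recorded in every report.
#' @param out_dir output directory (created); `NULL` returns results only.
#' @param positive positive class (default: `"MDD"`-style second group
#'   level for diagnosis, `"PO"` for outcome).
#' @return (Invisibly) list with `unimodal` (per-set `cv_result`),
#'   `perf_table`, `concat`, `forced`, `ensembles`, `screen`,
#'   `contributions`, `permutation`, `bootstrap`, `config`.
#' @export
run_experiment <- function(sets, clinical, task = c("diagnosis", "outcome"),
                           method = "mrmr", k_initial = 10, k_final = 5,
                           n_set_grid = c(3, 5), n_perm = 0, n_boot = 0,
                           seed = 1L, out_dir = NULL, positive = NULL) {
  task <- match.arg(task)
  if (is.character(sets) && length(sets) == 1L) {
    paths <- list.files(sets, pattern = "\\.csv$", full.names = TRUE)
    sets <- stats::setNames(lapply(paths, read_feature_set),
                            sub("\\.csv$", "", basename(paths)))
  }
  if (is.character(clinical)) clinical <- read_clinical(clinical)

  if (task == "diagnosis") {
    y <- factor(clinical$group)
    if (is.null(positive)) positive <- levels(y)[nlevels(y)]
    keep <- rep(TRUE, nrow(clinical))
  } else {
    keep <- !is.na(clinical$hdrs_followup) & clinical$hdrs_baseline > 0
    y <- label_outcome(clinical$hdrs_baseline[keep],
                       clinical$hdrs_followup[keep])
    if (is.null(positive)) positive <- "PO"
  }
  sets <- lapply(sets, function(s) {
    m <- as.matrix(s)[match(clinical$subject_id[keep], rownames(s)), ,
                      drop = FALSE]
    if (anyNA(m)) stop("schema error: subjects missing from a feature set")
    m
  })
  y <- droplevels(y)

  unimodal <- lapply(sets, function(X)
    run_nested_loocv(X, y, method = method, k_initial = k_initial,
                     k_final = k_final, positive = positive))
  perf_table <- do.call(rbind, lapply(names(unimodal), function(nm) {
    r <- unimodal[[nm]]$report
    data.frame(set = nm, auc = r$auc, accuracy = r$accuracy,
               sensitivity = r$sensitivity, specificity = r$specificity,
               precision = r$precision, f1 = r$f1,
               mean_k_optimal = mean(vapply(unimodal[[nm]]$folds, `[[`,
                                            numeric(1), "k_optimal")),
               stringsAsFactors = FALSE)
  }))

  concat <- run_nested_loocv(concatenate_sets(sets), y, method = method,
                             k_initial = k_initial, k_final = k_final,
                             positive = positive)
  forced <- run_forced_fusion(sets, y, method = method, positive = positive)
  n_set_grid <- n_set_grid[n_set_grid <= length(sets)]
  ensembles <- if (length(n_set_grid))
    do.call(rbind, lapply(n_set_grid, function(k)
      evaluate_ensembles(unimodal, k)))
  else data.frame()

  screen <- group_difference_screen(sets, y, positive = positive)
  contributions <- lapply(unimodal, outer_fold_contribution)

  best <- names(unimodal)[which.max(perf_table$auc)]
  permutation <- NULL; bootstrap <- NULL
  if (n_perm > 0) {
    runner <- function(X, yy) run_nested_loocv(
      X, yy, method = method, k_initial = k_initial, k_final = k_final,
      positive = positive)$report$auc
    permutation <- permutation_test(runner, sets[[best]], y, n_perm = n_perm,
                                    seed = child_seed(seed, "permtest"))
  }
  if (n_boot > 0)
    bootstrap <- bootstrap_auc_ci(unimodal[[best]]$decision, y, positive,
                                  n_boot = n_boot,
                                  seed = child_seed(seed, "bootstrap"))

  config <- list(task = task, method = method, k_initial = k_initial,
                 k_final = k_final, n_set_grid = n_set_grid,
                 n_perm = n_perm, n_boot = n_boot, seed = seed,
                 positive = positive, best_unimodal = best)
  res <- list(unimodal = unimodal, perf_table = perf_table, concat = concat,
              forced = forced, ensembles = ensembles, screen = screen,
              contributions = contributions, permutation = permutation,
              bootstrap = bootstrap, config = config)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(perf_table, file.path(out_dir, "unimodal_performance.csv"),
                     row.names = FALSE)
    if (nrow(ensembles))
      utils::write.csv(ensembles,
                       file.path(out_dir, "ensemble_performance.csv"),
                       row.names = FALSE)
    utils::write.csv(screen, file.path(out_dir, "group_screen.csv"),
                     row.names = FALSE)
    report <- list(
      config = config,
      unimodal = perf_table,
      concatenation = unclass(concat$report),
      forced_fusion = unclass(forced$report),
      best_ensemble = if (nrow(ensembles)) ensembles[1L, ] else NULL,
      permutation = if (!is.null(permutation))
        list(true_auc = permutation$true_auc, p = permutation$p,
             n_perm = permutation$n_perm),
      bootstrap = if (!is.null(bootstrap))
        list(auc = bootstrap$auc, ci = bootstrap$ci, n_boot = bootstrap$n_boot)
    )
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(res)
}

#' Read an experiment configuration from YAML
#'
#' @param path YAML file with fields matching [run_experiment()] arguments.
#' @return Named list.
#' @export
read_experiment_config <- function(path) yaml::read_yaml(path)
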