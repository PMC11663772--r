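#!/usr/bin/env Rscript
# Step 5: inferential layer.
#
# For the best uni-modal diagnosis model: a pipeline-preserving permutation
# test (label shuffles with the entire nested double-ranking pipeline
# re-run; 200 permutations here, the reference protocol uses 1000) and a
# 1000-resample bootstrap percentile CI for the AUC. Also runs the
# FDR-corrected mass-univariate group screen over all feature sets.

suppressMessages(library(mddfusion))
data_dir <- "results/data"
seed <- 20260927L
clinical <- read_clinical(file.path(data_dir, "clinical.csv"))
paths <- list.files(data_dir, pattern = "\\.csv$", full.names = TRUE)
paths <- paths[basename(paths) != "clinical.csv"]
sets <- stats::setNames(lapply(paths, read_feature_set),
                        sub("\\.csv$", "", basename(paths)))
y <- factor(clinical$group)
unimodal <- readRDS("scratch/unimodal_diagnosis.rds")
aucs <- vapply(unimodal, function(cv) cv$report$auc, numeric(1))
best <- names(which.max(aucs))
cat(sprintf("Best uni-modal model: %s (AUC %.3f)\n", best, max(aucs)))

t0 <- Sys.time()
runner <- function(X, yy) run_nested_loocv(X, yy, method = "mrmr",
                                           k_initial = 10, k_final = 5,
                                           positive = "MDD")$report$auc
pt <- permutation_test(runner, as.matrix(sets[[best]]), y, n_perm = 200,
                       seed = child_seed(seed, "permtest"))
bt <- bootstrap_auc_ci(unimodal[[best]]$decision, y, "MDD", n_boot = 1000,
                       seed = child_seed(seed, "bootstrap"))
ptxt <- if (pt$p == 0) sprintf("< %g", 1 / pt$n_perm) else sprintf("%.3f", pt$p)
cat(sprintf("  permutation p %s (%d perms); bootstrap 95%% CI [%.3f, %.3f] (%.1f min)\n",
            ptxt, pt$n_perm, bt$ci[1], bt$ci[2],
            as.numeric(Sys.time() - t0, units = "mins")))

screen <- group_difference_screen(sets, y, positive = "MDD")
write.csv(screen, "results/group_screen.csv", row.names = FALSE)
sig <- screen[screen$significant, ]
cat(sprintf("  FDR screen: %d of %d elements significant at q <= 0.05 (%s)\n",
            nrow(sig), nrow(screen),
            paste(unique(sig$set), collapse = ", ")))
jsonlite::write_json(
  list(best_model = best, auc = max(aucs), permutation_p = pt$p,
       n_perm = pt$n_perm, bootstrap_ci = bt$ci, n_boot = bt$n_boot,
       seed = seed),
  "results/inference_diagnosis.json", auto_unbox = TRUE, digits = NA)
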