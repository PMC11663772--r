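#!/usr/bin/env Rscript
# Step 4: multi-modal fusion.
#
# Compares the three fusion strategies on the diagnosis task: (1)
# concatenation of all feature sets into one vector, (2) forced fusion
# pooling each set's univariate top-5 before the final ranking, and (3)
# majority-vote ensembles over the stored uni-modal predictions for all
# combinations with n_set in {3, 5}. Writes the ranked ensemble table.

suppressMessages(library(mddfusion))
data_dir <- "results/data"
clinical <- read_clinical(file.path(data_dir, "clinical.csv"))
paths <- list.files(data_dir, pattern = "\\.csv$", full.names = TRUE)
paths <- paths[basename(paths) != "clinical.csv"]
sets <- stats::setNames(lapply(paths, read_feature_set),
                        sub("\\.csv$", "", basename(paths)))
y <- factor(clinical$group)
positive <- "MDD"
unimodal <- readRDS("scratch/unimodal_diagnosis.rds")

t0 <- Sys.time()
concat <- run_nested_loocv(concatenate_sets(sets), y, method = "mrmr",
                           k_initial = 10, k_final = 5, positive = positive)
forced <- run_forced_fusion(sets, y, method = "mrmr", positive = positive)
ens <- rbind(evaluate_ensembles(unimodal, 3), evaluate_ensembles(unimodal, 5))
write.csv(ens, "results/fusion_ensembles.csv", row.names = FALSE)

best_uni <- max(vapply(unimodal, function(cv) cv$report$auc, numeric(1)))
cat(sprintf("Fusion (diagnosis, %.1f min):\n",
            as.numeric(Sys.time() - t0, units = "mins")))
cat(sprintf("  best uni-modal AUC        %.3f\n", best_uni))
cat(sprintf("  concatenation AUC         %.3f\n", concat$report$auc))
cat(sprintf("  forced fusion AUC         %.3f\n", forced$report$auc))
cat(sprintf("  best ensemble (n=3|5) AUC %.3f  [%s]\n",
            ens$auc[1], ens$members[1]))
cat(sprintf("  %d of %d ensembles beat the best uni-modal model\n",
            sum(ens$auc > best_uni), nrow(ens)))
saveRDS(list(concat = concat, forced = forced), "scratch/fusion.rds")
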