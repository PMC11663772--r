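#!/usr/bin/env Rscript
# Step 1: simulate the study cohorts.
#
# Builds a synthetic diagnosis cohort (31 controls + 32 patients, mirroring
# the clinical group sizes) with scaled-down tabular feature sets, plants
# modest group effects in a subset of sets, generates HDRS trajectories
# whose 6-month outcome labels split the patients ~12 PO / 19 NO, and
# writes everything as CSV under results/data/. Set dimensionalities are
# reduced from the full study sizes (e.g. 60 instead of 3486 DTI edges) so
# the whole workflow runs in minutes; they are configuration, not contract.

suppressMessages(library(mddfusion))
seed <- 20260927L
out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

dims <- c(T1 = 40L, T2 = 30L, MD = 60L, FA = 60L, Act = 22L)
informative <- list(
  MD = lapply(1:4, function(i) list(index = i, d = 0.9, sign = 1)),
  FA = lapply(1:4, function(i) list(index = i, d = 0.8, sign = -1)),
  T1 = lapply(1:3, function(i) list(index = i, d = 0.7, sign = -1))
)
spec <- synthetic_spec(31, 32, set_dims = dims, informative = informative,
                       rho = 0.1, group_labels = c("HC", "MDD"),
                       seed = seed)
sets <- generate_feature_tables(spec)
clinical <- make_clinical_table(spec, rep(c("PO", "NO"), c(13, 19)))

# outcome-linked structural effect: NO patients carry higher FA on three
# edges (so the outcome task also has a recoverable signal)
no_idx <- which(clinical$group == "MDD" & clinical$outcome == "NO")
sets$FA[no_idx, 10:12] <- sets$FA[no_idx, 10:12] + 1.1

for (nm in names(sets))
  write_feature_set(sets[[nm]], file.path(out, paste0(nm, ".csv")))
write.csv(clinical, file.path(out, "clinical.csv"), row.names = FALSE)

mdd <- clinical$group == "MDD"
lab <- label_outcome(clinical$hdrs_baseline[mdd], clinical$hdrs_followup[mdd])
cat(sprintf(
  "Simulated %d subjects (%d HC / %d MDD); HDRS baseline (MDD) %.1f +/- %.1f;\n",
  nrow(clinical), sum(!mdd), sum(mdd),
  mean(clinical$hdrs_baseline[mdd]), sd(clinical$hdrs_baseline[mdd])))
cat(sprintf("outcome split: %d PO / %d NO. Wrote %d feature sets to %s\n",
            sum(lab == "PO"), sum(lab == "NO"), length(sets), out))
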