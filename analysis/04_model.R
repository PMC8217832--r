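#!/usr/bin/env Rscript
# Stage 4: full modeling pass — stratified 70/30 split, per-map Pearson
# filter + 10-fold LASSO + forward stepwise logistic regression, Youden
# threshold on the training ROC, frozen-threshold evaluation on the test
# set. Writes the per-map model specs (JSON) and a Table-6-style
# performance summary.

suppressPackageStartupMessages(library(kinetexture))

out_dir <- "results"
cfg <- run_config(seed = 42)
res <- run_pipeline(48, 54, config = cfg)

for (m in kinetic_map_names()) {
  write_model_spec(res$models[[m]]$model,
                   file.path(out_dir, "models", paste0(m, ".json")))
  md <- res$models[[m]]$model
  terms <- if (length(md$coefficients) == 0) "(intercept only)" else
    paste(sprintf("%+.3f*%s", md$coefficients, names(md$coefficients)),
          collapse = " ")
  message(sprintf("%-9s Y = %.3f %s%s", m, md$intercept, terms,
                  if (length(md$flags)) paste0("  [", paste(md$flags, collapse = ","), "]")
                  else ""))
}

write.csv(res$summary, file.path(out_dir, "model_performance.csv"),
          row.names = FALSE)
message("\nperformance summary (AUC / sensitivity / specificity / accuracy):")
print(res$summary, digits = 3)

best <- res$summary[res$summary$split == "training", ]
best <- best$map[which.max(best$auc)]
message(sprintf("\nbest training-set map: %s (test AUC %.3f)",
                best, res$summary$auc[res$summary$map == best &
                                      res$summary$split == "test"]))
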