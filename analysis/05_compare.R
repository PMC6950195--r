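#!/usr/bin/env Rscript

# Stage 5: the five-model comparison tables.
#
# Global models are compared on the mixed-mode panel and local models on
# the varying-mode panel (each against its own OLS benchmark), reporting
# AICc, adjusted/conditional R2, RMSE, MAE, residual Z-score moments and
# percentage RMSE/MAE reduction relative to OLS.

suppressPackageStartupMessages(library(stwreg))

global_fits <- readRDS("scratch/fits_global.rds")
local_fits <- readRDS("scratch/fits_local.rds")
ds_mixed <- load_panel("results/panel_mixed.csv")
ds_vary <- load_panel("results/panel_varying.csv")

tab_global <- compare_models(global_fits, ds_mixed)
ols_vary <- fit_ols(ds_vary)
tab_local <- compare_models(c(list(ols = ols_vary), local_fits), ds_vary)

write_results(tab_global, "results/comparison_global.json")
write_results(tab_local, "results/comparison_local.json")
utils::write.csv(tab_global, "results/comparison_global.csv",
                 row.names = FALSE)
utils::write.csv(tab_local, "results/comparison_local.csv",
                 row.names = FALSE)

message("global models (mixed-mode panel):")
print(tab_global, digits = 3)
message("local models vs OLS (varying-mode panel):")
print(tab_local, digits = 3)
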