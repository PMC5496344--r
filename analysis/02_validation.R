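#!/usr/bin/env Rscript
# Growth validation: (a) arithmetic over the published qualitative battery
# and growth-rate table; (b) the synthetic 32-condition battery run end to
# end; (c) a quantitative prediction from fixed uptake rates.

suppressMessages(library(phycoflux))
dir.create("results", showWarnings = FALSE)

## published tables ----------------------------------------------------------
batt_tab <- read.delim(system.file("extdata",
                                   "published_growth_battery.tsv",
                                   package = "phycoflux"))
agree <- batt_tab$in_vivo == batt_tab$in_silico
cs <- confusion_summary(TP = sum(batt_tab$in_vivo == "+" & agree),
                        TN = sum(batt_tab$in_vivo == "-" & agree),
                        FP = sum(batt_tab$in_vivo == "-" & !agree),
                        FN = sum(batt_tab$in_vivo == "+" & !agree))
cat("published battery:", cs$TP + cs$TN, "of", cs$n, "calls agree;",
    "simple accuracy", round(cs$accuracy_simple, 3), "\n")
cs_text <- confusion_summary(24, 5, 3, 0)
cat("from the published text counts (24/5/3/0): simple",
    round(cs_text$accuracy_simple, 3), "geometric",
    round(cs_text$accuracy_geometric, 3), "\n")

rate_tab <- read.delim(system.file("extdata", "published_growth_rates.tsv",
                                   package = "phycoflux"))
rec <- error_report(rate_tab$mu_experimental, rate_tab$mu_predicted)
cat("published growth rates: mean of printed errors",
    round(mean(rate_tab$error_pct), 2), "% | recomputed from rates",
    round(attr(rec, "mean_error_pct"), 2), "%\n")
write.table(cbind(rate_tab, recomputed_error_pct = rec$relative_error_pct),
            "results/quantitative_published.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)

## synthetic battery end to end ----------------------------------------------
tm <- make_toy_model()
batt <- make_condition_battery(tm$model, tm$truth)
write_battery(batt, "results/toy_battery.tsv")
res <- run_battery(tm$model, read_battery("results/toy_battery.tsv"))
write.table(res$calls, "results/toy_battery_calls.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
cat("\nsynthetic battery: reference mu", round(res$mu_reference, 4),
    "h^-1; confusion", res$summary$TP, "TP /", res$summary$TN, "TN /",
    res$summary$FP, "FP /", res$summary$FN, "FN; accuracy",
    round(res$summary$accuracy_simple, 3), "\n")

## quantitative prediction from fixed uptakes --------------------------------
# emulate a measured-uptake experiment: CO2 uptake from biofixation data,
# nitrate-limited growth
co2 <- co2_specific_uptake(C = 0.5, P = 0.24, X = 2)
cat("\nCO2 biofixation", round(co2$biofixation, 4),
    "g/L/d -> specific uptake", round(co2$specific_uptake, 4),
    "mmol/gDW/h\n")
ups <- c(EX_no3 = 2.5, EX_co2 = co2$specific_uptake, EX_photon = 30,
         EX_dsa = 2, EX_ac = 4, EX_o2 = 10)
mu_pred <- predict_growth_rate(tm$model, ups,
                               keep_open = c("EX_h2o", "EX_h"))
cat("predicted mu under measured uptakes:", round(mu_pred, 4), "h^-1\n")
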