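#!/usr/bin/env Rscript
# Descriptive summaries of the imaging cohort's demographics.

suppressPackageStartupMessages(library(pavasc))

out_dir <- "results"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

demo <- cohort_demographics()
vars <- list(age_years = "age (years)", bmi = "BMI (kg/m2)",
             sessions = "grafting sessions",
             interval_months = "interval surgery-to-imaging (months)")
rows <- lapply(names(vars), function(v) {
  s <- summarize_values(demo[[v]], "median_range", vars[[v]])
  cat(sprintf("%-38s median %.4g (range %.4g-%.4g)\n",
              vars[[v]], s$center, s$min, s$max))
  data.frame(variable = vars[[v]], median = s$center, min = s$min,
             max = s$max, n = s$n)
})
summary <- do.call(rbind, rows)
write.csv(summary, file.path(out_dir, "cohort_summary.csv"), row.names = FALSE)
cat("\nwrote", file.path(out_dir, "cohort_summary.csv"), "\n")
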