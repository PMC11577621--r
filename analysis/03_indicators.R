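#!/usr/bin/env Rscript
# Step 3 -- compute the nine performance indicators.
#
# For every included episode: acute and total episode length (days, floor
# 1, truncated at death), day-90 placement (home vs institutionalized,
# point-in-time occupancy among survivors), inpatient days within one year
# (interval union, capped at 365), 90-day and 1-year mortality, and per-diem
# costs of the episode and of the first year. Writes indicators.csv.

suppressPackageStartupMessages({
  library(strokebench)
  library(data.table)
})

data_dir <- "results/data"
reg <- read_register(data_dir)
cfg <- readRDS(file.path(data_dir, "scenario.rds"))
episodes <- fread("results/episodes.csv")
episodes[, index_date := as.Date(index_date)]
episodes[, acute_end_date := as.Date(acute_end_date)]
episodes[, episode_end_date := as.Date(episode_end_date)]
stays <- fread("results/stays_chained.csv")
stays[, admit_date := as.Date(admit_date)]
stays[, discharge_date := as.Date(discharge_date)]

ct <- synthetic_cost_table(cfg)
ind <- compute_indicators(episodes, stays, reg$patients, ct)
fwrite(ind, "results/indicators.csv")

cat("indicator rows:", nrow(ind), "(one per included episode)\n\n")
cat("pre-reform (2001-2005) means by region:\n")
pre <- ind[cohort_year %in% 2001:2005,
           .(acute_los = mean(acute_los), episode_los = mean(episode_los),
             home_90 = mean(home_90), inst_90 = mean(institutionalized_90),
             days_1y = mean(inpatient_days_1y), died_90 = mean(died_90),
             died_1y = mean(died_1y), episode_cost = mean(episode_cost),
             cost_1y = mean(cost_1y)), by = region]
print(pre, digits = 3)
cat("\npost-reform (2007-2012) means by region:\n")
post <- ind[cohort_year %in% 2007:2012,
            .(acute_los = mean(acute_los), episode_los = mean(episode_los),
              home_90 = mean(home_90), inst_90 = mean(institutionalized_90),
              died_1y = mean(died_1y), episode_cost = mean(episode_cost)),
            by = region]
print(post, digits = 3)
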