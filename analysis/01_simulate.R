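#!/usr/bin/env Rscript
# Step 1 -- simulate the study register.
#
# Generates a synthetic discharge register over cohort years 2001-2019 with
# the two staged rehabilitation interventions: the city-level reform
# effective 2006 (shorter episodes, fewer patients institutionalized at day
# 90, more discharged home) and the region-level reform effective 2013.
# The configured effects are the ground truth the later steps try to
# recover. Writes patients.csv, stays.csv and ground_truth.txt under
# results/data/.

suppressPackageStartupMessages({
  library(strokebench)
  library(data.table)
})

out_dir <- "results/data"
cfg <- scenario_config(
  n_patients_per_year = 800L,
  years = c(2001L, 2019L),
  region_shares = c(treated_city = 0.10, rest_treated_region = 0.12,
                    rest_country = 0.78),
  interventions = list(
    city_reform = list(
      regions = "treated_city", year = 2006L,
      effects = c(episode_mean = -4.0, p_inst90 = -0.051)),
    regional_reform = list(
      regions = c("treated_city", "rest_treated_region"), year = 2013L,
      effects = c(acute_mean = -1.5, episode_mean = -1.8))),
  seed = 20010101L)

reg <- generate_register(cfg)
write_register(reg, out_dir)
saveRDS(cfg, file.path(out_dir, "scenario.rds"))

cat("simulated register:", nrow(reg$patients), "patients,",
    nrow(reg$stays), "stays over", paste(cfg$years, collapse = "-"), "\n")
cat("regions:\n")
print(reg$patients[, .N, by = region])
cat("ground-truth intervention effects:\n")
print(reg$truth)
cat("written to", out_dir, "\n")
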