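#!/usr/bin/env Rscript

# Builds the synthetic study world: four decades of irregular training
# cruises over the embayment (5755 pH and 3850 alkalinity labels in the
# upper 50 m) and complete weekly predictor series 1995-2020 at 6 stations
# x 3 depth bins. Writes both tables and the planted truth under results/.

suppressPackageStartupMessages(library(riacarb))

dir.create("results/data", recursive = TRUE, showWarnings = FALSE)

spec <- world_spec(seed = 1)
world <- generate_world(spec)

write_hydro_table(world$training, "results/data/training.csv")
write_hydro_table(world$prediction, "results/data/prediction.csv")
utils::write.csv(world$truth$trend_table, "results/data/planted_trends.csv",
                 row.names = FALSE)

message(sprintf("training cruises: %d records (%d pH, %d TA labels), %d-%d",
                nrow(world$training), sum(!is.na(world$training$ph)),
                sum(!is.na(world$training$ta_umol_kg)),
                floor(min(world$training$year_decimal)),
                floor(max(world$training$year_decimal))))
message(sprintf("weekly station series: %d rows (%d strata x %d weeks)",
                nrow(world$prediction),
                length(unique(paste(world$prediction$station_id,
                                    world$prediction$depth_m))),
                length(weekly_dates(spec$years))))
message(sprintf("planted pH trends span %.4f to %.4f pH/yr; planted TA trend %.2f umol/kg/yr; planted alpha %.1f",
                min(world$truth$trend_table$ph_trend),
                max(world$truth$trend_table$ph_trend),
                spec$ta_trend_per_year, spec$ta_salinity_slope))
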