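#!/usr/bin/env Rscript

# Surface-layer time-series figures from the reconstruction of
# 02_reconstruct.R: weekly pH, [H+] and TA at each station with the fitted
# trend line, one PNG per variable, written under results/figures/.

suppressPackageStartupMessages(library(riacarb))

pred_path <- "results/reconstruction/predicted_series.csv"
if (!file.exists(pred_path)) stop("run analysis/02_reconstruct.R first")
pred <- utils::read.csv(pred_path, stringsAsFactors = FALSE)
surface <- pred[pred$depth_m == min(pred$depth_m), ]
stations <- sort(unique(surface$station_id))
dir.create("results/figures", recursive = TRUE, showWarnings = FALSE)

cols <- c(ph = "ph", h = "h_nmol_kg", ta = "ta_umol_kg")
for (v in names(cols)) {
  path <- file.path("results/figures", paste0(v, "_surface.png"))
  grDevices::png(path, width = 1400, height = 1600, res = 140)
  graphics::par(mfrow = c(length(stations), 1), mar = c(2.5, 4, 2, 1))
  for (st in stations) {
    sub <- surface[surface$station_id == st, ]
    sub <- sub[order(sub$year_decimal), ]
    s <- hydro_series(sub$year_decimal, sub[[cols[[v]]]],
                      stratum = sprintf("%s 0-5 m", st), variable = v)
    plot_series_trend(s)
  }
  grDevices::dev.off()
  message("wrote ", path)
}
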