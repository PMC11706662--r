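#!/usr/bin/env Rscript
# Stage 2: preprocess raw fixes.
#
# Reads the cohort fix table, clips each track to the 13 April - 1 July
# breeding season, projects to polar Lambert azimuthal equal-area
# coordinates (central meridian 45 E) and applies the 150 km/h
# iterative speed filter. Reports how much each step removed.

suppressMessages(library(nomadtrack))

tracks <- read_track_csv("results/sim/fixes.csv")
out <- "results"

clean <- list()
stats <- NULL
for (id in names(tracks)) {
  tr <- tracks[[id]]
  n0 <- nrow(tr)
  tr <- clip_season(tr, season_window())
  n1 <- nrow(tr)
  tr <- project_track(tr)
  flt <- speed_filter(tr, 150)
  clean[[id]] <- flt$track
  stats <- rbind(stats, data.frame(id = id, n_raw = n0,
                                   n_clipped = n0 - n1,
                                   n_speed_removed = length(flt$removed),
                                   n_clean = nrow(flt$track)))
}

all_clean <- do.call(rbind, clean)
write_track_csv(all_clean, file.path(out, "clean.csv"))
utils::write.csv(stats, file.path(out, "preprocess_stats.csv"),
                 row.names = FALSE)

cat(sprintf("kept %d / %d fixes (%.1f%% removed by the speed filter)\n",
            sum(stats$n_clean), sum(stats$n_raw),
            100 * sum(stats$n_speed_removed) / sum(stats$n_raw)))
cat("wrote results/clean.csv and results/preprocess_stats.csv\n")
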