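#!/usr/bin/env Rscript
# Raw accelerometry -> per-beep physical activity: ENMO in 5-second epochs,
# std/range nonwear scoring in sliding 60-minute windows, then the mean
# ENMO over the hour before each of the subject's beeps (missing when the
# window is nonwear or has insufficient coverage).
#
# Inputs:  results/data/ (from 01_simulate_study.R)
# Outputs: results/actigraphy/beep_activity.csv

library(emanet)

data_dir <- "results/data"
out <- "results/actigraphy"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

ema <- read_ema_csv(file.path(data_dir, "ema.csv"))
accel_files <- list.files(data_dir, pattern = "^accel_.*\\.csv$",
                          full.names = TRUE)
clock_origin <- 7 * 3600  # recordings start 07:00; beeps are clock seconds

rows <- list()
for (f in accel_files) {
  id <- sub("^accel_(.*)\\.csv$", "\\1", basename(f))
  sig <- read_accel_csv(f)
  enmo <- compute_enmo(sig, epoch_length = 5)
  nw <- score_nonwear(sig)
  message(sprintf("%s: %d windows scored, %d flagged nonwear (score > 1)",
                  id, nrow(nw), sum(nw$score > 1)))
  # day-1 beeps of this subject on the recording clock
  beeps <- ema[ema$subject_id == id & ema$day == 1, "timestamp"]
  secs <- as.numeric(beeps) - as.numeric(trunc(beeps[1], "days")) - clock_origin
  act <- summarize_prebeep(enmo, nw, beeps = sort(secs))
  act$subject_id <- id
  act$timestamp <- sort(beeps)
  rows[[id]] <- act
  message(sprintf("  %d beeps summarized, %d missing (nonwear/coverage)",
                  nrow(act), sum(is.na(act$mean_enmo))))
}
activity <- do.call(rbind, rows)
write_activity_csv(activity, file.path(out, "beep_activity.csv"))
message("wrote ", file.path(out, "beep_activity.csv"))
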