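#!/usr/bin/env Rscript

# Pivots the long feature table into the regression design: one row per
# (pose, session, averaging group), 19 time-of-flight columns then 19
# amplitude columns, plus the gaze labels.

suppressPackageStartupMessages(library(echogaze))

feats <- read.csv("results/features_long.csv")
fm <- build_feature_matrix(feats)

cat(sprintf("Feature matrix: %d rows x %d columns (%d poses x %d samples each)\n",
            nrow(fm$X), ncol(fm$X),
            nrow(unique(fm$meta[, c("theta_deg", "phi_deg")])),
            nrow(fm$X) / nrow(unique(fm$meta[, c("theta_deg", "phi_deg")]))))

wide <- cbind(fm$meta, as.data.frame(fm$X))
write_csv_with_sidecar(wide, "results/feature_matrix.csv",
                       meta = list(columns_tof = 19, columns_amp = 19))

# per-transmitter summaries at the central pose (profile shapes)
prof <- aggregate(cbind(tof_us, amp) ~ tx_deg, feats, mean)
write_csv_with_sidecar(prof, "results/feature_profiles.csv", meta = list())
cat(sprintf("Mean amplitude peaks at transmitter %+d deg (occlusion asymmetry);\n",
            prof$tx_deg[which.max(prof$amp)]))
cat("wrote results/feature_matrix.csv and results/feature_profiles.csv.\n")
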