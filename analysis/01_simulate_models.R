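#!/usr/bin/env Rscript
# Model comparison at 1g: symmetry-ratio tuning curves of the four
# optimal-control models across the 17 movement directions, the sigmoid
# fit of the Smooth-Effort curve, and its correlation with the work of
# gravity torque. Writes results/model_sr_curves.csv and
# results/model_summary.json.

suppressMessages({
  library(optparse)
  library(armplan)
  library(dplyr)
})
opts <- parse_args(OptionParser(option_list = list(
  make_option("--out", type = "character", default = "results"))))
dir.create(opts$out, recursive = TRUE, showWarnings = FALSE)

params <- anthropometrics_from_body(70, 0.70)
dirs <- direction_set(17)

message("Solving the four models over 17 directions ...")
curves <- bind_rows(lapply(
  c("smooth_effort", "jerk", "torque_change", "variance",
    "variance_muscle"),
  function(m) predict_sr_curve(params, cost_spec(m), dirs)))
write.csv(curves, file.path(opts$out, "model_sr_curves.csv"),
          row.names = FALSE)

se <- curves[curves$model == "smooth_effort", ]
fit <- fit_sigmoid(se$gamma, se$sr)
summary <- list(
  sr_wgt_correlation = correlate(se$sr, se$wgt),
  smooth_effort_sr_range = range(se$sr),
  sigmoid = list(p1 = fit$p1, p2 = fit$p2, p3 = fit$p3, p4 = fit$p4,
                 rmse = fit$rmse),
  flat_model_spread = sapply(
    c("jerk", "torque_change", "variance", "variance_muscle"),
    function(m) diff(range(curves$sr[curves$model == m])))
)
jsonlite::write_json(summary, file.path(opts$out, "model_summary.json"),
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)

message(sprintf(
  "Smooth-Effort SR spans [%.3f, %.3f] across directions (r with WGT = %.3f);",
  min(se$sr), max(se$sr), summary$sr_wgt_correlation))
message(sprintf(
  "the other models stay flat (max spread %.4f). Sigmoid fit RMSE %.2g.",
  max(unlist(summary$flat_model_spread)), fit$rmse))
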