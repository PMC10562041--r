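#!/usr/bin/env Rscript
# Sweep adaptive-trigger action levels for the two example parameters (the
# SCH-REF change in PTV D95% for the prostate + seminal vesicles group, and
# in rectum V40Gy for the fossa-boost group): proportion of treatments
# adapted and counterfactual percentile bands per trigger value. Writes
# sweep JSON/CSV and figures under results/.

suppressPackageStartupMessages({
  library(arttrigger)
  library(dplyr)
  library(ggplot2)
})

if (!file.exists("results/differences.csv")) {
  stop("run analysis/03_differences.R first", call. = FALSE)
}
d <- readr::read_csv("results/differences.csv", show_col_types = FALSE)
dir.create("results/figures", showWarnings = FALSE, recursive = TRUE)

for (i in seq_len(nrow(default_sweep_requests()))) {
  req <- default_sweep_requests()[i, ]
  dd <- filter(d, site == req$site, metric_id == req$metric_id)
  sw <- sweep_trigger(dd, contrast = req$contrast)
  key <- paste(req$site, req$metric_id, req$contrast, sep = "_")
  write_sweep_json(sw, file.path("results", paste0("sweep_", key, ".json")))
  readr::write_csv(tidy_sweep(sw), file.path("results", paste0("sweep_", key, ".csv")))

  unit <- attr(sw, "unit")
  xlab <- sprintf("%s trigger value for %s (%s)", req$contrast, req$metric_id,
                  if (unit == "Gy") "Gy" else "%")
  p_prop <- ggplot(sw, aes(value, proportion_adapted)) +
    geom_step(direction = "hv") + geom_point(size = 0.8) +
    labs(x = xlab, y = "Proportion of treatments adapted") +
    theme_minimal()
  ggsave(file.path("results/figures", paste0(key, "_proportion.png")),
         p_prop, width = 5, height = 3.4, dpi = 150)

  bands <- tidy_sweep(sw)
  ribbon <- function(lo, hi, fill) {
    geom_ribbon(
      data = tidyr::pivot_wider(bands, names_from = level, values_from = band,
                                names_prefix = "p"),
      aes(value, ymin = .data[[lo]], ymax = .data[[hi]]),
      inherit.aes = FALSE, fill = fill
    )
  }
  p_band <- ggplot() +
    ribbon("p5", "p95", "grey85") + ribbon("p10", "p90", "grey70") +
    ribbon("p25", "p75", "grey50") +
    geom_line(data = sw, aes(value, p50), linewidth = 0.7) +
    labs(x = xlab,
         y = sprintf("Counterfactual change in %s vs reference (%s)",
                     req$metric_id, if (unit == "Gy") "Gy" else "%")) +
    theme_minimal()
  ggsave(file.path("results/figures", paste0(key, "_bands.png")),
         p_band, width = 5, height = 3.4, dpi = 150)

  cat("\n== ", key, " ==\n", sep = "")
  show <- if (unit == "Gy") c(-1, -0.5, -0.25) else c(10, 5, 2)
  idx <- match(show, sw$value)
  ok <- !is.na(idx)
  cat("proportion adapted at", paste(show[ok], collapse = " / "), ":",
      paste(round(sw$proportion_adapted[idx[ok]], 3), collapse = " / "), "\n")
  cat("10th-percentile counterfactual at those values:",
      paste(round(sw$p10[idx[ok]], 3), collapse = " / "), "\n")
  cat("adaptation ceiling:", round(max(sw$proportion_adapted), 3),
      "(preference condition keeps it below 1)\n")
}
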