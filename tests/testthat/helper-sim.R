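# Desk-scale simulation settings: same statistical structure as the stated
# instrument conditions (AGC-controlled Poisson counts, drift, 10 microscans)
# but shorter blocks and a reduced ion load so that property-style tests over
# many seeds stay fast. Tests that check absolute precision figures use the
# full-scale settings explicitly.

desk_run_cfg <- function(...) {
  run_config(block_duration_min = 6, switch_discard_min = 1, ...)
}

desk_sim_cfg <- function(...) {
  sim_config(agc_target = 1e5, scan_period_s = 4, ...)
}

# A tiny deterministic scan table (two scans x two isotopologues) written to
# a tempfile; returns the path.
write_tiny_scan_table <- function(path = tempfile(fileext = ".tsv"),
                                  sep = "\t", extra_row = NULL,
                                  drop_col = NULL) {
  header <- c("scan", "time", "isotopolog", "intensity", "peakNoise",
              "resolution", "microscans")
  rows <- list(
    c("1", "0.5", "F92", "1000", "10", "90000", "10"),
    c("1", "0.5", "F92 15N", "4", "10", "90000", "10"),
    c("2", "0.6", "F92", "1100", "10", "90000", "10")
  )
  if (!is.null(extra_row)) rows <- c(rows, list(extra_row))
  if (!is.null(drop_col)) {
    keep <- header != drop_col
    header <- header[keep]
    rows <- lapply(rows, function(r) r[keep])
  }
  lines <- c(paste(header, collapse = sep),
             vapply(rows, paste, character(1), collapse = sep))
  writeLines(lines, path)
  path
}
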