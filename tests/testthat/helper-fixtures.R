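# Shared fixtures built in code.

# noiseless washout series: excess(t) = a0 * exp(-k t) above `baseline`
make_washout <- function(k, a0, times, baseline = 10, isotope = "2H") {
  data.frame(
    isotope = isotope,
    time_days = c(0, times),
    enrichment = c(baseline, baseline + a0 * exp(-k * times)),
    is_baseline = c(TRUE, rep(FALSE, length(times)))
  )
}

# derived cohort table + model frame for the packaged 34-row fixture
fixture_derived <- function(config = dlw_config()) {
  inp <- cohort_inputs()
  process_cohort(inp$participants, inp$isotopes, config)
}

# minute-epoch stream from per-minute axis counts
make_minute_stream <- function(axis1, axis2 = 0, axis3 = 0, steps = 0,
                               start = as.POSIXct("2022-06-20", tz = "UTC")) {
  n <- length(axis1)
  data.frame(
    timestamp = start + seq(0, by = 60, length.out = n),
    axis1 = axis1,
    axis2 = rep_len(axis2, n),
    axis3 = rep_len(axis3, n),
    steps = rep_len(steps, n)
  )
}
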