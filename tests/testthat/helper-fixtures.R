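# Small in-code fixtures shared across test files.

# A three-sample panel exercising all three concentration statuses.
tiny_panel <- function() {
  conc <- tibble::tribble(
    ~sample_id, ~element, ~status,       ~value, ~limit,
    "A1",       "Be",     "quantified",  5.6,    NA,
    "A1",       "Cd",     "quantified",  58.1,   NA,
    "A1",       "Li",     "below_limit", NA,     17.4,
    "A1",       "Al",     "above_range", NA,     NA,
    "A2",       "Be",     "below_limit", NA,     0.9,
    "A2",       "Cd",     "quantified",  40.0,   NA,
    "A2",       "Li",     "quantified",  30.3,   NA,
    "A2",       "Al",     "quantified",  1500,   NA,
    "A3",       "Be",     "quantified",  0.0,    NA,
    "A3",       "Cd",     "below_limit", NA,     0.61,
    "A3",       "Li",     "below_limit", NA,     17.4,
    "A3",       "Al",     "above_range", NA,     NA
  )
  meta <- tibble::tibble(
    sample_id = c("A1", "A2", "A3"),
    protein_type = c("whey", "pea", "whey"),
    serving_mass_g = c(60, 30, 25),
    weighed_mass_g = c(0.45, 0.49, 0.51)
  )
  load_panel(conc, meta)
}

write_panel_csv <- function(lines) {
  path <- withr::local_tempfile(fileext = ".csv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}
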