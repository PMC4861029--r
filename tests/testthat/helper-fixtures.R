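## Shared fixture builders. Everything is generated in code; sizes are kept
## small so the full suite stays fast.

## one full-sib cross between two founders
cross_config <- function(n = 50, founders = c("A", "B"), label = "F") {
  list(founders = founders,
       families = data.frame(label = label, parent1 = founders[1],
                             parent2 = founders[2], n_offspring = n,
                             stringsAsFactors = FALSE))
}

## scaled-down interconnected five-family pedigree
small_study_config <- function(scale = c(XB = 12, SG = 20, HIVW = 30,
                                         N = 8, P = 10)) {
  study_pedigree_config(scale)
}

## constant-temperature series helper
const_series <- function(temp, hours, start = "2012-01-01 00:00:00",
                         site = "S") {
  t0 <- as.POSIXct(start, tz = "UTC")
  temperature_series(site, t0 + 3600 * (seq_len(hours) - 1L),
                     rep(temp, hours))
}

## winter-to-spring season: cold block (chill) followed by warm block (heat)
season_series <- function(cold_hours = 1200, warm_hours = 3000,
                          cold_temp = 5, warm_temp = 15,
                          start = "2011-11-01 00:00:00", site = "S") {
  t0 <- as.POSIXct(start, tz = "UTC")
  n <- cold_hours + warm_hours
  temperature_series(site, t0 + 3600 * (seq_len(n) - 1L),
                     c(rep(cold_temp, cold_hours),
                       rep(warm_temp, warm_hours)))
}
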