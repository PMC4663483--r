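#' Reference sample aggregates: extant mortality events and fossil assemblages
#'
#' Built-in (SD, CV, n) coordinates of the ten extant ungulate samples from
#' documented mass-mortality events and the eleven fossil samples from five
#' Palaeolithic localities used to test the classifier. These are sample-level
#' aggregates: `n` specimens per sample, the standard deviation `sd` and the
#' coefficient of variation `cv` of scratch density (scratches per 0.16 mm^2)
#' across specimens. `duration_label` is the documented duration of the
#' mortality event for extant samples (`"nd"` where unknown) and `NA` for
#' fossil samples, whose duration is what the classifier estimates.
#'
#' @param source Which table to return: `"all"` (default), `"extant"` or
#'   `"fossil"`.
#' @return A tibble with columns `sample_id`, `species`, `locality`,
#'   `duration_label`, `n`, `sd`, `cv`, `source`.
#' @examples
#' reference_samples("extant")
#' reference_samples("fossil")
#' @export
reference_samples <- function(source = c("all", "extant", "fossil")) {
  source <- match.arg(source)
  extant <- tibble::tribble(
    ~sample_id, ~species, ~locality, ~duration_label, ~n, ~sd, ~cv,
    "1", "Rangifer tarandus", "Qamanirjuaq population (Canada)", "years", 473L, 4.555, 0.359,
    "2a", "Cervus elaphus", "Mount Saint Helens (Washington, USA)", "1 day", 63L, 1.054, 0.089,
    "2b", "Cervus elaphus", "Pierce and Lewis Counties (Washington, USA)", "years", 13L, 2.800, 0.159,
    "3a", "Antilocapra americana", "Green River (Wyoming, USA)", "1 day", 89L, 0.823, 0.094,
    "3b", "Antilocapra americana", "Lamont and Rawlins Counties (Wyoming, USA)", "years", 71L, 3.152, 0.314,
    "4", "Odocoileus hemionus", "Cache La Poudre River (Colorado, USA)", "years", 49L, 4.706, 0.261,
    "5", "Cervus elaphus", "Isle of Rum (Scotland, UK)", "season", 174L, 1.843, 0.155,
    "6", "Cervus nippon", "Kinkazan Island (Japan)", "season", 69L, 2.242, 0.122,
    "7", "Lama guanicoe", "Cardiel lake (Patagonia, Argentina)", "season", 91L, 2.246, 0.176,
    "8", "Equus quagga", "West of Mount Rumuruti (Kenya)", "nd", 28L, 3.952, 0.137
  )
  fossil <- tibble::tribble(
    ~sample_id, ~species, ~locality, ~n, ~sd, ~cv,
    "A1", "Rangifer tarandus", "Portel-Ouest, level F", 30L, 3.097, 0.122,
    "A2", "Equus ferus", "Portel-Ouest, level F", 27L, 3.910, 0.178,
    "A3", "Cervus elaphus", "Portel-Ouest, level F", 21L, 2.764, 0.147,
    "A4", "Bos/Bison", "Portel-Ouest, level F", 25L, 2.459, 0.107,
    "B1", "Cervus elaphus", "Abric Romani, level K", 14L, 6.970, 0.350,
    "B2", "Cervus elaphus", "Abric Romani, level M", 19L, 2.629, 0.092,
    "C1", "Rangifer tarandus", "Salzgitter Lebenstedt", 81L, 1.827, 0.170,
    "D1", "Bison priscus", "Taubach", 22L, 4.134, 0.242,
    "E1", "Equus ferus", "Caune de l'Arago, level G", 38L, 5.705, 0.174,
    "E2", "Cervus elaphus", "Caune de l'Arago, level J", 27L, 6.795, 0.329,
    "E3", "Rangifer tarandus", "Caune de l'Arago, level L", 30L, 3.121, 0.142
  )
  fossil$duration_label <- NA_character_
  fossil <- fossil[, names(extant)]
  extant$source <- "extant"
  fossil$source <- "fossil"
  out <- dplyr::bind_rows(extant, fossil)
  switch(source,
    all = out,
    extant = out[out$source == "extant", ],
    fossil = out[out$source == "fossil", ]
  )
}
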