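# Programmatic fixtures shared across test files.

# One full synthetic final (8 athletes, ranks 1..8) for a single edition.
make_final <- function(seed = 11L, medalist_loading = 0.85,
                       non_medalist_loading = 0.45, edition = "Sydney") {
  params <- default_edition_params(medalist_loading, non_medalist_loading)
  keep <- Filter(function(p) p$edition_label == edition, params)
  cfg <- synthetic_config(editions = keep, seed = seed)
  suppressWarnings(synthesize_cohorts(cfg))
}

# A deterministic 8-athlete data frame with hand-set values (no RNG).
make_manual_final <- function(edition = "Test") {
  n <- 8L
  height <- c(194, 196, 193, 195, 197, 192, 196, 194)
  weight <- c(86, 88, 85, 90, 92, 84, 87, 89)
  data.frame(
    edition = edition, rank = 1:8,
    age = c(22, 24, 23, 26, 27, 25, 28, 26),
    weight = weight, height = height,
    bmi = weight / (height / 100)^2,
    olympic_medals = c(7, 4, 2, 1, 0, 2, 1, 0),
    reaction_time = c(0.70, 0.72, 0.74, 0.76, 0.80, 0.78, 0.82, 0.75),
    race_time = c(21.4, 21.5, 21.6, 21.8, 21.9, 22.0, 22.1, 21.7),
    stringsAsFactors = FALSE
  )
}

# Uniform complete network on p nodes with common weight w, as a matrix.
uniform_complete <- function(p, w = 1) {
  m <- matrix(w, p, p)
  diag(m) <- 0
  dimnames(m) <- list(paste0("V", 1:p), paste0("V", 1:p))
  m
}
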