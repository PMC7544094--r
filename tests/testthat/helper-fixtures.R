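# Shared helpers: fixture paths and small in-code builders.

fixturePath <- function(...) {
  system.file("extdata", ..., package = "teloburden", mustWork = TRUE)
}

makeAssoc <- function(disease = "d1", or = 2, lo = or * 0.8, hi = or * 1.25,
                      direction = "per_sd_longer", source = "test",
                      significant = TRUE) {
  data.frame(disease_name = disease, or_per_sd = or, ci_lower = lo,
             ci_upper = hi, direction = direction, source = source,
             significant = significant, stringsAsFactors = FALSE)
}

makeBurden <- function(cause = "d1", measure = "incidence", value = 100,
                       lo = value * 0.9, hi = value * 1.1) {
  data.frame(cause_name = cause, measure = measure, value = value,
             ci_lower = lo, ci_upper = hi, population = "test",
             year = 2017L, stringsAsFactors = FALSE)
}

# random valid association table for round-trip / property tests
randomAssocTable <- function(n, seed) {
  set.seed(seed)
  or <- exp(rnorm(n, 0.4, 0.5))
  half <- runif(n, 0.05, 0.5)
  makeAssocTable <- data.frame(
    disease_name = sprintf("disease_%02d", seq_len(n)),
    or_per_sd = or, ci_lower = or * (1 - half), ci_upper = or * (1 + half),
    direction = sample(c("per_sd_longer", "per_sd_shorter"), n, TRUE),
    source = "synthetic", significant = sample(c(TRUE, FALSE), n, TRUE),
    stringsAsFactors = FALSE)
  makeAssocTable
}

# independent union-find oracle for LD clustering (kept deliberately naive)
unionFindClusters <- function(r2, cutoff) {
  n <- nrow(r2)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j && !is.na(r2[i, j]) && r2[i, j] >= cutoff) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[ri] <- rj
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}
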