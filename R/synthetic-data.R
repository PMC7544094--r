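# Seeded generators for complete synthetic studies: OR tables, burden
# tables, case-fraction tables and block-structured LD matrices with known
# ground truth. Because the attribution statistic is deterministic
# arithmetic, the generator can state the exact excess values its tables
# imply; pipeline runs must recover them with no estimation error.
#
# One integer seed drives one named pseudo-random stream per artifact table
# (sub-seeds derived from the base seed), so adding a table does not perturb
# the others.

#' @importFrom stats rlnorm rgamma runif setNames
NULL

.withStream <- function(seed, stream, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed",
                                          envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv())
  })
  # distinct sub-seed per named stream, kept inside 32-bit integer range
  set.seed((as.integer(seed) %% 1000003L) * 131L + stream)
  force(expr)
}

#' Simulate a complete attribution study with known truth
#'
#' Draws per-SD odds ratios with a log-normal excess (OR - 1), so long-gTL
#' diseases are risk-increasing per SD longer and short-gTL per SD shorter
#' by construction; age-standardized rates come from a gamma model with
#' symmetric relative CI half-widths. Defaults mirror a
#' study of 9 cancers and 5 degenerative diseases with ORs spanning roughly
#' 1.2-5 and rates spanning a few to a few hundred per 100,000. The returned
#' \code{truth} holds the exact per-disease and total excess values implied
#' by the generated tables.
#'
#' @param n_diseases_long,n_diseases_short disease counts per direction
#'   group.
#' @param or_log_mean,or_log_sd median and log-scale SD of the log-normal
#'   draw for the odds-ratio excess OR - 1.
#' @param incidence_shape,incidence_scale gamma parameters for incidence
#'   rates per 100,000; DALY rates use the same shape with scale
#'   \code{10 * incidence_scale}.
#' @param ci_halfwidth_frac relative half-width of the symmetric CIs placed
#'   on ORs and rates (0 gives degenerate point CIs).
#' @param fraction_partitions optional named list mapping a broad cause name
#'   to narrow fractions summing to <= 1; emits a case-fraction table.
#' @param seed integer seed; the same seed reproduces the tables bit for
#'   bit.
#' @return list with \code{or_table}, \code{burden_table},
#'   \code{fraction_table} (possibly empty) and \code{truth} (list with
#'   \code{rows} and \code{totals} excess data.frames).
#' @export
simulateStudy <- function(n_diseases_long = 9L, n_diseases_short = 5L,
                          or_log_mean = 0.6, or_log_sd = 0.5,
                          incidence_shape = 0.8, incidence_scale = 25,
                          ci_halfwidth_frac = 0.3,
                          fraction_partitions = NULL, seed = 1L) {
  stopifnot(n_diseases_long >= 0, n_diseases_short >= 0,
            or_log_sd >= 0, incidence_shape > 0, incidence_scale > 0,
            ci_halfwidth_frac >= 0)
  n <- n_diseases_long + n_diseases_short
  disease <- sprintf("disease_%02d", seq_len(n))
  direction <- rep(c("per_sd_longer", "per_sd_shorter"),
                   c(n_diseases_long, n_diseases_short))

  # OR - 1 is log-normal, so every disease is risk-increasing in its
  # declared direction by construction
  or <- 1 + .withStream(seed, 1L, rlnorm(n, log(or_log_mean), or_log_sd))
  or_lo <- pmax(or * (1 - ci_halfwidth_frac), 1e-6)
  or_hi <- or * (1 + ci_halfwidth_frac)
  or_table <- data.frame(
    disease_name = disease, or_per_sd = or, ci_lower = or_lo,
    ci_upper = or_hi, direction = direction, source = "synthetic",
    significant = TRUE, stringsAsFactors = FALSE)

  rates <- .withStream(seed, 2L, list(
    incidence = rgamma(n, shape = incidence_shape, scale = incidence_scale),
    daly = rgamma(n, shape = incidence_shape, scale = 10 * incidence_scale)))
  burden_table <- do.call(rbind, lapply(.MEASURES, function(meas) {
    v <- rates[[meas]]
    data.frame(cause_name = disease, measure = meas, value = v,
               ci_lower = v * (1 - ci_halfwidth_frac),
               ci_upper = v * (1 + ci_halfwidth_frac),
               population = "synthetic", year = 2017L,
               stringsAsFactors = FALSE)
  }))

  fraction_table <- data.frame(
    narrow_name = character(), broad_name = character(),
    narrow_count = numeric(), broad_count = numeric(),
    fraction = numeric(), source = character(), stringsAsFactors = FALSE)
  if (!is.null(fraction_partitions)) {
    totals_bc <- .withStream(seed, 3L,
      sample(1000:100000, length(fraction_partitions), replace = TRUE))
    fraction_table <- do.call(rbind, lapply(
      seq_along(fraction_partitions), function(b) {
        broad <- names(fraction_partitions)[b]
        f <- fraction_partitions[[b]]
        if (sum(f) > 1 + 1e-12)
          stop("fractions for ", broad, " sum to more than 1", call. = FALSE)
        do.call(rbind, lapply(seq_along(f), function(j) caseFraction(
          sprintf("%s narrow_%d", broad, j), broad,
          narrow_count = round(totals_bc[b] * f[j]),
          broad_count = totals_bc[b], source = "synthetic")))
      }))
  }

  rows <- do.call(rbind, lapply(seq_len(n), function(i) do.call(rbind,
    lapply(.MEASURES, function(meas) {
      v <- rates[[meas]][i]
      .excessRow(disease[i], meas, direction[i],
                 (or[i] - 1) * v, (or_lo[i] - 1) * v, (or_hi[i] - 1) * v,
                 disease[i])
    }))))
  grp <- unique(rows[, c("measure", "direction")])
  totals <- do.call(rbind, lapply(seq_len(nrow(grp)), function(g) {
    sel <- rows$measure == grp$measure[g] & rows$direction == grp$direction[g]
    totalExcess(rows[sel, , drop = FALSE],
                cause_name = sprintf("total %s (%s)", grp$measure[g],
                                     grp$direction[g]))
  }))

  list(or_table = or_table, burden_table = burden_table,
       fraction_table = fraction_table,
       truth = list(rows = rows, totals = totals))
}

#' Simulate a block-structured LD matrix with planted clusters
#'
#' Builds one symmetric R-squared matrix containing contiguous blocks whose
#' within-block values are drawn from \code{within_r2_range} and whose
#' between-block (and singleton) values are drawn from
#' \code{between_r2_range}. With the default unambiguous ranges (within
#' entirely at or above the cutoff, between entirely below), both clustering
#' rules recover the planted partition exactly.
#'
#' @param block_sizes integer vector of planted cluster sizes.
#' @param n_singletons number of additional unclustered SNPs.
#' @param within_r2_range,between_r2_range length-2 numeric ranges.
#' @param unambiguous require the ranges to straddle \code{cutoff} (error
#'   otherwise).
#' @param cutoff the threshold the planted structure must respect.
#' @param chromosome label for the synthetic chromosome.
#' @param seed integer seed.
#' @return list with \code{matrix} (an [LDMatrix-class]) and \code{labels}
#'   (integer vector of planted cluster ids per SNP; singletons get their
#'   own ids).
#' @export
simulateLd <- function(block_sizes = c(4L, 3L, 2L), n_singletons = 2L,
                       within_r2_range = c(0.6, 0.95),
                       between_r2_range = c(0, 0.3),
                       unambiguous = TRUE, cutoff = 0.5,
                       chromosome = "sim", seed = 1L) {
  stopifnot(all(block_sizes > 0), n_singletons >= 0)
  if (unambiguous) {
    if (min(within_r2_range) < cutoff)
      stop("within-block range must lie entirely at or above the cutoff",
           call. = FALSE)
    if (max(between_r2_range) >= cutoff)
      stop("between-block range must lie entirely below the cutoff",
           call. = FALSE)
  }
  labels <- c(rep(seq_along(block_sizes), block_sizes),
              seq_len(n_singletons) + length(block_sizes))
  n <- length(labels)
  rsids <- sprintf("rs_sim_%03d", seq_len(n))
  r2 <- .withStream(seed, 4L, {
    m <- matrix(0, n, n)
    for (i in seq_len(n)) for (j in seq_len(i - 1L)) {
      rng <- if (labels[i] == labels[j]) within_r2_range else
        between_r2_range
      m[i, j] <- m[j, i] <- runif(1, rng[1], rng[2])
    }
    diag(m) <- 1
    m
  })
  dimnames(r2) <- list(rsids, rsids)
  list(matrix = LDMatrix(r2, rsids, chromosome = chromosome),
       labels = setNames(labels, rsids))
}
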