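# Effect-direction harmonization for per-SD odds ratios.
#
# Convention throughout: an association is expressed "per SD longer gTL" or
# "per SD shorter gTL". Inverting an OR (1/OR, with reciprocal-and-swap CI
# bounds) flips the direction; no re-estimation on the log scale is done, so
# printed bounds such as 11.11 (6.67-20.00) <-> 0.09 (0.05-0.15) reproduce
# exactly.

.appendProvenance <- function(df, note) {
  if (!"provenance" %in% names(df)) df$provenance <- rep("", nrow(df))
  df$provenance <- ifelse(df$provenance == "", note,
                          paste(df$provenance, note, sep = "; "))
  df
}

#' Invert odds ratios onto the opposite effect direction
#'
#' Computes OR' = 1/OR with CI' = (1/upper, 1/lower) and flips the declared
#' direction. Involution: inverting twice recovers the input to machine
#' precision.
#'
#' @param assoc association data.frame (one or more rows; see [readOrTable()]).
#' @return the data.frame with inverted ORs, swapped bounds, flipped
#'   direction and a provenance note.
#' @examples
#' a <- data.frame(disease_name = "CHD", or_per_sd = 0.78, ci_lower = 0.67,
#'   ci_upper = 0.90, direction = "per_sd_longer", source = "meta",
#'   significant = TRUE)
#' invertOr(a)$or_per_sd  # 1.28 per SD shorter (2 dp)
#' @export
invertOr <- function(assoc) {
  assoc <- .validateAssociations(assoc)
  if (any(assoc$or_per_sd <= 0))
    stop("cannot invert a non-positive odds ratio", call. = FALSE)
  lo <- assoc$ci_lower; hi <- assoc$ci_upper
  assoc$or_per_sd <- 1 / assoc$or_per_sd
  assoc$ci_lower <- 1 / hi
  assoc$ci_upper <- 1 / lo
  assoc$direction <- ifelse(assoc$direction == "per_sd_longer",
                            "per_sd_shorter", "per_sd_longer")
  .appendProvenance(assoc, "inverted")
}

#' Harmonize a set of associations onto one effect direction
#'
#' Rows whose direction differs from \code{target} are inverted with
#' [invertOr()]; rows already on \code{target} pass through unchanged.
#' Harmonized ORs below 1 (protective in the target direction) are flagged
#' with a warning, not dropped: the analysis convention is that each disease
#' group is harmonized to its risk-increasing direction.
#'
#' @param assocs association data.frame.
#' @param target \code{"per_sd_longer"} or \code{"per_sd_shorter"}.
#' @return the harmonized data.frame with columns \code{harmonized_to} and
#'   \code{protective} added. Idempotent: applying twice equals once.
#' @export
normalizeDirection <- function(assocs, target = c("per_sd_longer",
                                                  "per_sd_shorter")) {
  target <- match.arg(target)
  assocs <- .validateAssociations(assocs)
  if (any(is.na(assocs$direction)))
    stop("missing direction metadata", call. = FALSE)
  if (!"provenance" %in% names(assocs)) assocs$provenance <- rep("", nrow(assocs))
  flip <- assocs$direction != target
  if (any(flip)) assocs[flip, ] <- invertOr(assocs[flip, ])
  assocs$harmonized_to <- target
  assocs$protective <- assocs$or_per_sd < 1
  if (any(assocs$protective))
    warning(sum(assocs$protective),
            " association(s) protective in the target direction (OR < 1)",
            call. = FALSE)
  assocs
}

#' Harmonize each association onto its risk-increasing direction
#'
#' Rows with OR < 1 are inverted so every disease is expressed in the
#' direction of gTL that increases its odds (cancers per SD longer,
#' degenerative diseases per SD shorter, in the source studies).
#'
#' @param assocs association data.frame.
#' @return data.frame with every \code{or_per_sd >= 1}.
#' @export
harmonizeRiskIncreasing <- function(assocs) {
  assocs <- .validateAssociations(assocs)
  if (!"provenance" %in% names(assocs)) assocs$provenance <- rep("", nrow(assocs))
  flip <- assocs$or_per_sd < 1
  if (any(flip)) assocs[flip, ] <- invertOr(assocs[flip, ])
  assocs
}

#' Drop non-significant associations (visible pipeline step)
#'
#' Implements the inclusion rule that only statistically significant odds
#' ratios enter the attribution; the count removed is reported via
#' \code{message()}.
#'
#' @param assocs association data.frame with a logical \code{significant}
#'   column.
#' @return the significant subset.
#' @export
dropNonsignificant <- function(assocs) {
  assocs <- .validateAssociations(assocs)
  drop <- !assocs$significant
  if (any(drop))
    message("dropping ", sum(drop), " of ", nrow(assocs),
            " association(s) without statistical significance: ",
            paste(assocs$disease_name[drop], collapse = ", "))
  assocs[!drop, , drop = FALSE]
}

#' Collapse several narrow-definition ORs into one burden-category OR
#'
#' Weighted mean on the OR scale (default) with the same weights applied to
#' each CI bound; used when a registry burden category spans several narrow
#' disease definitions whose ORs are weighted by relative incidence or
#' prevalence. Weights are normalized internally, so the result is invariant
#' to rescaling all weights by a constant. A geometric (log-scale) variant is
#' available via \code{scale = "geometric"}.
#'
#' @param assocs association data.frame, all rows sharing one direction.
#' @param weights positive weights, one per row (relative incidence or
#'   prevalence).
#' @param scale \code{"arithmetic"} (default) or \code{"geometric"}.
#' @param collapse_ci collapse CI bounds with the same weights (default
#'   \code{TRUE}); if \code{FALSE} the collapsed CI is set missing.
#' @param name label for the collapsed record.
#' @return a one-row association data.frame with provenance recording the
#'   member diseases and normalized weights.
#' @export
collapseOrs <- function(assocs, weights, scale = c("arithmetic", "geometric"),
                        collapse_ci = TRUE, name = NULL) {
  scale <- match.arg(scale)
  assocs <- .validateAssociations(assocs)
  if (length(unique(assocs$direction)) != 1L)
    stop("cannot collapse ORs with mixed directions", call. = FALSE)
  if (length(weights) != nrow(assocs))
    stop("need one weight per association", call. = FALSE)
  if (any(weights < 0) || sum(weights) <= 0)
    stop("weights must be non-negative with positive total", call. = FALSE)
  w <- weights / sum(weights)
  agg <- if (scale == "arithmetic") {
    function(x) sum(w * x)
  } else {
    function(x) exp(sum(w * log(x)))
  }
  if (is.null(name))
    name <- paste(assocs$disease_name, collapse = " + ")
  out <- data.frame(
    disease_name = name,
    or_per_sd = agg(assocs$or_per_sd),
    ci_lower = if (collapse_ci) agg(assocs$ci_lower) else NA_real_,
    ci_upper = if (collapse_ci) agg(assocs$ci_upper) else NA_real_,
    direction = assocs$direction[1],
    source = paste(unique(assocs$source), collapse = " + "),
    significant = all(assocs$significant),
    stringsAsFactors = FALSE)
  .appendProvenance(out, paste0(
    "collapsed[", scale, "]: ",
    paste(sprintf("%s (w=%.4g)", assocs$disease_name, w), collapse = ", ")))
}
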