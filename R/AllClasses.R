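#' @import methods
NULL

.DIRECTIONS <- c("per_sd_longer", "per_sd_shorter")
.MEASURES <- c("incidence", "daly")

#' LDMatrix: pairwise linkage disequilibrium for one chromosome
#'
#' A square, symmetric matrix of R-squared values between SNPs on a single
#' chromosome, as produced by LD lookup services. Entries may be \code{NA}
#' when LD could not be determined for a variant (an unmeasurable
#' correlation); the diagonal is 1 for measured variants and \code{NA} for
#' unmeasured ones.
#'
#' @slot chromosome single character chromosome label.
#' @slot rsids character vector of SNP identifiers, in matrix order.
#' @slot r2 numeric matrix of squared correlations in [0, 1] (or \code{NA}),
#'   with \code{dimnames} equal to \code{rsids}.
#'
#' @seealso [readLdMatrix()], [buildLdGraph()], [clusterVariants()]
#' @export
setClass("LDMatrix",
  slots = c(chromosome = "character", rsids = "character", r2 = "matrix")
)

setValidity("LDMatrix", function(object) {
  msg <- character()
  r2 <- object@r2
  n <- length(object@rsids)
  if (length(object@chromosome) != 1L || is.na(object@chromosome))
    msg <- c(msg, "'chromosome' must be a single non-NA label")
  if (anyDuplicated(object@rsids))
    msg <- c(msg, "duplicate rsids")
  if (!is.numeric(r2) || nrow(r2) != n || ncol(r2) != n)
    msg <- c(msg, sprintf("'r2' must be a %d x %d numeric matrix", n, n))
  else {
    if (!identical(rownames(r2), object@rsids) ||
        !identical(colnames(r2), object@rsids))
      msg <- c(msg, "dimnames of 'r2' must equal 'rsids'")
    vals <- r2[!is.na(r2)]
    if (any(vals < 0 | vals > 1))
      msg <- c(msg, "R-squared values must lie in [0, 1]")
    # symmetry: NA pattern and values must both match
    if (!isTRUE(all.equal(r2, t(r2), tolerance = 1e-12, check.attributes = FALSE)) &&
        !identical(is.na(r2), is.na(t(r2))))
      msg <- c(msg, "'r2' must be symmetric (within 1e-12)")
    else {
      d <- r2 - t(r2)
      if (any(abs(d[!is.na(d)]) > 1e-12))
        msg <- c(msg, "'r2' must be symmetric (within 1e-12)")
      if (!identical(is.na(r2), is.na(t(r2))))
        msg <- c(msg, "NA pattern of 'r2' must be symmetric")
    }
    dg <- diag(r2)
    if (any(!is.na(dg) & abs(dg - 1) > 1e-12))
      msg <- c(msg, "diagonal must be 1 for measured variants")
  }
  if (length(msg)) msg else TRUE
})

#' Construct an LDMatrix
#'
#' @param r2 square numeric matrix of R-squared values. A triangular input
#'   (one triangle all \code{NA} while its mirror cell is measured) is
#'   mirrored to a full symmetric matrix.
#' @param rsids SNP identifiers (defaults to \code{rownames(r2)}).
#' @param chromosome chromosome label.
#' @return an [LDMatrix-class] object.
#' @examples
#' m <- rbind(c(1, 0.95), c(0.95, 1))
#' LDMatrix(m, rsids = c("rs1", "rs2"), chromosome = "2")
#' @export
LDMatrix <- function(r2, rsids = rownames(r2), chromosome = "NA") {
  r2 <- as.matrix(r2)
  if (is.null(rsids)) stop("rsids must be supplied when 'r2' has no rownames")
  rsids <- as.character(rsids)
  storage.mode(r2) <- "double"
  r2 <- .mirrorTriangular(r2)
  dimnames(r2) <- list(rsids, rsids)
  new("LDMatrix", chromosome = as.character(chromosome),
      rsids = rsids, r2 = r2)
}

# Fill one triangle from the other where exactly one of the pair is measured.
.mirrorTriangular <- function(r2) {
  tr <- t(r2)
  fill <- is.na(r2) & !is.na(tr)
  r2[fill] <- tr[fill]
  r2
}

setMethod("show", "LDMatrix", function(object) {
  cat(sprintf("LDMatrix: chromosome %s, %d SNPs\n",
              object@chromosome, length(object@rsids)))
  off <- object@r2[upper.tri(object@r2)]
  cat(sprintf("  off-diagonal R^2: %d measured, %d missing; max %s\n",
              sum(!is.na(off)), sum(is.na(off)),
              if (all(is.na(off))) "NA" else format(max(off, na.rm = TRUE))))
  invisible(NULL)
})

#' AttributionReport: the result of a burden-attribution run
#'
#' Holds, for one study's inputs, the disease/measure pairs that entered the
#' excess calculation, those excluded with machine-readable reasons, the
#' per-disease excess rows and the per-measure, per-direction totals.
#'
#' @slot included data.frame of (disease, cause, measure, or) pairs used.
#' @slot excluded data.frame with columns disease, measure, reason.
#' @slot rows data.frame of per-disease excess estimates (see [excessBurden()]).
#' @slot totals data.frame of totals, one row per measure x direction.
#'
#' @seealso [attributeBurden()], [runPipeline()]
#' @export
setClass("AttributionReport",
  slots = c(included = "data.frame", excluded = "data.frame",
            rows = "data.frame", totals = "data.frame")
)

setValidity("AttributionReport", function(object) {
  msg <- character()
  need <- c("cause_name", "measure", "direction", "value",
            "ci_lower", "ci_upper", "components")
  if (!all(need %in% names(object@rows)))
    msg <- c(msg, "'rows' lacks excess-burden columns")
  if (!all(need %in% names(object@totals)))
    msg <- c(msg, "'totals' lacks excess-burden columns")
  if (!all(c("disease", "measure", "reason") %in% names(object@excluded)))
    msg <- c(msg, "'excluded' must have disease/measure/reason columns")
  if (length(msg)) msg else TRUE
})

setMethod("show", "AttributionReport", function(object) {
  cat(sprintf("AttributionReport: %d excess rows, %d exclusions\n",
              nrow(object@rows), nrow(object@excluded)))
  if (nrow(object@totals)) {
    cat("Totals (per 100,000 persons per SD of gTL):\n")
    t <- object@totals
    for (i in seq_len(nrow(t)))
      cat(sprintf("  %-10s %-14s %s\n", t$measure[i], t$direction[i],
                  formatExcessValue(t$value[i], t$ci_lower[i], t$ci_upper[i])))
  }
  invisible(NULL)
})
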