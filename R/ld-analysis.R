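# Counting independent telomere-length-associated variants from
# per-chromosome R-squared matrices. Pairs with R^2 below the cutoff are
# treated as uncorrelated. The counting rule does not disambiguate
# transitive cases (A~B, B~C, A!~C), so two rules are implemented and
# reported side by side: connected components (order-invariant) and a
# greedy sentinel sweep in table order (order-dependent, documented).

#' @importFrom igraph graph_from_adjacency_matrix components
NULL

#' Threshold an LD matrix into an adjacency matrix
#'
#' Undirected edge (i, j) iff \code{r2[i, j] >= r2_cutoff}; no self-edges.
#' Missing R-squared values yield no edge under
#' \code{missing_policy = "no_edge"} (an unmeasurable correlation cannot
#' justify merging) or an error under \code{"error"}.
#'
#' @param ldmat an [LDMatrix-class].
#' @param r2_cutoff correlation threshold in [0, 1]; pairs below it are
#'   treated as uncorrelated. Default 0.5.
#' @param missing_policy \code{"no_edge"} (default) or \code{"error"}.
#' @return logical adjacency matrix with rsid dimnames.
#' @export
buildLdGraph <- function(ldmat, r2_cutoff = 0.5,
                         missing_policy = c("no_edge", "error")) {
  missing_policy <- match.arg(missing_policy)
  stopifnot(is(ldmat, "LDMatrix"))
  if (is.na(r2_cutoff) || r2_cutoff < 0 || r2_cutoff > 1)
    stop("r2_cutoff must lie in [0, 1]", call. = FALSE)
  r2 <- ldValues(ldmat)
  off_na <- is.na(r2) & !diag(nrow(r2))
  if (missing_policy == "error" && any(off_na))
    stop("missing R-squared values on chromosome ", ldChromosome(ldmat),
         call. = FALSE)
  adj <- !is.na(r2) & r2 >= r2_cutoff
  diag(adj) <- FALSE
  adj
}

.clusterOne <- function(ldmat, r2_cutoff, method, missing_policy) {
  adj <- buildLdGraph(ldmat, r2_cutoff, missing_policy)
  ids <- ldRsids(ldmat)
  if (method == "connected_components") {
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    membership <- igraph::components(g)$membership
    # renumber by first appearance so labels are order-stable
    membership <- match(membership, unique(membership))
  } else {
    # greedy sentinel sweep in table order: each unclaimed SNP becomes a
    # sentinel and claims all still-unclaimed SNPs correlated with it
    membership <- rep(NA_integer_, length(ids))
    k <- 0L
    for (i in seq_along(ids)) {
      if (!is.na(membership[i])) next
      k <- k + 1L
      membership[i] <- k
      claim <- which(is.na(membership) & adj[i, ])
      membership[claim] <- k
    }
  }
  split(ids, membership)
}

#' Cluster SNPs into independent variants across chromosomes
#'
#' Applies the thresholded clustering rule per chromosome and numbers the
#' clusters sequentially across matrices. The number of independent variants
#' is the number of clusters. \code{connected_components} merges transitively
#' and is invariant to input order; \code{greedy_sentinel} sweeps SNPs in
#' table order and can split transitive chains (its order dependence is
#' intrinsic to the rule).
#'
#' @param matrices an [LDMatrix-class] or a list of them (one per
#'   chromosome); rsids must be unique across matrices. Chromosomes with a
#'   single listed SNP enter as 1 x 1 matrices.
#' @param r2_cutoff,missing_policy see [buildLdGraph()].
#' @param method \code{"connected_components"} (default) or
#'   \code{"greedy_sentinel"}.
#' @param snps optional SNP table (see [readSnpTable()]) used to pick each
#'   cluster's sentinel as the member with the lowest chromosomal position;
#'   without it the first member in matrix order is the sentinel.
#' @return data.frame with one row per cluster: \code{cluster_id,
#'   chromosome, sentinel, n_members} and a list column \code{members}.
#' @examples
#' m <- LDMatrix(rbind(c(1, .951), c(.951, 1)), c("rs11125529",
#'   "rs11890390"), chromosome = "2")
#' clusterVariants(m)$n_members  # 2: one cluster
#' @export
clusterVariants <- function(matrices, r2_cutoff = 0.5,
                            method = c("connected_components",
                                       "greedy_sentinel"),
                            missing_policy = c("no_edge", "error"),
                            snps = NULL) {
  method <- match.arg(method)
  missing_policy <- match.arg(missing_policy)
  if (is(matrices, "LDMatrix")) matrices <- list(matrices)
  all_ids <- unlist(lapply(matrices, ldRsids))
  dup <- unique(all_ids[duplicated(all_ids)])
  if (length(dup))
    stop("rsid(s) appear in more than one matrix: ",
         paste(dup, collapse = ", "), call. = FALSE)
  pos <- NULL
  if (!is.null(snps)) pos <- stats::setNames(snps$position, snps$rsid)

  out <- list(); k <- 0L
  for (m in matrices) {
    cl <- .clusterOne(m, r2_cutoff, method, missing_policy)
    for (members in cl) {
      k <- k + 1L
      sentinel <- if (!is.null(pos) && all(members %in% names(pos))) {
        members[order(pos[members], members)][1]
      } else members[1]
      out[[k]] <- data.frame(cluster_id = k, chromosome = ldChromosome(m),
                             sentinel = sentinel,
                             n_members = length(members),
                             stringsAsFactors = FALSE)
      out[[k]]$members <- list(members)
    }
  }
  do.call(rbind, out)
}

#' Count independent variants under both clustering rules
#'
#' @inheritParams clusterVariants
#' @return named integer vector with elements \code{connected_components}
#'   and \code{greedy_sentinel}.
#' @export
countIndependentVariants <- function(matrices, r2_cutoff = 0.5,
                                     missing_policy = "no_edge",
                                     snps = NULL) {
  c(connected_components = nrow(clusterVariants(
      matrices, r2_cutoff, "connected_components", missing_policy, snps)),
    greedy_sentinel = nrow(clusterVariants(
      matrices, r2_cutoff, "greedy_sentinel", missing_policy, snps)))
}

#' Summarize a SNP panel against its variant clusters
#'
#' @param snps SNP table (see [readSnpTable()]).
#' @param clusters cluster data.frame from [clusterVariants()].
#' @return list with \code{n_snps}, \code{n_chromosomes}, \code{n_clusters},
#'   \code{n_telomere_maintenance} (SNPs flagged as lying in known telomere
#'   maintenance genes), and \code{sentinels} (per-cluster annotation
#'   data.frame).
#' @export
summarizeSnpPanel <- function(snps, clusters) {
  snps <- .validateSnps(snps)
  members <- unlist(clusters$members)
  orphan <- setdiff(members, snps$rsid)
  if (length(orphan))
    stop("cluster member(s) absent from the SNP table: ",
         paste(orphan, collapse = ", "), call. = FALSE)
  sent <- merge(
    clusters[, c("cluster_id", "chromosome", "sentinel", "n_members")],
    snps[, c("rsid", "position", "telomere_maintenance")],
    by.x = "sentinel", by.y = "rsid", all.x = TRUE, sort = FALSE)
  sent <- sent[order(sent$cluster_id), ]
  rownames(sent) <- NULL
  list(
    n_snps = nrow(snps),
    n_chromosomes = length(unique(snps$chromosome)),
    n_clusters = nrow(clusters),
    n_telomere_maintenance = sum(snps$telomere_maintenance == "yes"),
    sentinels = sent)
}
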